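#' Blocked, binned distribution of pairwise differences in spike timing
#'
#' Within each analysis block, every cross pair of spikes between the two
#' trains contributes one difference `DST = t_B - t_A` (downstream minus
#' upstream by convention, so causal transmission shows up at positive
#' lags); differences within the window are binned at `bin` ms resolution
#' and the per-block histogram is normalized to sum to one. Blocks with no
#' in-window pairs are flagged with `n_dsts = 0`.
#'
#' @param train_A Upstream spike times (ms), sorted ascending.
#' @param train_B Downstream spike times (ms), sorted ascending.
#' @param block Block length (s).
#' @param bin Bin width (ms).
#' @param window Half-width of the lag window (ms); lags with
#'   `|DST| <= window` are kept.
#' @param t_range Optional numeric(2) overall time range (ms) defining
#'   block boundaries; defaults to the span of the data.
#' @return A list of class `dst_distribution_set`: `bin_mid` (bin centers,
#'   ms) and `blocks`, a list with `block_start` (s), `prob`, `counts`,
#'   `n_dsts` per block.
#' @export
dst_distribution <- function(train_A, train_B, block = 10, bin = 1,
                             window = 50, t_range = NULL) {
  if (is.unsorted(train_A) || is.unsorted(train_B)) {
    stop("spike trains must be sorted ascending")
  }
  block_ms <- block * 1000
  if (is.null(t_range)) {
    if (length(train_A) == 0 && length(train_B) == 0) {
      t_range <- c(0, block_ms)
    } else {
      t_range <- c(min(train_A, train_B), max(train_A, train_B))
    }
  }
  # bins centered on multiples of `bin` so grid-aligned lags (the simulation
  # emits integer-ms spike times) fall on bin centers
  edges <- seq(-window - bin / 2, window + bin / 2, by = bin)
  bin_mid <- utils::head(edges, -1) + bin / 2
  starts <- seq(t_range[1], t_range[2], by = block_ms)
  if (utils::tail(starts, 1) >= t_range[2]) starts <- utils::head(starts, -1)
  if (length(starts) == 0) starts <- t_range[1]
  blocks <- lapply(starts, function(s0) {
    a <- train_A[train_A >= s0 & train_A < s0 + block_ms]
    b <- train_B[train_B >= s0 & train_B < s0 + block_ms]
    counts <- dst_counts(a, b, edges, window)
    n <- sum(counts)
    list(block_start = s0 / 1000,
         prob = if (n > 0) counts / n else counts * 0,
         counts = counts, n_dsts = n)
  })
  structure(list(bin_mid = bin_mid, bin = bin, window = window,
                 block = block, blocks = blocks),
            class = "dst_distribution_set")
}

# All-pairs in-window lag histogram; uses a sliding index over the sorted
# downstream train so cost is O(pairs in window), not O(nA * nB).
dst_counts <- function(a, b, edges, window) {
  counts <- numeric(length(edges) - 1)
  if (length(a) == 0 || length(b) == 0) return(counts)
  lo <- 1
  nb <- length(b)
  for (ta in a) {
    while (lo <= nb && b[lo] < ta - window) lo <- lo + 1
    hi <- lo
    while (hi <= nb && b[hi] <= ta + window) hi <- hi + 1
    if (hi > lo) {
      d <- b[lo:(hi - 1)] - ta
      idx <- findInterval(d, edges, rightmost.closed = TRUE)
      ok <- idx >= 1 & idx <= length(counts)
      tab <- tabulate(idx[ok], nbins = length(counts))
      counts <- counts + tab
    }
  }
  counts
}

#' Pool a DST distribution set across blocks (and trials)
#'
#' Sums raw pair counts over all blocks of one or more distribution sets
#' and renormalizes, optionally stopping once approximately `target_n`
#' differences have been accumulated (used to equate DST counts across
#' conditions with different firing rates).
#'
#' @param ... One or more `dst_distribution_set` objects (or a list of
#'   them).
#' @param target_n Optional approximate number of DSTs to accumulate.
#' @return A list with `bin_mid`, `prob`, `counts`, `n_dsts`.
#' @export
dst_pool <- function(..., target_n = Inf) {
  sets <- list(...)
  if (length(sets) == 1 && !inherits(sets[[1]], "dst_distribution_set")) {
    sets <- sets[[1]]
  }
  bin_mid <- sets[[1]]$bin_mid
  counts <- numeric(length(bin_mid))
  n <- 0
  for (s in sets) {
    for (b in s$blocks) {
      counts <- counts + b$counts
      n <- n + b$n_dsts
      if (n >= target_n) break
    }
    if (n >= target_n) break
  }
  list(bin_mid = bin_mid, prob = if (n > 0) counts / n else counts,
       counts = counts, n_dsts = n)
}

#' Mode of a pooled DST distribution
#'
#' @param pooled Result of [dst_pool()].
#' @return Bin center (ms) with maximal probability.
#' @export
dst_mode <- function(pooled) {
  pooled$bin_mid[which.max(pooled$prob)]
}

#' Per-neuron firing-rate time series from a spike log
#'
#' @param spikes Data.frame with `time_ms` and `neuron_id`.
#' @param bin Bin length (s).
#' @param t_range Numeric(2) time range (s) covered by the log; defaults to
#'   `c(0, max spike time)` rounded up to a whole bin.
#' @param neurons Neuron ids to include (defaults to those present).
#' @return Data.frame `time_s` (bin end), `neuron_id`, `rate_hz`.
#' @export
firing_rate_series <- function(spikes, bin = 20, t_range = NULL,
                               neurons = NULL) {
  if (is.null(neurons)) neurons <- sort(unique(spikes$neuron_id))
  if (is.null(t_range)) {
    top <- if (nrow(spikes) > 0) max(spikes$time_ms) / 1000 else bin
    t_range <- c(0, ceiling(top / bin) * bin)
  }
  edges <- seq(t_range[1], t_range[2], by = bin)
  if (length(edges) < 2) edges <- c(t_range[1], t_range[1] + bin)
  mids <- edges[-1]
  out <- lapply(neurons, function(id) {
    tt <- spikes$time_ms[spikes$neuron_id == id] / 1000
    cnt <- tabulate(findInterval(tt, edges, left.open = TRUE,
                                 rightmost.closed = FALSE),
                    nbins = length(mids))
    data.frame(time_s = mids, neuron_id = id, rate_hz = cnt / bin)
  })
  do.call(rbind, out)
}

#' Group means of sampled weights over time
#'
#' @param weights Data.frame with `time_s`, `group`, `weight_pS` (as
#'   produced by [run_phase()]).
#' @param groups Character vector of group labels (a network synapse label
#'   such as `"I1_1->O"` or a background group `"bg:O"`).
#' @return Data.frame `time_s`, `group`, `mean_w`.
#' @export
mean_weight_series <- function(weights, groups) {
  missing <- setdiff(groups, unique(weights$group))
  if (length(missing) > 0) {
    stop("unknown weight group(s): ", paste(missing, collapse = ", "))
  }
  sub <- weights[weights$group %in% groups, ]
  agg <- stats::aggregate(weight_pS ~ time_s + group, data = sub, FUN = mean)
  names(agg)[names(agg) == "weight_pS"] <- "mean_w"
  agg[order(agg$group, agg$time_s), ]
}

#' Pearson correlation of two binned spike trains
#'
#' Bins both trains into binary indicator sequences at `bin` ms and returns
#' their Pearson correlation coefficient. A train with zero variance over
#' the span yields `NaN` with a warning.
#'
#' @param train_A,train_B Spike times (ms).
#' @param bin Bin width (ms).
#' @param span Numeric(2) analysis range (ms) covering both trains.
#' @return Pearson correlation coefficient.
#' @export
pairwise_spike_correlation <- function(train_A, train_B, bin = 1, span) {
  edges <- seq(span[1], span[2], by = bin)
  nb <- length(edges) - 1
  xa <- tabulate(findInterval(train_A, edges, left.open = TRUE,
                              rightmost.closed = FALSE), nbins = nb) > 0
  xb <- tabulate(findInterval(train_B, edges, left.open = TRUE,
                              rightmost.closed = FALSE), nbins = nb) > 0
  if (stats::var(xa) == 0 || stats::var(xb) == 0) {
    warning("zero-variance spike train; correlation undefined")
    return(NaN)
  }
  stats::cor(xa, xb)
}

#' Mean pairwise spike-train correlation among a set of neurons
#'
#' @param spikes Spike log data.frame (`time_ms`, `neuron_id`).
#' @param neurons Neuron ids.
#' @param bin Bin width (ms).
#' @param span Numeric(2) analysis range (ms).
#' @return Mean Pearson coefficient over all unordered pairs (pairs with an
#'   undefined coefficient are dropped).
#' @export
mean_network_correlation <- function(spikes, neurons, bin = 1, span) {
  trains <- lapply(neurons, function(id) {
    spikes$time_ms[spikes$neuron_id == id]
  })
  vals <- c()
  for (i in seq_along(trains)) {
    for (j in seq_len(i - 1)) {
      v <- suppressWarnings(
        pairwise_spike_correlation(trains[[i]], trains[[j]], bin, span))
      if (is.finite(v)) vals <- c(vals, v)
    }
  }
  mean(vals)
}

#' Earliest time a mean-weight series satisfies the steady-state criterion
#'
#' Scans window start times and returns the earliest `t` such that the
#' least-squares slope of the series over `[t, t + window]` satisfies
#' `|slope| * window <= tolerance`; `NA` if never satisfied.
#'
#' @param series Data.frame with `time_s` and `mean_w`.
#' @param criterion A [steady_state_criterion()].
#' @return Window start time (s) or `NA`.
#' @export
steady_state_time <- function(series, criterion) {
  t <- series$time_s
  w <- series$mean_w
  if (length(t) < 2 || max(t) - min(t) < criterion$window) return(NA_real_)
  for (k in seq_along(t)) {
    in_win <- t >= t[k] & t <= t[k] + criterion$window
    if (max(t) < t[k] + criterion$window) break
    if (sum(in_win) < 2) next
    slope <- stats::cov(t[in_win], w[in_win]) / stats::var(t[in_win])
    if (abs(slope) * criterion$window <= criterion$tolerance) return(t[k])
  }
  NA_real_
}
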