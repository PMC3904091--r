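# DST distributions, rate/weight series, correlation, steady-state search.

test_that("dst_distribution matches brute-force enumeration on hand-built trains", {
  # single cross pair at +20 ms
  d <- dst_distribution(100, 120, block = 10, bin = 1, window = 50,
                        t_range = c(0, 10000))
  p <- dst_pool(d)
  expect_equal(p$n_dsts, 1)
  expect_equal(p$prob[p$bin_mid == 20], 1)
  expect_equal(dst_mode(p), 20)

  # small trains: compare against outer() enumeration
  a <- c(50, 300, 310, 2100)
  b <- c(40, 290, 360, 2130, 9000)
  d2 <- dst_pool(dst_distribution(a, b, block = 10, bin = 1, window = 50,
                                  t_range = c(0, 10000)))
  lags <- as.vector(outer(b, a, "-"))
  lags <- lags[abs(lags) <= 50]
  for (k in unique(lags)) {
    expect_equal(d2$counts[d2$bin_mid == k], sum(lags == k))
  }
  expect_equal(d2$n_dsts, length(lags))
  expect_error(dst_distribution(c(3, 1), c(1, 2)), "sorted")
})

test_that("identical trains put maximal DST mass at zero lag", {
  a <- sort(runif(200, 0, 9999))
  p <- dst_pool(dst_distribution(a, a, t_range = c(0, 10000)))
  expect_equal(dst_mode(p), 0)
})

test_that("DST distributions are antisymmetric and normalized per block", {
  set.seed(31)
  a <- sort(runif(300, 0, 30000))
  b <- sort(runif(250, 0, 30000))
  ab <- dst_distribution(a, b, t_range = c(0, 30000))
  ba <- dst_distribution(b, a, t_range = c(0, 30000))
  for (k in seq_along(ab$blocks)) {
    expect_equal(ab$blocks[[k]]$counts, rev(ba$blocks[[k]]$counts))
    if (ab$blocks[[k]]$n_dsts > 0) {
      expect_equal(sum(ab$blocks[[k]]$prob), 1)
    } else {
      expect_equal(sum(ab$blocks[[k]]$prob), 0)
    }
  }
})

test_that("independent Poisson trains yield a flat DST distribution", {
  set.seed(8)
  dur <- 4e5
  a <- sort(runif(0.004 * dur, 0, dur))
  b <- sort(runif(0.004 * dur, 0, dur))
  p <- dst_pool(dst_distribution(a, b, block = dur / 1000, t_range = c(0, dur)))
  # chi-square uniformity over the 101 bins
  expect_gt(chisq.test(p$counts)$p.value, 0.001)
})

test_that("firing_rate_series counts spikes per bin and conserves totals", {
  sp <- data.frame(time_ms = numeric(), neuron_id = integer())
  empty <- firing_rate_series(sp, bin = 20, t_range = c(0, 100), neurons = 1)
  expect_true(all(empty$rate_hz == 0))

  sp <- data.frame(time_ms = sort(runif(16, 0, 20000)), neuron_id = 1L)
  r <- firing_rate_series(sp, bin = 20, t_range = c(0, 20))
  expect_equal(r$rate_hz, 0.8)
  sp2 <- data.frame(time_ms = sort(runif(137, 0, 95000)), neuron_id = 2L)
  r2 <- firing_rate_series(sp2, bin = 20, t_range = c(0, 100))
  expect_equal(sum(r2$rate_hz * 20), 137)
})

test_that("mean_weight_series averages groups and rejects unknown groups", {
  w <- data.frame(time_s = rep(c(400, 800), each = 3),
                  group = rep(c("a", "a", "b"), 2),
                  weight_pS = c(1000, 3000, 500, 2000, 4000, 500))
  m <- mean_weight_series(w, c("a", "b"))
  expect_equal(m$mean_w[m$group == "a"], c(2000, 3000))
  expect_equal(m$mean_w[m$group == "b"], c(500, 500))
  expect_true(all(m$mean_w >= 500 & m$mean_w <= 4000))
  expect_error(mean_weight_series(w, "nope"), "unknown")
})

test_that("pairwise spike correlation behaves at its analytic anchors", {
  a <- c(10, 500, 900, 2200)
  expect_equal(pairwise_spike_correlation(a, a, span = c(0, 5000)), 1)
  # disjoint single-spike trains: closed-form Pearson of two indicators
  n <- 1000
  got <- pairwise_spike_correlation(10, 600, span = c(0, n))
  expect_equal(got, -1 / (n - 1), tolerance = 1e-12)
  # independent Poisson: zero within ~4 standard errors (se = 1/sqrt(nbins))
  set.seed(12)
  span <- c(0, 4e5)
  x <- sort(runif(1600, span[1], span[2]))
  y <- sort(runif(1600, span[1], span[2]))
  expect_lt(abs(pairwise_spike_correlation(x, y, span = span)),
            4 / sqrt(diff(span)))
  expect_warning(v <- pairwise_spike_correlation(numeric(), a, span = c(0, 5000)),
                 "zero-variance")
  expect_true(is.nan(v))
})

test_that("steady_state_time finds the knee of a ramp-then-flat series", {
  crit <- steady_state_criterion(window = 5000, tolerance = 30)
  tt <- seq(0, 20000, by = 400)
  flat <- data.frame(time_s = tt, mean_w = rep(1700, length(tt)))
  expect_equal(steady_state_time(flat, crit), 0)
  ramp <- data.frame(time_s = tt, mean_w = 3000 - 0.1 * tt)
  expect_true(is.na(steady_state_time(ramp, crit)))
  knee <- data.frame(time_s = tt,
                     mean_w = ifelse(tt < 8000, 3000 + 0.15 * (8000 - tt), 3000))
  got <- steady_state_time(knee, crit)
  # exhaustive oracle scan at the sample resolution
  oracle <- NA_real_
  for (t0 in tt) {
    sel <- tt >= t0 & tt <= t0 + crit$window
    if (max(tt) < t0 + crit$window) break
    sl <- cov(tt[sel], knee$mean_w[sel]) / var(tt[sel])
    if (abs(sl) * crit$window <= crit$tolerance) { oracle <- t0; break }
  }
  expect_equal(got, oracle)
  expect_gte(got, 7600)  # at the knee within one sample period of 8000
  expect_lte(got, 8000)
})
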