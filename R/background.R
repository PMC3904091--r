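#' Solve the two-point mixture for correlated background trains
#'
#' The correlated background ensemble is realized as a global two-point
#' mixture: each time step is independently "hot" with probability
#' `q = 1/2`, and every train then spikes independently with probability
#' `p1` (hot) or `p0` (cold), where
#' `p1 = p_bar + sqrt(c * p_bar * (1 - p_bar))` and
#' `p0 = p_bar - sqrt(c * p_bar * (1 - p_bar))`. This preserves the
#' per-train marginal `p_bar` exactly and gives any two trains a within-step
#' Pearson correlation of exactly `c`, with zero correlation across steps.
#'
#' @param p_bar Per-step spike probability (`rate * dt`).
#' @param c Target within-step pairwise correlation, `0 <= c < 1`.
#' @return A list of class `mixture_scheme` with `q`, `p1`, `p0`.
#' @export
solve_mixture <- function(p_bar, c) {
  stopifnot(p_bar > 0, p_bar < 1, c >= 0, c < 1)
  s <- sqrt(c * p_bar * (1 - p_bar))
  p1 <- p_bar + s
  p0 <- p_bar - s
  if (p0 < 0) {
    stop("infeasible mixture: correlation ", c,
         " too large for per-step probability ", p_bar)
  }
  if (p1 >= 1) stop("infeasible mixture: p1 >= 1")
  structure(list(q = 0.5, p1 = p1, p0 = p0), class = "mixture_scheme")
}

#' Sample one step of a correlated background ensemble
#'
#' One global hot/cold draw is shared by all trains; conditional on it the
#' trains spike independently. Memoryless across steps.
#'
#' @param n Number of trains.
#' @param scheme A [solve_mixture()] scheme.
#' @return Integer 0/1 vector of length `n`.
#' @export
sample_background_step <- function(n, scheme) {
  p <- if (stats::runif(1) < scheme$q) scheme$p1 else scheme$p0
  as.integer(stats::runif(n) < p)
}

#' Monte-Carlo summary statistics of the background generator
#'
#' Simulates the ensemble with the compiled generator and returns the
#' empirical per-train rate, within-step pairwise correlation (estimated
#' from the variance of the per-step ensemble total of `n` exchangeable
#' trains), and the lag-1 autocorrelation of a tracked train.
#'
#' @param n Number of trains.
#' @param rate Train rate (spikes/s).
#' @param c_back Target within-step correlation.
#' @param n_steps Number of simulated steps.
#' @param dt Step size (ms).
#' @param seed Integer seed.
#' @return A list with `rate_hat`, `corr_hat`, `corr_se`, `lag1_hat`,
#'   `pair_rate_hat`.
#' @export
background_generator_stats <- function(n, rate, c_back, n_steps,
                                       dt = 1, seed = 1L) {
  p_bar <- rate * dt / 1000
  mm <- .mixture_moments(as.integer(n), p_bar, c_back, 0.5,
                         as.double(n_steps), as.double(seed))
  t_steps <- mm$n_steps
  mean_s <- mm$sum / t_steps
  var_s <- mm$sumsq / t_steps - mean_s^2
  pq <- p_bar * (1 - p_bar)
  corr_hat <- (var_s - n * pq) / (n * (n - 1) * pq)
  # sampling error of the variance-based estimator from the empirical
  # fourth central moment (the per-step totals are strongly leptokurtic at
  # rare-event rates, so the Gaussian 2*sigma^4/T formula underestimates)
  m2 <- var_s
  m4 <- mm$sumqu / t_steps - 4 * mean_s * (mm$sumcu / t_steps) +
    6 * mean_s^2 * (mm$sumsq / t_steps) - 3 * mean_s^4
  corr_se <- sqrt(pmax(m4 - m2^2, 0) / t_steps) / (n * (n - 1) * pq)
  list(rate_hat = mm$trainA / t_steps / dt * 1000,
       rate_hat_B = mm$trainB / t_steps / dt * 1000,
       corr_hat = corr_hat, corr_se = corr_se,
       pair_rate_hat = mm$coinc / t_steps,
       lag1_hat = {
         pa <- mm$trainA / t_steps
         (mm$lag1 / t_steps - pa^2) / (pa * (1 - pa))
       })
}

#' Equilibrate background weights with a single-neuron pre-simulation
#'
#' Runs one neuron receiving `params$n_trains` plastic background synapses
#' until the mean weight trajectory satisfies the steady-state criterion
#' (no discernible trend over the criterion window), then returns the final
#' weight vector. This is the standard preamble to building a network: the
#' equilibrated vector seeds every neuron's background ensemble.
#'
#' @param params A [background_params()].
#' @param stdp An [stdp_params()].
#' @param membrane A [membrane_params()].
#' @param kinetics A [synapse_kinetics()].
#' @param sim A [sim_params()].
#' @param stability A [steady_state_criterion()].
#' @param init Initial weight for every synapse (pS); mid-range by default.
#' @param max_duration Abort (with the trajectory attached) if the
#'   criterion is not met within this many seconds.
#' @param seed Integer seed.
#' @return A list with `weights` (length `n_trains`), `trajectory`
#'   (data.frame time_s, mean_w), `steady_at_s`, and `rate_hz` (output rate
#'   over the last criterion window).
#' @export
equilibrate_background_weights <- function(params, stdp = stdp_params(),
                                           membrane = membrane_params(),
                                           kinetics = synapse_kinetics(),
                                           sim = sim_params(),
                                           stability = steady_state_criterion(),
                                           init = stdp$g_max / 2,
                                           max_duration = 60000,
                                           seed = 1L) {
  net <- single_neuron_harness(params, stdp, membrane, kinetics, sim,
                               init = init)
  chunk_s <- stability$window
  traj_t <- numeric()
  traj_w <- numeric()
  rates <- numeric()
  elapsed <- 0
  chunk_i <- 0
  steady_at <- NA_real_
  while (elapsed < max_duration) {
    chunk_i <- chunk_i + 1
    ph <- run_phase(net, chunk_s, seed = derive_seed(seed, "equil-bg", chunk_i),
                    record_spikes = FALSE, w_every_s = 400, r_every_s = chunk_s)
    net <- ph$net
    traj_t <- c(traj_t, ph$fragment$weights$time_s[ph$fragment$weights$group == "bg:N"])
    traj_w <- c(traj_w, ph$fragment$weights$weight_pS[ph$fragment$weights$group == "bg:N"])
    rates <- c(rates, ph$fragment$rates$rate_hz)
    elapsed <- elapsed + chunk_s
    # require the latest full window to be trend-free (not just any earlier
    # window) so transient early flatness cannot end equilibration
    in_win <- traj_t > elapsed - stability$window
    if (sum(in_win) >= 2) {
      slope <- stats::cov(traj_t[in_win], traj_w[in_win]) /
        stats::var(traj_t[in_win])
      if (abs(slope) * stability$window <= stability$tolerance) {
        steady_at <- elapsed - stability$window
        break
      }
    }
  }
  if (is.na(steady_at)) {
    cond <- simpleError(paste0("background weights did not reach steady state ",
                               "within ", max_duration, " s"))
    cond$trajectory <- data.frame(time_s = traj_t, mean_w = traj_w)
    stop(cond)
  }
  list(weights = net$state$bg_w,
       trajectory = data.frame(time_s = traj_t, mean_w = traj_w),
       steady_at_s = steady_at,
       rate_hz = mean(utils::tail(rates, 1)))
}

# A 1-neuron "network" sharing the engine plumbing.
single_neuron_harness <- function(params, stdp, membrane, kinetics, sim,
                                  init) {
  state <- new_engine_state(list(rep(init, params$n_trains)),
                            params$rate, NULL, membrane)
  structure(list(
    roles = c(N = 1L),
    syn_labels = character(),
    params = list(membrane = membrane, kinetics = kinetics, sim = sim,
                  stdp = stdp, background = params),
    state = state), class = "adfp_network")
}

#' Calibrate the current gain against the single-neuron operating point
#'
#' Finds the drive gain at which a lone neuron with `n_trains` equilibrated
#' plastic background inputs at the reference rate settles at
#' `target_rate` spikes/s output, by bisection on log-gain with a fresh
#' equilibration per evaluation. This fixes the unit conversion of the
#' literal `I = w * g` drive once; the result is frozen as
#' [default_current_gain].
#'
#' @param target_rate Desired equilibrated output rate (spikes/s).
#' @param params A [background_params()].
#' @param bounds Search interval for the gain.
#' @param tol_rate Acceptable rate error (spikes/s).
#' @param equil_s Equilibration duration per evaluation (s).
#' @param measure_s Rate measurement window per evaluation (s).
#' @param seed Integer seed.
#' @param ... Passed to the parameter constructors.
#' @return A list with `gain`, `rate_hz`, and the evaluation `history`.
#' @export
calibrate_gain <- function(target_rate = 4, params = background_params(),
                           bounds = c(2000, 60000), tol_rate = 0.1,
                           equil_s = 20000, measure_s = 5000, seed = 1L, ...) {
  eval_rate <- function(gain) {
    kin <- synapse_kinetics(current_gain = gain, ...)
    net <- single_neuron_harness(params, stdp_params(), membrane_params(),
                                 kin, sim_params(), init = stdp_params()$g_max / 2)
    ph <- run_phase(net, equil_s, seed = derive_seed(seed, "cal-eq"),
                    record_spikes = FALSE, r_every_s = equil_s)
    ph2 <- run_phase(ph$net, measure_s, seed = derive_seed(seed, "cal-ms"),
                     record_spikes = FALSE, r_every_s = measure_s)
    ph2$fragment$rates$rate_hz[1]
  }
  lo <- bounds[1]; hi <- bounds[2]
  hist <- data.frame(gain = numeric(), rate_hz = numeric())
  r_lo <- eval_rate(lo); hist <- rbind(hist, data.frame(gain = lo, rate_hz = r_lo))
  r_hi <- eval_rate(hi); hist <- rbind(hist, data.frame(gain = hi, rate_hz = r_hi))
  if (r_lo > target_rate || r_hi < target_rate) {
    stop("calibration target rate not bracketed by gain bounds")
  }
  for (it in 1:18) {
    mid <- sqrt(lo * hi)
    r_mid <- eval_rate(mid)
    hist <- rbind(hist, data.frame(gain = mid, rate_hz = r_mid))
    if (abs(r_mid - target_rate) <= tol_rate) {
      return(list(gain = mid, rate_hz = r_mid, history = hist))
    }
    if (r_mid < target_rate) lo <- mid else hi <- mid
  }
  mid <- sqrt(lo * hi)
  list(gain = mid, rate_hz = eval_rate(mid), history = hist)
}
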