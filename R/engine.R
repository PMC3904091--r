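# R-side wrapper around the compiled stepper: state construction, phase
# execution, interventions.

engine_params <- function(membrane, kinetics, sim, stdp, c_back = 0,
                          sts = NULL, margin = 1.05) {
  p <- list(
    dt = sim$dt_step,
    C_memb = membrane$C_memb, R_memb = membrane$R_memb,
    E_rest = membrane$E_rest, V_thr = membrane$V_thr,
    tau_refrac = membrane$tau_refrac, t_delay_syn = membrane$t_delay_syn,
    tau_rise = kinetics$tau_rise, g_norm = kinetics$g_norm,
    current_gain = kinetics$current_gain,
    drive_mode = if (kinetics$drive_mode == "conductance") 1L else 0L,
    E_ex = kinetics$E_ex,
    A_p = stdp$A_p, tau_p = stdp$tau_p, A_d = stdp$A_d, tau_d = stdp$tau_d,
    g_max = stdp$g_max,
    c_back = c_back, q_hot = 0.5,
    sts_on = 0L, sts_source = 1L, sts_target = 1L, sts_delay_ms = 20,
    stim_impulse = 0)
  if (!is.null(sts)) {
    p$sts_on <- 1L
    p$sts_source <- as.integer(sts$source)
    p$sts_target <- as.integer(sts$target)
    p$sts_delay_ms <- sts$t_delay
    p$stim_impulse <- stim_impulse(membrane, kinetics, sim,
                                   margin = sts$margin %||% margin)
  }
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_engine_state <- function(bg_weights, bg_rate_hz, synapses, membrane) {
  # bg_weights: list of numeric vectors, one per neuron
  n <- length(bg_weights)
  stopifnot(length(bg_rate_hz) == n)
  lens <- vapply(bg_weights, length, integer(1))
  syn <- synapses %||% data.frame(pre = integer(), post = integer(),
                                  w = numeric(), plastic = logical())
  list(
    t_ms = 0,
    V = rep(membrane$E_rest, n),
    refrac = rep(0, n),
    last_emit = rep(NA_real_, n),
    A = rep(0, n), B = rep(0, n),
    A_stim = rep(0, n), B_stim = rep(0, n),
    bg_ptr = as.integer(c(0, cumsum(lens))),
    bg_w = as.numeric(unlist(bg_weights, use.names = FALSE)),
    bg_last_arr = rep(NA_real_, sum(lens)),
    bg_rate_hz = as.numeric(bg_rate_hz),
    bg_plastic = 1L,
    syn_pre = as.integer(syn$pre), syn_post = as.integer(syn$post),
    syn_w = as.numeric(syn$w),
    syn_last_arr = rep(NA_real_, nrow(syn)),
    syn_plastic = as.integer(syn$plastic),
    pend_syn_t = numeric(), pend_syn_id = integer(),
    pend_stim_t = numeric())
}

#' Run one simulation phase
#'
#' Advances a network by `duration_s` seconds of simulated time, mutating
#' its weights, membrane and kinetic state in place (phases chain), and
#' returns the recordings made during the phase. Interventions active
#' during the phase are passed via `sts`; a background rate step is applied
#' beforehand with [apply_rate_step()].
#'
#' @param net An [build_adfp()] network (or 1-neuron harness).
#' @param duration_s Simulated duration (s).
#' @param seed Integer seed for this phase's stochastic input streams.
#' @param sts Optional [sts_params()] with `source`/`target` resolved or as
#'   role names.
#' @param record_spikes Record individual spike times?
#' @param w_every_s Weight sampling cadence (s); 0 disables.
#' @param r_every_s Rate sampling cadence (s); 0 disables.
#' @return A list with the updated `net` and a `fragment` containing
#'   `spikes` (data.frame time_ms, neuron_id), `weights` (data.frame
#'   time_s, group, weight_pS), `rates` (data.frame time_s, neuron_id,
#'   rate_hz), and the phase `t_range` in seconds.
#' @export
run_phase <- function(net, duration_s, seed, sts = NULL,
                      record_spikes = TRUE, w_every_s = 400, r_every_s = 20) {
  stopifnot(duration_s >= 0)
  if (!is.null(sts)) {
    sts$source <- resolve_role(net, sts$source)
    sts$target <- resolve_role(net, sts$target)
  }
  par <- engine_params(net$params$membrane, net$params$kinetics,
                       net$params$sim, net$params$stdp,
                       c_back = net$params$background$c_back, sts = sts)
  if (is.null(sts)) net$state$pend_stim_t <- numeric()
  n_steps <- round(duration_s * 1000 / net$params$sim$dt_step)
  if (n_steps == 0) {
    return(list(net = net, fragment = empty_fragment(net)))
  }
  start_ms <- net$state$t_ms
  out <- .engine_run(net$state, par, as.integer(n_steps), as.double(seed),
                     record_spikes, w_every_s * 1000, r_every_s * 1000)
  net$state <- out$state
  frag <- fragment_from_engine(net, out, r_every_s, start_ms)
  list(net = net, fragment = frag)
}

empty_fragment <- function(net) {
  list(spikes = data.frame(time_ms = numeric(), neuron_id = integer()),
       weights = data.frame(time_s = numeric(), group = character(),
                            weight_pS = numeric()),
       rates = data.frame(time_s = numeric(), neuron_id = integer(),
                          rate_hz = numeric()),
       t_range = c(net$state$t_ms, net$state$t_ms) / 1000)
}

fragment_from_engine <- function(net, out, r_every_s, start_ms) {
  n <- length(net$state$V)
  groups <- c(paste0("bg:", names(net$roles)), net$syn_labels)
  w <- out$w_samples
  weights <- if (nrow(w) > 0) {
    data.frame(time_s = rep(w[, 1] / 1000, times = ncol(w) - 1),
               group = rep(groups, each = nrow(w)),
               weight_pS = as.vector(w[, -1, drop = FALSE]))
  } else {
    data.frame(time_s = numeric(), group = character(), weight_pS = numeric())
  }
  r <- out$r_counts
  rates <- if (nrow(r) > 0) {
    data.frame(time_s = rep(r[, 1] / 1000, times = n),
               neuron_id = rep(seq_len(n), each = nrow(r)),
               rate_hz = as.vector(r[, -1, drop = FALSE]) / r_every_s)
  } else {
    data.frame(time_s = numeric(), neuron_id = integer(), rate_hz = numeric())
  }
  list(spikes = data.frame(time_ms = out$spike_t, neuron_id = out$spike_id),
       weights = weights, rates = rates,
       t_range = c(start_ms, net$state$t_ms) / 1000)
}

resolve_role <- function(net, who) {
  if (is.character(who)) {
    if (!who %in% names(net$roles)) stop("unknown neuron role: ", who)
    unname(net$roles[who])
  } else {
    as.integer(who)
  }
}

#' Apply a background rate-step intervention
#'
#' Re-parameterizes the background ensemble of the target neuron to
#' `new_rate`, re-solving the correlated mixture so `c_back` is preserved.
#' Reversible: applying the original rate restores the network.
#'
#' @param net A network.
#' @param spec A [rate_step_spec()].
#' @return The updated network.
#' @export
apply_rate_step <- function(net, spec) {
  tgt <- resolve_role(net, spec$target)
  # feasibility under the current correlation
  solve_mixture(spec$new_rate * net$params$sim$dt_step / 1000,
                net$params$background$c_back)
  net$state$bg_rate_hz[tgt] <- spec$new_rate
  net
}

#' Closed-loop stimulation schedule for a sequence of source spikes
#'
#' Pure helper mirroring the engine's STS controller contract: every source
#' spike schedules one stimulation arrival `t_delay` later.
#'
#' @param source_spike_times Spike times of the recorded neuron (ms).
#' @param params An [sts_params()].
#' @return Scheduled stimulation arrival times (ms).
#' @export
sts_controller <- function(source_spike_times, params) {
  source_spike_times + params$t_delay
}

#' Run a full experiment: equilibrate once, fork trials
#'
#' Equilibrates the network, snapshots the common base state, then runs
#' `n_trials` trials from that snapshot with distinct input sub-seeds. Each
#' trial consists of a base phase, a peri-intervention phase (rate step or
#' STS active), and a post phase (intervention withdrawn; a stepped rate is
#' restored to its pre-intervention value).
#'
#' @param config An [experiment_config()].
#' @return A list of class `sts_experiment` with elements `base_net` (the
#'   equilibrated network), `equilibration` (recording fragment), `trials`
#'   (per-trial lists of `base`, `peri`, `post` fragments plus phase
#'   boundaries), and `config`.
#' @export
run_experiment <- function(config) {
  seed <- config$rng_seed
  net <- config$network
  if (is.null(net)) {
    bgw <- equilibrate_background_weights(
      config$spec$background, config$spec$stdp, config$spec$membrane,
      config$spec$kinetics, config$spec$sim,
      seed = derive_seed(seed, "bgweights"))$weights
    net <- build_adfp(config$spec, bgw, seed = derive_seed(seed, "build"))
  }
  eq <- run_phase(net, config$durations$equilibrate, seed = derive_seed(seed, "equil"),
                  record_spikes = FALSE)
  net <- eq$net
  snapshot <- net$state
  old_rate <- NULL
  trials <- vector("list", config$n_trials)
  for (tr in seq_len(config$n_trials)) {
    net$state <- snapshot
    base <- run_phase(net, config$durations$base,
                      seed = derive_seed(seed, "trial-base", tr))
    net <- base$net
    peri_sts <- NULL
    if (!is.null(config$intervention)) {
      if (inherits(config$intervention, "rate_step_spec")) {
        tgt <- resolve_role(net, config$intervention$target)
        old_rate <- net$state$bg_rate_hz[tgt]
        net <- apply_rate_step(net, config$intervention)
      } else if (inherits(config$intervention, "sts_params")) {
        peri_sts <- config$intervention
      }
    }
    peri <- run_phase(net, config$durations$peri,
                      seed = derive_seed(seed, "trial-peri", tr), sts = peri_sts)
    net <- peri$net
    if (!is.null(old_rate)) {
      net <- apply_rate_step(net, rate_step_spec(config$intervention$target,
                                                 old_rate))
      old_rate <- NULL
    }
    post <- run_phase(net, config$durations$post,
                      seed = derive_seed(seed, "trial-post", tr))
    net <- post$net
    trials[[tr]] <- list(base = base$fragment, peri = peri$fragment,
                         post = post$fragment,
                         boundaries_s = cumsum(c(snapshot$t_ms / 1000,
                                                 config$durations$base,
                                                 config$durations$peri,
                                                 config$durations$post)))
  }
  net$state <- snapshot
  structure(list(base_net = net, equilibration = eq$fragment,
                 trials = trials, config = config),
            class = "sts_experiment")
}

#' Experiment configuration
#'
#' @param spec A [network_spec()] (used when `network` is not supplied).
#' @param network Optionally a pre-built, possibly pre-equilibrated network.
#' @param intervention `NULL` (control), a [rate_step_spec()], or an
#'   [sts_params()].
#' @param durations Named list with `equilibrate`, `base`, `peri`, `post`
#'   durations in seconds. Reference protocol: 75,000 / 5,000 / 10,000 /
#'   10,000 s; reduced schedules are standard for desk-scale runs since the
#'   reference networks reach steady state by ~15,000 s.
#' @param n_trials Number of trials forked from the common base state.
#' @param rng_seed Master seed.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(spec = network_spec(), network = NULL,
                              intervention = NULL,
                              durations = list(equilibrate = 75000,
                                               base = 5000, peri = 10000,
                                               post = 10000),
                              n_trials = 10, rng_seed = 1L) {
  stopifnot(all(unlist(durations) >= 0), n_trials >= 1)
  need <- c("equilibrate", "base", "peri", "post")
  if (!all(need %in% names(durations))) {
    stop("durations must name: ", paste(need, collapse = ", "))
  }
  structure(list(spec = spec, network = network, intervention = intervention,
                 durations = durations, n_trials = as.integer(n_trials),
                 rng_seed = as.integer(rng_seed)),
            class = "experiment_config")
}
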