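# Shared fixtures: default parameter sets and a cache of equilibrated base
# networks so that the heavier protocol tests can share one equilibration
# per condition within a suite run.

default_membrane <- membrane_params()
default_kinetics <- synapse_kinetics()
default_stdp <- stdp_params()
default_sim <- sim_params()

.base_cache <- new.env(parent = emptyenv())

# Equilibrated base network for a named condition, computed once per run.
# Conditions: "uncorr" / "corr" single-path, "multi" 16-pathway.
base_network <- function(condition, equilibrate_s = 20000, seed = 1L) {
  key <- paste0(condition, "-", equilibrate_s, "-", seed)
  if (!is.null(.base_cache[[key]])) return(.base_cache[[key]])
  spec <- switch(condition,
    uncorr = network_spec(),
    corr = network_spec(background = background_params(c_back = 10^-3.5)),
    multi = network_spec(n_hidden_paths = 16,
                         n_background_removed_from_O = 64),
    stop("unknown condition ", condition))
  eq <- equilibrate_base_network(spec, equilibrate_s = equilibrate_s,
                                 seed = seed)
  .base_cache[[key]] <- eq
  eq
}

# Mean of a weight group over the trailing `tail_s` seconds of a fragment.
tail_mean_weight <- function(fragment, group, tail_s = 2000) {
  w <- fragment$weights[fragment$weights$group == group, ]
  mean(w$weight_pS[w$time_s > max(w$time_s) - tail_s])
}

mean_weight <- function(fragment, group) {
  mean(fragment$weights$weight_pS[fragment$weights$group == group])
}

# Mean firing rate of a neuron over the trailing `tail_s` seconds.
tail_mean_rate <- function(fragment, neuron, tail_s = 2000) {
  r <- fragment$rates[fragment$rates$neuron_id == neuron, ]
  mean(r$rate_hz[r$time_s > max(r$time_s) - tail_s])
}

# Spike train of one neuron from a fragment.
train_of <- function(fragment, neuron) {
  fragment$spikes$time_ms[fragment$spikes$neuron_id == neuron]
}

# n-trial base/peri runs forked from a shared snapshot; returns per-trial
# fragments. Used by the intervention-level tests.
forked_trials <- function(net, n_trials, base_s, peri_s, sts = NULL,
                          rate_step = NULL, seed = 1L,
                          record_spikes = FALSE) {
  snapshot <- net$state
  lapply(seq_len(n_trials), function(tr) {
    net$state <- snapshot
    b <- run_phase(net, base_s, seed = derive_seed(seed, "tb", tr),
                   record_spikes = record_spikes)
    net <- b$net
    if (!is.null(rate_step)) net <- apply_rate_step(net, rate_step)
    p <- run_phase(net, peri_s, seed = derive_seed(seed, "tp", tr),
                   sts = sts, record_spikes = record_spikes)
    list(base = b$fragment, peri = p$fragment)
  })
}
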