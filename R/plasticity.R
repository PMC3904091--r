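#' Weight-dependent STDP update for a single spike pairing
#'
#' Implements the soft-bounded pair rule
#' \deqn{\Delta w = A_p (g_{max} - w) e^{-|\Delta t|/\tau_p} \quad (\Delta t > 0)}
#' \deqn{\Delta w = -A_d \, w \, e^{-|\Delta t|/\tau_d} \quad (\Delta t < 0)}
#' where `dt_spikes` is the postsynaptic spike time minus the presynaptic
#' spike's arrival time (emission + synaptic delay). Pre-before-post
#' (positive difference) potentiates with an amplitude shrinking as the
#' weight approaches `g_max`; post-before-pre depresses in proportion to
#' the current weight. The rule is undefined at exactly zero difference, in
#' which case no update is applied.
#'
#' @param w Current synaptic weight (pS), in `[0, g_max]`.
#' @param dt_spikes Timing difference `t_post - t_pre_arrival` (ms). May be
#'   a vector.
#' @param params An [stdp_params()].
#' @return Signed weight change (pS), same length as `dt_spikes`.
#' @export
stdp_delta <- function(w, dt_spikes, params) {
  if (any(w < 0) || any(w > params$g_max)) {
    stop("weight outside [0, g_max]")
  }
  ifelse(dt_spikes > 0,
         params$A_p * (params$g_max - w) * exp(-abs(dt_spikes) / params$tau_p),
         ifelse(dt_spikes < 0,
                -params$A_d * w * exp(-abs(dt_spikes) / params$tau_d),
                0))
}

#' Latest-neighbor STDP bookkeeping for one emitted spike
#'
#' Reference implementation of the per-spike update schedule used by the
#' simulation engine, operating on an explicit last-spike table. When
#' neuron `neuron_id` emits a spike at `t_now`:
#' \itemize{
#'   \item every afferent synapse with a recorded latest presynaptic
#'     arrival receives a potentiation-side update with
#'     `dt = t_now - latest_arrival`;
#'   \item every efferent synapse schedules a depression-side update at the
#'     spike's arrival time `t_now + t_delay_syn`, pairing against the
#'     postsynaptic neuron's latest emission at that moment.
#' }
#' Only the most recent spike of each neuron participates in any pairing
#' ("latest-neighbor" / symmetric-interpretation scheme); exact ties
#' (`dt == 0`) produce no update; non-plastic synapses are untouched;
#' weights are clipped to `[0, g_max]`.
#'
#' @param neuron_id Index of the spiking neuron.
#' @param t_now Emission time (ms).
#' @param table Last-spike table as produced by [last_spike_table()].
#' @param synapses A data.frame with columns `pre`, `post`, `w`, `plastic`.
#' @param params An [stdp_params()].
#' @param t_delay_syn Synaptic delay (ms).
#' @return A list with the updated `synapses`, updated `table`, and a
#'   data.frame `applied` of per-synapse weight changes.
#' @export
stdp_on_spike <- function(neuron_id, t_now, table, synapses, params,
                          t_delay_syn = 1) {
  applied <- data.frame(synapse = integer(), dw = numeric())
  # potentiation side: afferents against their latest recorded arrival
  for (s in which(synapses$post == neuron_id)) {
    arr <- table$last_arrival[s]
    if (synapses$plastic[s] && !is.na(arr) && t_now - arr > 0) {
      dw <- stdp_delta(synapses$w[s], t_now - arr, params)
      synapses$w[s] <- clip_weight(synapses$w[s] + dw, params$g_max)
      applied <- rbind(applied, data.frame(synapse = s, dw = dw))
    }
  }
  # depression side: this spike's arrival at each efferent synapse pairs
  # against the postsynaptic neuron's latest emission
  for (s in which(synapses$pre == neuron_id)) {
    t_arr <- t_now + t_delay_syn
    post_emit <- table$last_emission[synapses$post[s]]
    if (synapses$plastic[s] && !is.na(post_emit) && post_emit - t_arr < 0) {
      dw <- stdp_delta(synapses$w[s], post_emit - t_arr, params)
      synapses$w[s] <- clip_weight(synapses$w[s] + dw, params$g_max)
      applied <- rbind(applied, data.frame(synapse = s, dw = dw))
    }
    table$last_arrival[s] <- t_arr
  }
  table$last_emission[neuron_id] <- t_now
  list(synapses = synapses, table = table, applied = applied)
}

#' Last-spike table for latest-neighbor pairing
#'
#' @param n_neurons Number of neurons.
#' @param n_synapses Number of synapses.
#' @return A list with `last_emission` (per neuron, ms or `NA`) and
#'   `last_arrival` (per synapse, ms or `NA`).
#' @export
last_spike_table <- function(n_neurons, n_synapses) {
  list(last_emission = rep(NA_real_, n_neurons),
       last_arrival = rep(NA_real_, n_synapses))
}

clip_weight <- function(w, g_max) pmin(pmax(w, 0), g_max)
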