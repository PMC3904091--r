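#' Create the state of a single neuron
#'
#' @param V_memb Membrane voltage (mV).
#' @param refrac_remaining Remaining absolute refractory time (ms).
#' @param last_spike_time Time of the most recent spike (ms) or `NA`.
#' @return An object of class `neuron_state`.
#' @export
neuron_state <- function(V_memb = -70, refrac_remaining = 0,
                         last_spike_time = NA_real_) {
  stopifnot(refrac_remaining >= 0)
  structure(list(V_memb = V_memb, refrac_remaining = refrac_remaining,
                 last_spike_time = last_spike_time),
            class = "neuron_state")
}

#' Create the kinetic state of one synapse
#'
#' Holds the weight and the (g, z) pair of first-order states whose
#' cascade reproduces the alpha waveform `t * exp(-t / tau_rise)` (up to
#' scale) in response to a single impulse.
#'
#' @param w Synaptic weight (pS).
#' @param g Alpha conductance state (dimensionless).
#' @param z Auxiliary alpha state (dimensionless).
#' @param pre_id,post_id Neuron indices (optional bookkeeping).
#' @param plastic Whether the synapse is subject to STDP.
#' @return An object of class `synapse_state`.
#' @export
synapse_state <- function(w = 0, g = 0, z = 0, pre_id = NA_integer_,
                          post_id = NA_integer_, plastic = TRUE) {
  stopifnot(w >= 0, g >= 0, z >= 0)
  structure(list(pre_id = pre_id, post_id = post_id, w = w, g = g, z = z,
                 plastic = plastic),
            class = "synapse_state")
}

#' Advance the alpha-function kinetics of one synapse by one step
#'
#' Forward-Euler update of the first-order cascade
#' `dg/dt = -g/tau + z`, `dz/dt = -z/tau + g_norm * delta(t)`.
#' Each presynaptic arrival within the step injects an impulse whose
#' integral is `g_norm` regardless of the grid, i.e. `z` jumps by `g_norm`
#' per arrival before the decay update. The impulse is visible in `g` (and
#' hence in the drive) within the same step.
#'
#' @param state A [synapse_state()].
#' @param n_impulses Number of presynaptic arrivals in this step.
#' @param kinetics A [synapse_kinetics()].
#' @param sim A [sim_params()].
#' @return The updated `synapse_state`.
#' @export
step_alpha <- function(state, n_impulses, kinetics, sim) {
  if (!is.numeric(n_impulses) || length(n_impulses) != 1 || n_impulses < 0 ||
      n_impulses != round(n_impulses)) {
    stop("n_impulses must be a single non-negative integer count")
  }
  dt <- sim$dt_step
  tau <- kinetics$tau_rise
  z <- state$z + n_impulses * kinetics$g_norm
  g <- state$g + dt * (-state$g / tau + z)
  z <- z - dt * z / tau
  state$g <- g
  state$z <- z
  state
}

#' Synaptic drive current from one synapse
#'
#' In current mode (the default) the drive is `gain * w * g`; in
#' conductance mode it is `gain * w * g * (E_ex - V)`.
#'
#' @param w Synaptic weight (pS).
#' @param g Alpha conductance state.
#' @param V Postsynaptic membrane voltage (mV); used in conductance mode.
#' @param kinetics A [synapse_kinetics()].
#' @return Drive current in model units (mV * pF / ms once divided by C).
#' @export
synaptic_drive <- function(w, g, V, kinetics) {
  stopifnot(all(w >= 0))
  base <- kinetics$current_gain * w * g
  if (kinetics$drive_mode == "conductance") base * (kinetics$E_ex - V) else base
}

#' Integrate one membrane step and detect threshold crossing
#'
#' One forward-Euler step of `C dV/dt = (E_rest - V)/R + I_total`. During
#' the absolute refractory period the voltage is clamped at `E_rest`, no
#' spike can occur, and the refractory clock is decremented. A
#' suprathreshold crossing resets the voltage to `E_rest`, arms the
#' refractory clock, and stamps the spike at `t_now`.
#'
#' @param state A [neuron_state()].
#' @param I_total Total input current this step (model units).
#' @param params A [membrane_params()].
#' @param sim A [sim_params()].
#' @param t_now Time of this step (ms).
#' @return A list with elements `state` (updated [neuron_state()]) and
#'   `spiked` (logical).
#' @export
integrate_membrane <- function(state, I_total, params, sim, t_now = 0) {
  if (!is.finite(I_total)) stop("I_total must be finite")
  stopifnot(state$refrac_remaining >= 0)
  dt <- sim$dt_step
  tau_m <- params$R_memb * params$C_memb  # GOhm * pF = ms
  if (state$refrac_remaining > 0) {
    state$V_memb <- params$E_rest
    state$refrac_remaining <- max(0, state$refrac_remaining - dt)
    return(list(state = state, spiked = FALSE))
  }
  V <- state$V_memb +
    dt * ((params$E_rest - state$V_memb) / tau_m + I_total / params$C_memb)
  spiked <- V > params$V_thr
  if (spiked) {
    state$V_memb <- params$E_rest
    state$refrac_remaining <- params$tau_refrac
    state$last_spike_time <- t_now
  } else {
    state$V_memb <- V
  }
  list(state = state, spiked = spiked)
}

#' Depolarization impulse guaranteeing a same-step evoked spike
#'
#' Size (in the auxiliary alpha state's units) of the stimulation impulse
#' such that the first integration step after arrival depolarizes the
#' membrane by `margin * (V_thr - E_rest)`, i.e. the stimulated neuron
#' crosses threshold in the arrival step from any subthreshold voltage.
#'
#' @param membrane A [membrane_params()].
#' @param kinetics A [synapse_kinetics()].
#' @param sim A [sim_params()].
#' @param margin Safety factor (> 1).
#' @return The impulse added to the stimulation channel's auxiliary state.
#' @export
stim_impulse <- function(membrane, kinetics, sim, margin = 1.05) {
  stopifnot(margin > 1)
  dv <- margin * (membrane$V_thr - membrane$E_rest)
  dv * membrane$C_memb / (kinetics$current_gain * sim$dt_step^2)
}
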