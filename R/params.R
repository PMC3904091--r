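#' Default drive gain for the current-based synaptic drive
#'
#' Single scalar converting the dimensionless product `w * g(t)` (weight in
#' pS times alpha state) into membrane current in the model's mV/pF/ms unit
#' system. The literal drive equation `I = w * g(t)` mixes units, so the
#' conversion is calibrated once, against the requirement that a lone neuron
#' receiving 200 equilibrated plastic background inputs at 0.8 spikes/s
#' settles at an output rate of about 4 spikes/s (the operating point all
#' network-level results assume). See [calibrate_gain()] to reproduce the
#' number.
#'
#' @format A single positive numeric.
#' @export
default_current_gain <- 11550

#' Membrane parameters for the leaky integrate-and-fire neuron
#'
#' Defaults are the model's reference parameter set: a 200 pF, 100 GOhm
#' membrane (tau_m = 20 s, i.e. a near-perfect integrator at the time scales
#' simulated), resting at -70 mV with threshold -55 mV, a 2 ms absolute
#' refractory period, and a 1 ms synaptic transmission delay.
#'
#' @param C_memb Membrane capacitance (pF).
#' @param R_memb Membrane resistance (GOhm). Note GOhm * pF = ms.
#' @param E_rest Resting (and reset) voltage (mV).
#' @param V_thr Spike threshold voltage (mV).
#' @param tau_refrac Absolute refractory period (ms).
#' @param t_delay_syn Synaptic transmission delay (ms).
#' @return An object of class `membrane_params`.
#' @export
membrane_params <- function(C_memb = 200, R_memb = 100, E_rest = -70,
                            V_thr = -55, tau_refrac = 2, t_delay_syn = 1) {
  stopifnot(C_memb > 0, R_memb > 0, tau_refrac > 0, t_delay_syn > 0)
  if (!(V_thr > E_rest)) stop("V_thr must exceed E_rest")
  structure(list(C_memb = C_memb, R_memb = R_memb, E_rest = E_rest,
                 V_thr = V_thr, tau_refrac = tau_refrac,
                 t_delay_syn = t_delay_syn),
            class = "membrane_params")
}

#' Alpha-function synaptic kinetics
#'
#' @param tau_rise Rise time constant of the alpha conductance waveform (ms);
#'   the single-impulse response peaks at `t = tau_rise`.
#' @param g_norm Impulse magnitude injected into the auxiliary state per
#'   presynaptic arrival (dimensionless).
#' @param E_ex Excitatory reversal potential (mV); only used in conductance
#'   drive mode.
#' @param drive_mode `"current"` (the literal `I = gain * w * g`) or
#'   `"conductance"` (`I = gain * w * g * (E_ex - V)`).
#' @param current_gain Scalar converting `w * g` into membrane current; see
#'   [default_current_gain].
#' @return An object of class `synapse_kinetics`.
#' @export
synapse_kinetics <- function(tau_rise = 2, g_norm = 1e-6, E_ex = 0,
                             drive_mode = c("current", "conductance"),
                             current_gain = default_current_gain) {
  drive_mode <- match.arg(drive_mode)
  stopifnot(tau_rise > 0, g_norm > 0, current_gain > 0)
  structure(list(tau_rise = tau_rise, g_norm = g_norm, E_ex = E_ex,
                 drive_mode = drive_mode, current_gain = current_gain),
            class = "synapse_kinetics")
}

#' Simulation grid parameters
#'
#' @param dt_step Integration time step (ms). Must not exceed the synaptic
#'   delay so transmission stays causal on the grid.
#' @param rng_seed Integer master seed; all stochastic streams are derived
#'   from it (see [derive_seed()]).
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(dt_step = 1, rng_seed = 1L) {
  stopifnot(dt_step > 0)
  structure(list(dt_step = dt_step, rng_seed = as.integer(rng_seed)),
            class = "sim_params")
}

#' Weight-dependent STDP parameters
#'
#' Potentiation scales with the headroom `(g_max - w)` and depression with
#' the current weight `w`, so weights stay in `[0, g_max]` with a stable
#' fixed point under symmetric pairing at `g_max * A_p / (A_p + A_d)`.
#'
#' @param A_p Potentiation amplitude (dimensionless).
#' @param tau_p Potentiation decay time constant (ms).
#' @param A_d Depression amplitude (dimensionless).
#' @param tau_d Depression decay time constant (ms).
#' @param g_max Soft upper bound on the synaptic conductance (pS).
#' @return An object of class `stdp_params`.
#' @export
stdp_params <- function(A_p = 0.001, tau_p = 20, A_d = 0.003, tau_d = 20,
                        g_max = 6000) {
  stopifnot(A_p >= 0, A_d >= 0, tau_p > 0, tau_d > 0, g_max > 0)
  structure(list(A_p = A_p, tau_p = tau_p, A_d = A_d, tau_d = tau_d,
                 g_max = g_max),
            class = "stdp_params")
}

#' Background input ensemble parameters
#'
#' Each neuron is driven by `n_trains` independent plastic synapses whose
#' presynaptic sources are Poisson-like binary trains with per-step
#' probability `rate * dt`, optionally sharing a global within-step
#' correlation `c_back` (two-point mixture construction, see
#' [solve_mixture()]).
#'
#' @param n_trains Number of background processes per neuron.
#' @param rate Background firing rate (spikes/s).
#' @param c_back Target within-step pairwise Pearson correlation among all
#'   background trains (0 for independent drive; `10^-3.5` is the
#'   "correlated" condition).
#' @return An object of class `background_params`.
#' @export
background_params <- function(n_trains = 200, rate = 0.8, c_back = 0) {
  stopifnot(n_trains >= 1, rate >= 0, c_back >= 0, c_back < 1)
  structure(list(n_trains = as.integer(n_trains), rate = rate,
                 c_back = c_back),
            class = "background_params")
}

#' Steady-state detection criterion for mean-weight trajectories
#'
#' A trajectory is steady over a window when the magnitude of its
#' least-squares trend across the window, `|slope| * window`, does not
#' exceed `tolerance`.
#'
#' @param window Window length (s).
#' @param tolerance Maximum tolerated net drift of the mean weight across
#'   one window (pS). Default 30 pS = 0.5% of `g_max`.
#' @return An object of class `steady_state_criterion`.
#' @export
steady_state_criterion <- function(window = 5000, tolerance = 30) {
  stopifnot(window > 0, tolerance > 0)
  structure(list(window = window, tolerance = tolerance),
            class = "steady_state_criterion")
}

#' Spike-triggered stimulation (STS) parameters
#'
#' Every spike of the `source` ("recording") neuron schedules a
#' suprathreshold depolarizing stimulus onto the `target` ("stimulation")
#' neuron `t_delay` ms later, delivered through a dedicated non-plastic
#' alpha conductance sized so the evoked spike lands in the arrival step
#' (unless the target is refractory).
#'
#' @param source Index or role name of the recorded neuron.
#' @param target Index or role name of the stimulated neuron (the output
#'   neuron in all the protocols shipped here).
#' @param t_delay Stimulation delay (ms).
#' @param w_stim_max Nominal stimulation strength (pS); suprathreshold by
#'   construction via the stimulation margin.
#' @param margin Safety factor on the threshold-crossing depolarization of
#'   the stimulus' first step.
#' @return An object of class `sts_params`.
#' @export
sts_params <- function(source, target = "O", t_delay = 20,
                       w_stim_max = 50000, margin = 1.05) {
  stopifnot(t_delay > 0, w_stim_max > 0, margin > 1)
  structure(list(source = source, target = target, t_delay = t_delay,
                 w_stim_max = w_stim_max, margin = margin),
            class = "sts_params")
}

#' Background rate-step intervention
#'
#' Re-parameterizes the background ensemble of one neuron to a new firing
#' rate (the mixture is re-solved so `c_back` is preserved).
#'
#' @param target Index or role name of the neuron whose background rate is
#'   stepped.
#' @param new_rate New background rate (spikes/s).
#' @return An object of class `rate_step_spec`.
#' @export
rate_step_spec <- function(target = "O", new_rate = 0.95) {
  stopifnot(new_rate > 0)
  structure(list(target = target, new_rate = new_rate),
            class = "rate_step_spec")
}

#' Derive a named sub-seed from a master seed
#'
#' Expands one global seed into independent per-stream seeds (background
#' generation, connection removal, per-trial inputs, ...) via integer
#' hashing, keeping every derived seed in the 32-bit positive range.
#'
#' @param seed Master seed (integer).
#' @param stream Stream label (character).
#' @param index Optional integer index within the stream.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, stream, index = 0L) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  x <- (as.double(seed) * 2654435761 + h * 40503 + as.double(index) * 69069) %% 2147483647
  as.integer(x) + 1L
}
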