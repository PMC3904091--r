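# Membrane and alpha-kinetics state transitions.

test_that("zero alpha state is a fixed point and impulses follow the alpha shape", {
  kin <- default_kinetics
  s <- synapse_state()
  s2 <- step_alpha(s, 0, kin, default_sim)
  expect_identical(c(s2$g, s2$z), c(0, 0))

  # single impulse, fine grid: g(t) peaks near t = tau_rise, matching the
  # closed form t * exp(-t / tau) evaluated on a dense grid
  sim <- sim_params(dt_step = 0.01)
  s <- step_alpha(synapse_state(), 1, kin, sim)
  tt <- seq(sim$dt_step, 8, by = sim$dt_step)
  g <- numeric(length(tt))
  g[1] <- s$g
  for (k in 2:length(tt)) {
    s <- step_alpha(s, 0, kin, sim)
    g[k] <- s$g
  }
  closed <- tt * exp(-tt / kin$tau_rise)
  expect_equal(tt[which.max(g)], kin$tau_rise, tolerance = 0.05)
  expect_equal(tt[which.max(closed)], kin$tau_rise, tolerance = 0.01)
  # shape match up to scale
  expect_gt(cor(g, closed), 0.9999)
})

test_that("alpha kinetics are linear: impulse trains superpose", {
  kin <- default_kinetics
  sim <- default_sim
  run <- function(impulses) {
    s <- synapse_state()
    out <- matrix(0, length(impulses), 2)
    for (k in seq_along(impulses)) {
      s <- step_alpha(s, impulses[k], kin, sim)
      out[k, ] <- c(s$g, s$z)
    }
    out
  }
  # two simultaneous impulses = exactly twice one impulse
  one <- run(c(1, 0, 0, 0, 0, 0))
  two <- run(c(2, 0, 0, 0, 0, 0))
  expect_equal(two, 2 * one, tolerance = 1e-15)
  # arbitrary train = sum of shifted single-impulse responses
  train <- c(1, 0, 2, 0, 0, 1)
  expected <- run(c(1, 0, 0, 0, 0, 0)) +
    2 * run(c(0, 0, 1, 0, 0, 0)) + run(c(0, 0, 0, 0, 0, 1))
  expect_equal(run(train), expected, tolerance = 1e-15)
})

test_that("step_alpha rejects negative impulse counts", {
  expect_error(step_alpha(synapse_state(), -1, default_kinetics, default_sim),
               "non-negative")
})

test_that("synaptic drive follows the drive equation in both modes", {
  kin <- synapse_kinetics(current_gain = 3)
  expect_identical(synaptic_drive(0, 0.5, -60, kin), 0)
  expect_identical(synaptic_drive(6000, 0, -60, kin), 0)
  expect_equal(synaptic_drive(6000, 0.5, -60, kin), 3 * 6000 * 0.5)
  kc <- synapse_kinetics(current_gain = 3, drive_mode = "conductance",
                         E_ex = 0)
  expect_identical(synaptic_drive(1000, 0.5, 0, kc), 0)  # zero driving force
  expect_equal(synaptic_drive(1000, 0.5, -70, kc), 3 * 1000 * 0.5 * 70)
})

test_that("membrane rests at E_rest and decays exponentially with tau = RC", {
  mp <- default_membrane
  sim <- sim_params(dt_step = 0.1)
  st <- neuron_state(V_memb = mp$E_rest)
  out <- integrate_membrane(st, 0, mp, sim)
  expect_false(out$spiked)
  expect_equal(out$state$V_memb, mp$E_rest)

  # decay from +10 mV: compare against analytic exponential
  decay <- function(dt) {
    sim <- sim_params(dt_step = dt)
    st <- neuron_state(V_memb = mp$E_rest + 10)
    tt <- seq(dt, 2000, by = dt)
    v <- numeric(length(tt))
    for (k in seq_along(tt)) {
      st <- integrate_membrane(st, 0, mp, sim)$state
      v[k] <- st$V_memb
    }
    analytic <- mp$E_rest + 10 * exp(-tt / (mp$R_memb * mp$C_memb))
    expect_true(all(diff(v) < 0))          # monotone toward rest
    expect_true(all(v > mp$E_rest))        # from above, never crosses
    max(abs(v - analytic))
  }
  err1 <- decay(2)
  err2 <- decay(1)
  # first-order method: halving dt about halves the global error
  expect_equal(err1 / err2, 2, tolerance = 0.2)
})

test_that("voltage never crosses threshold without input", {
  mp <- default_membrane
  sim <- default_sim
  for (v0 in c(mp$E_rest - 5, mp$V_thr - 1e-9)) {
    st <- neuron_state(V_memb = v0)
    for (k in 1:500) {
      out <- integrate_membrane(st, 0, mp, sim)
      st <- out$state
      expect_false(out$spiked)
    }
    expect_lt(abs(st$V_memb - mp$E_rest), abs(v0 - mp$E_rest) + 1e-12)
  }
})

test_that("absolute refractoriness clamps the membrane and blocks spikes", {
  mp <- default_membrane
  st <- neuron_state(V_memb = mp$E_rest, refrac_remaining = 2)
  out <- integrate_membrane(st, 1e12, mp, default_sim)
  expect_false(out$spiked)
  expect_equal(out$state$V_memb, mp$E_rest)
  expect_equal(out$state$refrac_remaining, 1)
})

test_that("threshold crossing resets, stamps the spike, and arms refractoriness", {
  mp <- default_membrane
  st <- neuron_state(V_memb = mp$V_thr - 0.5)
  out <- integrate_membrane(st, 1e4, mp, default_sim, t_now = 123)
  expect_true(out$spiked)
  expect_equal(out$state$V_memb, mp$E_rest)
  expect_equal(out$state$refrac_remaining, mp$tau_refrac)
  expect_equal(out$state$last_spike_time, 123)
  expect_error(integrate_membrane(st, NaN, mp, default_sim), "finite")
})

test_that("the stimulation impulse drives a spike from rest within its own step", {
  mp <- default_membrane
  kin <- default_kinetics
  sim <- default_sim
  # the stimulation channel's first-step depolarization exceeds the
  # rest-to-threshold gap by construction
  imp <- stim_impulse(mp, kin, sim, margin = 1.05)
  # inject the impulse into the auxiliary state as the engine does
  z <- imp
  g <- default_sim$dt_step * z
  dv <- sim$dt_step * kin$current_gain * g / mp$C_memb
  expect_equal(dv, 1.05 * (mp$V_thr - mp$E_rest), tolerance = 1e-12)
  st <- neuron_state(V_memb = mp$E_rest)
  out <- integrate_membrane(st, kin$current_gain * g, mp, sim)
  expect_true(out$spiked)
})
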