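# Weight-dependent STDP rule and latest-neighbor pairing.

test_that("stdp_delta reproduces the closed form and its boundary cases", {
  p <- default_stdp
  # hand-evaluated closed forms
  expect_equal(stdp_delta(0, 20, p), 0.001 * 6000 * exp(-1),
               tolerance = 1e-12)
  expect_equal(stdp_delta(3000, -20, p), -0.003 * 3000 * exp(-1),
               tolerance = 1e-12)
  expect_equal(stdp_delta(1234, 7, p), 0.001 * (6000 - 1234) * exp(-7 / 20),
               tolerance = 1e-12)
  # exact zeros at the soft bounds and at zero timing difference
  expect_identical(stdp_delta(6000, 5, p), 0)
  expect_identical(stdp_delta(0, -5, p), 0)
  expect_identical(stdp_delta(3000, 0, p), 0)
  expect_error(stdp_delta(-1, 5, p), "outside")
  expect_error(stdp_delta(6001, 5, p), "outside")
})

test_that("|dw| decays monotonically as |dt| grows on both branches", {
  p <- default_stdp
  dts <- seq(1, 200, by = 1)
  pot <- stdp_delta(3000, dts, p)
  dep <- stdp_delta(3000, -dts, p)
  expect_true(all(diff(pot) < 0))
  expect_true(all(diff(abs(dep)) < 0))
  expect_true(all(pot > 0) && all(dep < 0))
})

test_that("expected drift under symmetric pairing vanishes at g_max*A_p/(A_p+A_d)", {
  p <- default_stdp
  w_star <- p$g_max * p$A_p / (p$A_p + p$A_d)
  expect_equal(w_star, 1500)
  set.seed(7)
  dts <- rexp(20000, rate = 1 / 30)  # symmetric |dt| magnitudes
  drift <- function(w) mean(stdp_delta(w, dts, p) + stdp_delta(w, -dts, p))
  # closed-form expectation: drift(w) = E[e^-dt/tau] (A_p g_max - (A_p+A_d) w)
  expect_equal(drift(w_star), 0, tolerance = 1e-12)
  expect_gt(drift(w_star - 500), 0)
  expect_lt(drift(w_star + 500), 0)
})

test_that("latest-neighbor pairing matches a brute-force nearest-pair oracle on sparse trains", {
  p <- default_stdp
  delay <- 1
  # sparse trains: all gaps >> tau_p so only nearest pre/post pairs matter
  pre_emit <- c(100, 700, 1500)
  post_emit <- c(119, 690, 1520.5)

  # brute-force oracle: for each post spike the nearest preceding arrival,
  # for each arrival the nearest preceding post spike; sum closed forms on
  # a non-weight-dependent linearization (w fixed, updates not compounded)
  arr <- pre_emit + delay
  w0 <- 3000
  oracle <- 0
  for (tp in post_emit) {
    d <- tp - arr[arr < tp]
    if (length(d) > 0) oracle <- oracle + stdp_delta(w0, min(d), p)
  }
  for (ta in arr) {
    d <- post_emit[post_emit < ta] - ta
    if (length(d) > 0) oracle <- oracle + stdp_delta(w0, max(d), p)
  }

  # event-driven reference implementation, single synapse 1 -> 2, with the
  # weight frozen at w0 to match the linearized oracle
  syn <- data.frame(pre = 1L, post = 2L, w = w0, plastic = TRUE)
  tab <- last_spike_table(2, 1)
  events <- rbind(data.frame(t = pre_emit, id = 1L),
                  data.frame(t = post_emit, id = 2L))
  events <- events[order(events$t), ]
  total <- 0
  for (k in seq_len(nrow(events))) {
    res <- stdp_on_spike(events$id[k], events$t[k], tab, syn, p,
                         t_delay_syn = delay)
    tab <- res$table
    if (nrow(res$applied) > 0) total <- total + sum(res$applied$dw)
    res$synapses$w <- w0  # freeze for comparison with the linearized oracle
    syn <- res$synapses
  }
  expect_equal(total, oracle, tolerance = 1e-9)
})

test_that("on-spike updates skip unpaired synapses, exact ties, and non-plastic synapses", {
  p <- default_stdp
  syn <- data.frame(pre = c(1L, 3L), post = c(2L, 2L), w = c(3000, 3000),
                    plastic = c(TRUE, FALSE))
  tab <- last_spike_table(3, 2)
  # post fires with no prior pre spike recorded: no update
  res <- stdp_on_spike(2L, 50, tab, syn, p)
  expect_equal(nrow(res$applied), 0)
  expect_equal(res$synapses$w, c(3000, 3000))
  # pre emits at 10 (arrival 11), post at 31: dt = +20 on synapse 1
  tab <- res$table
  res <- stdp_on_spike(1L, 10, tab, syn, p)
  res <- stdp_on_spike(3L, 10, res$table, res$synapses, p)  # non-plastic pre
  res <- stdp_on_spike(2L, 31, res$table, res$synapses, p)
  expect_equal(res$synapses$w[1], 3000 + 0.001 * 3000 * exp(-1))
  expect_equal(res$synapses$w[2], 3000)  # untouched, plastic = FALSE
  # exact tie after delay adjustment: pre emits at 99 (arrival 100), post
  # fires at 100 -> dt = 0 -> no update
  syn2 <- data.frame(pre = 1L, post = 2L, w = 3000, plastic = TRUE)
  tab2 <- last_spike_table(2, 1)
  r <- stdp_on_spike(1L, 99, tab2, syn2, p)
  r <- stdp_on_spike(2L, 100, r$table, r$synapses, p)
  expect_equal(r$synapses$w, 3000)
})

test_that("weights stay within [0, g_max] under arbitrary event sequences", {
  p <- default_stdp
  set.seed(42)
  for (rep in 1:5) {
    syn <- data.frame(pre = 1L, post = 2L,
                      w = runif(1, 0, p$g_max), plastic = TRUE)
    tab <- last_spike_table(2, 1)
    events <- data.frame(t = sort(runif(200, 0, 2000)),
                         id = sample(1:2, 200, replace = TRUE))
    for (k in seq_len(nrow(events))) {
      res <- stdp_on_spike(events$id[k], events$t[k], tab, syn, p)
      tab <- res$table
      syn <- res$synapses
      expect_true(syn$w >= 0 && syn$w <= p$g_max)
    }
  }
})
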