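#' Specification of an aDFP network
#'
#' The augmented disynaptic feedforward pathway (aDFP) motif: a
#' disconnected control input `I0_1`, a monosynaptic input `I1_1 -> O`, one
#' or more parallel disynaptic pathways `I2_1 -> H1_k -> O`, and a
#' downstream neuron `O -> D`. Every neuron additionally receives its own
#' plastic background ensemble; a configurable number of background
#' connections can be pruned from the output neuron (used to hold its rate
#' fixed when many parallel pathways are added).
#'
#' @param n_hidden_paths Number of parallel disynaptic pathways (>= 1).
#' @param n_background_removed_from_O Background connections removed from
#'   the output neuron.
#' @param background A [background_params()].
#' @param membrane A [membrane_params()].
#' @param kinetics A [synapse_kinetics()].
#' @param stdp An [stdp_params()].
#' @param sim A [sim_params()].
#' @param init_network_w Initial weight of the in-network synapses (pS);
#'   mid-range by default, washed out by equilibration.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(n_hidden_paths = 1, n_background_removed_from_O = 0,
                         background = background_params(),
                         membrane = membrane_params(),
                         kinetics = synapse_kinetics(),
                         stdp = stdp_params(),
                         sim = sim_params(),
                         init_network_w = stdp$g_max / 2) {
  stopifnot(n_hidden_paths >= 1)
  if (n_background_removed_from_O < 0 ||
      n_background_removed_from_O >= background$n_trains) {
    stop("n_background_removed_from_O must be in [0, n_trains)")
  }
  structure(list(n_hidden_paths = as.integer(n_hidden_paths),
                 n_background_removed_from_O =
                   as.integer(n_background_removed_from_O),
                 background = background, membrane = membrane,
                 kinetics = kinetics, stdp = stdp, sim = sim,
                 init_network_w = init_network_w),
            class = "network_spec")
}

#' Build an aDFP network from a spec and equilibrated background weights
#'
#' Every neuron (including the disconnected control `I0_1` and the
#' downstream neuron `D`) receives `n_trains` background synapses whose
#' weights are an independently shuffled copy of the equilibrated vector;
#' the output neuron keeps `n_trains - n_background_removed_from_O` of
#' them, the removed subset chosen uniformly at random. In-network synapses
#' start at `init_network_w`. All synapses are plastic.
#'
#' @param spec A [network_spec()].
#' @param background_weights Equilibrated weight vector of length
#'   `n_trains` (see [equilibrate_background_weights()]).
#' @param seed Integer seed (shuffling and removal choice).
#' @return An object of class `adfp_network`.
#' @export
build_adfp <- function(spec, background_weights, seed = 1L) {
  nb <- spec$background$n_trains
  if (length(background_weights) != nb) {
    stop("background_weights must have length n_trains = ", nb)
  }
  nh <- spec$n_hidden_paths
  roles <- c(I0_1 = 1L, I1_1 = 2L, I2_1 = 3L,
             stats::setNames(3L + seq_len(nh), paste0("H1_", seq_len(nh))))
  roles <- c(roles, O = 4L + nh, D = 5L + nh)
  n <- 5L + nh
  o <- unname(roles["O"])

  syn <- data.frame(
    pre = c(roles[["I1_1"]], rep(roles[["I2_1"]], nh),
            3L + seq_len(nh), o),
    post = c(o, 3L + seq_len(nh), rep(o, nh), unname(roles["D"])),
    w = spec$init_network_w,
    plastic = TRUE)
  labels <- c("I1_1->O", paste0("I2_1->H1_", seq_len(nh)),
              paste0("H1_", seq_len(nh), "->O"), "O->D")

  set.seed(derive_seed(seed, "wiring"))
  bg <- lapply(seq_len(n), function(i) {
    w <- sample(background_weights)
    if (i == o && spec$n_background_removed_from_O > 0) {
      keep <- sort(sample.int(nb, nb - spec$n_background_removed_from_O))
      w <- w[keep]
    }
    w
  })

  state <- new_engine_state(bg, rep(spec$background$rate, n), syn,
                            spec$membrane)
  structure(list(
    spec = spec,
    roles = roles,
    syn_labels = labels,
    synapses = syn[, c("pre", "post")],
    params = list(membrane = spec$membrane, kinetics = spec$kinetics,
                  sim = spec$sim, stdp = spec$stdp,
                  background = spec$background),
    state = state), class = "adfp_network")
}

#' @export
print.adfp_network <- function(x, ...) {
  cat("aDFP network:", length(x$state$V), "neurons,",
      length(x$state$syn_w), "network synapses,",
      length(x$state$bg_w), "background synapses\n")
  cat("  roles:", paste(names(x$roles), collapse = " "), "\n")
  cat("  t =", x$state$t_ms / 1000, "s; mean bg weight =",
      round(mean(x$state$bg_w), 1), "pS\n")
  invisible(x)
}

#' Validate network invariants
#'
#' Checks the structural and state invariants of a built network:
#' feedforward acyclicity, the closed-form neuron and synapse counts, the
#' disconnected control neuron's isolation, background fan-ins, and weight
#' bounds. Returns a character vector of violations (empty when valid).
#'
#' @param net An [build_adfp()] network.
#' @return Character vector of violation messages.
#' @export
validate_network <- function(net) {
  v <- character()
  n <- length(net$state$V)
  nh <- net$spec$n_hidden_paths
  if (n != 5L + nh) {
    v <- c(v, sprintf("neuron count %d != 5 + n_hidden_paths (%d)", n, 5L + nh))
  }
  s <- length(net$state$syn_w)
  if (s != 2L + 2L * nh) {
    v <- c(v, sprintf("network synapse count %d != 2 + 2*n_hidden_paths (%d)",
                      s, 2L + 2L * nh))
  }
  i0 <- unname(net$roles["I0_1"])
  if (any(net$state$syn_pre == i0) || any(net$state$syn_post == i0)) {
    v <- c(v, "disconnected control neuron I0_1 has network synapses")
  }
  # acyclicity by iterative source removal (Kahn)
  pre <- net$state$syn_pre; post <- net$state$syn_post
  alive <- rep(TRUE, length(pre))
  nodes <- seq_len(n)
  repeat {
    indeg <- tabulate(post[alive], nbins = n)
    src <- nodes[indeg[nodes] == 0]
    if (length(src) == 0 || length(nodes) == 0) break
    alive <- alive & !(pre %in% src)
    nodes <- setdiff(nodes, src)
  }
  if (any(alive)) v <- c(v, "network contains a cycle")
  g_max <- net$params$stdp$g_max
  if (any(net$state$syn_w < 0 | net$state$syn_w > g_max)) {
    v <- c(v, "network synapse weight outside [0, g_max]")
  }
  if (any(net$state$bg_w < 0 | net$state$bg_w > g_max)) {
    v <- c(v, "background weight outside [0, g_max]")
  }
  nb <- diff(net$state$bg_ptr)
  o <- unname(net$roles["O"])
  expect_bg <- rep(net$spec$background$n_trains, n)
  expect_bg[o] <- expect_bg[o] - net$spec$n_background_removed_from_O
  if (!all(nb == expect_bg)) v <- c(v, "background fan-in mismatch")
  v
}
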