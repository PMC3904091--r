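#' Load an experiment configuration from a YAML file
#'
#' Unspecified fields fall back to the reference defaults (the parameter
#' constructors' defaults). Scalar fields accepted under the top-level
#' keys `membrane`, `kinetics`, `stdp`, `background`, `sim`, `network`
#' (`n_hidden_paths`, `n_background_removed_from_O`, `init_network_w`),
#' `durations`, `intervention` (`type`: none/rate_step/sts plus its
#' fields), `n_trials`, `seed`. `c_back` may be given in the notation
#' `"10^-3.5"`.
#'
#' @param path Path to a YAML file (an empty file yields the full default
#'   configuration).
#' @return An [experiment_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("membrane", "kinetics", "stdp", "background", "sim", "network",
             "durations", "intervention", "n_trials", "seed")
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) stop("unknown config key(s): ", paste(bad, collapse = ", "))

  build <- function(ctor, block, extra = list()) {
    args <- raw[[block]] %||% list()
    if (block == "background" && !is.null(args$c_back)) {
      args$c_back <- parse_power(args$c_back)
    }
    allowed <- names(formals(ctor))
    bad <- setdiff(names(args), allowed)
    if (length(bad) > 0) {
      stop("unknown key(s) in '", block, "': ", paste(bad, collapse = ", "))
    }
    tryCatch(do.call(ctor, c(args, extra)),
             error = function(e) stop("invalid '", block, "' block: ",
                                      conditionMessage(e), call. = FALSE))
  }
  membrane <- build(membrane_params, "membrane")
  kinetics <- build(synapse_kinetics, "kinetics")
  stdp <- build(stdp_params, "stdp")
  background <- build(background_params, "background")
  sim <- build(sim_params, "sim")
  if (sim$dt_step > membrane$t_delay_syn) {
    stop("invalid 'sim' block: dt_step must not exceed t_delay_syn")
  }
  netargs <- raw$network %||% list()
  spec <- network_spec(
    n_hidden_paths = netargs$n_hidden_paths %||% 1,
    n_background_removed_from_O = netargs$n_background_removed_from_O %||% 0,
    background = background, membrane = membrane, kinetics = kinetics,
    stdp = stdp, sim = sim,
    init_network_w = netargs$init_network_w %||% (stdp$g_max / 2))

  iv <- raw$intervention
  intervention <- NULL
  if (!is.null(iv) && !identical(iv$type, "none")) {
    if (identical(iv$type, "rate_step")) {
      intervention <- rate_step_spec(target = iv$target %||% "O",
                                     new_rate = iv$new_rate %||% 0.95)
    } else if (identical(iv$type, "sts")) {
      intervention <- sts_params(source = iv$source %||% "I0_1",
                                 target = iv$target %||% "O",
                                 t_delay = iv$t_delay %||% 20,
                                 w_stim_max = iv$w_stim_max %||% 50000)
    } else {
      stop("unknown intervention type: ", iv$type)
    }
  }
  dur <- raw$durations %||% list()
  experiment_config(
    spec = spec, intervention = intervention,
    durations = list(equilibrate = dur$equilibrate %||% 75000,
                     base = dur$base %||% 5000,
                     peri = dur$peri %||% 10000,
                     post = dur$post %||% 10000),
    n_trials = raw$n_trials %||% 10,
    rng_seed = raw$seed %||% 1L)
}

parse_power <- function(x) {
  if (is.numeric(x)) return(x)
  m <- regmatches(x, regexec("^10\\^(-?[0-9.]+)$", x))[[1]]
  if (length(m) == 2) return(10^as.numeric(m[2]))
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v)) stop("cannot parse numeric value: ", x)
  v
}

#' Write a simulation fragment to delimited text files
#'
#' Writes `spikes.tsv` (time_ms, neuron_id), `weights.tsv` (time_s, group,
#' weight_pS), `rates.tsv` (time_s, neuron_id, rate_hz), optionally
#' `dst.tsv` (block_start_s, pair, bin_center_ms, probability, n_dsts),
#' and `manifest.json`.
#'
#' @param result A fragment from [run_phase()] (or merged fragments).
#' @param dir Output directory (created if missing).
#' @param dst Optional named list of `dst_distribution_set` objects, one
#'   per neuron pair.
#' @param manifest Optional manifest list (see [run_manifest()]).
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(result, dir, dst = NULL, manifest = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(spikes = file.path(dir, "spikes.tsv"),
             weights = file.path(dir, "weights.tsv"),
             rates = file.path(dir, "rates.tsv"))
  write_tsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  write_tsv(result$spikes, paths["spikes"])
  write_tsv(result$weights, paths["weights"])
  write_tsv(result$rates, paths["rates"])
  if (!is.null(dst)) {
    rows <- lapply(names(dst), function(pair) {
      s <- dst[[pair]]
      do.call(rbind, lapply(s$blocks, function(b) {
        data.frame(block_start_s = b$block_start, pair = pair,
                   bin_center_ms = s$bin_mid, probability = b$prob,
                   n_dsts = b$n_dsts)
      }))
    })
    write_tsv(do.call(rbind, rows), file.path(dir, "dst.tsv"))
    paths <- c(paths, dst = file.path(dir, "dst.tsv"))
  }
  if (!is.null(manifest)) {
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, manifest = file.path(dir, "manifest.json"))
  }
  invisible(paths)
}

#' Read back a spike log written by [write_outputs()]
#'
#' @param path Path to `spikes.tsv`.
#' @return Data.frame with `time_ms`, `neuron_id`.
#' @export
read_spikes <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}

#' Run manifest: everything needed to reproduce a run bit-identically
#'
#' @param config An [experiment_config()].
#' @param phases Named numeric vector of phase boundary times (s).
#' @return A list with a config digest, the seed, phase boundaries,
#'   package version, and the calibration constants in effect.
#' @export
run_manifest <- function(config, phases = NULL) {
  cfg_plain <- rapply(unclass(config), unclass, how = "replace")
  digest <- sum(utf8ToInt(paste(deparse(cfg_plain), collapse = "")) *
                  (seq_along(utf8ToInt(paste(deparse(cfg_plain),
                                             collapse = ""))) %% 97 + 1)) %%
    2147483647
  list(config_hash = digest,
       seed = config$rng_seed,
       phase_boundaries_s = as.list(phases),
       version = as.character(utils::packageVersion("stsnet")),
       calibration = list(
         current_gain = config$spec$kinetics$current_gain,
         drive_mode = config$spec$kinetics$drive_mode))
}
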