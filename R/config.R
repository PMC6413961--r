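#' Load a run configuration
#'
#' Reads a YAML configuration with sections `stimulus`, `periphery`, `sacf`,
#' `cortex`, `experiment` and top-level keys `seed`, `output_dir`,
#' `log_level`. Every omitted cortical parameter falls back to the reference
#' defaults of [cortical_params()]; unknown keys anywhere are rejected by
#' name, so typos never silently fall back to defaults.
#'
#' @param path Path to a YAML file.
#' @return A list of class `run_config` with fully resolved parameter
#'   objects (`config$model` is a [model_config()]).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path),
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()

  top_allowed <- c("seed", "output_dir", "log_level", "stimulus", "periphery",
                   "sacf", "cortex", "experiment")
  check_keys <- function(x, allowed, section) {
    unknown <- setdiff(names(x), allowed)
    if (length(unknown)) {
      stop(sprintf("unknown key(s) in %s: %s", section,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }
  check_keys(raw, top_allowed, "config")

  num1 <- function(x, key, section, lo = -Inf, hi = Inf) {
    if (is.null(x)) return(NULL)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop(sprintf("key '%s' in %s must be a single number", key, section),
           call. = FALSE)
    }
    if (x < lo || x > hi) {
      stop(sprintf("key '%s' in %s is out of range [%g, %g]", key, section,
                   lo, hi), call. = FALSE)
    }
    x
  }

  stim_defaults <- list(kind = "irn", interval = "P5", tuning = "just",
                        delay_T0_ms = 8, iterations = 16, gain = 1,
                        band = c(800, 3200), duration_s = 0.75,
                        level_db = 80, sample_rate = 48000,
                        noise_dur_s = 0.75, fade_ms = 10)
  stim <- utils::modifyList(stim_defaults, raw$stimulus %||% list())
  check_keys(raw$stimulus %||% list(), names(stim_defaults), "stimulus")
  num1(stim$delay_T0_ms, "delay_T0_ms", "stimulus", lo = 1e-3)
  num1(stim$iterations, "iterations", "stimulus", lo = 1)
  num1(stim$gain, "gain", "stimulus", lo = 0, hi = 1)

  per_defaults <- list(name = "simple", n_channels = 40, f_low = 125,
                       f_high = 10000, internal_rate = 10000)
  per <- utils::modifyList(per_defaults, raw$periphery %||% list())
  check_keys(raw$periphery %||% list(), names(per_defaults), "periphery")
  if (!identical(per$name, "simple")) {
    stop(sprintf("unknown periphery '%s' (available: simple)", per$name),
         call. = FALSE)
  }

  sacf_def <- unclass(sacf_params())
  check_keys(raw$sacf %||% list(), names(sacf_def), "sacf")
  sacf <- do.call(sacf_params, utils::modifyList(list(),
                                                 raw$sacf %||% list()))

  check_keys(raw$cortex %||% list(), names(unclass(cortical_params())),
             "cortex")
  params <- do.call(cortical_params, raw$cortex %||% list())

  exp_defaults <- list(type = "none", delays_ms = c(4, 8, 12, 16),
                       iterations = NULL, intervals = dyad_table()$interval,
                       n_runs = 10)
  expc <- utils::modifyList(exp_defaults, raw$experiment %||% list(),
                            keep.null = TRUE)
  check_keys(raw$experiment %||% list(), names(exp_defaults), "experiment")
  if (!expc$type %in% c("none", "irn_sweep", "dyads")) {
    stop(sprintf("unknown experiment type '%s'", expc$type), call. = FALSE)
  }

  bank <- channel_bank(per$n_channels, per$f_low, per$f_high,
                       per$internal_rate)
  structure(list(
    seed = as.integer(raw$seed %||% 1L),
    output_dir = raw$output_dir %||% "pitchcortex-out",
    log_level = raw$log_level %||% "info",
    stimulus = stim, periphery = per, experiment = expc,
    model = model_config(params = params, sacf = sacf, bank = bank)
  ), class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_stimulus_wave <- function(config, seed) {
  s <- config$stimulus
  band <- s$band
  if (s$kind == "dyad_irn") {
    dy <- dyad_spec(s$interval, tuning = s$tuning)
    spec <- stimulus_spec(kind = "dyad_irn", delay_T0 = s$delay_T0_ms / 1000,
                          iterations = s$iterations, gain = s$gain,
                          band_low = band[1], band_high = band[2],
                          duration = s$duration_s, level = s$level_db,
                          sample_rate = s$sample_rate,
                          seed = derive_seed(seed, "stimulus", 1L))
    pw <- generate_dyad_irn(spec, dy)
  } else {
    spec <- stimulus_spec(kind = "irn", delay_T0 = s$delay_T0_ms / 1000,
                          iterations = s$iterations, gain = s$gain,
                          band_low = band[1], band_high = band[2],
                          duration = s$duration_s, level = s$level_db,
                          sample_rate = s$sample_rate,
                          seed = derive_seed(seed, "stimulus", 1L))
    pw <- generate_irn(spec)
  }
  wave <- make_noise_pitch_sequence(s$noise_dur_s, pw, fade = s$fade_ms / 1000,
                                    band_low = band[1], band_high = band[2],
                                    level = s$level_db,
                                    noise_seed = derive_seed(seed, "precursor", 1L))
  list(wave = wave, spec = spec)
}

#' Run a configured pipeline and write its artifacts
#'
#' Synthesises the configured stimulus, runs the model (or a batch
#' experiment), and writes WAV + JSON sidecar, CSV tables, summary JSON,
#' figures and a manifest (parameter snapshot, seeds, package version)
#' sufficient to replay the run, into the configured output directory.
#'
#' @param config A `run_config` from [load_config()].
#' @param output_dir Overrides `config$output_dir`.
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  out <- output_dir %||% config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  probe <- file.path(out, ".write-test")
  ok <- tryCatch({ file.create(probe) && file.remove(probe) },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!isTRUE(ok)) stop(sprintf("output directory '%s' is not writable", out),
                        call. = FALSE)

  seed <- config$seed
  manifest <- list(
    package_version = as.character(utils::packageVersion("pitchcortex")),
    seed = seed,
    stimulus = config$stimulus,
    periphery = config$periphery,
    sacf = unclass(config$model$sacf),
    cortex = unclass(config$model$params),
    experiment_kind = "none"
  )

  etype <- config$experiment$type %||% "none"
  manifest$experiment_kind <- etype

  if (etype == "none") {
    sw <- config_stimulus_wave(config, seed)
    write_wav(sw$wave, file.path(out, "stimulus.wav"),
              spec = unclass(sw$spec))
    ps <- run_pitch_model(sw$wave, config$model,
                          mode = if (config$stimulus$kind == "dyad_irn")
                            "dyad" else "single",
                          seed = derive_seed(seed, "cortex", 1L))
    utils::write.csv(ps$dipole, file.path(out, "dipole.csv"),
                     row.names = FALSE)
    utils::write.csv(tibble::tibble(time = ps$sim$time,
                                    network_rate_decoder = colMeans(ps$sim$H_e),
                                    network_rate_sustainer = colMeans(ps$sim$Hh_e)),
                     file.path(out, "network_rates.csv"), row.names = FALSE)
    summary_json <- list(
      latency_ms = if (is.na(ps$latency)) NULL else 1000 * ps$latency,
      decoded = as.list(ps$pitch)
    )
    jsonlite::write_json(summary_json, file.path(out, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    fig <- ggplot2::autoplot(ps)
  } else if (etype == "irn_sweep") {
    ex <- run_irn_latency_sweep(delays = config$experiment$delays_ms / 1000,
                                iterations = config$stimulus$iterations,
                                n_runs = config$experiment$n_runs,
                                config = config$model, seed = seed,
                                band = config$stimulus$band,
                                noise_dur = config$stimulus$noise_dur_s,
                                pitch_dur = config$stimulus$duration_s)
    utils::write.csv(ex$runs, file.path(out, "runs.csv"), row.names = FALSE)
    utils::write.csv(ex$summary, file.path(out, "summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(ex$summary, file.path(out, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    fig <- ggplot2::autoplot(ex)
  } else {
    ex <- run_dyad_experiment(intervals = config$experiment$intervals,
                              T0 = config$stimulus$delay_T0_ms / 1000,
                              n_runs = config$experiment$n_runs,
                              config = config$model, seed = seed,
                              iterations = config$stimulus$iterations,
                              band = config$stimulus$band,
                              tuning = config$stimulus$tuning,
                              noise_dur = config$stimulus$noise_dur_s,
                              pitch_dur = config$stimulus$duration_s)
    utils::write.csv(ex$runs, file.path(out, "runs.csv"), row.names = FALSE)
    utils::write.csv(ex$summary, file.path(out, "summary.csv"),
                     row.names = FALSE)
    cmp <- compare_consonance(ex)
    jsonlite::write_json(list(summary = ex$summary,
                              consonance = list(W = cmp$W, p = cmp$p.value)),
                         file.path(out, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    fig <- ggplot2::autoplot(ex)
  }
  ggplot2::ggsave(file.path(out, "figure.png"), fig, width = 7, height = 4,
                  dpi = 120)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out)
}
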