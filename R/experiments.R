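# Deterministic seed substreams: one global seed fans out to independent
# per-condition, per-run seeds through an integer hash, so adding or
# reordering conditions never shifts another condition's draws.
derive_seed <- function(seed, label, run, stream = 0L) {
  h <- 0
  for (ch in utf8ToInt(as.character(label))) h <- (h * 31 + ch) %% 1e6
  s <- (as.numeric(seed) * 48271 + h * 2017 + run * 7919 + stream * 104729) %%
    2147483647
  as.integer(max(1, s))
}

# One seeded model run for a single-IRN condition: fresh source noise and
# fresh precursor per run, band-matched; returns latency and decode.
run_single_irn_once <- function(delay, iterations, band, config, seed,
                                noise_dur = 0.75, pitch_dur = 0.75,
                                level = 80) {
  spec <- stimulus_spec(kind = "irn", delay_T0 = delay,
                        iterations = iterations, band_low = band[1],
                        band_high = band[2], duration = pitch_dur,
                        level = level, seed = derive_seed(seed, "irn", 1L, 1L))
  irn <- generate_irn(spec)
  wave <- make_noise_pitch_sequence(noise_dur, irn, band_low = band[1],
                                    band_high = band[2], level = level,
                                    noise_seed = derive_seed(seed, "noise", 1L, 2L))
  run_pitch_model(wave, config, mode = "single",
                  seed = derive_seed(seed, "cortex", 1L, 3L))
}

run_dyad_once <- function(interval, T0, iterations, band, tuning, config,
                          seed, noise_dur = 0.75, pitch_dur = 0.75,
                          level = 80) {
  dy <- dyad_spec(interval, tuning = tuning)
  spec <- stimulus_spec(kind = "dyad_irn", delay_T0 = T0,
                        iterations = iterations, band_low = band[1],
                        band_high = band[2], duration = pitch_dur,
                        level = level, seed = derive_seed(seed, interval, 1L, 1L))
  dyad_wave <- generate_dyad_irn(spec, dy)
  wave <- make_noise_pitch_sequence(noise_dur, dyad_wave, band_low = band[1],
                                    band_high = band[2], level = level,
                                    noise_seed = derive_seed(seed, interval, 1L, 2L))
  run_pitch_model(wave, config, mode = "dyad",
                  seed = derive_seed(seed, interval, 1L, 3L))
}

summarise_runs <- function(runs) {
  runs |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_decided = sum(!is.na(.data$latency_ms)),
      mean_latency_ms = mean(.data$latency_ms, na.rm = TRUE),
      sd_latency_ms = stats::sd(.data$latency_ms, na.rm = TRUE),
      se_latency_ms = .data$sd_latency_ms / sqrt(.data$n_decided),
      .groups = "drop"
    )
}

#' Latency sweep over single IRN tones
#'
#' Runs the full model on noise-preceded IRN tones, either across comb
#' delays at fixed iteration count or across iteration counts at fixed
#' delay, with fresh stimulus noise per run, and collects POR latencies.
#' The reference presets mirror the single-IRN experiments: 16 iterations
#' with varying delay, or a 16 ms delay with varying iterations, both
#' band-passed 0.8-3.2 kHz.
#'
#' @param delays Comb delays in seconds (one condition each).
#' @param iterations Iteration counts; scalar (shared) or one per condition
#'   when `delays` is scalar.
#' @param n_runs Seeded runs per condition.
#' @param config A [model_config()].
#' @param seed Global seed; per-run seeds are derived deterministically.
#' @param band Stimulus band in Hz.
#' @param noise_dur,pitch_dur Segment durations in seconds.
#' @return A `por_experiment` object; see [tidy.por_experiment()].
#' @export
run_irn_latency_sweep <- function(delays = c(4, 8, 12, 16) * 1e-3,
                                  iterations = 16L, n_runs = 10L,
                                  config = model_config(), seed = 1L,
                                  band = c(800, 3200), noise_dur = 0.75,
                                  pitch_dur = 0.75) {
  if (length(delays) > 1L && length(iterations) > 1L) {
    stop("vary either `delays` or `iterations`, not both", call. = FALSE)
  }
  conds <- if (length(iterations) > 1L) {
    tibble::tibble(condition = sprintf("its%d", iterations),
                   delay = delays, iterations = as.integer(iterations))
  } else {
    tibble::tibble(condition = sprintf("T%.3gms", 1000 * delays),
                   delay = delays, iterations = as.integer(iterations))
  }
  rows <- list()
  for (ci in seq_len(nrow(conds))) {
    for (r in seq_len(n_runs)) {
      run_seed <- derive_seed(seed, conds$condition[ci], r)
      ps <- run_single_irn_once(conds$delay[ci], conds$iterations[ci], band,
                                config, run_seed, noise_dur, pitch_dur)
      dec <- if (nrow(ps$pitch)) ps$pitch$period[1] else NA_real_
      rows[[length(rows) + 1L]] <- tibble::tibble(
        condition = conds$condition[ci], delay_ms = 1000 * conds$delay[ci],
        iterations = conds$iterations[ci], run = r, seed = run_seed,
        latency_ms = 1000 * ps$latency, decoded_period_ms = 1000 * dec)
    }
  }
  runs <- dplyr::bind_rows(rows)
  structure(list(runs = runs, summary = summarise_runs(runs),
                 kind = "irn_sweep", seed = as.integer(seed),
                 params = config$params, sacf = config$sacf),
            class = "por_experiment")
}

#' Helmholtz consonance sets
#'
#' The extended consonant (P1, M3, P4, P5, P8) and dissonant (m2, M2, TT,
#' m7, M7) interval sets used to pool latencies in the dyad experiments.
#'
#' @return A list with elements `consonant` and `dissonant`.
#' @export
consonance_sets <- function() {
  list(consonant = c("P1", "M3", "P4", "P5", "P8"),
       dissonant = c("m2", "M2", "TT", "m7", "M7"))
}

#' Latency experiment over IRN dyads
#'
#' Runs the model on noise-preceded IRN dyads for a set of chromatic
#' intervals above a fixed lower note (default 160 Hz, i.e. `T0 = 6.25` ms;
#' 8 comb iterations, band 125-2000 Hz), collecting the POR latency and the
#' decoded periods of each run. Consonance classes are attached from the
#' dyad table.
#'
#' @param intervals Interval names (default: the 13 chromatic intervals).
#' @param T0 Lower-note delay in seconds.
#' @param n_runs Seeded runs per interval.
#' @param config A [model_config()].
#' @param seed Global seed.
#' @param iterations Comb iterations.
#' @param band Stimulus band in Hz.
#' @param tuning `"just"` or `"equal"`.
#' @param noise_dur,pitch_dur Segment durations in seconds.
#' @return A `por_experiment` object.
#' @export
run_dyad_experiment <- function(intervals = dyad_table()$interval,
                                T0 = 6.25e-3, n_runs = 10L,
                                config = model_config(), seed = 1L,
                                iterations = 8L, band = c(125, 2000),
                                tuning = c("just", "equal"),
                                noise_dur = 0.75, pitch_dur = 0.75) {
  tuning <- match.arg(tuning)
  tab <- dyad_table()
  rows <- list()
  for (iv in intervals) {
    cls <- tab$class[tab$interval == iv]
    for (r in seq_len(n_runs)) {
      run_seed <- derive_seed(seed, iv, r)
      ps <- run_dyad_once(iv, T0, iterations, band, tuning, config, run_seed,
                          noise_dur, pitch_dur)
      per <- sort(ps$pitch$period, decreasing = TRUE)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        condition = iv, class = cls, tuning = tuning, run = r,
        seed = run_seed, latency_ms = 1000 * ps$latency,
        decoded_low_ms = if (length(per) >= 1) 1000 * per[1] else NA_real_,
        decoded_high_ms = if (length(per) >= 2) 1000 * per[2] else NA_real_)
    }
  }
  runs <- dplyr::bind_rows(rows)
  runs$condition <- factor(runs$condition, levels = intervals)
  structure(list(runs = runs, summary = summarise_runs(runs),
                 kind = "dyads", seed = as.integer(seed), T0 = T0,
                 tuning = tuning, params = config$params,
                 sacf = config$sacf),
            class = "por_experiment")
}

#' @export
print.por_experiment <- function(x, ...) {
  cat(sprintf("<por_experiment> %s, %d runs, global seed %d\n", x$kind,
              nrow(x$runs), x$seed))
  print(x$summary, n = Inf)
  invisible(x)
}

#' Per-run results of a latency experiment
#'
#' @param x A `por_experiment`.
#' @param ... Unused.
#' @return The per-run tibble (one row per seeded model run).
#' @method tidy por_experiment
#' @export
tidy.por_experiment <- function(x, ...) x$runs

#' One-row-per-condition summary of a latency experiment
#'
#' @param x A `por_experiment`.
#' @param ... Unused.
#' @return A tibble with mean, SD and SE of the latency per condition and
#'   the number of runs that produced a decision.
#' @method glance por_experiment
#' @export
glance.por_experiment <- function(x, ...) x$summary

#' One-tailed Wilcoxon rank-sum test
#'
#' Rank-sum statistic `W` (sum of the midranks of `x` in the pooled sample)
#' with an exact p-value by complete enumeration of rank assignments when
#' both samples have at most 10 observations, and a normal approximation
#' with tie correction and continuity correction otherwise.
#'
#' @param x,y Numeric samples.
#' @param alternative `"less"` (x tends smaller than y), `"greater"`, or
#'   `"two.sided"`.
#' @return A list with `W`, `p.value`, `n_x`, `n_y`, `exact`.
#' @export
rank_sum_test <- function(x, y, alternative = c("less", "greater",
                                                "two.sided")) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both samples must be non-empty", call. = FALSE)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  ranks <- rank(c(x, y))   # midranks for ties
  W <- sum(ranks[seq_len(n1)])

  if (max(n1, n2) <= 10L) {
    combs <- utils::combn(N, n1)
    Ws <- colSums(matrix(ranks[combs], nrow = n1))
    p_le <- mean(Ws <= W)
    p_ge <- mean(Ws >= W)
    p <- switch(alternative,
                less = p_le, greater = p_ge,
                two.sided = min(1, 2 * min(p_le, p_ge)))
    return(list(W = W, p.value = p, n_x = n1, n_y = n2, exact = TRUE))
  }

  mu <- n1 * (N + 1) / 2
  ties <- table(ranks)
  tie_corr <- sum(ties^3 - ties) / (N * (N - 1))
  sig2 <- n1 * n2 / 12 * ((N + 1) - tie_corr)
  z_less <- (W - mu + 0.5) / sqrt(sig2)
  z_greater <- (W - mu - 0.5) / sqrt(sig2)
  p <- switch(alternative,
              less = stats::pnorm(z_less),
              greater = stats::pnorm(z_greater, lower.tail = FALSE),
              two.sided = min(1, 2 * min(stats::pnorm(z_less),
                                         stats::pnorm(z_greater,
                                                      lower.tail = FALSE))))
  list(W = W, p.value = p, n_x = n1, n_y = n2, exact = FALSE)
}

#' Consonant-versus-dissonant latency comparison
#'
#' Pools per-run latencies of a dyad experiment over a consonant and a
#' dissonant interval set and tests whether consonant latencies are
#' stochastically smaller (one-tailed rank-sum).
#'
#' @param experiment A `por_experiment` from [run_dyad_experiment()].
#' @param consonant,dissonant Interval name sets (defaults:
#'   [consonance_sets()]).
#' @return A list with the pooled samples, `W` and `p.value`.
#' @export
compare_consonance <- function(experiment,
                               consonant = consonance_sets()$consonant,
                               dissonant = consonance_sets()$dissonant) {
  runs <- experiment$runs
  lc <- runs$latency_ms[runs$condition %in% consonant & !is.na(runs$latency_ms)]
  ld <- runs$latency_ms[runs$condition %in% dissonant & !is.na(runs$latency_ms)]
  ts <- rank_sum_test(lc, ld, alternative = "less")
  c(ts, list(consonant = lc, dissonant = ld,
             mean_consonant = mean(lc), mean_dissonant = mean(ld)))
}

#' Minimal number of harmonic inputs that activates an inhibitory ensemble
#'
#' Controlled current-injection experiment on the decoder network: a fixed
#' depolarising current is injected into the excitatory ensembles at the
#' first `k` harmonics \{T, 2T, ..., kT\} of a base period, with no
#' subcortical input and no synaptic noise, and the inhibitory ensemble at
#' the base period is monitored. The ensemble counts as activated when its
#' rate reaches `threshold` (decision-scale activity, comparable to the
#' 80-150 Hz of a committed pitch decision) within the observation window.
#' Returns the smallest `k` that activates; the reference tuning requires
#' three simultaneous harmonic inputs.
#'
#' @param config A [model_config()].
#' @param base_period Base period T in seconds (default 5 ms).
#' @param inject Injected current, nA (representative of the saturated
#'   subcortical drive during a stimulus).
#' @param k_max Largest number of harmonics tried.
#' @param duration Observation window, s.
#' @param threshold Activation threshold on the inhibitory rate, Hz.
#' @return A list with `k_min` (integer, `NA` if none activates) and the
#'   peak inhibitory rate per `k`.
#' @export
harmonics_to_activate <- function(config = model_config(),
                                  base_period = 5e-3, inject = 0.30,
                                  k_max = 4L, duration = 0.4,
                                  threshold = 50) {
  p <- config$params
  p$sigma <- 0
  n <- config$grid$n
  base_col <- nearest_column(config$grid, base_period)
  peaks <- numeric(k_max)
  steps <- round(duration / p$dt)
  for (k in seq_len(k_max)) {
    cols <- nearest_column(config$grid, base_period * seq_len(k))
    inj <- numeric(n)
    inj[cols] <- inject
    sim <- simulate_cortex(matrix(0, n, steps), config$conn, p, seed = 1L,
                           settle = 0.2,
                           inject = function(t) {
                             if (t > 0) list(e = inj) else list()
                           })
    peaks[k] <- max(sim$H_i[base_col, sim$time > 0])
  }
  k_min <- which(peaks >= threshold)
  list(k_min = if (length(k_min)) min(k_min) else NA_integer_,
       peak_rates = peaks)
}
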