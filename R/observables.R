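#' Equivalent dipole moment of the decoder network
#'
#' Under the assumption that all microcolumns share a similar orientation,
#' the neuromagnetic field elicited by the decoder network is monotonically
#' related to its collective excitatory activity: the dipole moment is the
#' column sum of the decoder excitatory rates, reported on a time axis
#' shifted by the subcortical processing delay (50 ms for single tones,
#' 75 ms for dyads), so that latencies read off `m(t)` are directly
#' comparable with measured POR latencies.
#'
#' @param sim A `cortical_sim` from [simulate_cortex()].
#' @param delay Subcortical delay in seconds (e.g. `params$delay_single`).
#' @return A tibble with columns `time` (s, stimulus clock plus delay) and
#'   `m` (summed rate, Hz).
#' @export
dipole_moment <- function(sim, delay = sim$params$delay_single) {
  stopifnot(inherits(sim, "cortical_sim"))
  tibble::tibble(time = sim$time + delay, m = colSums(sim$H_e))
}

#' POR latency from the dipole moment
#'
#' The predicted pitch-onset-response latency is the time of the maximum of
#' the dipole moment within an analysis window after pitch onset (default
#' 0-350 ms), the moment at which the network commits to a pitch decision.
#' Ties break to the earliest sample. Runs in which the windowed maximum
#' does not exceed the prominence floor (a fraction of the trace's dynamic
#' range) are flagged as "no decision" and return `NA`.
#'
#' @param m A tibble from [dipole_moment()] (columns `time`, `m`), or a
#'   numeric vector with a matching `time` argument.
#' @param pitch_onset Pitch onset on the same clock as `m$time`, in seconds.
#'   Note the subcortical delay is already folded into `m$time`.
#' @param window Analysis window relative to pitch onset, seconds.
#' @param prominence Fraction of the whole-trace dynamic range that the
#'   windowed peak must exceed (above the trace minimum).
#' @param time Time axis when `m` is a bare vector.
#' @param smooth Width (s) of the centred moving average applied before
#'   peak picking; evoked-field latencies are conventionally read from
#'   low-pass-filtered (1-20 Hz) source waveforms, and the equivalent
#'   smoothing stabilises the argmax against integration-step jitter.
#'   Set 0 to disable.
#' @param pick `"argmax"` (default) reports the strict windowed maximum;
#'   `"first_prominent"` instead reports the earliest local maximum
#'   reaching at least `frac` of the windowed maximum.
#' @param frac Fraction of the windowed maximum a local peak must reach
#'   under `pick = "first_prominent"`.
#' @return Latency in seconds relative to pitch onset, or `NA` (no decision).
#' @export
extract_por_latency <- function(m, pitch_onset, window = c(0, 0.350),
                                prominence = 0.1, time = NULL,
                                smooth = 0.025,
                                pick = c("argmax", "first_prominent"),
                                frac = 0.8) {
  pick <- match.arg(pick)
  if (is.data.frame(m)) {
    time <- m$time
    m <- m$m
  }
  if (is.null(time)) stop("need a time axis", call. = FALSE)
  if (smooth > 0 && length(time) > 3L) {
    dt <- stats::median(diff(time))
    w <- max(1L, round(smooth / dt))
    if (w > 1L) {
      ms <- stats::filter(m, rep(1 / w, w), sides = 2)
      m <- ifelse(is.na(ms), m, as.numeric(ms))
    }
  }
  sel <- which(time >= pitch_onset + window[1] & time <= pitch_onset + window[2])
  if (!length(sel)) stop("analysis window lies outside the record", call. = FALSE)
  rng <- range(m)
  floor_val <- rng[1] + prominence * (rng[2] - rng[1])
  peak <- max(m[sel])
  flat <- (rng[2] - rng[1]) <= 1e-9 * (abs(rng[2]) + 1e-12)
  if (!(peak > floor_val) || flat) return(NA_real_)
  if (pick == "argmax") {
    i <- sel[which.max(m[sel])] # which.max takes the earliest of exact ties
    return(time[i] - pitch_onset)
  }
  ms <- m[sel]
  nw <- length(ms)
  thr <- rng[1] + frac * (peak - rng[1])
  is_pk <- c(FALSE, ms[2:(nw - 1)] >= ms[1:(nw - 2)] &
               ms[2:(nw - 1)] > ms[3:nw], FALSE)
  is_pk[nw] <- ms[nw] > ms[nw - 1]    # rising into the window edge
  cand <- which(is_pk & ms >= thr)
  i <- if (length(cand)) sel[cand[1]] else sel[which.max(ms)]
  time[i] - pitch_onset
}

#' Decode pitch(es) from the decoder inhibitory profile
#'
#' The decoded pitch is read from the time-averaged profile of the decoder
#' inhibitory ensembles in a window after the decision (default 250-300 ms
#' post onset): local maxima are prominence-filtered (10% of the profile
#' dynamic range) and the top `max_pitches` by height are returned as
#' periods on the lag grid.
#'
#' @param sim A `cortical_sim`.
#' @param window Averaging window relative to `onset`, seconds.
#' @param max_pitches Number of pitches to report (1 single tones, 2 dyads).
#' @param onset Window reference on the simulation clock, s (default: the
#'   `pitch_onset` marker if present, else 0).
#' @param prominence Fraction of the profile dynamic range a peak must rise
#'   above the profile minimum.
#' @param min_rate Absolute floor (Hz) a peak must reach: a committed
#'   decision drives the winning inhibitory ensemble to tens of Hz, so
#'   residual leakage through single harmonic connections (a few Hz) does
#'   not count as a decoded pitch.
#' @param sub_dominance A winner must also have beaten its subharmonic
#'   templates: the inhibitory ensembles at P/2 and P/3 receive the
#'   candidate's harmonic series as their own harmonics, so after a real
#'   winner-take-all decision they are largely silenced, whereas an
#'   undecided ridge (e.g. a period beyond the decodable range) leaves
#'   them comparably active. The candidate peak must exceed
#'   `sub_dominance` times the profile at its subharmonic columns.
#' @return A tibble with columns `period` (s), `frequency` (Hz), `rate`
#'   (profile height, Hz); zero rows if no peak qualifies ("no pitch").
#' @export
decode_pitch <- function(sim, window = c(0.250, 0.300), max_pitches = 1L,
                         onset = NULL, prominence = 0.1, min_rate = 10,
                         sub_dominance = 1.5) {
  stopifnot(inherits(sim, "cortical_sim"))
  if (is.null(onset)) {
    onset <- if ("pitch_onset" %in% names(sim$markers)) {
      sim$markers[["pitch_onset"]]
    } else 0
  }
  sel <- which(sim$time >= onset + window[1] & sim$time <= onset + window[2])
  if (!length(sel)) stop("decode window lies outside the simulation", call. = FALSE)
  prof <- rowMeans(sim$H_i[, sel, drop = FALSE])
  n <- length(prof)
  empty <- function() {
    out <- tibble::tibble(period = numeric(0), frequency = numeric(0),
                          rate = numeric(0))
    attr(out, "n_candidates") <- 0L
    out
  }
  rng <- range(prof)
  if (rng[2] <= rng[1]) return(empty())
  floor_val <- max(rng[1] + prominence * (rng[2] - rng[1]), min_rate)
  is_peak <- c(FALSE, prof[2:(n - 1)] >= prof[1:(n - 2)] &
                 prof[2:(n - 1)] > prof[3:n], FALSE)
  # grid-edge columns count as peaks if they dominate their neighbour
  is_peak[1] <- prof[1] > prof[2]
  is_peak[n] <- prof[n] > prof[n - 1]
  idx <- which(is_peak & prof >= floor_val)
  n_candidates <- length(idx)
  if (length(idx) && sub_dominance > 0) {
    keep <- vapply(idx, function(i) {
      P <- sim$grid$lags[i]
      subs <- c(P / 2, P / 3)
      subs <- subs[subs >= sim$grid$lags[1] - sim$grid$step / 2]
      if (!length(subs)) return(TRUE)
      cols <- unique(pmin(n, pmax(1L, rep(nearest_column(sim$grid, subs),
                                          each = 3L) + (-1:1))))
      prof[i] > sub_dominance * max(prof[cols])
    }, logical(1))
    idx <- idx[keep]
  }
  if (!length(idx)) {
    out <- empty()
    attr(out, "n_candidates") <- n_candidates
    return(out)
  }
  idx <- idx[order(prof[idx], decreasing = TRUE)]
  idx <- utils::head(idx, max_pitches)
  out <- tibble::tibble(period = sim$grid$lags[idx],
                        frequency = 1 / sim$grid$lags[idx],
                        rate = prof[idx])
  # candidate peaks before the subharmonic-dominance filter: evidence that
  # the network committed to something, used by the no-decision flagging
  attr(out, "n_candidates") <- n_candidates
  out
}

#' Model configuration bundle
#'
#' Gathers the front-end and network configuration used by the pipeline and
#' experiment runners, so that the channel bank, lag grid and connectivity
#' matrices are built once and reused across runs.
#'
#' @param params A [cortical_params()].
#' @param sacf A [sacf_params()].
#' @param bank A [channel_bank()].
#' @param grid A [lag_grid()].
#' @param conn Optional precomputed [build_connectivity()]; built on demand.
#' @return A list of class `model_config`.
#' @export
model_config <- function(params = cortical_params(), sacf = sacf_params(),
                         bank = channel_bank(), grid = lag_grid(),
                         conn = NULL) {
  if (is.null(conn)) conn <- build_connectivity(grid, params)
  structure(list(params = params, sacf = sacf, bank = bank, grid = grid,
                 conn = conn),
            class = "model_config")
}

#' Run the full pitch-processing pipeline on one waveform
#'
#' Waveform -> auditory-nerve probabilities -> SACF -> regularisation ->
#' decoder/sustainer simulation -> observables. The waveform should carry a
#' `pitch_onset` marker (see [make_noise_pitch_sequence()]); otherwise the
#' stimulus onset is used as the latency reference.
#'
#' @param wave A [waveform()].
#' @param config A [model_config()].
#' @param mode `"single"` or `"dyad"` (selects SACF rescale and subcortical
#'   delay).
#' @param seed Integer seed for the cortical synaptic noise.
#' @param tail Input tail appended after the stimulus, s (the network is
#'   observed beyond the stimulus).
#' @param max_pitches Pitches to decode (default 1 single / 2 dyad).
#' @return A list of class `pitch_sim`: the `cortical_sim` (`sim`), the
#'   regularised SACF (`sacf`), dipole tibble (`dipole`), `latency` (s,
#'   relative to pitch onset, `NA` for no decision) and `pitch` (decoded
#'   tibble).
#' @export
run_pitch_model <- function(wave, config = model_config(),
                            mode = c("single", "dyad"), seed = 1L,
                            tail = 0.35, max_pitches = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(wave, "waveform"), inherits(config, "model_config"))
  if (is.null(max_pitches)) max_pitches <- if (mode == "dyad") 2L else 1L

  an <- auditory_nerve_probability(wave, config$bank)
  sacf <- compute_sacf(an, config$grid, config$sacf, dt_out = config$params$dt)
  sacf <- regularize(sacf, config$sacf, mode = mode)
  if (tail > 0) {
    n_tail <- round(tail / config$params$dt)
    sacf$Ahat <- cbind(sacf$Ahat, matrix(0, nrow(sacf$Ahat), n_tail))
  }
  sim <- simulate_cortex(sacf, config$conn, config$params, seed = seed)

  delay <- if (mode == "dyad") config$params$delay_dyad else
    config$params$delay_single
  dip <- dipole_moment(sim, delay)
  onset <- if ("pitch_onset" %in% names(sim$markers)) {
    sim$markers[["pitch_onset"]]
  } else 0
  latency <- extract_por_latency(dip, pitch_onset = onset)
  pitch <- decode_pitch(sim, max_pitches = max_pitches, onset = onset)
  # a run without any candidate decision peak never committed: its dipole
  # maximum does not time a decision, so the latency is flagged NA
  n_cand <- attr(pitch, "n_candidates")
  if (is.null(n_cand)) n_cand <- nrow(pitch)
  if (n_cand == 0L) latency <- NA_real_

  structure(list(sim = sim, sacf = sacf, dipole = dip, latency = latency,
                 pitch = pitch, mode = mode, seed = as.integer(seed)),
            class = "pitch_sim")
}

#' @export
print.pitch_sim <- function(x, ...) {
  cat(sprintf("<pitch_sim> mode = %s, seed = %d\n", x$mode, x$seed))
  if (is.na(x$latency)) {
    cat("POR latency: no decision\n")
  } else {
    cat(sprintf("POR latency: %.1f ms after pitch onset\n", 1000 * x$latency))
  }
  if (nrow(x$pitch)) {
    cat("decoded pitch:",
        paste(sprintf("%.1f Hz (T = %.2f ms)", x$pitch$frequency,
                      1000 * x$pitch$period), collapse = ", "), "\n")
  } else {
    cat("decoded pitch: none\n")
  }
  invisible(x)
}
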