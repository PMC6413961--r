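#' Stimulus specification
#'
#' Collects every synthesis parameter used by the stimulus generators.
#' Iterated rippled noise (IRN) is produced by a delay-and-add filter applied
#' to white noise: the signal is `s(t) = sum_{n=0}^{its-1} g^n s0(t - n T)`,
#' eliciting a pitch at `1/T` whose salience grows with the number of
#' iterations. Dyads apply the same comb to two delays `T0` and `T1` drawn
#' from the same source noise.
#'
#' @param kind One of `"irn"`, `"dyad_irn"`, `"pure_tone"`,
#'   `"harmonic_complex"`, `"click_train"`, `"noise"`.
#' @param delay_T0 Delay of the (lower-note) comb filter in seconds.
#' @param delay_T1 Delay of the upper note (dyads only), seconds. Usually
#'   derived from a [dyad_spec()] rather than set directly.
#' @param iterations Number of delay-and-add iterations (>= 1).
#' @param gain Comb-filter gain `g` in \[0, 1\].
#' @param band_low,band_high Band-pass edges in Hz (`band_high` must stay
#'   below the Nyquist frequency); `NULL` to skip filtering.
#' @param duration Duration in seconds.
#' @param level Presentation level in dB SPL (see [set_level()]).
#' @param sample_rate Sampling rate in Hz; the experiments use 48000 Hz.
#' @param seed Integer seed for the source noise; same seed and spec give a
#'   bit-identical waveform.
#' @return A list of class `stimulus_spec`.
#' @export
stimulus_spec <- function(kind = "irn", delay_T0 = 8e-3, delay_T1 = NULL,
                          iterations = 16L, gain = 1, band_low = 800,
                          band_high = 3200, duration = 0.75, level = 80,
                          sample_rate = 48000, seed = 1L) {
  kinds <- c("irn", "dyad_irn", "pure_tone", "harmonic_complex",
             "click_train", "noise")
  kind <- match.arg(kind, kinds)
  iterations <- as.integer(iterations)
  if (iterations < 1L) stop("`iterations` must be >= 1", call. = FALSE)
  if (gain < 0 || gain > 1) stop("`gain` must lie in [0, 1]", call. = FALSE)
  if (!is.null(delay_T0) && (delay_T0 <= 0 || delay_T0 > duration)) {
    stop("`delay_T0` must satisfy 0 < delay <= duration", call. = FALSE)
  }
  if (!is.null(delay_T1) && (delay_T1 <= 0 || delay_T1 > duration)) {
    stop("`delay_T1` must satisfy 0 < delay <= duration", call. = FALSE)
  }
  if (!is.null(band_low)) {
    if (band_low >= band_high) stop("`band_low` must be < `band_high`", call. = FALSE)
    if (band_high >= sample_rate / 2) {
      stop("`band_high` must be below the Nyquist frequency", call. = FALSE)
    }
  }
  structure(list(kind = kind, delay_T0 = delay_T0, delay_T1 = delay_T1,
                 iterations = iterations, gain = gain, band_low = band_low,
                 band_high = band_high, duration = duration, level = level,
                 sample_rate = sample_rate, seed = as.integer(seed)),
            class = "stimulus_spec")
}

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so stimulus synthesis never perturbs other draws.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Zero-phase band-pass: 4th-order Butterworth run forward and backward
# (signal::filtfilt), so filtering adds no group delay that would bias the
# latency estimates downstream.
bandpass <- function(x, sample_rate, band_low, band_high) {
  if (is.null(band_low) || is.null(band_high)) return(x)
  ny <- sample_rate / 2
  bf <- signal::butter(2, c(band_low, band_high) / ny, type = "pass")
  signal::filtfilt(bf, x)
}

#' Dyad interval table
#'
#' The 13 intervals of the chromatic scale (unison to octave) with their just
#' intonation frequency ratios, equal-temperament semitone counts and
#' consonance class: perfect consonant (PC), imperfect consonant (IC) or
#' dissonant (D), following Western music theory and the Helmholtz ordering.
#'
#' @return A tibble with columns `interval`, `semitones`, `ratio_num`,
#'   `ratio_den`, `class`.
#' @export
dyad_table <- function() {
  tibble::tibble(
    interval  = c("P1", "m2", "M2", "m3", "M3", "P4", "TT",
                  "P5", "m6", "M6", "m7", "M7", "P8"),
    semitones = 0:12,
    ratio_num = c(1, 16, 9, 6, 5, 4, 45, 3, 8, 5, 16, 15, 2),
    ratio_den = c(1, 15, 8, 5, 4, 3, 32, 2, 5, 3,  9,  8, 1),
    class     = c("PC", "D", "D", "IC", "IC", "PC", "D",
                  "PC", "IC", "IC", "D", "D", "PC")
  )
}

#' Dyad specification
#'
#' Resolves an interval name into the frequency ratio of the dyad's upper note
#' relative to its lower note, under just intonation (small-integer ratios) or
#' equal temperament (`2^(semitones/12)`).
#'
#' @param interval Interval name: one of P1, m2, M2, m3, M3, P4, TT, P5, m6,
#'   M6, m7, M7, P8.
#' @param tuning `"just"` or `"equal"`.
#' @return A list of class `dyad_spec` with fields `interval`, `ratio`,
#'   `class`, `tuning`.
#' @export
dyad_spec <- function(interval, tuning = c("just", "equal")) {
  tuning <- match.arg(tuning)
  tab <- dyad_table()
  row <- tab[tab$interval == interval, ]
  if (nrow(row) != 1L) {
    stop(sprintf("unknown interval '%s'; valid intervals: %s", interval,
                 paste(tab$interval, collapse = ", ")), call. = FALSE)
  }
  ratio <- if (tuning == "just") row$ratio_num / row$ratio_den else
    2^(row$semitones / 12)
  structure(list(interval = interval, ratio = ratio, class = row$class,
                 semitones = row$semitones, tuning = tuning),
            class = "dyad_spec")
}

#' Upper-note frequency of a dyad
#'
#' @param dyad A [dyad_spec()].
#' @param delay_T0 Lower-note delay in seconds (the experiments use 6.25 ms,
#'   i.e. a 160 Hz lower note).
#' @return Upper-note frequency in Hz (`ratio / T0`).
#' @export
dyad_upper_frequency <- function(dyad, delay_T0 = 6.25e-3) {
  stopifnot(inherits(dyad, "dyad_spec"))
  dyad$ratio / delay_T0
}

# Delay-and-add comb on continuous noise. `s0` must carry `pre` samples of
# pre-roll so every delayed copy reads real noise: the comb is in steady state
# from the first output sample (no periodicity build-up at segment onset).
# Returns out[i] = sum_d sum_k g^k s0[i + pre - k*d], i = 1..n.
delay_add <- function(s0, n, delays_samp, iterations, gain, pre) {
  out <- numeric(n)
  for (d in delays_samp) {
    for (k in seq_len(iterations) - 1L) {
      shift <- k * d
      if (shift > pre) {
        stop(sprintf(paste0("delay of %d samples times iteration %d exceeds ",
                            "the pre-roll buffer (offending parameter: ",
                            "delay_T)"), d, k), call. = FALSE)
      }
      out <- out + gain^k * s0[(pre - shift + 1L):(pre - shift + n)]
    }
  }
  out
}

#' Generate an iterated rippled noise tone
#'
#' Applies the delay-and-add filter `s(t) = sum_{n=0}^{its-1} g^n s0(t - nT)`
#' to seeded white noise and band-pass filters the result (zero-phase
#' Butterworth). With `iterations = 1` or `gain = 0` the output is plain
#' filtered noise.
#'
#' @param spec A [stimulus_spec()] with `kind = "irn"`.
#' @return A [waveform()] with markers `onset` and `offset` (uncalibrated;
#'   apply [set_level()] or assemble with [make_noise_pitch_sequence()]).
#' @export
generate_irn <- function(spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  if (spec$kind != "irn") stop("spec$kind must be 'irn'", call. = FALSE)
  fs <- spec$sample_rate
  n <- round(spec$duration * fs)
  d <- round(spec$delay_T0 * fs)
  if (d >= n) {
    stop(sprintf("delay_T0 (%g s) does not fit in the %g s buffer",
                 spec$delay_T0, spec$duration), call. = FALSE)
  }
  pre <- (spec$iterations - 1L) * d
  x <- with_seed(spec$seed, {
    # main segment drawn first: the undelayed term (and hence the
    # iterations = 1 / gain = 0 degenerate cases) is pre-roll-invariant
    main <- stats::rnorm(n)
    s0 <- c(stats::rnorm(pre), main)
    delay_add(s0, n, d, spec$iterations, spec$gain, pre)
  })
  x <- bandpass(x, fs, spec$band_low, spec$band_high)
  waveform(x, fs, markers = c(onset = 1L, offset = n))
}

#' Generate an iterated rippled noise dyad
#'
#' Both delayed copies are drawn from the same source noise:
#' `s(t) = sum_n g^n (s0(t - n T0) + s0(t - n T1))`, with `T1 = T0 / ratio`
#' given by the dyad's interval, so the two notes form the requested musical
#' interval above the `1/T0` lower note.
#'
#' @param spec A [stimulus_spec()] with `kind = "dyad_irn"` (`delay_T0` set).
#' @param dyad A [dyad_spec()].
#' @return A [waveform()] with markers `onset` and `offset`.
#' @export
generate_dyad_irn <- function(spec, dyad) {
  stopifnot(inherits(spec, "stimulus_spec"), inherits(dyad, "dyad_spec"))
  if (spec$kind != "dyad_irn") stop("spec$kind must be 'dyad_irn'", call. = FALSE)
  fs <- spec$sample_rate
  n <- round(spec$duration * fs)
  T1 <- spec$delay_T0 / dyad$ratio
  d0 <- round(spec$delay_T0 * fs)
  d1 <- round(T1 * fs)
  pre <- (spec$iterations - 1L) * max(d0, d1)
  x <- with_seed(spec$seed, {
    main <- stats::rnorm(n)
    s0 <- c(stats::rnorm(pre), main)
    delay_add(s0, n, unique(c(d0, d1)), spec$iterations, spec$gain, pre)
  })
  # unison: the two delayed copies coincide, so the comb sum counts twice
  if (d0 == d1) x <- 2 * x
  x <- bandpass(x, fs, spec$band_low, spec$band_high)
  waveform(x, fs, markers = c(onset = 1L, offset = n))
}

#' Band-limited Gaussian noise
#'
#' @param duration Seconds.
#' @param band_low,band_high Band edges in Hz (or `NULL` for white noise).
#' @param sample_rate Hz.
#' @param seed Integer seed.
#' @return A [waveform()].
#' @export
generate_noise <- function(duration, band_low = NULL, band_high = NULL,
                           sample_rate = 48000, seed = 1L) {
  n <- round(duration * sample_rate)
  x <- with_seed(seed, stats::rnorm(n))
  x <- bandpass(x, sample_rate, band_low, band_high)
  waveform(x, sample_rate, markers = c(onset = 1L, offset = n))
}

#' Assemble a noise precursor followed by a pitch-evoking segment
#'
#' Builds the energy-balanced sequence used to isolate the pitch onset
#' response: a band-matched noise segment, a raised-cosine cross-fade into the
#' pitch segment, 10 ms onset/offset ramps, and finally level calibration.
#' The cross-fade envelopes are complementary in power (`cos^2 + sin^2 = 1`),
#' so the summed squared envelope stays approximately constant through the
#' transition; the `pitch_onset` marker sits at the cross-fade midpoint.
#' The fade overlaps the boundary symmetrically, so the total duration is
#' `noise_dur + duration(pitch_wave) - fade/2` (the pitch segment's first
#' `fade` is consumed by the cross-fade ramp).
#'
#' @param noise_dur Noise precursor duration in seconds (0.75 in the
#'   experiments).
#' @param pitch_wave A [waveform()] holding the pitch segment (e.g. from
#'   [generate_irn()]).
#' @param fade Cross-fade duration in seconds (default 10 ms); 0 concatenates.
#' @param band_low,band_high Noise band; defaults should match the pitch
#'   segment's band so the precursor is energy-balanced and band-matched.
#' @param level Calibration level in dB SPL applied to the full sequence.
#' @param ramp Onset/offset raised-cosine ramp duration (default 10 ms).
#' @param noise_seed Seed for the precursor noise (fresh noise per run unless
#'   fixed).
#' @return A [waveform()] with markers `onset`, `pitch_onset`, `offset`.
#' @export
make_noise_pitch_sequence <- function(noise_dur, pitch_wave, fade = 10e-3,
                                      band_low = NULL, band_high = NULL,
                                      level = 80, ramp = 10e-3,
                                      noise_seed = 1L) {
  stopifnot(inherits(pitch_wave, "waveform"))
  fs <- pitch_wave$sample_rate
  pitch_dur <- wave_duration(pitch_wave)
  if (fade < 0) stop("`fade` must be >= 0", call. = FALSE)
  if (fade > noise_dur || fade > pitch_dur) {
    stop("`fade` must not exceed either segment duration", call. = FALSE)
  }
  nf <- round(fade * fs)
  n_noise <- round(noise_dur * fs) + nf %/% 2L
  n_pitch <- length(pitch_wave$samples)

  noise <- generate_noise(n_noise / fs, band_low, band_high, fs,
                          seed = noise_seed)$samples
  pitch <- pitch_wave$samples
  # energy balance: match the precursor RMS to the pitch segment RMS
  if (stats::sd(noise) > 0) noise <- noise * (sqrt(mean(pitch^2)) / sqrt(mean(noise^2)))

  if (nf > 0L) {
    xfrac <- (seq_len(nf) - 0.5) / nf
    env_down <- cos(pi * xfrac / 2)
    env_up <- sin(pi * xfrac / 2)
    head_pitch <- pitch[seq_len(nf %/% 2L + nf %/% 2L)]
    # overlap the last nf samples of the noise with the first nf of the pitch
    noise_tail <- noise[(n_noise - nf + 1L):n_noise] * env_down
    pitch_head <- pitch[seq_len(nf)] * env_up
    x <- c(noise[seq_len(n_noise - nf)],
           noise_tail + pitch_head,
           pitch[(nf + 1L):n_pitch])
    pitch_onset <- n_noise - nf %/% 2L
  } else {
    x <- c(noise, pitch)
    pitch_onset <- n_noise + 1L
  }

  nr <- round(ramp * fs)
  if (nr > 0L) {
    w <- 0.5 * (1 - cos(pi * (seq_len(nr) - 0.5) / nr))
    x[seq_len(nr)] <- x[seq_len(nr)] * w
    x[(length(x) - nr + 1L):length(x)] <- x[(length(x) - nr + 1L):length(x)] * rev(w)
  }

  out <- waveform(x, fs, markers = c(onset = 1L, pitch_onset = pitch_onset,
                                     offset = length(x)))
  set_level(out, level)
}

#' Pure tone
#' @param freq Frequency in Hz.
#' @param duration Seconds.
#' @param sample_rate Hz.
#' @param phase Initial phase in radians.
#' @return A [waveform()].
#' @export
generate_pure_tone <- function(freq, duration, sample_rate = 48000, phase = 0) {
  t <- (seq_len(round(duration * sample_rate)) - 1L) / sample_rate
  waveform(sin(2 * pi * freq * t + phase), sample_rate,
           markers = c(onset = 1L, offset = length(t)))
}

#' Harmonic complex tone
#'
#' Sum of equal-amplitude cosine partials at `f0 * harmonics`; omitting the
#' first harmonic yields a missing-fundamental (virtual pitch) complex.
#'
#' @param f0 Fundamental frequency in Hz.
#' @param harmonics Integer vector of harmonic numbers (e.g. `1:6`, `2:5`).
#' @param duration Seconds.
#' @param sample_rate Hz.
#' @param band_low,band_high Optional band-pass limits.
#' @return A [waveform()].
#' @export
generate_harmonic_complex <- function(f0, harmonics = 1:6, duration = 0.5,
                                      sample_rate = 48000, band_low = NULL,
                                      band_high = NULL) {
  harmonics <- as.integer(harmonics)
  if (!length(harmonics)) stop("`harmonics` must be non-empty", call. = FALSE)
  if (any(harmonics < 1L)) stop("harmonic numbers must be >= 1", call. = FALSE)
  t <- (seq_len(round(duration * sample_rate)) - 1L) / sample_rate
  x <- numeric(length(t))
  for (h in harmonics) x <- x + cos(2 * pi * h * f0 * t)
  if (!is.null(band_low)) x <- bandpass(x, sample_rate, band_low, band_high)
  waveform(x, sample_rate, markers = c(onset = 1L, offset = length(t)))
}

#' Click train
#'
#' Unit impulses at the inter-click interval; elicits the same pitch as a tone
#' with period equal to that interval.
#'
#' @param interval Inter-click interval in seconds.
#' @param duration Seconds.
#' @param sample_rate Hz.
#' @return A [waveform()].
#' @export
generate_click_train <- function(interval, duration, sample_rate = 48000) {
  n <- round(duration * sample_rate)
  idx <- seq(1L, n, by = max(1L, round(interval * sample_rate)))
  x <- numeric(n)
  x[idx] <- 1
  waveform(x, sample_rate, markers = c(onset = 1L, offset = n))
}

#' Auxiliary stimulus dispatcher
#'
#' @param kind `"pure_tone"`, `"harmonic_complex"`, `"click_train"` or
#'   `"noise"`.
#' @param ... Passed to the matching generator.
#' @return A [waveform()].
#' @export
generate_auxiliary <- function(kind, ...) {
  switch(match.arg(kind, c("pure_tone", "harmonic_complex", "click_train",
                           "noise")),
         pure_tone = generate_pure_tone(...),
         harmonic_complex = generate_harmonic_complex(...),
         click_train = generate_click_train(...),
         noise = generate_noise(...))
}

#' Normalised autocorrelation of a waveform
#'
#' Helper used throughout the tests: autocorrelation normalised by the zero-lag
#' value, returned over a lag range in seconds.
#'
#' @param wave A [waveform()].
#' @param max_lag Maximum lag in seconds.
#' @return A tibble with columns `lag` (s) and `r`.
#' @export
wave_autocorrelation <- function(wave, max_lag = 0.03) {
  x <- wave$samples - mean(wave$samples)
  n <- length(x)
  m <- round(max_lag * wave$sample_rate)
  ac <- stats::acf(x, lag.max = m, plot = FALSE, demean = FALSE)$acf[, 1, 1]
  tibble::tibble(lag = (seq_along(ac) - 1L) / wave$sample_rate, r = ac)
}
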