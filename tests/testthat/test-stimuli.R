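test_that("degenerate comb settings reduce to filtered noise", {
  base <- stimulus_spec(kind = "irn", delay_T0 = 8e-3, iterations = 1L,
                        band_low = 800, band_high = 3200, duration = 0.3,
                        seed = 3L)
  one <- generate_irn(base)

  zero_gain <- base
  zero_gain$iterations <- 8L
  zero_gain$gain <- 0
  zg <- generate_irn(zero_gain)

  # iterations = 1: only the n = 0 term survives; gain = 0 kills all delayed
  # terms, so both equal the band-passed source noise
  expect_equal(zg$samples, one$samples, tolerance = 1e-12)

  noise <- generate_noise(0.3, 800, 3200, 48000, seed = 3L)
  expect_equal(one$samples, noise$samples, tolerance = 1e-12)
})

test_that("IRN autocorrelation peaks at the comb delay and its multiples", {
  spec <- stimulus_spec(kind = "irn", delay_T0 = 8e-3, iterations = 16L,
                        band_low = 800, band_high = 3200, duration = 0.5,
                        seed = 11L)
  irn <- generate_irn(spec)
  ac <- wave_autocorrelation(irn, max_lag = 0.03)
  r8 <- ac$r[which.min(abs(ac$lag - 8e-3))]
  off <- ac$lag > 3e-3 & ac$lag < 30e-3 &
    abs((ac$lag * 1000) %% 8) > 1 & abs((ac$lag * 1000) %% 8) < 7
  expect_gt(r8, max(ac$r[off]))
})

test_that("periodicity salience is non-decreasing in iteration count", {
  mean_r <- function(its) {
    vals <- vapply(1:10, function(s) {
      spec <- stimulus_spec(kind = "irn", delay_T0 = 8e-3, iterations = its,
                            band_low = 800, band_high = 3200, duration = 0.4,
                            seed = 100L + s)
      irn <- generate_irn(spec)
      ac <- wave_autocorrelation(irn, max_lag = 0.01)
      ac$r[which.min(abs(ac$lag - 8e-3))]
    }, numeric(1))
    mean(vals)
  }
  sal <- vapply(c(1L, 4L, 8L, 16L), mean_r, numeric(1))
  expect_true(all(diff(sal) >= -1e-6))
})

test_that("same seed and spec give bit-identical waveforms", {
  spec <- stimulus_spec(kind = "irn", delay_T0 = 6e-3, iterations = 8L,
                        band_low = 125, band_high = 2000, duration = 0.25,
                        seed = 9L)
  expect_identical(generate_irn(spec)$samples, generate_irn(spec)$samples)
  dy <- dyad_spec("P5")
  spec$kind <- "dyad_irn"
  expect_identical(generate_dyad_irn(spec, dy)$samples,
                   generate_dyad_irn(spec, dy)$samples)
})

test_that("dyad table reproduces the experimental upper-note frequencies", {
  # lower note 160 Hz (T0 = 6.25 ms); rounded upper-note frequencies
  expected <- c(P1 = 160, P5 = 240, M3 = 200, TT = 225, m7 = 284, m2 = 171)
  for (iv in names(expected)) {
    f <- dyad_upper_frequency(dyad_spec(iv, tuning = "just"), 6.25e-3)
    expect_equal(round(f), unname(expected[iv]), info = iv)
  }
  # consonance classes of the six experimental conditions
  expect_equal(dyad_spec("P1")$class, "PC")
  expect_equal(dyad_spec("P5")$class, "PC")
  expect_equal(dyad_spec("M3")$class, "IC")
  expect_true(all(vapply(c("TT", "m7", "m2"),
                         function(iv) dyad_spec(iv)$class, "") == "D"))
})

test_that("unknown dyad interval errors with the valid set", {
  expect_error(dyad_spec("X9"), "valid intervals.*P1")
})

test_that("equal temperament upper notes follow 2^(k/12)", {
  for (iv in c("m2", "TT", "P5")) {
    dy <- dyad_spec(iv, tuning = "equal")
    expect_equal(dy$ratio, 2^(dy$semitones / 12))
  }
})

test_that("dyad comb uses both delays from shared source noise", {
  spec <- stimulus_spec(kind = "dyad_irn", delay_T0 = 6.25e-3,
                        iterations = 8L, band_low = 125, band_high = 2000,
                        duration = 0.5, seed = 5L)
  dy <- dyad_spec("P5")
  w <- generate_dyad_irn(spec, dy)
  ac <- wave_autocorrelation(w, max_lag = 0.012)
  T1 <- 6.25e-3 / dy$ratio
  r_t0 <- ac$r[which.min(abs(ac$lag - 6.25e-3))]
  r_t1 <- ac$r[which.min(abs(ac$lag - T1))]
  off <- ac$r[which.min(abs(ac$lag - 5.5e-3))]
  expect_gt(r_t0, off)
  expect_gt(r_t1, off)
})

test_that("noise-pitch sequence has the specified segment structure", {
  irn <- generate_irn(stimulus_spec(kind = "irn", delay_T0 = 8e-3,
                                    iterations = 16L, band_low = 800,
                                    band_high = 3200, duration = 0.75,
                                    seed = 2L))
  seq_w <- make_noise_pitch_sequence(0.75, irn, band_low = 800,
                                     band_high = 3200, level = 80,
                                     noise_seed = 4L)
  # total duration: noise + pitch minus the half-fade consumed by the ramp
  expect_equal(wave_duration(seq_w), 1.5 - 0.005, tolerance = 1e-3)
  expect_equal(marker_time(seq_w, "pitch_onset"), 0.75, tolerance = 2e-3)

  # energy balance: RMS in 50 ms windows just before vs just after the
  # transition differs by < 1 dB
  fs <- seq_w$sample_rate
  on <- seq_w$markers[["pitch_onset"]]
  pre <- seq_w$samples[(on - round(0.06 * fs)):(on - round(0.01 * fs))]
  post <- seq_w$samples[(on + round(0.01 * fs)):(on + round(0.06 * fs))]
  db <- 20 * abs(log10(sqrt(mean(pre^2)) / sqrt(mean(post^2))))
  expect_lt(db, 1)

  # no discontinuity: largest step around the transition is no bigger than
  # the largest within-segment step
  d <- abs(diff(seq_w$samples))
  around <- d[(on - 480):(on + 480)]
  expect_lte(max(around), max(d))
})

test_that("zero fade concatenates with the marker at noise_dur", {
  irn <- generate_irn(stimulus_spec(kind = "irn", delay_T0 = 8e-3,
                                    iterations = 4L, band_low = 800,
                                    band_high = 3200, duration = 0.2,
                                    seed = 2L))
  seq_w <- make_noise_pitch_sequence(0.3, irn, fade = 0, band_low = 800,
                                     band_high = 3200, noise_seed = 4L)
  expect_equal(seq_w$markers[["pitch_onset"]], round(0.3 * 48000) + 1L)
  expect_error(make_noise_pitch_sequence(0.005, irn, fade = 10e-3),
               "fade")
})

test_that("level calibration is exact, idempotent and linear", {
  tone <- generate_pure_tone(1000, 0.2)
  cal <- set_level(tone, 80)
  # closed form: 80 dB SPL re 20 uPa is an RMS of 0.2 Pa
  expect_equal(wave_rms(cal), 0.2, tolerance = 1e-9)
  expect_equal(wave_level(set_level(cal, 80)), 80, tolerance = 1e-9)
  doubled <- cal
  doubled$samples <- doubled$samples * 2
  expect_equal(wave_level(doubled) - wave_level(cal), 20 * log10(2),
               tolerance = 1e-9)
  silent <- waveform(numeric(100), 48000)
  expect_error(set_level(silent, 80), "silent")
})

test_that("auxiliary stimuli have the constructed spectra and periodicity", {
  hc <- generate_harmonic_complex(200, 1:6, duration = 0.25)
  spec <- Mod(stats::fft(hc$samples))[1:6000]
  freqs <- (seq_along(spec) - 1) / 0.25
  peaks <- freqs[order(spec, decreasing = TRUE)[1:6]]
  expect_setequal(round(sort(peaks)), round(200 * 1:6))

  # missing fundamental: no spectral energy at 200 Hz
  mf <- generate_harmonic_complex(200, 2:5, duration = 0.25)
  spec_mf <- Mod(stats::fft(mf$samples))
  i200 <- round(200 * 0.25) + 1L
  i400 <- round(400 * 0.25) + 1L
  expect_lt(spec_mf[i200], 1e-6 * spec_mf[i400])

  ct <- generate_click_train(5e-3, 0.3)
  ac <- wave_autocorrelation(ct, max_lag = 0.008)
  lag_peak <- ac$lag[ac$lag > 1e-3][which.max(ac$r[ac$lag > 1e-3])]
  expect_equal(lag_peak, 5e-3, tolerance = 1e-4)

  expect_error(generate_harmonic_complex(200, integer(0)), "non-empty")
})

test_that("WAV files round-trip through the writer and reader", {
  w <- generate_pure_tone(440, 0.05)
  w <- set_level(w, 70)
  w$markers <- c(onset = 1L, offset = length(w$samples))
  path <- tempfile(fileext = ".wav")
  write_wav(w, path, bits = 32L, spec = list(kind = "pure_tone"))
  r <- read_wav(path)
  expect_equal(r$samples, w$samples, tolerance = 1e-7)
  expect_equal(r$sample_rate, 48000)
  expect_equal(r$markers, w$markers)
  path16 <- tempfile(fileext = ".wav")
  write_wav(w, path16, bits = 16L, sidecar = FALSE)
  r16 <- read_wav(path16)
  expect_equal(r16$samples, w$samples, tolerance = 1e-3)
  unlink(c(path, paste0(path, ".json"), path16))
})

test_that("stimulus specs validate their invariants", {
  expect_error(stimulus_spec(iterations = 0), "iterations")
  expect_error(stimulus_spec(gain = 1.2), "gain")
  expect_error(stimulus_spec(delay_T0 = 1, duration = 0.5), "delay")
  expect_error(stimulus_spec(band_low = 3000, band_high = 2000), "band_low")
  expect_error(stimulus_spec(band_low = 100, band_high = 30000,
                             sample_rate = 48000), "Nyquist")
  expect_error(waveform(c(0, NA), 48000), "finite")
  expect_error(waveform(0:10, 48000, markers = c(a = 5, b = 3)),
               "increasing")
})
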