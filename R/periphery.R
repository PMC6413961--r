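#' Cochlear channel bank
#'
#' Forty channels with centre frequencies log-spaced between 125 Hz and
#' 10 kHz, mirroring the resolution of the peripheral stage feeding the
#' periodicity detectors. `internal_rate` is the rate to which the firing
#' probabilities are decimated before the autocorrelation product (10 kHz
#' keeps the shortest 0.5 ms lag representable with 5 samples).
#'
#' @param n_channels Number of channels (default 40).
#' @param f_low,f_high Centre-frequency range in Hz.
#' @param internal_rate Output rate of the firing probabilities, Hz.
#' @return A list of class `channel_bank` with the centre frequencies `cf`.
#' @export
channel_bank <- function(n_channels = 40L, f_low = 125, f_high = 10000,
                         internal_rate = 10000) {
  if (f_low <= 0 || f_high <= f_low) stop("need 0 < f_low < f_high", call. = FALSE)
  cf <- exp(seq(log(f_low), log(f_high), length.out = n_channels))
  structure(list(n_channels = as.integer(n_channels), cf = cf,
                 f_low = f_low, f_high = f_high,
                 internal_rate = internal_rate),
            class = "channel_bank")
}

# Equivalent rectangular bandwidth (Glasberg & Moore) in Hz.
erb_bandwidth <- function(f) 24.7 + 0.108 * f

# 4th-order gammatone FIR kernel at centre frequency `cf`, peak gain 1 at cf.
# The returned list carries the kernel and its envelope group delay in
# samples, used to phase-align channels so that cross-channel summation in
# the SACF does not smear periodicity onsets.
gammatone_kernel <- function(cf, fs, dur = 0.04) {
  b <- 1.019 * erb_bandwidth(cf)
  t <- (seq_len(round(dur * fs)) - 0.5) / fs
  h <- t^3 * exp(-2 * pi * b * t) * cos(2 * pi * cf * t)
  # normalise to unit magnitude response at cf
  gain <- Mod(sum(h * exp(-2i * pi * cf * t)))
  list(h = h / gain, delay = round(3 / (2 * pi * b) * fs))
}

#' Auditory-nerve firing probability
#'
#' Phenomenological front end converting a pressure waveform into per-channel
#' instantaneous firing probabilities: gammatone band-pass filtering at each
#' centre frequency, half-wave rectification, power-law compression (exponent
#' 0.3), 3 kHz low-pass smoothing (loss of phase locking above the
#' auditory-nerve limit), decimation to the
#' bank's internal rate and normalisation into \[0, 1\]. Channel outputs are
#' aligned by the gammatone envelope group delay. The stage is deterministic:
#' all stochasticity lives in the stimulus and in the cortical synapses.
#'
#' @param wave A [waveform()], at least 50 ms long.
#' @param bank A [channel_bank()].
#' @return A list of class `an_response` with fields `p` (channels x time
#'   matrix of probabilities in \[0,1\]), `rate` (Hz), `bank`, and `markers`
#'   (sample indices on the decimated time axis).
#' @export
auditory_nerve_probability <- function(wave, bank = channel_bank()) {
  stopifnot(inherits(wave, "waveform"))
  if (anyNA(wave$samples)) stop("input waveform contains NaN", call. = FALSE)
  if (wave_duration(wave) < 0.05) {
    stop("input must be at least 50 ms long", call. = FALSE)
  }
  fs <- wave$sample_rate
  x <- wave$samples
  n <- length(x)

  # shared FFT of the input, padded for linear convolution with the kernels
  klen <- round(0.04 * fs)
  nfft <- stats::nextn(n + klen, 2)
  X <- stats::fft(c(x, numeric(nfft - n)))

  # low-pass for phase-locking loss (~3 kHz limit), applied zero-phase
  lp <- signal::butter(2, min(0.99, 3000 / (fs / 2)), type = "low")

  t_out <- seq(0, (n - 1) / fs, by = 1 / bank$internal_rate)
  t_in <- (seq_len(n) - 1L) / fs
  p <- matrix(0, nrow = bank$n_channels, ncol = length(t_out))
  for (m in seq_len(bank$n_channels)) {
    kern <- gammatone_kernel(bank$cf[m], fs, dur = 0.04)
    H <- stats::fft(c(kern$h, numeric(nfft - length(kern$h))))
    y <- Re(stats::fft(X * H, inverse = TRUE)) / nfft
    # compensate the gammatone envelope delay, keep the original n samples
    i0 <- 1L + kern$delay
    y <- y[i0:(i0 + n - 1L)]
    y <- pmax(y, 0)^0.3                     # rectify + compress
    y <- signal::filtfilt(lp, y)
    y <- pmax(y, 0)
    p[m, ] <- stats::approx(t_in, y, xout = t_out, rule = 2)$y
  }

  # normalisation: global scale set by the 99th percentile of the response,
  # floored at 0.05 (in compressed-pressure units) so that silence maps to
  # p ~ 0 rather than being amplified -- the documented spontaneous-rate floor
  q <- stats::quantile(p, 0.99, names = FALSE)
  p <- p / max(q, 0.05)
  p[p > 1] <- 1

  markers <- vapply(wave$markers, function(i) {
    max(1L, min(length(t_out), 1L + as.integer(round((i - 1L) / fs * bank$internal_rate))))
  }, integer(1))
  structure(list(p = p, rate = bank$internal_rate, bank = bank,
                 markers = markers),
            class = "an_response")
}

#' @export
print.an_response <- function(x, ...) {
  cat(sprintf("<an_response> %d channels x %d samples @ %g Hz\n",
              nrow(x$p), ncol(x$p), x$rate))
  invisible(x)
}
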