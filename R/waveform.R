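#' Sampled pressure waveform
#'
#' A `waveform` is the basic audio container of the package: a numeric vector
#' of pressure samples (Pa once calibrated, arbitrary units before), a sample
#' rate, and named sample markers locating the stimulus onset, the pitch onset
#' (noise-to-tone transition) and the offset.
#'
#' @param samples Numeric vector of finite pressure samples.
#' @param sample_rate Sampling rate in Hz.
#' @param markers Named integer vector of sample indices; must be strictly
#'   increasing and lie within `[1, length(samples)]`.
#' @return An object of class `waveform`.
#' @export
waveform <- function(samples, sample_rate, markers = integer(0)) {
  if (!is.numeric(samples) || !all(is.finite(samples))) {
    stop("`samples` must be a finite numeric vector", call. = FALSE)
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0) {
    stop("`sample_rate` must be a single positive number", call. = FALSE)
  }
  nm <- names(markers)
  markers <- as.integer(round(markers))
  names(markers) <- nm
  if (length(markers)) {
    if (is.null(names(markers)) || any(!nzchar(names(markers)))) {
      stop("`markers` must be named", call. = FALSE)
    }
    if (any(markers < 1L) || any(markers > length(samples))) {
      stop("markers must lie within the sample range", call. = FALSE)
    }
    if (any(diff(markers) <= 0L)) {
      stop("markers must be strictly increasing", call. = FALSE)
    }
  }
  structure(
    list(samples = as.numeric(samples), sample_rate = sample_rate,
         markers = markers),
    class = "waveform"
  )
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples @ %g Hz (%.3f s)\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate))
  if (length(x$markers)) {
    cat("markers:",
        paste(sprintf("%s=%.1f ms", names(x$markers),
                      1000 * (x$markers - 1L) / x$sample_rate),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Duration of a waveform in seconds
#' @param wave A `waveform`.
#' @export
wave_duration <- function(wave) length(wave$samples) / wave$sample_rate

#' Time axis of a waveform in seconds (first sample at t = 0)
#' @param wave A `waveform`.
#' @export
wave_time <- function(wave) (seq_along(wave$samples) - 1L) / wave$sample_rate

#' Marker position in seconds
#' @param wave A `waveform`.
#' @param name Marker name, e.g. `"pitch_onset"`.
#' @export
marker_time <- function(wave, name) {
  if (!name %in% names(wave$markers)) {
    stop(sprintf("waveform has no marker '%s'", name), call. = FALSE)
  }
  (wave$markers[[name]] - 1L) / wave$sample_rate
}

#' Root-mean-square amplitude
#' @param wave A `waveform`.
#' @export
wave_rms <- function(wave) sqrt(mean(wave$samples^2))

#' Calibrate a waveform to a sound pressure level
#'
#' Scales the waveform so that its RMS pressure corresponds to the requested
#' level in dB SPL (re 20 uPa). The package convention is that 1.0 full scale
#' equals 1 Pa, so e.g. 80 dB SPL maps to an RMS of 0.2 Pa. Only relative
#' level matters downstream (the auditory-nerve stage is normalised), but the
#' convention pins absolute numbers for reproducibility.
#'
#' @param wave A `waveform` with nonzero RMS.
#' @param level Target level in dB SPL.
#' @return The calibrated `waveform`.
#' @export
set_level <- function(wave, level) {
  r <- wave_rms(wave)
  if (r == 0) stop("cannot calibrate a silent waveform (RMS = 0)", call. = FALSE)
  target <- 20e-6 * 10^(level / 20)
  wave$samples <- wave$samples * (target / r)
  wave
}

#' Measured level of a waveform in dB SPL
#' @param wave A `waveform`.
#' @export
wave_level <- function(wave) 20 * log10(wave_rms(wave) / 20e-6)
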