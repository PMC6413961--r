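#' Lag grid of the periodicity detectors
#'
#' 250 candidate periods uniformly spaced between 0.5 ms (a conservative
#' phase-locking limit of the auditory nerve) and 30 ms (the lower limit of
#' melodic pitch). Each lag has one leaky-integrator detector; the same grid
#' indexes the 250 cortical columns.
#'
#' @param n Number of lags (default 250).
#' @param lag_min,lag_max Lag range in seconds.
#' @return A list of class `lag_grid` with `lags` (s) and `step` (s).
#' @export
lag_grid <- function(n = 250L, lag_min = 0.5e-3, lag_max = 30e-3) {
  lags <- seq(lag_min, lag_max, length.out = n)
  structure(list(n = as.integer(n), lags = lags, step = lags[2] - lags[1]),
            class = "lag_grid")
}

#' Index of the grid column nearest a period
#' @param grid A [lag_grid()].
#' @param period Period(s) in seconds.
#' @export
nearest_column <- function(grid, period) {
  pmin(grid$n, pmax(1L, as.integer(round((period - grid$lags[1]) / grid$step)) + 1L))
}

#' SACF parameters
#'
#' Integration time constants and regularisation constants of the summary
#' autocorrelation stage. The per-lag time constant is
#' `tau_n = max(tau_floor, tau_scale * lag_n)`; `tau_scale` and `tau_floor`
#' were calibrated once so that the lag-T channel first reaches half of its
#' steady response about `1.25 T` after pitch onset for IRNs with T in
#' \{2, 8\} ms, and are held fixed thereafter. Regularisation is a divisive
#' normalisation across the lag axis with semi-saturation `k`, followed by a
#' baseline subtraction (`theta`) and an affine rescale to the input range the
#' decoder expects; single tones and dyads use separate rescale factors.
#'
#' @param tau_floor Minimum integration time constant (s).
#' @param tau_scale Slope of the lag-proportional time constant.
#' @param k Semi-saturation constant of the divisive normalisation.
#' @param theta Baseline (in units of the lag-mean) subtracted before
#'   rescaling; activity below baseline is clipped to zero.
#' @param scale_single,scale_dyad Affine rescale applied to the normalised
#'   contrast for single-pitch and dyad stimuli respectively.
#' @param baseline `"flat"` subtracts the scalar `theta` from `r`
#'   everywhere; `"precursor"` subtracts, per lag, the time average of `r`
#'   over the noise-precursor window (plus the margin `theta - 1`) when the
#'   record carries a `pitch_onset` marker.
#' @param sat Saturation of the normalised contrast (in units of `r`):
#'   contrast above baseline is clipped at `sat` before rescaling, so the
#'   cortical input saturates like the neuronal populations implementing
#'   the normalisation; this keeps the stimulus-noise flicker of strong
#'   detector channels from punching through the decoder's inhibition
#'   after a decision.
#' @return A list of class `sacf_params`.
#' @export
sacf_params <- function(tau_floor = 1.5e-3, tau_scale = 0.25, k = 0.5,
                        theta = 1.03, scale_single = 500, scale_dyad = 400,
                        sat = 0.10, baseline = c("flat", "precursor")) {
  baseline <- match.arg(baseline)
  structure(list(tau_floor = tau_floor, tau_scale = tau_scale, k = k,
                 theta = theta, scale_single = scale_single,
                 scale_dyad = scale_dyad, sat = sat, baseline = baseline),
            class = "sacf_params")
}

sacf_tau <- function(grid, params) {
  pmax(params$tau_floor, params$tau_scale * grid$lags)
}

#' Summary autocorrelation of the auditory-nerve activity
#'
#' For each candidate period `lag_n` a leaky integrator accumulates the
#' channel-summed product of the firing probability with its delayed copy:
#' `tau_n dA_n/dt = -A_n + sum_m p_m(t) p_m(t - lag_n)`. Fractional delays
#' are linearly interpolated on the internal sample grid; the integrator uses
#' the exact exponential (zero-order-hold) update. The output is resampled to
#' the 1 ms cortical step.
#'
#' @param an An `an_response` from [auditory_nerve_probability()].
#' @param grid A [lag_grid()].
#' @param params A [sacf_params()].
#' @param dt_out Output time step in seconds (default 1 ms).
#' @param keep_native If `TRUE`, also return the integrator output at the
#'   native internal rate (used by convergence checks).
#' @return A list of class `sacf_output` with fields `A` (lag x time at
#'   `dt_out`), `dt`, `grid`, `markers` (column indices on the output axis).
#' @export
compute_sacf <- function(an, grid = lag_grid(), params = sacf_params(),
                         dt_out = 1e-3, keep_native = FALSE) {
  stopifnot(inherits(an, "an_response"))
  p <- an$p
  rate <- an$rate
  nt <- ncol(p)
  if (nt / rate <= max(grid$lags)) {
    stop(sprintf("input duration (%.3f s) must exceed the maximum lag (%.3f s)",
                 nt / rate, max(grid$lags)), call. = FALSE)
  }
  dt <- 1 / rate
  taus <- sacf_tau(grid, params)
  alphas <- exp(-dt / taus)

  A <- matrix(0, nrow = grid$n, ncol = nt)
  # cache integer-shift correlation products: adjacent lags share shifts
  qcache <- new.env(parent = emptyenv())
  corr_at <- function(j) {
    key <- as.character(j)
    if (!is.null(qcache[[key]])) return(qcache[[key]])
    v <- numeric(nt)
    if (j < nt) {
      v[(j + 1L):nt] <- .colSums(p[, (j + 1L):nt, drop = FALSE] *
                                   p[, 1L:(nt - j), drop = FALSE],
                                 nrow(p), nt - j)
    }
    qcache[[key]] <- v
    v
  }
  for (n_i in seq_len(grid$n)) {
    del <- grid$lags[n_i] * rate
    j0 <- floor(del)
    w <- del - j0
    drive <- (1 - w) * corr_at(j0) + w * corr_at(j0 + 1L)
    # exact exponential update of tau A' = -A + drive
    A[n_i, ] <- stats::filter(drive * (1 - alphas[n_i]), alphas[n_i],
                              method = "recursive")
  }

  keep <- seq(1L, nt, by = max(1L, round(dt_out * rate)))
  out_markers <- vapply(an$markers, function(i) {
    max(1L, min(length(keep), 1L + as.integer(round((i - 1L) * dt / dt_out))))
  }, integer(1))
  structure(list(A = A[, keep, drop = FALSE], dt = dt_out, grid = grid,
                 markers = out_markers,
                 native = if (keep_native) list(A = A, dt = dt) else NULL),
            class = "sacf_output")
}

#' Regularise the SACF into the cortical input
#'
#' Divisive normalisation across the lag axis at each time step,
#' `r_n = A_n / (k + mean A)`, removes the dependence on stimulus intensity;
#' subtracting a baseline and rescaling (with saturation) maps the
#' periodicity contrast onto the input range the decoder network expects.
#'
#' Two refinements of the plain cross-lag mean keep the contrast unbiased:
#' the divisive pool averages over the causally live detectors only (those
#' whose lag is shorter than the elapsed record time), since early in the
#' record the empty long-lag integrators would otherwise drag the pool mean
#' towards zero and create a spurious onset transient; and when the record
#' carries a `pitch_onset` marker (a noise-precursor paradigm), the
#' subtracted baseline is the per-lag time average of `r` over the
#' precursor window plus the margin `theta - 1`, so that lags with
#' different noise-driven floors (short lags carry more envelope
#' correlation) are referenced to their own baseline. Without a marker a
#' flat baseline `theta` is used. Activity below baseline is clipped to
#' zero, so a flat lag profile (e.g. an all-zero input) yields a flat
#' regularised output at the documented baseline value 0.
#'
#' @param sacf A `sacf_output` from [compute_sacf()].
#' @param params A [sacf_params()].
#' @param mode `"single"` or `"dyad"`: selects the rescale factor.
#' @return A `sacf_output` with an additional matrix `Ahat`.
#' @export
regularize <- function(sacf, params = sacf_params(),
                       mode = c("single", "dyad")) {
  mode <- match.arg(mode)
  scale <- if (mode == "single") params$scale_single else params$scale_dyad
  A <- sacf$A
  nt <- ncol(A)
  # number of live detectors at each time step (lags are sorted ascending)
  elapsed <- (seq_len(nt)) * sacf$dt
  n_live <- findInterval(elapsed, sacf$grid$lags)
  csum <- apply(A, 2L, cumsum)
  m <- numeric(nt)
  live <- n_live > 0L
  m[live] <- csum[cbind(n_live[live], which(live))] / n_live[live]
  r <- sweep(A, 2L, params$k + m, "/")

  on <- sacf$markers["pitch_onset"]
  min_base <- round(0.1 / sacf$dt)    # need >= 100 ms of usable precursor
  skip <- round(0.06 / sacf$dt)       # discard the integrator warm-up
  if (identical(params$baseline, "precursor") &&
      length(on) == 1L && !is.na(on) && on - skip > min_base) {
    i1 <- on - round(0.02 / sacf$dt)
    base <- rowMeans(r[, skip:i1, drop = FALSE]) + (params$theta - 1)
    x <- pmax(sweep(r, 1L, base, "-"), 0)
  } else {
    x <- pmax(r - params$theta, 0)
  }
  Ahat <- scale * pmin(x, params$sat)
  sacf$Ahat <- Ahat
  sacf$mode <- mode
  sacf
}

#' @export
print.sacf_output <- function(x, ...) {
  cat(sprintf("<sacf_output> %d lags x %d steps @ %g ms%s\n",
              nrow(x$A), ncol(x$A), 1000 * x$dt,
              if (!is.null(x$Ahat)) sprintf(" (regularised, %s)", x$mode) else ""))
  invisible(x)
}

#' Half-rise time of the lag-matched detector after pitch onset
#'
#' Measures the first time after the pitch-onset marker at which the SACF
#' channel tuned to `period` reaches half of its late-window steady value,
#' both referenced to the pre-onset (noise-driven) baseline. A short centred
#' moving average removes the integrator's residual flicker, and the
#' crossing must be sustained for 5 ms so that baseline fluctuations do not
#' register as rises. Used to calibrate and verify the `~1.25 T` activation
#' time of the periodicity detectors.
#'
#' @param sacf A `sacf_output`.
#' @param period Stimulus fundamental period in seconds.
#' @param steady_window Window (s, relative to pitch onset) over which the
#'   steady response is measured.
#' @param smooth Moving-average width in seconds.
#' @return Half-rise time in seconds (relative to pitch onset), or `NA` if
#'   the channel never crosses.
#' @export
sacf_half_rise <- function(sacf, period, steady_window = c(0.25, 0.6),
                           smooth = 2e-3) {
  if (!"pitch_onset" %in% names(sacf$markers)) {
    stop("input has no pitch_onset marker", call. = FALSE)
  }
  ch <- nearest_column(sacf$grid, period)
  x <- sacf$A[ch, ]
  w <- max(1L, round(smooth / sacf$dt))
  if (w > 1L) x <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  on <- sacf$markers[["pitch_onset"]]
  iw <- on + round(steady_window / sacf$dt)
  iw[2] <- min(iw[2], sum(!is.na(x)))
  steady <- mean(x[iw[1]:iw[2]], na.rm = TRUE)
  base <- mean(x[max(1L, on - round(0.2 / sacf$dt)):on], na.rm = TRUE)
  if (steady <= base) return(NA_real_)
  thr <- base + 0.5 * (steady - base)
  xs <- x[on:length(x)]
  hold <- max(1L, round(5e-3 / sacf$dt))
  above <- !is.na(xs) & xs >= thr
  run <- stats::filter(as.numeric(above), rep(1, hold), sides = 1)
  idx <- which(run == hold)
  if (!length(idx)) return(NA_real_)
  (idx[1] - hold) * sacf$dt
}
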