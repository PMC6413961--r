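#' Plot a single model run
#'
#' Dipole moment around pitch onset with the extracted POR latency, plus the
#' time-averaged decoder-inhibitory profile with the decoded period(s).
#'
#' @param object A `pitch_sim` from [run_pitch_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pitch_sim
#' @export
autoplot.pitch_sim <- function(object, ...) {
  dip <- object$dipole
  onset <- if ("pitch_onset" %in% names(object$sim$markers)) {
    object$sim$markers[["pitch_onset"]]
  } else 0
  p <- ggplot2::ggplot(dip, ggplot2::aes(x = 1000 * (.data$time - onset),
                                         y = .data$m)) +
    ggplot2::geom_line(colour = "grey20") +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = "time re pitch onset (ms)",
                  y = "dipole moment (summed exc. rate, Hz)",
                  title = "Decoder collective response") +
    ggplot2::theme_minimal()
  if (!is.na(object$latency)) {
    p <- p + ggplot2::geom_vline(xintercept = 1000 * object$latency,
                                 colour = "firebrick", linetype = 2)
  }
  p
}

#' Plot an experiment's latency summary
#'
#' Mean POR latency per condition with standard-error bars; dyad experiments
#' are coloured by consonance class.
#'
#' @param object A `por_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot por_experiment
#' @export
autoplot.por_experiment <- function(object, ...) {
  s <- object$summary
  if (object$kind == "dyads") {
    cls <- object$runs |>
      dplyr::distinct(.data$condition, .data$class)
    s <- dplyr::left_join(s, cls, by = "condition")
    ggplot2::ggplot(s, ggplot2::aes(x = .data$condition,
                                    y = .data$mean_latency_ms,
                                    colour = .data$class)) +
      ggplot2::geom_point(size = 2) +
      ggplot2::geom_errorbar(ggplot2::aes(
        ymin = .data$mean_latency_ms - .data$se_latency_ms,
        ymax = .data$mean_latency_ms + .data$se_latency_ms), width = 0.2) +
      ggplot2::scale_colour_manual(values = c(PC = "forestgreen",
                                              IC = "olivedrab",
                                              D = "firebrick")) +
      ggplot2::labs(x = "interval", y = "POR latency (ms)",
                    colour = "class",
                    title = "Predicted POR latency by dyad") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(s, ggplot2::aes(x = .data$condition,
                                    y = .data$mean_latency_ms, group = 1)) +
      ggplot2::geom_line(colour = "grey40") +
      ggplot2::geom_point(size = 2) +
      ggplot2::geom_errorbar(ggplot2::aes(
        ymin = .data$mean_latency_ms - .data$se_latency_ms,
        ymax = .data$mean_latency_ms + .data$se_latency_ms), width = 0.2) +
      ggplot2::labs(x = "condition", y = "POR latency (ms)",
                    title = "Predicted POR latency") +
      ggplot2::theme_minimal()
  }
}

#' Heatmap of the regularised SACF
#'
#' @param sacf A regularised `sacf_output`.
#' @param max_lag_ms Upper lag limit shown, ms.
#' @return A ggplot object.
#' @export
plot_sacf <- function(sacf, max_lag_ms = 20) {
  stopifnot(inherits(sacf, "sacf_output"))
  M <- if (!is.null(sacf$Ahat)) sacf$Ahat else sacf$A
  keep <- which(1000 * sacf$grid$lags <= max_lag_ms)
  df <- expand.grid(lag = 1000 * sacf$grid$lags[keep],
                    time = (seq_len(ncol(M)) - 1L) * sacf$dt)
  df$value <- as.vector(M[keep, ])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$lag,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "activity") +
    ggplot2::labs(x = "time (s)", y = "lag (ms)",
                  title = "Periodicity-detector activity") +
    ggplot2::theme_minimal()
}
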