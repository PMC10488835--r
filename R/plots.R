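# ggplot2 views of the analysis results.

#' Plot estimated marginal means per location
#'
#' Point-and-errorbar plot of the EMM table from [emm_at()]: one estimate
#' with its confidence interval per chamber or wall, at the reference
#' heart rate.
#'
#' @param emm tibble from [emm_at()].
#' @param ylab axis label (e.g. `"conduction velocity (m/s)"`).
#' @return a ggplot object.
#' @export
plot_emm <- function(emm, ylab = "estimate") {
  loc <- names(emm)[1]
  ggplot2::ggplot(emm, ggplot2::aes(x = .data[[loc]], y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower,
                                          ymax = .data$upper)) +
    ggplot2::labs(x = NULL, y = ylab,
                  subtitle = sprintf("estimated marginal means at %g bpm",
                                     emm$heart_rate[1])) +
    ggplot2::theme_minimal()
}

#' @rdname plot_emm
#' @param object an `eamap_mixed_model`.
#' @param heart_rate reference heart rate (bpm).
#' @param ... unused.
#' @method autoplot eamap_mixed_model
#' @export
autoplot.eamap_mixed_model <- function(object, heart_rate = 90, ...) {
  plot_emm(emm_at(object, heart_rate = heart_rate),
           ylab = if (object$response == "log_cv")
             "conduction velocity (m/s)" else "voltage amplitude (mV)")
}

#' Scatter of voltage amplitude against conduction velocity
#'
#' One point per valid circle, coloured by chamber — the view in which a
#' slow-conduction / low-voltage association (or its absence) shows up.
#'
#' @param measurements measurement tibble.
#' @param cv_cap optional m/s cap on the x axis (e.g. 1.5).
#' @return a ggplot object.
#' @export
plot_cv_va <- function(measurements, cv_cap = NULL) {
  d <- filter(measurements, .data$valid, !is.na(.data$cv), !is.na(.data$va))
  if (!is.null(cv_cap)) d <- filter(d, .data$cv < cv_cap)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cv, y = .data$va,
                                  colour = .data$chamber)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = "conduction velocity (m/s)",
                  y = "voltage amplitude (mV)", colour = "chamber") +
    ggplot2::theme_minimal()
}

#' Histogram of per-circle conduction velocities
#'
#' @param measurements measurement tibble; excluded circles are shown in
#'   their own facet when present.
#' @param binwidth histogram bin width in m/s.
#' @return a ggplot object.
#' @export
plot_cv_distribution <- function(measurements, binwidth = 0.1) {
  d <- filter(measurements, !is.na(.data$cv))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cv, fill = .data$valid)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0) +
    ggplot2::labs(x = "conduction velocity (m/s)", y = "circles",
                  fill = "valid") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
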