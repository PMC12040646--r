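# ggplot2 figures: gain/phase/coherence spectra on a log-frequency axis and
# the head-position probability distribution.

#' Plot a transfer-function estimate
#'
#' Gain, phase and coherence of a single estimate against log frequency.
#'
#' @param object A `tf_estimate` from [estimate_sensitivity()].
#' @param ... Unused.
#' @return A ggplot object (facets: gain, phase, coherence).
#' @export
autoplot.tf_estimate <- function(object, ...) {
  long <- tidyr::pivot_longer(tidy(object),
                              cols = c("gain", "phase_deg", "coherence"),
                              names_to = "quantity", values_to = "value")
  long$quantity <- factor(long$quantity,
                          levels = c("gain", "phase_deg", "coherence"),
                          labels = c("GAIN", "PHASE (deg)", "COHERENCE"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$frequency_hz, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Frequency (Hz)", y = NULL) +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Group-mean gain spectra with confidence intervals
#'
#' Mean gain per group and segment against log frequency, with the 95%
#' confidence whiskers of the cell means; one panel per group.
#'
#' @param summary A summary tibble from [aggregate_estimates()], pooled or
#'   filtered to one visual/amplitude condition beforehand as desired.
#' @param quantity Column to plot: `"mean_gain"` (default),
#'   `"mean_phase_deg"` or `"mean_coherence"`.
#' @return A ggplot object.
#' @export
plot_gain_spectra <- function(summary, quantity = "mean_gain") {
  ci_col <- switch(quantity, mean_gain = "gain_ci",
                   mean_phase_deg = "phase_ci", NULL)
  if (!quantity %in% names(summary))
    stop("Column `", quantity, "` not found in `summary`.", call. = FALSE)
  agg <- summary |>
    dplyr::group_by(.data$group, .data$segment, .data$frequency_hz) |>
    dplyr::summarise(value = mean(.data[[quantity]]),
                     ci = if (!is.null(ci_col)) mean(.data[[ci_col]]) else NA_real_,
                     .groups = "drop")
  p <- ggplot2::ggplot(agg, ggplot2::aes(x = .data$frequency_hz,
                                         y = .data$value,
                                         colour = .data$segment)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(head = "#c0392b",
                                            shoulder = "#27ae60",
                                            hip = "#2980b9")) +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "Frequency (Hz)", y = quantity, colour = "Segment") +
    ggplot2::theme_bw()
  if (!is.null(ci_col) && any(is.finite(agg$ci)))
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$value - .data$ci,
                   ymax = .data$value + .data$ci), width = 0.02)
  p
}

#' Plot a head-position probability distribution
#'
#' @param histogram A tibble from [head_position_histogram()].
#' @return A ggplot object.
#' @export
plot_head_histogram <- function(histogram) {
  ggplot2::ggplot(histogram, ggplot2::aes(x = .data$bin_center_cm,
                                          y = .data$probability)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = "Anteroposterior head position (cm)",
                  y = "Probability") +
    ggplot2::theme_bw()
}
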