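#' Plot an autocorrelation function
#'
#' @param object A `cg_acf`.
#' @param ... Unused.
#' @return A ggplot: normalised autocorrelation against lag time, with the
#'   1/e level marked.
#' @method autoplot cg_acf
#' @export
autoplot.cg_acf <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$lag, y = .data$c)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = exp(-1), linetype = "dashed") +
    ggplot2::labs(x = "lag (simulation time units)",
                  y = "normalised autocorrelation",
                  title = paste0(attr(object, "kind"),
                                 " end-to-end autocorrelation")) +
    ggplot2::theme_minimal()
}

#' Plot a cohesiveness sweep of ensemble summaries
#'
#' @param data A tibble of stacked [ensemble_summary()] rows across a
#'   cohesiveness grid.
#' @return A ggplot of the chain dimensions against cohesiveness.
#' @export
plot_dimension_sweep <- function(data) {
  long <- tidyr::pivot_longer(
    dplyr::mutate(data,
                  re2_over_6 = .data$mean_re2 / 6,
                  rg2 = .data$mean_rg2,
                  rk2 = .data$rk^2),
    cols = c("re2_over_6", "rg2", "rk2"),
    names_to = "dimension", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$eps, y = sqrt(.data$value),
                                     colour = .data$dimension)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "cohesiveness eps (kT)", y = "dimension (sim. units)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an end-to-end distance distribution
#'
#' @param shape Result of [end_distance_shape()].
#' @return A ggplot of the histogram and its smoothed envelope.
#' @export
plot_end_distance <- function(shape) {
  h <- shape$histogram
  ggplot2::ggplot(h, ggplot2::aes(x = .data$re_mid)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$prob), alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), colour = "red") +
    ggplot2::labs(x = "end-to-end distance (sim. units)",
                  y = "probability",
                  subtitle = sprintf("%d peak(s), variance %.3g",
                                     shape$n_peaks, shape$variance)) +
    ggplot2::theme_minimal()
}

#' Plot conditional end-to-end distributions against the ball-model
#' reference
#'
#' @param cond Output of [conditional_distribution()].
#' @param rg_bins Optional subset of `rg_mid` values to facet.
#' @return A ggplot faceted by Rg bin, overlaying the
#'   [sanchez_haran_pdf()] density (scaled to bin mass).
#' @export
plot_conditional_distribution <- function(cond, rg_bins = NULL) {
  if (!is.null(rg_bins)) cond <- dplyr::filter(cond, .data$rg_mid %in% rg_bins)
  bin <- min(diff(sort(unique(cond$re_mid))))
  ref <- dplyr::group_by(cond, .data$rg_mid) |>
    dplyr::reframe(re_mid = .data$re_mid,
                   ref = sanchez_haran_pdf(.data$re_mid, .data$rg_mid[1]) * bin)
  ggplot2::ggplot(cond, ggplot2::aes(x = .data$re_mid)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$prob), alpha = 0.5) +
    ggplot2::geom_line(data = ref, ggplot2::aes(y = .data$ref), colour = "black",
                       linetype = "dashed") +
    ggplot2::facet_wrap(~.data$rg_mid, scales = "free") +
    ggplot2::labs(x = "end-to-end distance (sim. units)", y = "probability") +
    ggplot2::theme_minimal()
}

#' Plot a monotone patterning regression
#'
#' @param object A `cg_scd_regression`.
#' @param ... Unused.
#' @return A ggplot of the data, isotonic fit and smoothed curve.
#' @method autoplot cg_scd_regression
#' @export
autoplot.cg_scd_regression <- function(object, ...) {
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(x = .data$scd)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$ratio)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$fitted), colour = "grey50") +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), colour = "black") +
    ggplot2::labs(x = "sequence charge decoration",
                  y = "observable") +
    ggplot2::theme_minimal()
}
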