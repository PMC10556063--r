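#' Plot a digit-distribution audit
#'
#' Bar chart of the whole-dataset observed first-digit frequencies with the
#' analytic Benford expectation overlaid as a line, annotated with the
#' regression R-squared.
#'
#' @param object A `benford_audit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.benford_audit <- function(object, ...) {
  dat <- dplyr::left_join(object$whole$distribution, benford_expected(),
                          by = "digit")
  r2 <- object$whole$r_squared$r_squared
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$digit))) +
    ggplot2::geom_col(ggplot2::aes(y = .data$freq), fill = "white",
                      colour = "grey30") +
    ggplot2::geom_line(ggplot2::aes(y = .data$expected, group = 1),
                       colour = "black") +
    ggplot2::geom_point(ggplot2::aes(y = .data$expected), colour = "black") +
    ggplot2::labs(
      x = "first digit", y = "relative frequency",
      title = "Observed first digits vs. Benford's law",
      subtitle = sprintf("R² = %.3f over %d abundance values",
                         r2, object$whole$r_squared$n_values)
    ) +
    ggplot2::theme_minimal()
}

#' Plot an occurrence-threshold scan
#'
#' True skill statistic against the candidate minimum number of occurrence
#' sites, with the selected threshold (the first TSS maximum) highlighted as
#' a blue circle.
#'
#' @param object An `occurrence_scan` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.occurrence_scan <- function(object, ...) {
  scan <- dplyr::filter(object$scan, .data$defined)
  sel <- object$selected
  ggplot2::ggplot(scan, ggplot2::aes(x = .data$candidate, y = .data$tss)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 0.8, colour = "grey40") +
    ggplot2::geom_point(data = sel, colour = "blue", size = 3, shape = 1,
                        stroke = 1.2) +
    ggplot2::labs(
      x = "candidate minimum occurrence sites",
      y = "true skill statistic",
      title = "Minimum occurrence-site threshold selection",
      subtitle = sprintf("selected %d sites: TSS %.3f, overall accuracy %.3f",
                         sel$candidate, sel$tss, sel$overall_accuracy)
    ) +
    ggplot2::theme_minimal()
}
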