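#' Plot per-criterion MetS prevalence with exact confidence intervals
#'
#' Point-and-errorbar display of the prevalence table of a
#' [run_mets_analysis()] report, overall and by sex.
#'
#' @param prevalence The `prevalence` tibble of a `mets_report`.
#' @return A ggplot object.
#' @export
plot_prevalence <- function(prevalence) {
  ggplot2::ggplot(
    prevalence,
    ggplot2::aes(x = .data$criterion, y = 100 * .data$estimate,
                 colour = .data$stratum)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = 100 * .data$conf_low,
                   ymax = 100 * .data$conf_high),
      width = 0.25, position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(x = NULL, y = "MetS prevalence (%)",
                  colour = NULL,
                  title = "MetS prevalence by diagnostic definition") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Forest-style plot of sensitivity and specificity per criterion
#'
#' @param accuracy The `accuracy` tibble of a `mets_report` (from
#'   [compare_criteria()]).
#' @param metrics Which metrics to show.
#' @return A ggplot object.
#' @export
plot_accuracy <- function(accuracy, metrics = c("se", "sp")) {
  dat <- dplyr::filter(accuracy, .data$metric %in% metrics)
  ggplot2::ggplot(
    dat,
    ggplot2::aes(x = 100 * .data$estimate, y = .data$criterion,
                 colour = .data$metric)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = 100 * .data$conf_low,
                   xmax = 100 * .data$conf_high),
      height = 0.2, position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(x = "% (95% CI)", y = NULL, colour = NULL,
                  title = "Validity vs the gold standard") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mets_report <- function(object, what = c("prevalence", "accuracy"),
                                 ...) {
  what <- match.arg(what)
  if (what == "prevalence") plot_prevalence(object$prevalence)
  else plot_accuracy(object$accuracy)
}
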