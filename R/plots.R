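#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a measurement-error experiment
#'
#' Mean GREML heritability (with Monte-Carlo error bars) of each value-added
#' measure against the baseline measurement-error variance.
#'
#' @param object a [run_measurement_error_experiment()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot vaherit_me_experiment
#' @export
autoplot.vaherit_me_experiment <- function(object, ...) {
  sm <- summary(object)
  ggplot2::ggplot(sm, ggplot2::aes(x = .data$error_var, y = 100 * .data$mean_h2,
                                   colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = 100 * (.data$mean_h2 - 1.96 * .data$mc_se),
      ymax = 100 * (.data$mean_h2 + 1.96 * .data$mc_se))) +
    ggplot2::labs(x = "baseline measurement-error variance",
                  y = expression("mean " * h[SNP]^2 * " (%)"),
                  colour = "measure") +
    ggplot2::theme_minimal()
}

#' Plot a full-analysis heritability table
#'
#' Point estimates with 95% confidence intervals per measure, in the style of
#' a forest plot; polygenic-score rows are shown in a separate facet on their
#' own (percentage-point) scale.
#'
#' @param object a [run_full_analysis()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot vaherit_full_analysis
#' @export
autoplot.vaherit_full_analysis <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$label <- paste0(d$measure, " ", d$from,
                    ifelse(d$from == d$to, "", paste0("-", d$to)))
  d$shown <- ifelse(d$metric == "h2", 100 * d$estimate, d$estimate)
  d$lo <- ifelse(d$metric == "h2", 100 * d$ci_lo, NA_real_)
  d$hi <- ifelse(d$metric == "h2", 100 * d$ci_hi, NA_real_)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$shown, y = .data$label,
                                  colour = .data$measure)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2, na.rm = TRUE) +
    ggplot2::facet_wrap(~ .data$metric, scales = "free_x") +
    ggplot2::labs(x = "estimate (%)", y = NULL, colour = "measure") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
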