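#' Coefficient interval plot for a fitted model
#'
#' Posterior medians with 95% credibility intervals for every parameter of
#' a fitted growth-rate or nest-production model, in the style of a
#' forest plot. Parameters whose interval excludes zero are highlighted.
#'
#' @param fit A `climpaths_rdsem` or `climpaths_msem` fit (or any tibble
#'   with `term`, `median`, `ci_lower`, `ci_upper`, `nonzero` columns).
#' @return A ggplot object.
#' @export
plot_coefficients <- function(fit) {
  sm <- if (is.data.frame(fit)) fit else fit$summary
  sm$term <- factor(sm$term, levels = rev(sm$term))
  ggplot2::ggplot(sm, ggplot2::aes(x = .data$median, y = .data$term,
                                   colour = .data$nonzero)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_lower,
                                          xmax = .data$ci_upper)) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "black", `FALSE` = "grey55"), guide = "none"
    ) +
    ggplot2::labs(x = "posterior median (95% credibility interval)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.climpaths_rdsem <- function(object, ...) plot_coefficients(object)

#' @exportS3Method ggplot2::autoplot
autoplot.climpaths_msem <- function(object, ...) plot_coefficients(object)
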