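#' Plot methods
#'
#' ggplot2 visualisations of the validation outputs.
#'
#' @name plots
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Cumulative-risk curves
#'
#' Step curves of observed cumulative invasive-cancer risk per risk group
#' with pointwise 95% confidence ribbons.
#'
#' @param object A `km_curves` tibble from [km_cumulative_risk()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.km_curves <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$time, y = .data$cum_risk, colour = .data$group,
    fill = .data$group
  )) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Years since risk assessment",
                  y = "Cumulative invasive cancer risk",
                  colour = "Risk group", fill = "Risk group") +
    ggplot2::theme_minimal()
}

#' Calibration coefficient over follow-up
#'
#' Scaled Schoenfeld residual estimates of beta at each event time with a
#' LOESS smooth (visual only) and the fitted linear trend.
#'
#' @param object A `calibration_fit` from [calibration_coefficient()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.calibration_fit <- function(object, ...) {
  sch <- stats::residuals(object$fit, type = "scaledsch")
  df <- tibble::tibble(
    time = as.numeric(rownames(as.matrix(sch))),
    beta_t = as.numeric(sch) + object$beta
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$beta_t)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.5) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "firebrick", linewidth = 0.6) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = "Years since risk assessment",
                  y = "Calibration coefficient beta(t)") +
    ggplot2::theme_minimal()
}
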