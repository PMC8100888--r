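# ggplot2 visualizations for the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Forest plot of a fitted Cox model
#'
#' Hazard ratios with 95% CIs, treatment terms highlighted, log-scaled
#' x axis.
#'
#' @param object A `harm_cox_model`.
#' @param treatment_only Show treatment terms only (default TRUE).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.harm_cox_model <- function(object, treatment_only = TRUE, ...) {
  tab <- object$hr_table
  if (treatment_only) tab <- tab[tab$is_treatment, ]
  tab$term <- factor(tab$term, levels = rev(tab$term))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$hr, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.2
    ) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Hazard ratio (95% CI)", y = NULL,
                  title = paste("Cox model:", object$model,
                                "- reference", object$reference)) +
    ggplot2::theme_minimal()
}

#' Sensitivity panel for a threshold sweep
#'
#' Hazard ratios with CIs per regimen across imputation thresholds.
#'
#' @param object A `threshold_sweep`.
#' @param terms Optional term subset (regex matched).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.threshold_sweep <- function(object, terms = NULL, ...) {
  tab <- dplyr::bind_rows(object$hr_tables)
  tab <- tab[tab$is_treatment, ]
  if (!is.null(terms)) tab <- tab[grepl(terms, tab$term), ]
  ggplot2::ggplot(tab, ggplot2::aes(x = factor(.data$threshold),
                                    y = .data$hr)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high),
      width = 0.2
    ) +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~term) +
    ggplot2::labs(x = "Self-harm probability threshold",
                  y = "Hazard ratio (95% CI)") +
    ggplot2::theme_minimal()
}

#' Plot a spline hazard-ratio curve
#'
#' @param curve Tibble from [spline_hazard_curve()].
#' @param xlab X-axis label.
#' @return A ggplot with the HR curve and its pointwise 95% CI ribbon.
#' @export
plot_spline_hr <- function(curve, xlab = "x") {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$x, y = .data$hr)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high),
      fill = "steelblue", alpha = 0.2
    ) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = xlab, y = "Hazard ratio (95% CI)") +
    ggplot2::theme_minimal()
}
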