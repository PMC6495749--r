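#' Diagnostic plot of a growth-rate fit
#'
#' Semi-log plot of the counts with the fitted exponential; points outside
#' the fitting window are not shown (the fit object retains only the
#' window).
#'
#' @param object A `growth_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.growth_fit <- function(object, ...) {
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_h, y = .data$count)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(
      data = tibble(
        time_h = d$time_h,
        count = exp(object$ln_intercept + object$k * d$time_h)
      ),
      linetype = "dashed"
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "time (h)", y = "cells",
      title = sprintf("k = %.3g h⁻¹ (r² = %.3f)",
                      object$k, object$r_squared)
    )
}

#' Diagnostic plot of a Rayleigh drawdown trajectory
#'
#' Residual-reactant and accumulated-product delta13C against the fraction
#' of reactant remaining (f decreases left to right as the pool is
#' consumed).
#'
#' @param object A `rayleigh_sys` from [rayleigh_forward()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rayleigh_sys <- function(object, ...) {
  d <- object$states |>
    tidyr::pivot_longer(
      cols = c("delta_residual_permil", "delta_product_cum_permil"),
      names_to = "pool", values_to = "delta_permil"
    ) |>
    dplyr::mutate(pool = dplyr::recode(.data$pool,
      delta_residual_permil = "residual CO2",
      delta_product_cum_permil = "accumulated CH4"
    ))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$f, y = .data$delta_permil,
                                  color = .data$pool)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(
      x = "fraction of reactant remaining",
      y = expression(delta^13 * C ~ "(‰)"),
      title = sprintf("Rayleigh drawdown, ε = %.1f‰",
                      object$epsilon_permil)
    )
}

#' Plot condition-level kinetics summaries
#'
#' Point-and-error-bar panels of growth rate, cell-specific rate, and
#' yield across conditions, mirroring the usual per-condition comparison
#' figure of a kinetics study.
#'
#' @param summary A tibble from [run_condition()].
#' @return A ggplot.
#' @export
plot_condition_summary <- function(summary) {
  long <- dplyr::bind_rows(
    tibble(condition = summary$condition_label, quantity = "k (h-1)",
           value = summary$k_per_h, se = summary$k_se),
    tibble(condition = summary$condition_label,
           quantity = "q (fmol cell-1 h-1)",
           value = summary$q_fmol_per_cell_h, se = summary$q_se),
    tibble(condition = summary$condition_label, quantity = "Y (cells mol-1)",
           value = summary$y_cells_per_mol, se = summary$y_se)
  ) |>
    dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$condition, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$value - .data$se,
                   ymax = .data$value + .data$se),
      width = 0.2, na.rm = TRUE
    ) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
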