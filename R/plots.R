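#' Plot a pressure-amount isotherm with its saturation construction
#'
#' Shows the pi(n) points together with the two least-squares lines whose
#' interception defines the saturation point.
#'
#' @param data Pressure-amount tibble (`n_nmol`, `pi_mN_per_m`).
#' @param sat Optional result of [detect_saturation()]; computed from
#'   `data` if omitted (requires the trough-area attribute or argument).
#' @param trough_area_cm2 Trough area, passed to [detect_saturation()].
#' @return A ggplot object.
#' @export
plot_saturation <- function(data, sat = NULL, trough_area_cm2 = NULL) {
  if (is.null(sat)) {
    sat <- detect_saturation(data, trough_area_cm2 = trough_area_cm2)
  }
  steep_int <- sat$pi_sat_mNm - sat$slope_steep * sat$n_sat_nmol
  plat_int <- sat$pi_sat_mNm - sat$slope_plateau * sat$n_sat_nmol
  ggplot2::ggplot(data, ggplot2::aes(x = .data$n_nmol, y = .data$pi_mN_per_m)) +
    ggplot2::geom_point(shape = 1) +
    ggplot2::geom_abline(intercept = steep_int, slope = sat$slope_steep,
                         linetype = 2) +
    ggplot2::geom_abline(intercept = plat_int, slope = sat$slope_plateau,
                         linetype = 2) +
    ggplot2::annotate("point", x = sat$n_sat_nmol, y = sat$pi_sat_mNm,
                      shape = 4, size = 3) +
    ggplot2::labs(x = "total lipid (nmol)", y = "surface pressure (mN/m)")
}

#' Plot a pressure-area isotherm with a fitted polynomial
#'
#' @param data Area isotherm tibble (`area_A2`, `pi_mN_per_m`).
#' @param fit Optional `isotherm_fit`; drawn over its fitted range.
#' @param pi_ref Horizontal reference pressure (mN/m), default 30; `NULL`
#'   suppresses it.
#' @return A ggplot object.
#' @export
plot_isotherm <- function(data, fit = NULL, pi_ref = 30) {
  p <- ggplot2::ggplot(data,
                       ggplot2::aes(x = .data$area_A2, y = .data$pi_mN_per_m)) +
    ggplot2::geom_point(shape = 1) +
    ggplot2::labs(x = "mean area per lipid (Å²)",
                  y = "surface pressure (mN/m)")
  if (!is.null(fit)) {
    grid <- seq(fit$area_range[1], fit$area_range[2], length.out = 200)
    curve <- tibble::tibble(area_A2 = grid,
                            pi_mN_per_m = predict_pressure(fit, grid))
    p <- p + ggplot2::geom_line(data = curve)
  }
  if (!is.null(pi_ref)) {
    p <- p + ggplot2::geom_hline(yintercept = pi_ref, linetype = 3)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.pressure_cor <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$psi_sat_mV, y = .data$psi30_mV)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope) +
    ggplot2::geom_abline(intercept = 0, slope = 1, linetype = 3) +
    ggplot2::labs(
      x = expression(psi[d]^sat ~ "(mV)"),
      y = expression(psi[d]^{"30 mN/m"} ~ "(mV)"),
      subtitle = sprintf("R² = %.2f (%s)", object$r_squared, object$eq)
    )
}

#' @export
autoplot.partition_fit <- function(object, ...) {
  ggplot2::ggplot(object$residuals,
                  ggplot2::aes(x = .data$psi_d_mV, y = .data$ddG_kJ_mol,
                               shape = .data$held_out)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 8),
                                name = "held out") +
    ggplot2::labs(x = expression(psi[d] ~ "(mV)"),
                  y = expression(Delta * Delta * G[P]^o ~ "(kJ/mol)"))
}

#' Predicted versus observed mixture properties
#'
#' The identity-line view of mixture behaviour: points below the line are
#' condensed relative to the prediction, points above are expanded.
#'
#' @param report Deviation report tibble (from [deviation_report()] or
#'   [study_mixture_table()]).
#' @return A ggplot object, faceted by property.
#' @export
plot_mixture_deviations <- function(report) {
  ggplot2::ggplot(report,
                  ggplot2::aes(x = .data$predicted, y = .data$observed,
                               colour = .data$scheme)) +
    ggplot2::geom_abline(intercept = 0, slope = 1, linetype = 3) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~property, scales = "free") +
    ggplot2::labs(x = "predicted", y = "observed")
}
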