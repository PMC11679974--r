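#' Detect the saturation point of a pressure-amount isotherm
#'
#' In the constant-area method the monolayer is built by successive additions
#' of lipid to a trough of fixed area; the surface pressure rises steeply and
#' then plateaus once the interface saturates and excess lipid aggregates in
#' the subphase. The saturation point is located as the interception of two
#' least-squares lines: one through the steepest contiguous window of the
#' pi(n) curve, the other through the plateau points (all points with
#' `pi >= max(pi) - plateau_tol`). The mean area per lipid at saturation
#' follows from the trough area and the amount of lipid at the interception.
#'
#' @param data Tibble with columns `n_nmol` (total lipid spread, nmol,
#'   strictly increasing, at least 6 points) and `pi_mN_per_m` (surface
#'   pressure, mN/m, non-negative).
#' @param trough_area_cm2 Fixed trough area in cm^2. If missing, taken from
#'   the `trough_area_cm2` attribute of `data` (set by the readers and the
#'   synthetic generator).
#' @param plateau_tol_mNm Pressure band below the maximum that defines the
#'   plateau (mN/m); at least 3 points must fall in it.
#' @param steep_window Number of consecutive points in the sliding window
#'   used to find the steepest region (ties broken toward larger amounts).
#' @return A one-row tibble: `n_sat_nmol`, `pi_sat_mNm`, `A_sat_A2`,
#'   `slope_steep` (mN/m per nmol), `slope_plateau`, `n_plateau_points`.
#' @examples
#' iso <- tibble::tibble(n_nmol = seq(20, 50, length.out = 16))
#' iso$pi_mN_per_m <- pmin(4 * iso$n_nmol - 100, 50)
#' detect_saturation(iso, trough_area_cm2 = 100)
#' @export
detect_saturation <- function(data, trough_area_cm2 = NULL,
                              plateau_tol_mNm = 0.5, steep_window = 5) {
  check_columns(data, c("n_nmol", "pi_mN_per_m"), "pressure-amount isotherm")
  if (is.null(trough_area_cm2)) {
    trough_area_cm2 <- attr(data, "trough_area_cm2")
  }
  if (is.null(trough_area_cm2) || !is.finite(trough_area_cm2) ||
      trough_area_cm2 <= 0) {
    stop_dipot("a positive trough_area_cm2 is required", "validation")
  }
  n <- data$n_nmol
  p <- data$pi_mN_per_m
  if (length(n) < 6) stop_dipot("need at least 6 isotherm points", "validation")
  if (any(diff(n) <= 0)) {
    stop_dipot("n_nmol must be strictly increasing", "validation")
  }
  if (any(p < -1e-9)) stop_dipot("surface pressures must be >= 0", "validation")
  if (steep_window < 2 || steep_window > length(n)) {
    stop_dipot("steep_window must be between 2 and the number of points",
               "validation")
  }

  # closed-form simple least squares (identical to lm, cheap inside the
  # sliding window)
  fit_line <- function(idx) {
    xx <- n[idx]; yy <- p[idx]
    b <- stats::cov(xx, yy) / stats::var(xx)
    c(intercept = mean(yy) - b * mean(xx), slope = b)
  }

  # sliding-window regression slope; ties toward larger n
  n_win <- length(n) - steep_window + 1
  slopes <- vapply(seq_len(n_win), function(i) {
    idx <- i:(i + steep_window - 1)
    fit_line(idx)["slope"]
  }, numeric(1))
  i_steep <- max(which(slopes >= max(slopes) - 1e-12))
  steep_idx <- i_steep:(i_steep + steep_window - 1)
  steep <- fit_line(steep_idx)

  # plateau: all points within plateau_tol of the maximum, but at least the
  # 3 highest-pressure points (the raw maximum can be a noise outlier)
  plateau_idx <- which(p >= max(p) - plateau_tol_mNm)
  if (length(plateau_idx) < 3) {
    plateau_idx <- order(p, decreasing = TRUE)[1:3]
  }
  plateau <- fit_line(plateau_idx)

  # precondition: a real plateau, i.e. the steep region is much steeper than
  # the final window of the curve
  final_idx <- (length(n) - steep_window + 1):length(n)
  final_slope <- fit_line(final_idx)["slope"]
  if (!(max(slopes) >= 5 * abs(final_slope))) {
    stop_dipot("isotherm does not flatten: steepest slope is less than 5x the final-window slope",
               "no_plateau")
  }

  # angle between the two lines (slopes in data units; this guards
  # against a numerically ill-conditioned interception)
  ang <- abs(atan(steep["slope"]) - atan(plateau["slope"])) * 180 / pi
  if (ang < 1) {
    stop_dipot("steep and plateau lines are near-parallel (< 1 degree)",
               "degenerate_lines")
  }

  n_sat <- (plateau["intercept"] - steep["intercept"]) /
    (steep["slope"] - plateau["slope"])
  pi_sat <- steep["intercept"] + steep["slope"] * n_sat
  A_sat <- trough_area_cm2 * 1e16 / (n_sat * 1e-9 * .const$N_A)

  tibble::tibble(
    n_sat_nmol = unname(n_sat),
    pi_sat_mNm = unname(pi_sat),
    A_sat_A2 = unname(A_sat),
    slope_steep = unname(steep["slope"]),
    slope_plateau = unname(plateau["slope"]),
    n_plateau_points = length(plateau_idx)
  )
}

#' Convert a pressure-amount isotherm to a pressure-area isotherm
#'
#' Each amount of spread lipid corresponds to a mean area per molecule
#' `A = trough_area / (N_A * n)`; the returned table is ordered by
#' decreasing amount so that the area increases down the rows while the
#' pressure decreases.
#'
#' @inheritParams detect_saturation
#' @return Tibble with columns `area_A2`, `pi_mN_per_m` (and `n_nmol`),
#'   ordered by increasing area.
#' @examples
#' iso <- tibble::tibble(n_nmol = c(20, 33.6, 40),
#'                       pi_mN_per_m = c(5, 30, 50))
#' to_area_isotherm(iso, trough_area_cm2 = 100)
#' @export
to_area_isotherm <- function(data, trough_area_cm2 = NULL) {
  check_columns(data, c("n_nmol", "pi_mN_per_m"), "pressure-amount isotherm")
  if (is.null(trough_area_cm2)) {
    trough_area_cm2 <- attr(data, "trough_area_cm2")
  }
  if (is.null(trough_area_cm2) || trough_area_cm2 <= 0) {
    stop_dipot("a positive trough_area_cm2 is required", "validation")
  }
  if (any(data$n_nmol <= 0)) {
    stop_dipot("all lipid amounts must be positive", "validation")
  }
  out <- tibble::tibble(
    area_A2 = trough_area_cm2 * 1e16 / (data$n_nmol * 1e-9 * .const$N_A),
    pi_mN_per_m = data$pi_mN_per_m,
    n_nmol = data$n_nmol
  )
  dplyr::arrange(out, .data$area_A2)
}

#' Fit a polynomial to a pressure-area isotherm
#'
#' Least-squares polynomial description of pi(A) restricted to the
#' liquid-expanded/condensed region (areas below `max_area_A2`), used to
#' interpolate the area per lipid at a chosen lateral pressure.
#'
#' @param data Tibble with columns `area_A2`, `pi_mN_per_m`.
#' @param max_area_A2 Only points with `area_A2 <= max_area_A2` enter the
#'   fit (default 100 A^2).
#' @param degree Polynomial degree (default 3).
#' @return An object of class `isotherm_fit` with elements `coefficients`
#'   (ascending powers), `degree`, `area_range` (of the fitted points),
#'   `pi_range`, `rms` (residual RMS, mN/m), `n`, and the underlying `lm`
#'   fit. [generics::tidy()] and [generics::glance()] methods are provided.
#' @examples
#' aiso <- tibble::tibble(area_A2 = seq(50, 95, 5))
#' aiso$pi_mN_per_m <- 120 - aiso$area_A2
#' fit_isotherm_polynomial(aiso, degree = 1)
#' @export
fit_isotherm_polynomial <- function(data, max_area_A2 = 100, degree = 3) {
  check_columns(data, c("area_A2", "pi_mN_per_m"), "area isotherm")
  sub <- data[data$area_A2 <= max_area_A2 & is.finite(data$pi_mN_per_m), ]
  if (nrow(sub) < degree + 2) {
    stop_dipot(sprintf(
      "need at least %d points with area <= %.3g A^2 for a degree-%d fit (have %d)",
      degree + 2, max_area_A2, degree, nrow(sub)), "insufficient_points")
  }
  X <- outer(sub$area_A2, 0:degree, `^`)
  fit <- stats::lm.fit(X, sub$pi_mN_per_m)
  coefs <- unname(fit$coefficients)
  structure(
    list(
      coefficients = coefs,
      degree = degree,
      area_range = range(sub$area_A2),
      pi_range = range(sub$pi_mN_per_m),
      rms = sqrt(mean(fit$residuals^2)),
      n = nrow(sub)
    ),
    class = "isotherm_fit"
  )
}

#' Evaluate an isotherm polynomial
#'
#' @param model An `isotherm_fit`.
#' @param area_A2 Areas (A^2) at which to evaluate pi.
#' @return Surface pressures (mN/m).
#' @export
predict_pressure <- function(model, area_A2) {
  stopifnot(inherits(model, "isotherm_fit"))
  drop(outer(area_A2, seq_along(model$coefficients) - 1, `^`) %*%
         model$coefficients)
}

#' @export
print.isotherm_fit <- function(x, ...) {
  cat(sprintf("<isotherm_fit> degree %d, %d points, area %.1f-%.1f A^2, RMS %.3g mN/m\n",
              x$degree, x$n, x$area_range[1], x$area_range[2], x$rms))
  cat("coefficients (ascending powers):",
      paste(format(x$coefficients, digits = 6), collapse = ", "), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.isotherm_fit <- function(x, ...) {
  tibble::tibble(term = paste0("A^", seq_along(x$coefficients) - 1),
                 estimate = x$coefficients)
}

#' @export
glance.isotherm_fit <- function(x, ...) {
  tibble::tibble(degree = x$degree, n = x$n, rms = x$rms,
                 area_min_A2 = x$area_range[1], area_max_A2 = x$area_range[2])
}

#' Area per lipid at a given lateral pressure
#'
#' Inverts a fitted isotherm polynomial: finds the area at which the fitted
#' pi(A) equals the requested pressure, restricted to the fitted area range
#' and to the physically meaningful branch where pressure decreases with
#' increasing area. If several such roots exist (high-order fits can
#' wiggle), the largest area is returned.
#'
#' @param model An `isotherm_fit` from [fit_isotherm_polynomial()].
#' @param pi_mNm Target surface pressure (mN/m), default 30 (the pressure at
#'   which monolayers are conventionally compared with bilayers).
#' @return The area per lipid (A^2).
#' @examples
#' aiso <- tibble::tibble(area_A2 = seq(50, 95, 5))
#' aiso$pi_mN_per_m <- 120 - aiso$area_A2
#' m <- fit_isotherm_polynomial(aiso, degree = 1)
#' area_at_pressure(m, 30) # 90
#' @export
area_at_pressure <- function(model, pi_mNm = 30) {
  stopifnot(inherits(model, "isotherm_fit"))
  if (pi_mNm < model$pi_range[1] - 1e-9 || pi_mNm > model$pi_range[2] + 1e-9) {
    stop_dipot(sprintf(
      "pressure %.3g mN/m outside the fitted range [%.3g, %.3g]",
      pi_mNm, model$pi_range[1], model$pi_range[2]), "no_root")
  }
  cf <- model$coefficients
  cf[1] <- cf[1] - pi_mNm
  roots <- polyroot(cf)
  real <- Re(roots[abs(Im(roots)) < 1e-8 * (1 + abs(Re(roots)))])
  lo <- model$area_range[1] - 1e-9
  hi <- model$area_range[2] + 1e-9
  real <- real[real >= lo & real <= hi]
  if (length(real) > 0) {
    # decreasing branch: dpi/dA < 0 at the root
    dcf <- model$coefficients[-1] * seq_len(model$degree)
    deriv <- vapply(real, function(a) {
      sum(dcf * a^(seq_along(dcf) - 1))
    }, numeric(1))
    real <- real[deriv < 0]
  }
  if (length(real) == 0) {
    stop_dipot(sprintf(
      "no root of pi(A) = %.3g mN/m on the decreasing branch within [%.3g, %.3g] A^2",
      pi_mNm, model$area_range[1], model$area_range[2]), "no_root")
  }
  max(real)
}
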