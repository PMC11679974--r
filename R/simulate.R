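#' Ground truth for synthetic monolayer data
#'
#' Defines the "true" monolayer underlying the synthetic generators: a
#' polynomial pressure-area relation that is strictly decreasing over its
#' validity range, a saturation point on that curve, a transverse dipole
#' moment, an area-independent offset, and noise levels. The default
#' anchors emulate a POPC-like film: saturation at 49.4 A^2 / 50 mN/m, the
#' curve passing through (64.5 A^2, 30 mN/m), and a gentle tail to ~1 mN/m
#' at 100 A^2. All truth values are carried on the object so that recovery
#' by the analysis pipeline can be scored exactly.
#'
#' @param A_sat_A2 True saturation area per lipid (A^2).
#' @param pi_sat_mNm True saturation pressure (mN/m).
#' @param anchors Tibble (`area_A2`, `pi_mN_per_m`) of points the underlying
#'   polynomial must pass through; the first anchor is forced to the
#'   saturation point. Its length sets the polynomial degree (n - 1).
#' @param area_range Validity range of the polynomial (A^2); it must be
#'   strictly decreasing here.
#' @param mu_true_mD True transverse dipole moment (mD).
#' @param delta_V0_true_mV True area-independent offset (mV).
#' @param noise_pi_mNm Gaussian noise sd on pressures (mN/m), default 0.3.
#' @param noise_psi_mV Gaussian noise sd on potentials (mV), default 5
#'   (matching typical measurement scatter).
#' @return Object of class `monolayer_truth`: a list with the polynomial
#'   coefficients (ascending powers) and all parameters above.
#' @examples
#' popc_like_truth()
#' @export
popc_like_truth <- function(A_sat_A2 = 49.4, pi_sat_mNm = 50,
                            anchors = NULL,
                            area_range = c(A_sat_A2 - 8, 100),
                            mu_true_mD = 546, delta_V0_true_mV = 0,
                            noise_pi_mNm = 0.3, noise_psi_mV = 5) {
  if (is.null(anchors)) {
    # Default anchors lie on pi = c (A^-q - K) with q = 2.5, interpolating
    # the saturation point and (64.5 A^2, 30 mN/m). In amount space
    # (A proportional to 1/n at fixed trough area) this makes the pressure
    # rise with mildly increasing slope toward the saturation knee, the
    # compression-region geometry the two-line construction assumes: the
    # steepest contiguous window sits directly below the plateau.
    q <- 2.5
    cc <- (pi_sat_mNm - 30) / (A_sat_A2^-q - 64.5^-q)
    K <- A_sat_A2^-q - pi_sat_mNm / cc
    aa <- c(A_sat_A2, 64.5, 80, 100)
    anchors <- tibble::tibble(area_A2 = aa, pi_mN_per_m = cc * (aa^-q - K))
  }
  anchors$area_A2[1] <- A_sat_A2
  anchors$pi_mN_per_m[1] <- pi_sat_mNm
  deg <- nrow(anchors) - 1
  coefs <- solve(outer(anchors$area_A2, 0:deg, `^`), anchors$pi_mN_per_m)

  # the generator contract requires pi(A) strictly decreasing on area_range
  grid <- seq(area_range[1], area_range[2], length.out = 400)
  dcf <- coefs[-1] * seq_len(deg)
  deriv <- drop(outer(grid, seq_len(deg) - 1, `^`) %*% dcf)
  if (any(deriv >= 0)) {
    stop_dipot("anchor set yields a non-monotone pressure-area polynomial",
               "validation")
  }

  structure(
    list(
      A_sat_A2 = A_sat_A2, pi_sat_mNm = pi_sat_mNm,
      coefficients = unname(coefs), degree = deg, area_range = area_range,
      mu_true_mD = mu_true_mD, delta_V0_true_mV = delta_V0_true_mV,
      noise_pi_mNm = noise_pi_mNm, noise_psi_mV = noise_psi_mV
    ),
    class = "monolayer_truth"
  )
}

#' @export
print.monolayer_truth <- function(x, ...) {
  cat(sprintf(
    "<monolayer_truth> A_sat %.1f A^2, pi_sat %.1f mN/m, mu %.0f mD, dV0 %.0f mV\n",
    x$A_sat_A2, x$pi_sat_mNm, x$mu_true_mD, x$delta_V0_true_mV))
  invisible(x)
}

# evaluate the truth polynomial
truth_pi <- function(truth, area_A2) {
  drop(outer(area_A2, 0:truth$degree, `^`) %*% truth$coefficients)
}

#' Simulate a pressure-amount isotherm
#'
#' Emulates the constant-area spreading experiment: for each total amount of
#' lipid `n` the mean area per molecule is `A = trough / (N_A * n)`; the
#' pressure follows the truth polynomial, clipped above at the saturation
#' pressure (excess lipid leaves the interface, producing the plateau whose
#' knee sits exactly at the true saturation area), with additive Gaussian
#' noise clipped below at zero. The same seed and parameters always produce
#' the identical dataset (the seed is applied locally; global RNG state is
#' untouched).
#'
#' @param truth A [popc_like_truth()] object.
#' @param trough_area_cm2 Fixed trough area (cm^2), default 100.
#' @param n_points Number of additions (>= 10), default 40.
#' @param n_max_nmol Largest amount spread (nmol); default places the final
#'   point ~20% past the saturation amount.
#' @param pi_min_mNm Pressure at which recording starts (mN/m, default 10):
#'   the first point is placed where the truth curve reaches this pressure.
#'   Below ~10 mN/m the film is in the dilute regime that carries no
#'   information for the two-line construction.
#' @param seed Integer seed; `NULL` leaves the RNG stream alone.
#' @return Tibble (`n_nmol`, `pi_mN_per_m`) with attributes
#'   `trough_area_cm2` and `truth`.
#' @examples
#' iso <- simulate_pressure_amount(popc_like_truth(), seed = 1)
#' detect_saturation(iso)
#' @export
simulate_pressure_amount <- function(truth, trough_area_cm2 = 100,
                                     n_points = 40, n_max_nmol = NULL,
                                     pi_min_mNm = 10, seed = NULL) {
  stopifnot(inherits(truth, "monolayer_truth"))
  if (n_points < 10) stop_dipot("need at least 10 points", "validation")
  amount_at_area <- function(A) {
    trough_area_cm2 * 1e16 / (A * 1e-9 * .const$N_A)
  }
  A_start <- truth$area_range[2]
  if (truth_pi(truth, A_start) < pi_min_mNm) {
    A_start <- stats::uniroot(
      function(a) truth_pi(truth, a) - pi_min_mNm,
      c(truth$A_sat_A2, truth$area_range[2]), tol = 1e-10)$root
  }
  n_min <- amount_at_area(A_start)
  n_sat <- amount_at_area(truth$A_sat_A2)
  if (is.null(n_max_nmol)) n_max_nmol <- 1.2 * n_sat
  if (n_max_nmol <= n_min) {
    stop_dipot("n_max_nmol must exceed the amount at the largest valid area",
               "validation")
  }
  n <- seq(n_min, n_max_nmol, length.out = n_points)
  A <- trough_area_cm2 * 1e16 / (n * 1e-9 * .const$N_A)
  p_clean <- pmin(truth_pi(truth, A), truth$pi_sat_mNm)
  noise <- if (truth$noise_pi_mNm > 0) {
    if (!is.null(seed)) {
      withr::with_seed(seed, stats::rnorm(n_points, 0, truth$noise_pi_mNm))
    } else {
      stats::rnorm(n_points, 0, truth$noise_pi_mNm)
    }
  } else {
    0
  }
  out <- tibble::tibble(n_nmol = n, pi_mN_per_m = pmax(p_clean + noise, 0))
  attr(out, "trough_area_cm2") <- trough_area_cm2
  attr(out, "truth") <- truth
  out
}

#' Simulate a pressure-area isotherm
#'
#' Evaluates the truth polynomial on a supplied area grid with optional
#' Gaussian noise — the fixture for polynomial fitting and area-at-pressure
#' interpolation.
#'
#' @inheritParams simulate_pressure_amount
#' @param area_grid Areas (A^2) within the truth's validity range; must be
#'   non-empty.
#' @return Tibble (`area_A2`, `pi_mN_per_m`) with attribute `truth`.
#' @examples
#' simulate_area_isotherm(popc_like_truth(), seq(50, 95, 5))
#' @export
simulate_area_isotherm <- function(truth, area_grid, seed = NULL) {
  stopifnot(inherits(truth, "monolayer_truth"))
  if (length(area_grid) == 0) {
    stop_dipot("area_grid must be non-empty", "validation")
  }
  if (any(area_grid < truth$area_range[1] - 1e-9) ||
      any(area_grid > truth$area_range[2] + 1e-9)) {
    stop_dipot("area_grid extends beyond the truth polynomial's range",
               "validation")
  }
  p <- truth_pi(truth, area_grid)
  if (truth$noise_pi_mNm > 0) {
    noise <- if (!is.null(seed)) {
      withr::with_seed(seed,
                       stats::rnorm(length(area_grid), 0, truth$noise_pi_mNm))
    } else {
      stats::rnorm(length(area_grid), 0, truth$noise_pi_mNm)
    }
    p <- p + noise
  }
  out <- tibble::tibble(area_A2 = as.numeric(area_grid), pi_mN_per_m = p)
  attr(out, "truth") <- truth
  out
}

#' Simulate measured interfacial potentials
#'
#' Generates measured-potential replicates for a composition at a given
#' area: the Helmholtz dipole term from the true dipole moment, plus the
#' true offset, plus the Gouy-Chapman surface potential implied by the
#' composition's formal charge at that area, plus Gaussian noise. Inverting
#' these measurements with [analyze_monolayers()] recovers the true dipole
#' moment (exactly at zero noise, unbiasedly under noise).
#'
#' @inheritParams simulate_pressure_amount
#' @param comp Composition (string or tibble).
#' @param area_A2 Mean area per lipid (A^2).
#' @param sub Subphase for the surface-potential term.
#' @param n Number of replicates.
#' @param registry Lipid registry.
#' @return Numeric vector of measured potentials (mV), with the true
#'   surface potential attached as attribute `psi0_true_mV`.
#' @examples
#' simulate_potential_measurement(popc_like_truth(), "POPC", 49.4, n = 3,
#'                                seed = 1)
#' @export
simulate_potential_measurement <- function(truth, comp, area_A2,
                                           sub = study_subphase(), n = 1,
                                           seed = NULL,
                                           registry = lipid_registry()) {
  stopifnot(inherits(truth, "monolayer_truth"))
  if (area_A2 <= 0) stop_dipot("area must be positive", "validation")
  sigma <- surface_charge_density(area_A2, comp, registry)
  psi0 <- grahame_psi0(sigma, sub)
  clean <- helmholtz_potential(truth$mu_true_mD, area_A2,
                               truth$delta_V0_true_mV) + psi0
  noise <- if (truth$noise_psi_mV > 0) {
    if (!is.null(seed)) {
      withr::with_seed(seed, stats::rnorm(n, 0, truth$noise_psi_mV))
    } else {
      stats::rnorm(n, 0, truth$noise_psi_mV)
    }
  } else {
    rep(0, n)
  }
  out <- clean + noise
  attr(out, "psi0_true_mV") <- psi0
  out
}
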