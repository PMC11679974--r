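#' Helmholtz dipole-layer potential
#'
#' Treats the monolayer as a parallel-plate capacitor of aligned molecular
#' dipoles: the potential drop across the hydrated film is
#' `dV = 12 * pi * mu / A (+ dV0)` in millivolts, with the transverse dipole
#' moment `mu` in millidebye and the mean area per lipid `A` in square
#' angstroms. The optional area-independent offset `dV0` accommodates the
#' empirically observed finite intercept of dV versus 1/A (about 100 mV for
#' zwitterionic phospholipids).
#'
#' @param mu_perp_mD Transverse dipole moment (mD).
#' @param area_A2 Mean area per lipid (A^2, positive).
#' @param delta_V0_mV Area-independent offset (mV), default 0.
#' @return Dipole potential (mV). Vectorised over all arguments.
#' @examples
#' helmholtz_potential(546, 64.5)        # ~319 mV
#' helmholtz_potential(415, 64.5, 100)   # ~343 mV
#' @export
helmholtz_potential <- function(mu_perp_mD, area_A2, delta_V0_mV = 0) {
  if (any(area_A2 <= 0, na.rm = TRUE)) {
    stop_dipot("area per lipid must be positive", "validation")
  }
  .const$K_helmholtz * mu_perp_mD / area_A2 + delta_V0_mV
}

#' Transverse dipole moment from a dipole potential
#'
#' Inverse of [helmholtz_potential()]: `mu = (dV - dV0) * A / (12 * pi)`.
#' The transverse dipole moment is not measured directly; it is retrieved
#' from the dipole potential and the area per lipid.
#'
#' @param delta_V_mV Dipole potential (mV).
#' @inheritParams helmholtz_potential
#' @return Transverse dipole moment (mD). Vectorised.
#' @examples
#' helmholtz_dipole(417, 49.4)        # ~546 mD
#' helmholtz_dipole(494, 42, 100)     # ~439 mD
#' @export
helmholtz_dipole <- function(delta_V_mV, area_A2, delta_V0_mV = 0) {
  if (any(area_A2 <= 0, na.rm = TRUE)) {
    stop_dipot("area per lipid must be positive", "validation")
  }
  (delta_V_mV - delta_V0_mV) * area_A2 / .const$K_helmholtz
}

#' Surface charge density of a monolayer
#'
#' Mole-fraction-weighted formal charge per molecule divided by the area per
#' molecule: `sigma = sum(x_i * z_i) * e / (A * 1e-20)` in C/m^2.
#'
#' @param area_A2 Mean area per lipid (A^2, positive).
#' @param comp Composition (string, or tibble from [composition()]).
#' @param registry Lipid registry supplying formal charges.
#' @return Surface charge density (C/m^2); negative for anionic films.
#' @examples
#' surface_charge_density(49.4, "POPS")            # ~ -0.324
#' surface_charge_density(49.7, "POPC:POPS (9:1)") # ~ -0.032
#' @export
surface_charge_density <- function(area_A2, comp, registry = lipid_registry()) {
  if (any(area_A2 <= 0, na.rm = TRUE)) {
    stop_dipot("area per lipid must be positive", "validation")
  }
  zbar <- mean_formal_charge(comp, registry)
  zbar * .const$e_charge / (area_A2 * 1e-20)
}

# sigma(psi) for an arbitrary electrolyte: the Grahame relation
# sigma^2 = 2000 eps0 epsr R T sum_i C_i (exp(-z_i F psi / (R T)) - 1),
# signed with sign(psi). psi in volts, C_i in mol/L, sigma in C/m^2.
grahame_sigma_of_psi <- function(psi_V, species, temperature_K,
                                 rel_permittivity) {
  RT <- .const$R * temperature_K
  s2 <- vapply(psi_V, function(v) {
    sum(species$conc_M * expm1(-species$z * .const$F * v / RT))
  }, numeric(1))
  s2 <- 2000 * .const$eps0 * rel_permittivity * RT * s2
  # s2 >= 0 analytically; clamp tiny negative rounding
  sign(psi_V) * sqrt(pmax(s2, 0))
}

#' Diffuse-layer surface potential from the Grahame equation
#'
#' Solves the Gouy-Chapman (Grahame) relation between the surface charge
#' density and the diffuse-double-layer potential,
#' `sigma^2 = 2000 eps0 epsr R T sum_i C_i (exp(-z_i F psi0 / (R T)) - 1)`,
#' for an arbitrary electroneutral electrolyte mixture, by bracketed
#' root-finding on the monotone function sigma(psi0). The returned potential
#' carries the sign of the charge density. For a single 1:1 electrolyte the
#' solution coincides with the closed form
#' `psi0 = (2RT/F) asinh(sigma / sqrt(8000 eps0 epsr R T C))`.
#'
#' @param sigma_C_m2 Surface charge density (C/m^2); vectorised.
#' @param sub A [subphase()] object (electroneutral; at least one species
#'   with positive concentration unless sigma is 0).
#' @param bracket_mV Initial search bracket for |psi0| (mV); widened once to
#'   twice its value if the root is not contained, then an error is raised.
#' @param tol Convergence tolerance on the charge-density residual (C/m^2).
#' @return Surface potential psi0 (mV), same sign as sigma.
#' @examples
#' grahame_psi0(-0.3243, study_subphase()) # ~ -136.8 mV
#' @export
grahame_psi0 <- function(sigma_C_m2, sub = study_subphase(),
                         bracket_mV = 500, tol = 1e-10) {
  stopifnot(inherits(sub, "subphase"))
  species <- sub$species[sub$species$conc_M > 0, ]
  vapply(sigma_C_m2, function(sig) {
    if (!is.finite(sig)) return(NA_real_)
    if (sig == 0) return(0)
    if (nrow(species) == 0) {
      stop_dipot("charged surface in an ion-free subphase has no finite psi0",
                 "bracket")
    }
    f <- function(psi_V) {
      grahame_sigma_of_psi(psi_V, species, sub$temperature_K,
                           sub$rel_permittivity) - sig
    }
    b <- bracket_mV / 1000
    if (f(-b) * f(b) > 0) {
      b <- 2 * b
      if (f(-b) * f(b) > 0) {
        stop_dipot(sprintf(
          "no sign change of the Grahame residual within +/- %.0f mV",
          b * 1000), "bracket")
      }
    }
    root <- stats::uniroot(f, c(-b, b), tol = 1e-14)$root
    # polish by bisection until the charge-density residual meets `tol`
    lo <- root - 1e-9; hi <- root + 1e-9
    if (f(lo) * f(hi) <= 0) {
      while (abs(f(root)) > tol && (hi - lo) > 1e-17) {
        mid <- (lo + hi) / 2
        if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
        root <- mid
      }
    }
    root * 1000
  }, numeric(1))
}

#' Correct a measured interfacial potential for the surface-charge term
#'
#' For charged monolayers the measured potential is the sum of the dipole
#' potential and the diffuse-double-layer surface potential:
#' `psi_measured = psi_dipole + psi0`. This returns
#' `psi_dipole = psi_measured - psi0`; for anionic films (psi0 < 0) the
#' dipole potential therefore exceeds the measured value.
#'
#' @param psi_measured_mV Measured potential (mV).
#' @param psi0_mV Gouy-Chapman surface potential (mV).
#' @return Dipole potential (mV). Vectorised.
#' @examples
#' correct_measured_potential(330, -135) # 465
#' @export
correct_measured_potential <- function(psi_measured_mV, psi0_mV) {
  psi_measured_mV - psi0_mV
}

#' Full electrostatic analysis of monolayer records
#'
#' The per-composition pipeline: from the measured potential and the areas
#' per lipid at saturation and at 30 mN/m, compute the surface charge
#' density at saturation, the Gouy-Chapman surface potential, the corrected
#' saturation dipole potential, the transverse dipole moment under the plain
#' Helmholtz relation (`dV0 = 0`, "eq1" columns) and under the offset
#' variant (`dV0 = delta_V0_mV`, "eq2" columns), and the dipole potential
#' re-projected to 30 mN/m from each dipole moment and the 30 mN/m area.
#'
#' Input rows may carry either `psi_measured_mV` (raw measurement, corrected
#' here) or `psi_dipole_sat_mV` (already corrected). Rows lacking
#' `A_sat_A2` may supply the dipole moments directly through
#' `mu_eq1_given_mD` / `mu_eq2_given_mD` (and optionally
#' `psi30_eq1_given_mV` / `psi30_eq2_given_mV`), which are passed through
#' unchanged; this accommodates literature records for which the saturation
#' area is not available.
#'
#' @param data Tibble with columns `composition`, `A_sat_A2`, `A30_A2` and
#'   one of `psi_measured_mV` / `psi_dipole_sat_mV`; optional given-value
#'   columns as described above.
#' @param sub Subphase for the Gouy-Chapman correction.
#' @param delta_V0_mV Area-independent offset for the "eq2" variant (mV),
#'   default 100.
#' @param registry Lipid registry.
#' @return The input tibble augmented with `sigma_C_m2`, `psi0_mV`,
#'   `psi_dipole_sat_mV`, `mu_eq1_mD`, `psi30_eq1_mV`, `mu_eq2_mD`,
#'   `psi30_eq2_mV`.
#' @examples
#' analyze_monolayers(tibble::tibble(
#'   composition = "POPC", psi_measured_mV = 417,
#'   A_sat_A2 = 49.4, A30_A2 = 64.5))
#' @export
analyze_monolayers <- function(data, sub = study_subphase(),
                               delta_V0_mV = 100,
                               registry = lipid_registry()) {
  check_columns(data, c("composition", "A_sat_A2", "A30_A2"),
                "monolayer records")
  if (!any(c("psi_measured_mV", "psi_dipole_sat_mV") %in% names(data))) {
    stop_dipot("need a psi_measured_mV or psi_dipole_sat_mV column",
               "missing_field")
  }
  data <- tibble::as_tibble(data)
  n <- nrow(data)
  get_opt <- function(col) {
    if (col %in% names(data)) data[[col]] else rep(NA_real_, n)
  }
  psi_meas <- get_opt("psi_measured_mV")
  psi_dip_in <- get_opt("psi_dipole_sat_mV")
  mu1_given <- get_opt("mu_eq1_given_mD")
  mu2_given <- get_opt("mu_eq2_given_mD")
  p301_given <- get_opt("psi30_eq1_given_mV")
  p302_given <- get_opt("psi30_eq2_given_mV")

  out <- purrr::pmap(
    list(data$composition, psi_meas, psi_dip_in, data$A_sat_A2, data$A30_A2,
         mu1_given, mu2_given, p301_given, p302_given),
    function(comp, pm, pd, a_sat, a30, mu1g, mu2g, p301g, p302g) {
      sigma <- NA_real_
      psi0 <- NA_real_
      if (is.finite(a_sat)) {
        sigma <- surface_charge_density(a_sat, comp, registry)
        psi0 <- grahame_psi0(sigma, sub)
      } else if (mean_formal_charge(comp, registry) == 0) {
        psi0 <- 0
      }
      psi_dip <- if (is.finite(pd)) pd else pm - psi0
      if (is.finite(a_sat)) {
        mu1 <- helmholtz_dipole(psi_dip, a_sat, 0)
        mu2 <- helmholtz_dipole(psi_dip, a_sat, delta_V0_mV)
      } else {
        mu1 <- mu1g
        mu2 <- mu2g
      }
      p301 <- if (is.finite(p301g)) p301g else
        if (is.finite(mu1) && is.finite(a30))
          helmholtz_potential(mu1, a30, 0) else NA_real_
      p302 <- if (is.finite(p302g)) p302g else
        if (is.finite(mu2) && is.finite(a30))
          helmholtz_potential(mu2, a30, delta_V0_mV) else NA_real_
      tibble::tibble(
        sigma_C_m2 = sigma, psi0_mV = psi0, psi_dipole_sat_mV = psi_dip,
        mu_eq1_mD = mu1, psi30_eq1_mV = p301,
        mu_eq2_mD = mu2, psi30_eq2_mV = p302
      )
    }
  )
  derived <- dplyr::bind_rows(out)
  keep <- setdiff(names(data), names(derived))
  dplyr::bind_cols(data[keep], derived)
}

#' Round an analyzed monolayer table for reporting
#'
#' Applies the conventional integer rounding (ties away from zero) to the
#' dipole-moment and potential columns, leaving the areas untouched.
#'
#' @param records Output of [analyze_monolayers()].
#' @return Tibble with rounded `psi_dipole_sat_mV`, `mu_eq1_mD`,
#'   `psi30_eq1_mV`, `mu_eq2_mD`, `psi30_eq2_mV` (and `psi0_mV`).
#' @export
round_report <- function(records) {
  cols <- intersect(
    c("psi0_mV", "psi_dipole_sat_mV", "mu_eq1_mD", "psi30_eq1_mV",
      "mu_eq2_mD", "psi30_eq2_mV"),
    names(records)
  )
  dplyr::mutate(records, dplyr::across(dplyr::all_of(cols), round_half_away))
}
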