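#' Registry of the study lipids
#'
#' Tabulates the lipid species handled by the analysis: name, formal charge
#' per molecule (elementary charges; phosphatidylserine carries -1 at
#' physiological pH, the other headgroups are zwitterionic), and, where the
#' literature provides them, a reference pure-monolayer area per molecule and
#' transverse dipole moment used by the mixture additivity predictions.
#' Cholesterol's reference values (30 A^2, 373 mD) come from classic
#' monolayer work; cholesterol monolayers are not measured by this pipeline.
#'
#' @param extra Optional tibble of additional species with the same columns
#'   (`lipid`, `formal_charge`, `ref_area_A2`, `ref_dipole_mD`); appended
#'   after validation.
#' @return A tibble with one row per species.
#' @examples
#' lipid_registry()
#' @export
lipid_registry <- function(extra = NULL) {
  reg <- tibble::tibble(
    lipid = c("POPC", "POPE", "POPS", "SPM", "CHOL"),
    formal_charge = c(0L, 0L, -1L, 0L, 0L),
    ref_area_A2 = c(NA, NA, NA, NA, 30),
    ref_dipole_mD = c(NA, NA, NA, NA, 373)
  )
  if (!is.null(extra)) {
    check_columns(extra, c("lipid", "formal_charge"), "extra registry entries")
    extra <- tibble::as_tibble(extra)
    if (!"ref_area_A2" %in% names(extra)) extra$ref_area_A2 <- NA_real_
    if (!"ref_dipole_mD" %in% names(extra)) extra$ref_dipole_mD <- NA_real_
    reg <- dplyr::bind_rows(reg, extra[names(reg)])
  }
  if (anyDuplicated(reg$lipid)) {
    stop_dipot("lipid names must be unique in the registry", "validation")
  }
  if (any(!is.na(reg$ref_area_A2) & reg$ref_area_A2 <= 0)) {
    stop_dipot("reference areas must be positive", "validation")
  }
  reg
}

#' Define an electrolyte subphase
#'
#' Builds the aqueous-subphase description consumed by the Grahame solver:
#' a set of ionic species (bulk concentration in mol/L and integer valence),
#' the temperature and the relative permittivity of the medium. The species
#' set must be electroneutral; alternatively a monovalent counter-ion can be
#' added automatically to balance the charge.
#'
#' @param species Tibble (or data frame) with columns `ion`, `z` (integer
#'   valence) and `conc_M` (mol/L, non-negative).
#' @param temperature_K Absolute temperature (K), default 298.15.
#' @param rel_permittivity Relative permittivity of the medium
#'   (dimensionless, > 1), default 78.5 (water at 25 C).
#' @param auto_counterion If `TRUE`, a monovalent counter-ion (named
#'   `"counter"`) is appended to restore electroneutrality instead of
#'   erroring.
#' @return An object of class `subphase`: a list with elements `species`,
#'   `temperature_K`, `rel_permittivity`.
#' @examples
#' subphase(tibble::tibble(ion = c("Na+", "Cl-"), z = c(1, -1),
#'                         conc_M = c(0.15, 0.15)))
#' @export
subphase <- function(species, temperature_K = 298.15, rel_permittivity = 78.5,
                     auto_counterion = FALSE) {
  check_columns(species, c("ion", "z", "conc_M"), "subphase species")
  species <- tibble::as_tibble(species)
  if (any(species$conc_M < 0)) {
    stop_dipot("electrolyte concentrations must be non-negative", "validation")
  }
  if (any(species$z == 0)) {
    stop_dipot("electrolyte species must have non-zero valence", "validation")
  }
  imbalance <- sum(species$z * species$conc_M)
  if (abs(imbalance) > 1e-9) {
    if (auto_counterion) {
      species <- dplyr::bind_rows(
        species,
        tibble::tibble(ion = "counter", z = -sign(imbalance),
                       conc_M = abs(imbalance))
      )
    } else {
      stop_dipot(
        sprintf("subphase is not electroneutral (sum z*C = %.3g mol/L); %s",
                imbalance, "fix concentrations or use auto_counterion = TRUE"),
        class = "validation"
      )
    }
  }
  if (temperature_K <= 0) stop_dipot("temperature must be positive", "validation")
  if (rel_permittivity <= 1) {
    stop_dipot("relative permittivity must exceed 1", "validation")
  }
  structure(
    list(species = species, temperature_K = temperature_K,
         rel_permittivity = rel_permittivity),
    class = "subphase"
  )
}

#' @export
print.subphase <- function(x, ...) {
  cat(sprintf("<subphase> %.2f K, eps_r = %.1f\n", x$temperature_K,
              x$rel_permittivity))
  print(x$species)
  invisible(x)
}

#' The study subphase
#'
#' The buffer of the monolayer experiments: 150 mM NaCl with HEPES 10 mM,
#' EDTA 1 mM and azide at pH 7.4. By default only the dominant NaCl is
#' modelled, as a 1:1 electrolyte at 298.15 K with relative permittivity
#' 78.5. With `extended = TRUE` the buffer components are included as an
#' approximate speciation (HEPES as a 1:1 pair at half the nominal
#' concentration given its pKa near 7.5, EDTA as a divalent anion with Na+
#' counter-ions); this shifts computed surface potentials by a few mV at
#' most and is provided for sensitivity checks.
#'
#' @param extended Include the approximate buffer speciation beyond NaCl.
#' @inheritParams subphase
#' @return A `subphase` object.
#' @examples
#' study_subphase()
#' @export
study_subphase <- function(extended = FALSE, temperature_K = 298.15,
                           rel_permittivity = 78.5) {
  sp <- tibble::tibble(
    ion = c("Na+", "Cl-"),
    z = c(1, -1),
    conc_M = c(0.150, 0.150)
  )
  if (extended) {
    sp <- dplyr::bind_rows(
      sp,
      tibble::tibble(
        ion = c("HEPES-", "Na+(HEPES)", "EDTA2-", "Na+(EDTA)"),
        z = c(-1, 1, -2, 1),
        conc_M = c(0.005, 0.005, 0.001, 0.002)
      )
    )
  }
  subphase(sp, temperature_K = temperature_K,
           rel_permittivity = rel_permittivity)
}
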