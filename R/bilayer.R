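#' Transbilayer dipole potential of an asymmetric membrane
#'
#' For a bilayer whose leaflets have different lipid compositions, the
#' transbilayer dipole potential is the difference between the leaflet
#' dipole potentials, taken as inner minus outer (positive for the
#' plasma-membrane model, whose inner leaflet carries the larger dipole
#' potential). Three modes select which potential is differenced: the
#' saturation value, or the 30 mN/m value under either Helmholtz variant.
#' Optionally the diffuse-layer surface potential of each leaflet is added
#' before differencing (`include_psi0 = TRUE`), giving the total interfacial
#' potential difference; for the saturation mode both variants are of
#' interest because the charged inner leaflet adds a negative surface term.
#'
#' @param records Analyzed monolayer tibble (from [analyze_monolayers()])
#'   with a `composition` column.
#' @param inner,outer Composition strings selecting the two leaflets.
#' @param mode One of `"sat"`, `"30mNm_eq1"`, `"30mNm_eq2"`.
#' @param include_psi0 Add each leaflet's `psi0_mV` to its dipole potential
#'   before differencing (requires finite `psi0_mV` for both rows).
#' @return Transbilayer potential (mV), inner minus outer.
#' @examples
#' tbl <- study_dipole_table(rounded = TRUE)
#' transbilayer_potential(tbl, "POPC:CHOL:POPE:POPS (4:3:2:1)",
#'                        "SPM:CHOL (6:4)", mode = "30mNm_eq1") # 26
#' @export
transbilayer_potential <- function(records, inner, outer,
                                   mode = c("sat", "30mNm_eq1", "30mNm_eq2"),
                                   include_psi0 = FALSE) {
  mode <- match.arg(mode)
  col <- switch(mode,
    sat = "psi_dipole_sat_mV",
    `30mNm_eq1` = "psi30_eq1_mV",
    `30mNm_eq2` = "psi30_eq2_mV"
  )
  check_columns(records, c("composition", col), "records")
  pick <- function(cmp) {
    i <- match(cmp, records$composition)
    if (is.na(i)) {
      stop_dipot(sprintf("composition '%s' not found in records", cmp),
                 "missing_field")
    }
    v <- records[[col]][i]
    if (!is.finite(v)) {
      stop_dipot(sprintf("'%s' has no %s value", cmp, col), "missing_field")
    }
    if (include_psi0) {
      p0 <- records[["psi0_mV"]][i]
      if (is.null(p0) || !is.finite(p0)) {
        stop_dipot(sprintf("'%s' has no psi0_mV value", cmp), "missing_field")
      }
      v <- v + p0
    }
    v
  }
  pick(inner) - pick(outer)
}

#' Percent change between two values
#'
#' `100 * (to - from) / from`, rounded to the nearest integer with ties away
#' from zero — the convention used when quoting dipole-potential changes.
#'
#' @param from,to Numeric values; `from` must be non-zero.
#' @return Integer percent change. Vectorised.
#' @examples
#' percent_change(341, 408) # 20
#' percent_change(463, 481) # 4
#' @export
percent_change <- function(from, to) {
  if (any(from == 0)) {
    stop_dipot("percent change from zero is undefined", "validation")
  }
  round_half_away(100 * (to - from) / from)
}

#' Correlation between saturation and 30 mN/m dipole potentials
#'
#' Ordinary least-squares fit of the 30 mN/m dipole potential (under the
#' chosen Helmholtz variant) on the saturation dipole potential across a set
#' of monolayer systems. A weak correlation indicates that compression from
#' 30 mN/m to saturation changes the dipole density by very different
#' amounts across compositions.
#'
#' @param records Analyzed monolayer tibble; rows lacking either potential
#'   are dropped.
#' @param eq `"eq1"` (plain Helmholtz) or `"eq2"` (with the 100 mV offset).
#' @return An object of class `pressure_cor` with elements `slope`,
#'   `intercept`, `r`, `r_squared`, `n`, `eq` and the underlying `lm` fit;
#'   `tidy()` and `glance()` methods are provided.
#' @examples
#' glance(pressure_correlation(study_dipole_table(rounded = TRUE)))
#' @export
pressure_correlation <- function(records, eq = c("eq1", "eq2")) {
  eq <- match.arg(eq)
  ycol <- paste0("psi30_", eq, "_mV")
  check_columns(records, c("psi_dipole_sat_mV", ycol), "records")
  d <- records[is.finite(records$psi_dipole_sat_mV) &
                 is.finite(records[[ycol]]), ]
  if (nrow(d) < 3) {
    stop_dipot("need at least 3 records with both potentials", "validation")
  }
  fit <- stats::lm(d[[ycol]] ~ d$psi_dipole_sat_mV)
  r <- stats::cor(d$psi_dipole_sat_mV, d[[ycol]])
  structure(
    list(
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r = r,
      r_squared = r^2,
      n = nrow(d),
      eq = eq,
      fit = fit,
      data = tibble::tibble(psi_sat_mV = d$psi_dipole_sat_mV,
                            psi30_mV = d[[ycol]])
    ),
    class = "pressure_cor"
  )
}

#' @export
print.pressure_cor <- function(x, ...) {
  cat(sprintf(
    "<pressure_cor> psi30(%s) = %.3f * psi_sat %+.1f mV; R^2 = %.3f (n = %d)\n",
    x$eq, x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' @export
tidy.pressure_cor <- function(x, ...) {
  tibble::tibble(term = c("intercept", "psi_sat_mV"),
                 estimate = c(x$intercept, x$slope))
}

#' @export
glance.pressure_cor <- function(x, ...) {
  tibble::tibble(r = x$r, r_squared = x$r_squared, n = x$n, eq = x$eq)
}

#' Compare retrieved dipole moments with literature reference values
#'
#' Relative differences `(mu_calc - mu_ref) / mu_ref` between the dipole
#' moments retrieved here and reference values from earlier monolayer work,
#' per lipid and per Helmholtz variant.
#'
#' @param records Analyzed monolayer tibble containing the pure lipids.
#' @param reference Named numeric vector of reference dipole moments (mD);
#'   default [reference_dipoles()].
#' @return Tibble with columns `lipid`, `eq`, `mu_calc_mD`, `mu_ref_mD`,
#'   `rel_diff` (fraction) and `rel_diff_pct`.
#' @examples
#' compare_reference_dipoles(study_dipole_table(rounded = TRUE))
#' @export
compare_reference_dipoles <- function(records, reference = reference_dipoles()) {
  check_columns(records, c("composition", "mu_eq1_mD", "mu_eq2_mD"), "records")
  lipids <- names(reference)
  idx <- match(lipids, records$composition)
  if (anyNA(idx)) {
    stop_dipot(sprintf("records lack reference lipid(s): %s",
                       paste(lipids[is.na(idx)], collapse = ", ")),
               "missing_reference")
  }
  tidyr::crossing(lipid = lipids, eq = c("eq1", "eq2")) |>
    dplyr::mutate(
      mu_calc_mD = purrr::map2_dbl(.data$lipid, .data$eq, function(l, e) {
        records[[paste0("mu_", e, "_mD")]][match(l, records$composition)]
      }),
      mu_ref_mD = unname(reference[.data$lipid]),
      rel_diff = (.data$mu_calc_mD - .data$mu_ref_mD) / .data$mu_ref_mD,
      rel_diff_pct = 100 * .data$rel_diff
    )
}

#' Linear relation between partition free energy and dipole potential
#'
#' Fits, by ordinary least squares, the relative partition free energy of an
#' amphiphile (water to membrane, relative to POPC; kJ/mol) against the
#' membrane dipole potential. Points can be held out of the fit (e.g. the
#' complex mixtures) and their residuals against the fitted line reported.
#'
#' @param pairs Tibble with columns `psi_d_mV` and `ddG_kJ_mol`; optional
#'   `system` labels.
#' @param holdout Optional logical vector (or column name) marking rows
#'   excluded from the fit but evaluated against it.
#' @return Object of class `partition_fit` with elements `slope`,
#'   `intercept`, `r`, `r_squared`, `n`, `residuals` (tibble incl. held-out
#'   rows, with `held_out` flag); `tidy()`/`glance()` methods provided.
#' @examples
#' d <- tibble::tibble(psi_d_mV = c(417, 463, 490),
#'                     ddG_kJ_mol = c(0, -1.8, -2.9))
#' glance(partition_energy_fit(d))
#' @export
partition_energy_fit <- function(pairs, holdout = NULL) {
  check_columns(pairs, c("psi_d_mV", "ddG_kJ_mol"), "partition pairs")
  pairs <- tibble::as_tibble(pairs)
  if (is.character(holdout) && length(holdout) == 1) {
    holdout <- as.logical(pairs[[holdout]])
  }
  if (is.null(holdout)) holdout <- rep(FALSE, nrow(pairs))
  fit_rows <- pairs[!holdout, ]
  if (nrow(fit_rows) < 3) {
    stop_dipot("need at least 3 non-held-out pairs", "validation")
  }
  fit <- stats::lm(ddG_kJ_mol ~ psi_d_mV, data = fit_rows)
  cf <- stats::coef(fit)
  pred <- cf[1] + cf[2] * pairs$psi_d_mV
  r <- stats::cor(fit_rows$psi_d_mV, fit_rows$ddG_kJ_mol)
  structure(
    list(
      slope = unname(cf[2]),
      intercept = unname(cf[1]),
      r = r,
      r_squared = r^2,
      n = nrow(fit_rows),
      fit = fit,
      residuals = dplyr::mutate(pairs,
                                predicted = pred,
                                residual = .data$ddG_kJ_mol - pred,
                                held_out = holdout)
    ),
    class = "partition_fit"
  )
}

#' @export
print.partition_fit <- function(x, ...) {
  cat(sprintf(
    "<partition_fit> ddG = %.4g * psi_d %+.4g kJ/mol; R^2 = %.3f (n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' @export
tidy.partition_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "psi_d_mV"),
                 estimate = c(x$intercept, x$slope))
}

#' @export
glance.partition_fit <- function(x, ...) {
  tibble::tibble(r = x$r, r_squared = x$r_squared, n = x$n)
}

#' Cross-system summary of the study records
#'
#' Collects the headline derived statistics into one tibble: the
#' transbilayer potentials of the plasma-membrane model (inner
#' quaternary mixture versus outer SPM:CHOL leaflet) at saturation and at
#' 30 mN/m, the POPC-POPE leaflet difference, the cholesterol-induced
#' percent changes, and the saturation/30 mN/m correlation under both
#' Helmholtz variants.
#'
#' @param records Analyzed monolayer tibble; default the rounded study table.
#' @return Tibble with columns `quantity`, `value`, `units`.
#' @examples
#' bilayer_summary()
#' @export
bilayer_summary <- function(records = study_dipole_table(rounded = TRUE)) {
  inner <- "POPC:CHOL:POPE:POPS (4:3:2:1)"
  outer <- "SPM:CHOL (6:4)"
  r2 <- function(eq) glance(pressure_correlation(records, eq))$r_squared
  val <- function(cmp) {
    records$psi_dipole_sat_mV[match(cmp, records$composition)]
  }
  tibble::tibble(
    quantity = c(
      "transbilayer_sat_mV", "transbilayer_sat_incl_psi0_mV",
      "transbilayer_30mNm_eq1_mV", "transbilayer_30mNm_eq2_mV",
      "popc_pope_sat_mV", "popc_pope_30mNm_eq1_mV",
      "pct_spm_to_spmchol", "pct_pcchol73_to_ternary",
      "r_squared_eq1", "r_squared_eq2"
    ),
    value = c(
      transbilayer_potential(records, inner, outer, "sat"),
      transbilayer_potential(records, inner, outer, "sat",
                             include_psi0 = TRUE),
      transbilayer_potential(records, inner, outer, "30mNm_eq1"),
      transbilayer_potential(records, inner, outer, "30mNm_eq2"),
      transbilayer_potential(records, "POPE", "POPC", "sat"),
      transbilayer_potential(records, "POPE", "POPC", "30mNm_eq1"),
      percent_change(val("SPM"), val("SPM:CHOL (6:4)")),
      percent_change(val("POPC:CHOL (7:3)"), val("POPC:CHOL:POPE (5:3:2)")),
      r2("eq1"), r2("eq2")
    ),
    units = c(rep("mV", 6), rep("%", 2), rep("", 2))
  )
}
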