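#' Additive (linear-combination) prediction for a mixture property
#'
#' Predicts a per-molecule property of a mixed monolayer (area per lipid,
#' transverse dipole moment) as the mole-fraction-weighted linear
#' combination of the pure-component values: `sum(x_i * v_i)`. Deviations
#' of the observed value from this prediction quantify condensation
#' (observed below) or expansion (observed above).
#'
#' @param comp Composition (string or tibble from [composition()]).
#' @param pure_values Named numeric vector mapping species to pure values;
#'   every species in the composition must be present.
#' @param registry Lipid registry (used when `comp` is a string).
#' @return The predicted value (same units as `pure_values`).
#' @examples
#' predict_additive("POPC:CHOL (7:3)", c(POPC = 64.5, CHOL = 30)) # 54.15
#' @export
predict_additive <- function(comp, pure_values, registry = lipid_registry()) {
  if (is.character(comp)) comp <- parse_composition(comp, registry)
  missing <- setdiff(comp$lipid, names(pure_values))
  if (length(missing) > 0) {
    stop_dipot(sprintf("no pure value for species: %s",
                       paste(missing, collapse = ", ")),
               "missing_pure_value")
  }
  v <- pure_values[comp$lipid]
  if (anyNA(v)) {
    stop_dipot(sprintf("pure value is NA for species: %s",
                       paste(comp$lipid[is.na(v)], collapse = ", ")),
               "missing_pure_value")
  }
  sum(comp$fraction * v)
}

#' Replacement prediction for a mixture property
#'
#' Alternative prediction for ternary/quaternary mixtures built around a
#' reference binary (e.g. POPC:CHOL 7:3): the reference pair is assumed to
#' keep its measured per-lipid value, and the fraction of the base lipid
#' that was substituted is replaced by the pure values of the substituting
#' species: `base_fraction * base_value + sum(f_j * v_j)`, with
#' `base_fraction + sum(f_j) = 1`.
#'
#' @param base_value Measured per-lipid value of the reference binary,
#'   counting all molecules (e.g. 48.0 A^2 for POPC:CHOL 7:3).
#' @param base_fraction Mole fraction of the mixture occupied by the
#'   reference pair.
#' @param substitutions Named numeric vector of substituted mole fractions
#'   (names are species, for the report only).
#' @param values Named numeric vector of the substituting species' pure
#'   values, same names.
#' @return The predicted value.
#' @examples
#' # ternary 5:3:2: 80% POPC:CHOL pair at 48.0 plus 20% POPE at 56.0
#' predict_replacement(48.0, 0.8, c(POPE = 0.2), c(POPE = 56.0)) # 49.6
#' @export
predict_replacement <- function(base_value, base_fraction, substitutions,
                                values) {
  if (abs(base_fraction + sum(substitutions) - 1) > 1e-9) {
    stop_dipot("base fraction plus substituted fractions must sum to 1",
               "validation")
  }
  missing <- setdiff(names(substitutions), names(values))
  if (length(missing) > 0) {
    stop_dipot(sprintf("no pure value for species: %s",
                       paste(missing, collapse = ", ")),
               "missing_pure_value")
  }
  base_fraction * base_value +
    sum(substitutions * values[names(substitutions)])
}

#' Deviation report for mixture predictions
#'
#' Given predicted and observed per-lipid values, computes absolute and
#' relative deviations and classifies each system as condensed (observed
#' below prediction) or expanded (observed above), the pattern visualised
#' by predicted-versus-observed plots with an identity line.
#'
#' @param predictions Tibble with columns `composition`, `property`,
#'   `scheme`, `predicted`, `observed`.
#' @return The input with `deviation_abs` (obs - pred), `deviation_rel`
#'   ((obs - pred)/pred) and `direction` ("condensed", "expanded" or
#'   "additive" when the deviation is exactly zero) appended.
#' @examples
#' deviation_report(tibble::tibble(
#'   composition = "POPC:CHOL (7:3)", property = "area_A2",
#'   scheme = "additive", predicted = 54.15, observed = 48.0))
#' @export
deviation_report <- function(predictions) {
  check_columns(predictions,
                c("composition", "property", "scheme", "predicted", "observed"),
                "prediction table")
  if (anyNA(predictions$observed)) {
    stop_dipot("observed values must be present for a deviation report",
               "validation")
  }
  dplyr::mutate(
    tibble::as_tibble(predictions),
    deviation_abs = .data$observed - .data$predicted,
    deviation_rel = (.data$observed - .data$predicted) / .data$predicted,
    direction = dplyr::case_when(
      .data$deviation_abs < 0 ~ "condensed",
      .data$deviation_abs > 0 ~ "expanded",
      TRUE ~ "additive"
    )
  )
}

#' Mixture predictions for the study systems
#'
#' Assembles the predicted-versus-observed table for the mixed monolayers of
#' the study: additive predictions for every mixture from the pure-component
#' values, plus replacement predictions for the ternary and quaternary
#' mixtures (POPC:CHOL 7:3 kept as the reference pair, substituted POPC
#' replaced by POPE/POPS). Areas are the 30 mN/m values; dipole moments are
#' the plain-Helmholtz ("eq1", default) or offset ("eq2") estimates.
#' Cholesterol, not measured as a pure monolayer, contributes its registry
#' reference values (30 A^2, 373 mD).
#'
#' @param records Analyzed records, default [study_dipole_table()].
#' @param eq Which dipole-moment basis to use for the mu predictions.
#' @param registry Lipid registry (for cholesterol's reference values).
#' @return A deviation report tibble (see [deviation_report()]).
#' @examples
#' study_mixture_table()
#' @export
study_mixture_table <- function(records = study_dipole_table(), eq = c("eq1", "eq2"),
                                registry = lipid_registry()) {
  eq <- match.arg(eq)
  mu_col <- paste0("mu_", eq, "_mD")
  check_columns(records, c("composition", "A30_A2", mu_col), "records")

  pure <- c("POPC", "POPE", "POPS", "SPM")
  idx <- match(pure, records$composition)
  if (anyNA(idx)) {
    stop_dipot("records must contain the four pure lipids", "validation")
  }
  chol <- registry[registry$lipid == "CHOL", ]
  pure_area <- c(stats::setNames(records$A30_A2[idx], pure),
                 CHOL = chol$ref_area_A2)
  pure_mu <- c(stats::setNames(records[[mu_col]][idx], pure),
               CHOL = chol$ref_dipole_mD)

  mixtures <- setdiff(records$composition, pure)
  obs_area <- stats::setNames(records$A30_A2, records$composition)
  obs_mu <- stats::setNames(records[[mu_col]], records$composition)

  additive <- purrr::map_dfr(mixtures, function(cmp) {
    tibble::tibble(
      composition = cmp,
      property = c("area_A2", "mu_mD"),
      scheme = "additive",
      predicted = c(predict_additive(cmp, pure_area, registry),
                    predict_additive(cmp, pure_mu, registry)),
      observed = c(obs_area[[cmp]], obs_mu[[cmp]])
    )
  })

  # replacement scheme: POPC:CHOL 7:3 as the reference pair
  base <- "POPC:CHOL (7:3)"
  repl <- NULL
  if (base %in% records$composition) {
    base_area <- obs_area[[base]]
    base_mu <- obs_mu[[base]]
    repl_defs <- list(
      "POPC:CHOL:POPE (5:3:2)" = c(POPE = 0.2),
      "POPC:CHOL:POPE:POPS (4:3:2:1)" = c(POPE = 0.2, POPS = 0.1)
    )
    repl_defs <- repl_defs[names(repl_defs) %in% records$composition]
    repl <- purrr::imap_dfr(repl_defs, function(subs, cmp) {
      bf <- 1 - sum(subs)
      tibble::tibble(
        composition = cmp,
        property = c("area_A2", "mu_mD"),
        scheme = "replacement",
        predicted = c(
          predict_replacement(base_area, bf, subs, pure_area),
          predict_replacement(base_mu, bf, subs, pure_mu)
        ),
        observed = c(obs_area[[cmp]], obs_mu[[cmp]])
      )
    })
  }

  out <- dplyr::bind_rows(additive, repl)
  out <- out[stats::complete.cases(out[c("predicted", "observed")]), ]
  deviation_report(out)
}
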