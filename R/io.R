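#' Read an isotherm table from delimited text
#'
#' Reads a two-column delimited file (comma or tab, auto-detected) holding
#' either a pressure-amount isotherm (`n_nmol`, `pi_mN_per_m`) or a
#' pressure-area isotherm (`area_A2`, `pi_mN_per_m`). Column names carry
#' their units to prevent silent unit mistakes.
#'
#' @param path File path.
#' @param trough_area_cm2 Optional trough area attached as an attribute
#'   (used downstream by [detect_saturation()] / [to_area_isotherm()]).
#' @return A tibble with attribute `isotherm_kind` set to
#'   `"pressure_amount"` or `"area"` (and `trough_area_cm2` if given).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' readr::write_csv(tibble::tibble(n_nmol = c(20, 30, 40),
#'                                 pi_mN_per_m = c(5, 20, 50)), f)
#' read_isotherm_table(f)
#' @export
read_isotherm_table <- function(path, trough_area_cm2 = NULL) {
  if (!file.exists(path)) {
    stop_dipot(sprintf("file not found: %s", path), "validation")
  }
  header <- readLines(path, n = 1)
  delim <- if (grepl("\t", header)) "\t" else ","
  data <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                            trim_ws = TRUE)
  kind <- if ("n_nmol" %in% names(data)) {
    check_columns(data, c("n_nmol", "pi_mN_per_m"), path)
    "pressure_amount"
  } else if ("area_A2" %in% names(data)) {
    check_columns(data, c("area_A2", "pi_mN_per_m"), path)
    "area"
  } else {
    stop_dipot(sprintf(
      "%s: header must contain 'n_nmol' or 'area_A2' alongside 'pi_mN_per_m'",
      path), "schema")
  }
  if (any(data$pi_mN_per_m < 0)) {
    stop_dipot(sprintf("%s: negative surface pressures", path), "validation")
  }
  attr(data, "isotherm_kind") <- kind
  if (!is.null(trough_area_cm2)) {
    attr(data, "trough_area_cm2") <- trough_area_cm2
  }
  data
}

#' Write an isotherm (or any flat result table) as delimited text
#'
#' Numeric fields are serialised at full precision (15 significant digits),
#' so a write/read round trip is lossless for analysis purposes; all
#' report rounding is left to the caller.
#'
#' @param data Tibble to write.
#' @param path Output path; extension `.tsv` selects tab delimiting,
#'   anything else comma.
#' @return `path`, invisibly.
#' @export
write_flat_table <- function(data, path) {
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  num <- vapply(data, is.numeric, logical(1))
  out <- data
  out[num] <- lapply(out[num], function(x) {
    ifelse(is.na(x), NA_character_, formatC(x, digits = 15, format = "g"))
  })
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(path)
}

#' Run the full monolayer-electrostatics pipeline
#'
#' Orchestrates the analysis for a set of monolayer records: the
#' electrostatic analysis (surface charge, Gouy-Chapman correction,
#' dipole moments and 30 mN/m potentials under both Helmholtz variants),
#' the mixture additivity/replacement deviation table, and the cross-system
#' bilayer summary (transbilayer potentials, percent changes, pressure
#' correlations). Per-row analysis failures are isolated: the offending
#' composition is reported in the `errors` element and the remaining rows
#' are analysed.
#'
#' @param records Monolayer input tibble (see [analyze_monolayers()]);
#'   default [study_monolayers()].
#' @param sub Subphase.
#' @param delta_V0_mV Offset for the "eq2" variant (mV).
#' @param mixture_eq Dipole-moment basis for the mixture predictions.
#' @return A list of class `dipot_report`: `records` (analyzed, full
#'   precision), `records_rounded`, `mixtures` (deviation report or NULL),
#'   `bilayer` (summary tibble or NULL), `errors` (tibble of failed
#'   compositions and messages).
#' @examples
#' rep <- run_pipeline()
#' rep$records_rounded
#' @export
run_pipeline <- function(records = study_monolayers(), sub = study_subphase(),
                         delta_V0_mV = 100, mixture_eq = "eq1") {
  records <- tibble::as_tibble(records)
  errors <- tibble::tibble(composition = character(), message = character())
  if (nrow(records) == 0) {
    return(structure(list(records = records, records_rounded = records,
                          mixtures = NULL, bilayer = NULL, errors = errors),
                     class = "dipot_report"))
  }
  rows <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    rows[[i]] <- tryCatch(
      analyze_monolayers(records[i, ], sub = sub, delta_V0_mV = delta_V0_mV),
      error = function(e) {
        errors <<- dplyr::bind_rows(errors, tibble::tibble(
          composition = as.character(records$composition[i]),
          message = conditionMessage(e)))
        NULL
      }
    )
  }
  analyzed <- dplyr::bind_rows(rows)
  mixtures <- NULL
  bilayer <- NULL
  if (nrow(analyzed) > 0) {
    mixtures <- tryCatch(
      study_mixture_table(analyzed, eq = mixture_eq),
      error = function(e) NULL
    )
    bilayer <- tryCatch(
      bilayer_summary(round_report(analyzed)),
      error = function(e) NULL
    )
  }
  structure(
    list(records = analyzed,
         records_rounded = if (nrow(analyzed) > 0) round_report(analyzed)
                           else analyzed,
         mixtures = mixtures, bilayer = bilayer, errors = errors),
    class = "dipot_report"
  )
}

#' @export
print.dipot_report <- function(x, ...) {
  cat(sprintf("<dipot_report> %d record(s) analyzed, %d error(s)\n",
              nrow(x$records), nrow(x$errors)))
  if (nrow(x$records) > 0) print(x$records_rounded)
  invisible(x)
}

#' Write a pipeline report bundle to a directory
#'
#' Serialises the tables of a [run_pipeline()] report as CSV files
#' (`records.csv`, `mixtures.csv`, `bilayer.csv`, `errors.csv`, as
#' applicable), at full numeric precision.
#'
#' @param report A `dipot_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "dipot_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_flat_table(report$records, file.path(dir, "records.csv"))
  if (!is.null(report$mixtures)) {
    write_flat_table(report$mixtures, file.path(dir, "mixtures.csv"))
  }
  if (!is.null(report$bilayer)) {
    write_flat_table(report$bilayer, file.path(dir, "bilayer.csv"))
  }
  if (nrow(report$errors) > 0) {
    write_flat_table(report$errors, file.path(dir, "errors.csv"))
  }
  invisible(dir)
}
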