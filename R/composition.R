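#' Parse a lipid composition string into mole fractions
#'
#' Accepts the notation used for mixed monolayers: lipid names joined by
#' `:` with an optional molar-ratio part in parentheses, e.g.
#' `"POPC:CHOL (7:3)"`, `"POPC:CHOL:POPE:POPS (4:3:2:1)"`, or a pure lipid
#' `"POPC"`. Fractions given directly (`"POPC:CHOL (0.7:0.3)"`) are also
#' accepted; ratios are normalised to mole fractions. Leaflet annotations
#' such as `"^Inner"` / `"^outer"` are ignored.
#'
#' @param x Composition string.
#' @param registry Lipid registry tibble; component names must occur in it.
#' @return A tibble with columns `lipid` and `fraction`; fractions sum to 1.
#' @examples
#' parse_composition("POPC:CHOL (7:3)")
#' @export
parse_composition <- function(x, registry = lipid_registry()) {
  stopifnot(is.character(x), length(x) == 1)
  s <- gsub("\\^\\s*\\w+", "", x)     # strip leaflet annotations
  s <- trimws(s)
  ratio <- NULL
  m <- regmatches(s, regexec("^(.*?)\\s*\\(([^)]*)\\)\\s*$", s))[[1]]
  if (length(m) == 3) {
    s <- m[2]
    ratio <- as.numeric(strsplit(m[3], "[:,]")[[1]])
  }
  lipids <- toupper(trimws(strsplit(s, ":")[[1]]))
  alias <- c(PC = "POPC", PE = "POPE", PS = "POPS", C = "CHOL",
             CHOLESTEROL = "CHOL", SM = "SPM", ESM = "SPM",
             SPHINGOMYELIN = "SPM")
  hit <- lipids %in% names(alias)
  lipids[hit] <- alias[lipids[hit]]
  if (is.null(ratio)) ratio <- rep(1, length(lipids))
  if (length(ratio) != length(lipids) || anyNA(ratio) || any(ratio < 0)) {
    stop_dipot(sprintf("cannot parse composition '%s'", x), "validation")
  }
  if (anyDuplicated(lipids)) {
    stop_dipot(sprintf("repeated species in composition '%s'", x), "validation")
  }
  unknown <- setdiff(lipids, registry$lipid)
  if (length(unknown) > 0) {
    stop_dipot(sprintf("unknown lipid(s) in composition '%s': %s", x,
                       paste(unknown, collapse = ", ")), "validation")
  }
  composition(lipids, ratio / sum(ratio))
}

#' Construct a validated composition
#'
#' A composition is a set of lipid names with mole fractions that are
#' non-negative and sum to 1 (within 1e-9). Fractions that do not sum to 1
#' are rejected rather than silently renormalised; use [parse_composition()]
#' for ratio notation.
#'
#' @param lipid Character vector of species names (unique).
#' @param fraction Numeric mole fractions, same length, summing to 1.
#' @return A tibble with columns `lipid`, `fraction`.
#' @examples
#' composition(c("POPC", "CHOL"), c(0.7, 0.3))
#' @export
composition <- function(lipid, fraction) {
  if (length(lipid) != length(fraction)) {
    stop_dipot("lipid and fraction must have equal length", "validation")
  }
  if (anyDuplicated(lipid)) {
    stop_dipot("repeated species in composition", "validation")
  }
  if (any(fraction < 0)) {
    stop_dipot("mole fractions must be non-negative", "validation")
  }
  if (abs(sum(fraction) - 1) > 1e-9) {
    stop_dipot(sprintf("mole fractions must sum to 1 (got %.12g)",
                       sum(fraction)), "validation")
  }
  tibble::tibble(lipid = as.character(lipid), fraction = as.numeric(fraction))
}

#' Mean formal charge of a composition
#'
#' Mole-fraction-weighted formal charge per molecule, in elementary charges.
#'
#' @param comp Composition tibble (from [composition()] or
#'   [parse_composition()]) or a composition string.
#' @param registry Lipid registry.
#' @return A single number (e.g. -0.1 for 10 mol% phosphatidylserine).
#' @examples
#' mean_formal_charge("POPC:CHOL:POPE:POPS (4:3:2:1)")
#' @export
mean_formal_charge <- function(comp, registry = lipid_registry()) {
  if (is.character(comp)) comp <- parse_composition(comp, registry)
  z <- registry$formal_charge[match(comp$lipid, registry$lipid)]
  if (anyNA(z)) {
    stop_dipot("composition contains species absent from the registry",
               "validation")
  }
  sum(comp$fraction * z)
}
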