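#' Round half away from zero
#'
#' Integer rounding with ties going away from zero (so 370.5 becomes 371 and
#' -370.5 becomes -371), the convention used for all reported integer
#' millivolt / millidebye / percent values. Base [round()] rounds ties to
#' even, which does not reproduce tabulated values computed with conventional
#' rounding.
#'
#' A guard of 1e-9 absorbs floating-point representation error: a value that
#' is an exact tie in real arithmetic but lands a few ulp below .5 after a
#' chain of multiplications still rounds away from zero.
#'
#' @param x Numeric vector.
#' @return Numeric vector of the same length, rounded to whole numbers.
#' @examples
#' round_half_away(c(370.5, -370.5, 2.4)) # 371 -371 2
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5 + 1e-9)
}

# abort with a package-classed condition so callers can test on class
stop_dipot <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("dipot_error_", class), "dipot_error"), ...)
}

# check that `data` has the named columns; error names the first missing one
check_columns <- function(data, cols, what = "input") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    stop_dipot(
      sprintf("%s is missing required column(s): %s", what,
              paste(missing, collapse = ", ")),
      class = "schema"
    )
  }
  invisible(data)
}
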