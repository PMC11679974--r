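#' Physical constants used throughout the package
#'
#' Returns the fixed set of physical constants used by the Helmholtz and
#' Gouy-Chapman computations. `K_helmholtz` is exactly `12 * pi`: with the
#' transverse dipole moment in millidebye (mD) and the area per lipid in
#' square angstroms, `12 * pi * mu / A` is a potential in millivolts. All
#' other constants are SI (CODATA).
#'
#' @return A named list with elements `K_helmholtz` (mV A^2 / mD), `F`
#'   (Faraday constant, C/mol), `R` (gas constant, J/(mol K)), `eps0` (vacuum
#'   permittivity, F/m), `e_charge` (elementary charge, C) and `N_A`
#'   (Avogadro constant, 1/mol).
#' @examples
#' physical_constants()$K_helmholtz / pi # 12
#' @export
physical_constants <- function() {
  list(
    K_helmholtz = 12 * pi,
    F = 96485.33,
    R = 8.314463,
    eps0 = 8.8541878e-12,
    e_charge = 1.602177e-19,
    N_A = 6.022141e23
  )
}

# internal shorthand; constants are never mutated
.const <- list(
  K_helmholtz = 12 * pi,
  F = 96485.33,
  R = 8.314463,
  eps0 = 8.8541878e-12,
  e_charge = 1.602177e-19,
  N_A = 6.022141e23
)
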