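# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the closed form uses asinh directly, and the
# bisection solver is hand-rolled rather than uniroot-based.

# closed-form Gouy-Chapman potential for a single symmetric 1:1 electrolyte
psi0_closed_form_mV <- function(sigma_C_m2, conc_M, temperature_K = 298.15,
                                rel_permittivity = 78.5) {
  Fc <- 96485.33; R <- 8.314463; eps0 <- 8.8541878e-12
  RT <- R * temperature_K
  1000 * (2 * RT / Fc) *
    asinh(sigma_C_m2 / sqrt(8000 * eps0 * rel_permittivity * RT * conc_M))
}

# brute-force bisection on the Grahame relation for an arbitrary electrolyte
psi0_bisect_mV <- function(sigma_C_m2, species, temperature_K = 298.15,
                           rel_permittivity = 78.5, lo = -1, hi = 1,
                           iter = 200) {
  Fc <- 96485.33; R <- 8.314463; eps0 <- 8.8541878e-12
  RT <- R * temperature_K
  f <- function(psi_V) {
    s2 <- 2000 * eps0 * rel_permittivity * RT *
      sum(species$conc_M * (exp(-species$z * Fc * psi_V / RT) - 1))
    sign(psi_V) * sqrt(max(s2, 0)) - sigma_C_m2
  }
  if (sigma_C_m2 == 0) return(0)
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
  }
  1000 * (lo + hi) / 2
}

# exact piecewise-linear pressure-amount fixture: pi = min(a*n + b, pi_sat)
two_line_isotherm <- function(a = 4, b = -100, pi_sat = 50,
                              n = seq(26, 45, by = 1)) {
  tibble::tibble(n_nmol = n, pi_mN_per_m = pmin(a * n + b, pi_sat))
}

# printed study integers for the derived dipole table (eleven systems, in
# study_monolayers() row order)
printed_table2 <- function() {
  tibble::tibble(
    mu_eq1_mD = c(546, 543, 550, 380, 597, 511, 553, 559, 592, 625, 379),
    psi30_eq1_mV = c(319, 372, 371, 298, 322, 323, 434, 479, 399, 383, 357),
    mu_eq2_mD = c(415, 426, 439, 268, 461, 390, 433, 445, 469, 493, 286),
    psi30_eq2_mV = c(343, 392, 396, 311, 349, 347, 440, 481, 416, 402, 370)
  )
}
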