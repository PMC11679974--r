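test_that("two-line interception is exact on piecewise-linear data", {
  iso <- two_line_isotherm(a = 4, b = -100, pi_sat = 50)
  sat <- detect_saturation(iso, trough_area_cm2 = 100)
  expect_equal(sat$n_sat_nmol, 37.5, tolerance = 1e-9)
  expect_equal(sat$pi_sat_mNm, 50, tolerance = 1e-9)
  # A_sat from direct unit arithmetic
  expect_equal(sat$A_sat_A2, 100 * 1e16 / (37.5e-9 * 6.022141e23),
               tolerance = 1e-12)
})

test_that("saturation detection rejects curves without a plateau", {
  n <- seq(10, 30, by = 1)
  rising <- tibble::tibble(n_nmol = n, pi_mN_per_m = 2 * n)
  expect_error(detect_saturation(rising, trough_area_cm2 = 100),
               class = "dipot_error_no_plateau")
})

test_that("near-parallel construction lines are rejected", {
  # slope 500 then slope 100: ratio 5 passes the plateau precondition but
  # the angle between the lines is under a degree
  n <- 1:12
  p <- ifelse(n <= 6, 500 * (n - 1), 2500 + 100 * (n - 6))
  iso <- tibble::tibble(n_nmol = n, pi_mN_per_m = p)
  expect_error(detect_saturation(iso, trough_area_cm2 = 100),
               class = "dipot_error_degenerate_lines")
})

test_that("input validation catches malformed isotherms", {
  iso <- two_line_isotherm()
  expect_error(detect_saturation(iso), class = "dipot_error_validation")
  short <- iso[1:4, ]
  expect_error(detect_saturation(short, trough_area_cm2 = 100),
               class = "dipot_error_validation")
  dup <- iso
  dup$n_nmol[2] <- dup$n_nmol[1]
  expect_error(detect_saturation(dup, trough_area_cm2 = 100),
               class = "dipot_error_validation")
})

test_that("amount-to-area conversion is exact inverse proportionality", {
  iso <- tibble::tibble(n_nmol = c(33.6, 67.2), pi_mN_per_m = c(30, 50))
  aiso <- to_area_isotherm(iso, trough_area_cm2 = 100)
  expect_equal(aiso$area_A2[aiso$n_nmol == 33.6],
               1e18 / (33.6 * 6.022141e14), tolerance = 1e-12)
  # doubling the amount halves the area
  expect_equal(aiso$area_A2[aiso$n_nmol == 67.2] * 2,
               aiso$area_A2[aiso$n_nmol == 33.6], tolerance = 1e-12)
  expect_equal(nrow(aiso), nrow(iso))
  expect_true(all(diff(aiso$area_A2) > 0))
})

test_that("area conversion round-trips the generator ground truth", {
  truth <- popc_like_truth(noise_pi_mNm = 0)
  iso <- simulate_pressure_amount(truth, trough_area_cm2 = 100)
  aiso <- to_area_isotherm(iso)
  expected <- 100 * 1e16 / (aiso$n_nmol * 1e-9 * 6.022141e23)
  expect_equal(aiso$area_A2, expected, tolerance = 1e-12)
})

test_that("polynomial fit recovers exact linear data to machine precision", {
  aiso <- tibble::tibble(area_A2 = seq(50, 95, 5))
  aiso$pi_mN_per_m <- 120 - aiso$area_A2
  fit <- fit_isotherm_polynomial(aiso, degree = 1)
  expect_equal(fit$coefficients, c(120, -1), tolerance = 1e-10)
  expect_lt(fit$rms, 1e-10)
})

test_that("polynomial fit recovers noisy cubic coefficients within 3 se", {
  truth_cf <- c(220, -5.7, 0.055, -0.0002)
  grid <- seq(45, 99, length.out = 40)
  clean <- drop(outer(grid, 0:3, `^`) %*% truth_cf)
  noisy <- clean + withr::with_seed(42, stats::rnorm(40, 0, 0.2))
  aiso <- tibble::tibble(area_A2 = grid, pi_mN_per_m = noisy)
  fit <- fit_isotherm_polynomial(aiso, degree = 3)
  # oracle: standard errors from lm on the same raw-power design
  oracle <- stats::lm(noisy ~ poly(grid, 3, raw = TRUE))
  se <- sqrt(diag(stats::vcov(oracle)))
  expect_true(all(abs(fit$coefficients - truth_cf) < 3 * se))
  # and the two least-squares routes agree
  expect_equal(fit$coefficients, unname(stats::coef(oracle)),
               tolerance = 1e-8)
})

test_that("underdetermined polynomial fits are rejected", {
  aiso <- tibble::tibble(area_A2 = c(50, 60, 70), pi_mN_per_m = c(40, 30, 20))
  expect_error(fit_isotherm_polynomial(aiso, degree = 3),
               class = "dipot_error_insufficient_points")
})

test_that("area at pressure inverts the fitted polynomial", {
  aiso <- tibble::tibble(area_A2 = seq(50, 95, 5))
  aiso$pi_mN_per_m <- 120 - aiso$area_A2
  m <- fit_isotherm_polynomial(aiso, degree = 1)
  expect_equal(area_at_pressure(m, 30), 90, tolerance = 1e-9)

  # noiseless synthetic curve built through (64.5, 30)
  truth <- popc_like_truth(noise_pi_mNm = 0)
  aiso2 <- simulate_area_isotherm(truth, seq(42, 99, length.out = 30))
  m2 <- fit_isotherm_polynomial(aiso2, degree = 3)
  a30 <- area_at_pressure(m2, 30)
  expect_equal(a30, 64.5, tolerance = 0.1)
  # round trip on the valid branch
  expect_lt(abs(predict_pressure(m2, a30) - 30), 1e-8)

  expect_error(area_at_pressure(m, 500), class = "dipot_error_no_root")
})

test_that("tidy and glance summarise an isotherm fit", {
  aiso <- tibble::tibble(area_A2 = seq(50, 95, 5))
  aiso$pi_mN_per_m <- 120 - aiso$area_A2
  fit <- fit_isotherm_polynomial(aiso, degree = 1)
  td <- tidy(fit)
  expect_equal(td$term, c("A^0", "A^1"))
  gl <- glance(fit)
  expect_equal(gl$degree, 1)
  expect_equal(gl$n, nrow(aiso))
})
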