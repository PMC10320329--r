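test_that("critical wavelength: scaling in h and R", {
  expect_equal(critical_wavelength(0.002, 10) /
                 critical_wavelength(0.001, 10), 2, tolerance = 1e-14)
  expect_equal(critical_wavelength(0.001, 80) /
                 critical_wavelength(0.001, 10), 2, tolerance = 1e-14)
  expect_error(critical_wavelength(0.001, 1), "R <= 1")
  expect_error(critical_wavelength(0.001, 0.5), "R <= 1")
  # increasing in both h and R
  expect_true(all(diff(critical_wavelength(0.001, c(2, 5, 20, 100))) > 0))
  expect_true(all(diff(sapply(c(1, 2, 4) * 1e-3, critical_wavelength,
                              R = 10)) > 0))
})

test_that("critical strain: scaling in R and admissible range", {
  for (R1 in c(5, 10, 40)) for (R2 in c(7, 20, 160)) {
    expect_equal(critical_strain(R1) / critical_strain(R2),
                 (R2 / R1)^(2 / 3), tolerance = 1e-14)
  }
  expect_equal(critical_strain(8 * 20) / critical_strain(20), 0.25,
               tolerance = 1e-14)
  expect_error(critical_strain(1), "R <= 1")
  expect_true(all(diff(critical_strain(c(2, 5, 20, 100))) < 0))
  # physically sensible onset strains for R > ~3
  eps <- critical_strain(c(4, 10, 100))
  expect_true(all(eps > 0 & eps < 1))
})

test_that("oracle exponents are exact by construction", {
  R <- c(5, 10, 20, 40, 80)
  expect_equal(fit_scaling_exponent(R, critical_wavelength(1e-3,
                                                           R))$exponent,
               1 / 3, tolerance = 1e-12)
  expect_equal(fit_scaling_exponent(R, critical_strain(R))$exponent,
               -2 / 3, tolerance = 1e-12)
})

test_that("growth-to-strain: fixed extent and bulged base", {
  scn <- cross_section_scenario("flat")
  expect_equal(growth_to_strain(scn, 0), 0, tolerance = 1e-12)
  # g_f1(1) = 1.5 on a fixed extent: eps = 1 - 1/1.5 = 1/3
  expect_equal(growth_to_strain(scn, 1), 1 / 3, tolerance = 1e-6)
  # no growth, fixed extent: zero at all t
  scn0 <- cross_section_scenario("flat", C1 = 0, C2 = 0)
  expect_true(all(abs(growth_to_strain(scn0, c(0, 0.5, 1))) < 1e-9))
  # a bulged base lengthens the available extent: smaller strain, onset
  # delayed relative to flat
  scnc <- cross_section_scenario("curved")
  expect_lt(growth_to_strain(scnc, 0.8), growth_to_strain(scn, 0.8))
  expect_gt(predict_onset_time(scnc), predict_onset_time(scn))
})

test_that("scaling-exponent fit recovers exact power laws", {
  x <- c(1, 2, 5, 10, 30)
  expect_lt(abs(fit_scaling_exponent(x, 7 * x^(1 / 3))$exponent - 1 / 3),
            1e-12)
  expect_lt(abs(fit_scaling_exponent(x, 2 * x^(-2 / 3))$exponent + 2 / 3),
            1e-12)
  expect_error(fit_scaling_exponent(c(1, 2), c(1, 2)), "3")
  expect_error(fit_scaling_exponent(c(1, -2, 3), c(1, 2, 3)), "positive")
})
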