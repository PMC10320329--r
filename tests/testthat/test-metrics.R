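test_that("top-profile extraction: undeformed, thickened, synthetic wave", {
  p <- tiny_problem()
  mesh <- p$mesh; geom <- p$geom
  ndof <- nrow(mesh$coords) * 2
  prof <- extract_top_profile(mesh, numeric(ndof))
  expect_true(all(abs(prof$height - geom$depth) < 1e-14))
  # homogeneous thickening: heights constant above H_o
  u <- as.vector(t(cbind(0 * mesh$coords[, 1], 0.1 * mesh$coords[, 2])))
  prof2 <- extract_top_profile(mesh, u)
  expect_true(all(abs(prof2$height - 1.1 * geom$depth) < 1e-12))
  # a prescribed cosine on the top surface is recovered exactly
  k <- 2 * pi / 0.05
  uz <- 1e-3 * cos(k * mesh$coords[, 1])
  uz[mesh$coords[, 2] < geom$depth - 1e-12] <- 0
  u3 <- as.vector(t(cbind(0 * uz, uz)))
  prof3 <- extract_top_profile(mesh, u3)
  expect_lt(max(abs(prof3$height -
                    (geom$depth + 1e-3 * cos(k * attr(prof3, "x_ref"))))),
            1e-12)
})

test_that("detrending separates bulge from oscillation", {
  lam <- 0.1
  # pure parabola: the trend is the parabola itself (quadratic basis)
  flatp <- make_profile("parabola", width = 1, rate = 0.3, amplitude = 0,
                        wavenumber = 2 * pi / lam)
  det0 <- detrend_profile(flatp, window = 3 * lam)
  # the profile is parametrised by arc length, under which the parabola
  # is only approximately quadratic; the residual is far below the
  # oscillation scales of interest
  expect_lt(max(abs(det0$oscillation)) / 0.3, 1e-4)
  # flat profile: zero oscillation
  flat <- make_profile("flat", width = 1, amplitude = 0,
                       wavenumber = 2 * pi / lam)
  expect_lt(max(abs(detrend_profile(flat, 3 * lam)$oscillation)), 1e-12)
  # cosine on a parabolic trend: oscillation recovers the cosine to 2%
  # over the interior (half a window trimmed at each end)
  A <- 0.01
  mix <- make_profile("parabola", width = 1, rate = 0.3, amplitude = A,
                      wavenumber = 2 * pi / lam)
  det1 <- detrend_profile(mix, window = 3 * lam, passes = 1)
  xr <- attr(mix, "x_ref")
  interior <- xr > 1.5 * lam & xr < 1 - 1.5 * lam
  # the height component of the normal-offset wave is A cos(kx) t_x
  gp <- 0.3 * (2 * xr - 1)
  truth <- A * cos(2 * pi / lam * xr) / sqrt(1 + gp^2)
  expect_lt(max(abs(det1$oscillation[interior] - truth[interior])),
            0.02 * A)
  # reconstruction is exact by construction
  expect_equal(det1$trend + det1$oscillation, mix$height)
  expect_error(detrend_profile(mix, window = 1e-5), "spacing")
})

test_that("amplitude estimator: exact waves, flat, noisy waves", {
  lam <- 0.1; A <- 0.01
  prof <- make_profile("flat", width = 1, amplitude = A,
                       wavenumber = 2 * pi / lam)
  det <- detrend_profile(prof, window = 3 * lam)
  expect_equal(measure_amplitude(det), A, tolerance = 0.01)
  expect_equal(measure_amplitude(rep(0, 100)), 0)
  # seeded 10% height noise: estimate within 10% of truth
  profn <- make_profile("flat", width = 1, amplitude = A,
                        wavenumber = 2 * pi / lam, noise_sd = 0.1 * A,
                        seed = 4)
  detn <- detrend_profile(profn, window = 3 * lam, passes = 1)
  expect_lt(abs(measure_amplitude(detn) - A) / A, 0.1)
})

test_that("amplitude estimator is unbiased across a decade of k", {
  for (lam in c(0.02, 0.05, 0.1, 0.2)) {
    prof <- make_profile("flat", width = 40 * lam, amplitude = 0.004,
                         wavenumber = 2 * pi / lam)
    det <- detrend_profile(prof, window = 3 * lam)
    expect_equal(measure_amplitude(det), 0.004, tolerance = 0.01)
  }
})

test_that("wavelength measurement: flat waves, undefined states", {
  lam <- 0.2; A <- 0.01
  prof <- make_profile("flat", width = 2, amplitude = A,
                       wavenumber = 2 * pi / lam)
  wl <- measure_wavelength(prof, lambda_hint = lam)
  expect_false(wl$undefined)
  expect_equal(wl$mean, lam, tolerance = 0.01)
  # a flat profile has no crests: undefined, not an error
  flat <- make_profile("flat", width = 2, amplitude = 0,
                       wavenumber = 2 * pi / lam)
  wlf <- measure_wavelength(flat, lambda_hint = lam)
  expect_true(wlf$undefined)
  expect_true(is.na(wlf$mean))
})

test_that("wavelengths on a curved base match the crest-distance map", {
  lam <- 0.1; A <- 0.008; rate <- 0.4
  prof <- make_profile("parabola", width = 1.6, rate = rate,
                       amplitude = A, wavenumber = 2 * pi / lam,
                       n_per_wave = 32)
  wl <- measure_wavelength(prof, lambda_hint = lam)
  truth <- curved_wavelength_map(function(x) rate * x * (x - 1.6), A,
                                 2 * pi / lam, c(0, 1.6),
                                 deriv = function(x) rate * (2 * x - 1.6))
  # align each measured wave with the map by crest position
  expect_gt(length(wl$per_wave), 5)
  idx <- vapply(wl$positions[-length(wl$positions)],
                function(x) which.min(abs(truth$x - x)), integer(1))
  mapped <- truth$lambda_n[idx]
  expect_lt(max(abs(wl$per_wave - mapped) / mapped), 0.01)
})

test_that("curved crest map: exactness against brute-force mapping", {
  # flat base: reduces to the flat wavelength
  flat <- curved_wavelength_map(function(x) rep(0, length(x)), 0.01,
                                2 * pi / 0.1, c(0, 1))
  expect_true(all(abs(flat$lambda_n - 0.1) < 1e-12))
  # zero amplitude: hypotenuse of height difference and flat spacing
  g <- function(x) 0.3 * x * (x - 1)
  m0 <- curved_wavelength_map(g, 0, 2 * pi / 0.1, c(0, 1),
                              deriv = function(x) 0.3 * (2 * x - 1))
  xn <- seq(0, 1, by = 0.1)
  hyp <- sqrt(0.1^2 + diff(g(xn))^2)
  expect_lt(max(abs(m0$lambda_n - hyp[seq_len(nrow(m0))])), 1e-12)
  # 50 seeded random (A, k, parabola) triples: closed form vs brute force
  set.seed(42)
  for (i in 1:50) {
    A <- runif(1, 0, 0.02)
    lam <- runif(1, 0.05, 0.2)
    r <- runif(1, -0.5, 0.5)
    w <- runif(1, 1, 2)
    gf <- function(x) r * x * (x - w)
    gd <- function(x) r * (2 * x - w)
    m <- curved_wavelength_map(gf, A, 2 * pi / lam, c(0, w), deriv = gd)
    bf <- brute_crest_distances(gf, A, 2 * pi / lam, c(0, w), deriv = gd)
    expect_lt(max(abs(m$lambda_n - bf)), 1e-10)
  }
})

test_that("curvature inflates wavelength dispersion", {
  A <- 0.01; k <- 2 * pi / 0.1
  curved <- curved_wavelength_map(function(x) 0.4 * x * (x - 1.5), A, k,
                                  c(0, 1.5),
                                  deriv = function(x) 0.4 * (2 * x - 1.5))
  flat <- curved_wavelength_map(function(x) rep(0, length(x)), A, k,
                                c(0, 1.5))
  expect_gt(sd(curved$lambda_n), sd(flat$lambda_n))
})

test_that("onset detection requires a sustained crossing", {
  h <- 0.01
  s <- data.frame(t = 1:5 / 5,
                  amplitude = c(0, 0, 0.01, 0.2, 0.5) * h)
  expect_equal(detect_onset(s, h = h, threshold = 0.05), 4 / 5)
  flat <- data.frame(t = 1:5 / 5, amplitude = rep(1e-6 * h, 5))
  expect_true(is.na(detect_onset(flat, h = h)))
  # a single-step spike is not onset
  spike <- data.frame(t = 1:5 / 5, amplitude = c(0, 0.2, 0, 0, 0) * h)
  expect_true(is.na(detect_onset(spike, h = h)))
})
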