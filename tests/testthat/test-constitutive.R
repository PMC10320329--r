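test_that("Lame parameters: values, scaling, degenerate Poisson ratio", {
  lp <- lame_parameters(1, 0.45)
  expect_equal(lp[["mu"]], 0.3448276, tolerance = 1e-6)
  expect_equal(lp[["lambda"]], 3.1034483, tolerance = 1e-6)
  expect_error(lame_parameters(1, 0.5), "0.5")
  expect_error(lame_parameters(0, 0.4))
  # linear in E: lame(R E) = R lame(E), so mu_f/mu_s = lambda_f/lambda_s = R
  for (R in c(2, 10, 80)) {
    expect_equal(lame_parameters(R, 0.48), R * lame_parameters(1, 0.48),
                 tolerance = 1e-14)
  }
  mat <- material(R = 20, nu = 0.48)
  expect_equal(mat$mu_f / mat$mu_s, 20, tolerance = 1e-14)
  expect_equal(mat$lambda_f / mat$lambda_s, 20, tolerance = 1e-14)
})

test_that("elastic decomposition recovers A and the invariants", {
  # compatible homogeneous growth: F = G leaves no elastic strain
  G <- diag(c(1.3, 0.9, 1.1))
  st <- elastic_decomposition(G, G)
  expect_equal(st$A, diag(3), tolerance = 1e-14)
  expect_equal(st$I1, 3, tolerance = 1e-14)
  expect_equal(st$Je, 1, tolerance = 1e-14)
  # no growth: A is F itself
  F <- matrix(c(1.1, 0.1, -0.05, 0.95), 2)
  st2 <- elastic_decomposition(F, diag(2))
  expect_equal(st2$A, F)
  # random states: A G reconstructs F elementwise to 1e-12
  for (s in 1:20) {
    st <- make_random_kinematic_state(seed = s)
    expect_lt(max(abs(st$A %*% st$G - st$F)), 1e-12)
    expect_gt(st$Je, 0)
  }
  expect_error(elastic_decomposition(diag(2), matrix(0, 2, 2)),
               "singular")
})

test_that("strain energy: zero at identity, printed substitution, >= 0", {
  mu <- 0.4; lam <- 2.1
  st <- elastic_decomposition(diag(3), diag(3))
  expect_equal(strain_energy_density(st, mu, lam), 0)
  stA <- elastic_decomposition(diag(c(2, 1, 1)), diag(3))
  expect_equal(strain_energy_density(stA, mu, lam),
               1.5 * mu - mu * log(2) + lam / 2 * log(2)^2,
               tolerance = 1e-14)
  for (s in 1:20) {
    st <- make_random_kinematic_state(seed = 100 + s)
    expect_gte(strain_energy_density(st, mu, lam), 0)
  }
})

test_that("strain energy is objective: Psi(QA) = Psi(A)", {
  mu <- 0.37; lam <- 3.3
  set.seed(11)
  st <- make_random_kinematic_state(seed = 5)
  psi <- strain_energy_density(st, mu, lam)
  for (r in 1:20) {
    Q <- random_rotation(3)
    stQ <- elastic_decomposition(Q %*% st$F, st$G)
    expect_equal(strain_energy_density(stQ, mu, lam), psi,
                 tolerance = 1e-12)
  }
})

test_that("nominal stress: stress-free grown states and small strain", {
  mu <- 0.344828; lam <- 3.103448
  # compatible homogeneous growth of an unconstrained body is stress-free
  for (G in list(diag(c(1.5, 2)), diag(c(1.2, 0.8, 1.4)))) {
    st <- elastic_decomposition(G, G)
    expect_lt(max(abs(nominal_stress(st, mu, lam))), 1e-12)
  }
  # linearization limit: uniaxial P11 -> (lambda + 2 mu) eps as eps -> 0
  eps <- 1e-7
  F <- diag(3); F[1, 1] <- 1 + eps
  st <- elastic_decomposition(F, diag(3))
  P <- nominal_stress(st, mu, lam)
  expect_equal(P[1, 1] / eps, lam + 2 * mu, tolerance = 1e-6)
})

test_that("nominal stress is the energy gradient (finite differences)", {
  # 100 seeded random (F, G) pairs; componentwise agreement with central
  # differences of J_g Psi(F G^-1), relative tolerance 1e-6
  mu <- 0.52; lam <- 2.7
  worst <- 0
  for (s in 1:100) {
    st <- make_random_kinematic_state(seed = 200 + s,
                                      dim = if (s %% 2) 3L else 2L)
    P <- nominal_stress(st, mu, lam)
    Pfd <- fd_nominal_stress(st$F, st$G, mu, lam)
    worst <- max(worst, max(abs(P - Pfd)) / max(abs(Pfd)))
  }
  expect_lt(worst, 1e-6)
})
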