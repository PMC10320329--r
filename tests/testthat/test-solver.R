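test_that("trivial equilibria: no growth and no base motion keep u = 0", {
  p <- tiny_problem()
  ndof <- nrow(p$mesh$coords) * 2
  a <- assemble_weak_residual(p$mesh, p$mat, p$nogrowth, 0.5,
                              numeric(ndof))
  expect_true(a$ok)
  expect_lt(max(abs(a$resid)), 1e-14)
  expect_equal(a$energy, 0)
  sol <- solve_equilibrium(numeric(ndof), p$mesh, p$mat, p$nogrowth,
                           boundary_flat(), 0, 0.7)
  expect_identical(max(abs(sol$u)), 0)
})

test_that("compatible homogeneous growth is residual-free", {
  p <- tiny_problem()
  sch <- growth_schedule(
    film = list(linear_growth_law(0.5), linear_growth_law(0.3)),
    substrate = list(linear_growth_law(0.5), linear_growth_law(0.3)))
  t <- 0.4
  g <- c(1 + 0.5 * t, 1 + 0.3 * t)
  u <- as.vector(t(cbind(p$mesh$coords[, 1] * (g[1] - 1),
                         p$mesh$coords[, 2] * (g[2] - 1))))
  a <- assemble_weak_residual(p$mesh, p$mat, sch, t, u, tangent = FALSE)
  expect_true(a$ok)
  expect_lt(max(abs(a$resid)), 1e-12)
  expect_lt(abs(a$energy), 1e-15)
})

test_that("assembled residual is the gradient of the assembled energy", {
  p <- tiny_problem()
  ndof <- nrow(p$mesh$coords) * 2
  u <- with_seed_test(42, 2e-4 * rnorm(ndof))
  t <- 0.4
  a <- assemble_weak_residual(p$mesh, p$mat, p$growth, t, u,
                              tangent = FALSE)
  expect_true(a$ok)
  idx <- with_seed_test(7, sample(ndof, 25))
  eps <- 1e-6
  for (i in idx) {
    up <- u; up[i] <- up[i] + eps
    um <- u; um[i] <- um[i] - eps
    fd <- (total_energy(p$mesh, p$mat, p$growth, t, up) -
             total_energy(p$mesh, p$mat, p$growth, t, um)) / (2 * eps)
    expect_lt(abs(a$resid[i] - fd), 1e-6 * max(1, abs(fd)))
  }
})

test_that("element inversion is reported with the element id", {
  p <- tiny_problem()
  ndof <- nrow(p$mesh$coords) * 2
  u <- numeric(ndof)
  # collapse one film node through its element
  top <- p$mesh$sets$top[1]
  u[(top - 1) * 2 + 2] <- -0.02
  a <- assemble_weak_residual(p$mesh, p$mat, p$nogrowth, 0, u)
  expect_false(a$ok)
  expect_true(a$bad_element >= 1 &&
                a$bad_element <= nrow(p$mesh$conn))
})

test_that("boundary conditions follow the schedules", {
  p <- tiny_problem()
  w <- p$geom$width
  # parabolic turgor bulge: zero at the endpoints, r w^2/4 towards the
  # free surface at the midpoint
  bc <- apply_boundary_conditions(p$mesh, boundary_parabola(rate = 0.2,
                                                            cap = 0.65),
                                  t = 0.5)
  base <- p$mesh$sets$base
  xz <- p$mesh$coords[base, ]
  zdofs <- (base - 1) * 2 + 2
  vals <- bc$value[match(zdofs, bc$dof)]
  expect_equal(vals[which.min(abs(xz[, 1]))], 0)
  expect_equal(vals[which.min(abs(xz[, 1] - w))], 0)
  imid <- which.min(abs(xz[, 1] - w / 2))
  expect_equal(abs(vals[imid]), 0.1 * w^2 / 4, tolerance = 1e-12)
  expect_gt(vals[imid], 0)  # bulge towards the free surface
  # ramp is capped: r(0.8) = 0.2 * 0.65
  bc2 <- apply_boundary_conditions(p$mesh, boundary_parabola(0.2, 0.65),
                                   t = 0.8)
  vals2 <- bc2$value[match(zdofs, bc2$dof)]
  expect_equal(abs(vals2[imid]), 0.2 * 0.65 * w^2 / 4, tolerance = 1e-12)
  # schedules referencing missing facets are errors
  expect_error(apply_boundary_conditions(p$mesh,
                                         boundary_sine_product(), 0.5),
               "cross-section")
})

test_that("segmented base: bulges vanish at segment ends and clamps", {
  geom <- bilayer_geometry(width = 1, depth = 0.1, film = 0.005)
  mesh <- build_cross_section_mesh(geom, wavelength = 0.1, resolution = 8,
                                   n_substrate_layers = 3)
  segs <- data.frame(x0 = c(0.05, 0.45), width = c(0.3, 0.4),
                     rate = c(1, 2))
  bc <- apply_boundary_conditions(mesh, boundary_segments(segs, cap = 1),
                                  t = 0.5)
  base <- mesh$sets$base
  x <- mesh$coords[base, 1]
  zdofs <- (base - 1) * 2 + 2
  vals <- bc$value[match(zdofs, bc$dof)]
  in_clamp <- x < 0.05 | (x > 0.35 & x < 0.45) | x > 0.85
  expect_true(all(abs(vals[in_clamp]) < 1e-14))
  inside1 <- x > 0.1 & x < 0.3
  expect_true(all(vals[inside1] > 0))  # bulges towards the free surface
})

test_that("3D sine-product base vanishes on in-plane edges and stretches y", {
  geom <- bilayer_geometry(width = 0.3, depth = 0.1, film = 0.01,
                           length = 0.2)
  mesh <- build_volume_mesh(geom, wavelength = 0.1, resolution = 8,
                            ny = 3, n_substrate_layers = 3)
  sch <- boundary_sine_product(rate = 0.5, kx_factor = 3, ky_factor = 1,
                               power = 2,
                               stretch = linear_growth_law(0.75))
  bc <- apply_boundary_conditions(mesh, sch, t = 0.2)
  base <- mesh$sets$base
  xy <- mesh$coords[base, 1:2]
  zdofs <- (base - 1) * 3 + 3
  vals <- bc$value[match(zdofs, bc$dof)]
  edge <- abs(xy[, 1]) < 1e-12 | abs(xy[, 2]) < 1e-12 |
    abs(xy[, 1] - 0.3) < 1e-12 | abs(xy[, 2] - 0.2) < 1e-12
  expect_true(all(abs(vals[edge]) < 1e-12))
  # y stretch: base y-displacement is (k(t) - 1) y with k = 1 + 0.75 t
  ydofs <- (base - 1) * 3 + 2
  yvals <- bc$value[match(ydofs, bc$dof)]
  expect_equal(yvals, 0.75 * 0.2 * xy[, 2], tolerance = 1e-12)
})

test_that("quasi-static runs are deterministic", {
  scn <- wrinkle_study_scenario(R = 10, waves = 10, steps = 8)
  scn$time$t_end <- 0.2   # pre-onset stretch of the trajectory
  s1 <- run_quasistatic(scn, keep = "last")
  s2 <- run_quasistatic(scn, keep = "last")
  expect_identical(s1$mesh$coords, s2$mesh$coords)
  expect_lt(max(abs(s1$u_last - s2$u_last)), 1e-12)
  expect_equal(s1$summary, s2$summary, tolerance = 1e-12)
  # every accepted state is a converged equilibrium
  expect_true(all(s1$summary$residual < 1e-6))
})
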