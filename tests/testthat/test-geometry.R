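test_that("geometry invariants: film + substrate partition the depth", {
  geom <- bilayer_geometry(width = 2, depth = 0.2, film = 0.008 * 0.2)
  expect_identical(geom$substrate + geom$film, geom$depth)
  expect_equal(geom$film / geom$depth, 0.008, tolerance = 1e-15)
  expect_error(bilayer_geometry(width = 1, depth = 0.1, film = 0.2),
               "film")
})

test_that("cross-section mesh: film band, area, layer partition", {
  geom <- bilayer_geometry(width = 2, depth = 0.2, film = 0.008 * 0.2)
  mesh <- build_cross_section_mesh(geom, wavelength = 0.05,
                                   resolution = 8)
  # film band depth is exactly h = 0.0016
  zc <- mesh$coords[, 2]
  expect_equal(max(zc) - geom$substrate, 0.0016, tolerance = 1e-12)
  film_nodes_z <- range(zc[zc > geom$substrate + 1e-12])
  expect_true(all(film_nodes_z <= geom$depth + 1e-12))
  # area equals the analytic reference area to machine precision
  expect_equal(mesh_measure(mesh), geom$width * geom$depth,
               tolerance = 1e-12)
  # layer tags partition: every element tagged exactly once, and film
  # elements are exactly those whose centre depth exceeds H_s
  expect_true(all(mesh$layer %in% c(1L, 2L)))
  corners <- mesh$conn[, c(1, 3, 7, 9)]
  zcen <- rowMeans(matrix(mesh$coords[corners, 2], ncol = 4))
  expect_identical(mesh$layer == 1L, zcen > geom$substrate)
  # film resolved by at least 2 element layers through its thickness
  film_z <- sort(unique(zc[zc >= geom$substrate - 1e-12]))
  expect_gte(length(film_z), 5)  # 2 quadratic layers = 5 node levels
})

test_that("symmetric bilayer meshes symmetrically", {
  geom <- bilayer_geometry(width = 1, depth = 0.2, film = 0.1)
  mesh <- build_cross_section_mesh(geom, wavelength = 0.2, resolution = 8,
                                   n_film_layers = 2,
                                   n_substrate_layers = 2)
  expect_equal(sum(mesh$layer == 1L), sum(mesh$layer == 2L))
})

test_that("under-resolved meshes are refused", {
  geom <- bilayer_geometry(width = 1, depth = 0.2, film = 0.01)
  expect_error(build_cross_section_mesh(geom, wavelength = 0.05,
                                        resolution = 4), "resolution")
  expect_error(build_volume_mesh(bilayer_geometry(1, 0.2, 0.01,
                                                  length = 0.5),
                                 wavelength = 0.05, resolution = 4),
               "resolution")
})

test_that("volume mesh: film band, volume, base facet tagging", {
  geom <- bilayer_geometry(width = 0.1, depth = 1, film = 1 / 41,
                           length = 0.1)
  mesh <- build_volume_mesh(geom, wavelength = 0.2, resolution = 8,
                            ny = 4, n_substrate_layers = 4)
  expect_equal(max(mesh$coords[, 3]) - geom$substrate, 1 / 41,
               tolerance = 1e-12)
  expect_equal(mesh_measure(mesh),
               geom$width * geom$length * geom$depth, tolerance = 1e-12)
  base <- mesh$sets$base
  expect_true(all(abs(mesh$coords[base, 3]) < 1e-12))
  expect_false(anyDuplicated(base) > 0)
  # base nodes cover the full in-plane grid exactly once
  expect_equal(length(base), (mesh$nx + 1L) * (mesh$ny + 1L))
})

test_that("imperfection seeding is reproducible, bounded, optional", {
  geom <- bilayer_geometry(width = 1, depth = 0.2, film = 0.01)
  mesh <- build_cross_section_mesh(geom, wavelength = 0.1, resolution = 8,
                                   n_substrate_layers = 3)
  m0 <- seed_imperfection(mesh, 0, seed = 3)
  expect_identical(m0$coords, mesh$coords)
  m1 <- seed_imperfection(mesh, 1e-4, seed = 7)
  m2 <- seed_imperfection(mesh, 1e-4, seed = 7)
  expect_identical(m1$coords, m2$coords)
  dz <- abs(m1$coords[, 2] - mesh$coords[, 2])
  expect_lte(max(dz), 1e-4 * geom$film * (1 + 1e-12))
  expect_gt(max(dz), 0)
  # only film nodes move
  moved <- which(dz > 0)
  expect_true(all(mesh$coords[moved, 2] > geom$substrate))
  # a different seed gives a different imperfection
  m3 <- seed_imperfection(mesh, 1e-4, seed = 8)
  expect_false(identical(m1$coords, m3$coords))
})
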