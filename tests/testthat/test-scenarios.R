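test_that("cross-section registry carries the canonical parameters", {
  scn <- cross_section_scenario("flat")
  expect_equal(scn$material$R, 10)
  expect_equal(scn$material$nu, 0.45)
  expect_equal(scn$geometry$width, 2.0)
  expect_equal(scn$geometry$depth, 0.2)
  expect_equal(scn$geometry$film / scn$geometry$depth, 0.008)
  # curved base, thickness frozen: g_f2(1) = 1 + 5 * 0.25 = 2.25
  scnB <- cross_section_scenario("curved", thickness_freeze = TRUE)
  g2 <- morphowrinkle:::growth_law_from_spec(scnB$growth$film[[2]])
  expect_equal(g2$fun(1.0), 2.25)
  # ramp capped at tau = 0.65: r(0.8) = 0.2 * 0.65 = 0.13
  scnA <- cross_section_scenario("curved")
  expect_equal(morphowrinkle:::ramp_at(scnA$boundary$pars$rate,
                                       scnA$boundary$pars$cap, 0.8), 0.13)
})

test_that("three-cell registry: segment layout and per-case settings", {
  for (case in c("A", "B", "C", "D", "E")) {
    scn <- three_cell_scenario(case)
    seg <- as.data.frame(scn$boundary$pars$segments)
    # segments plus the four equal clamps tile the base exactly
    expect_equal(sum(seg$width), sum(c(1.48, 2.4, 1.84)))
    clamp <- (scn$geometry$width - sum(seg$width)) / 4
    expect_gt(clamp, 0)
    expect_equal(seg$x0[1], clamp)
    expect_equal(seg$x0[2], clamp + seg$width[1] + clamp)
    expect_equal(seg$x0[3] + seg$width[3] + clamp, scn$geometry$width)
    expect_equal(scn$material$R, 20)
    expect_equal(scn$material$nu, 0.48)
    expect_equal(scn$geometry$film / scn$geometry$depth, 0.0066)
  }
  # case A: the middle cell stays flat
  segA <- as.data.frame(three_cell_scenario("A")$boundary$pars$segments)
  expect_equal(segA$rate[2], 0)
  expect_true(all(segA$rate[c(1, 3)] > 0))
  # case B: every cell bulges
  segB <- as.data.frame(three_cell_scenario("B")$boundary$pars$segments)
  expect_true(all(segB$rate > 0))
  # case E: thinner domain, substrate thickening frozen at t = 0.8
  scnE <- three_cell_scenario("E")
  expect_equal(scnE$geometry$depth, 0.07)
  gsub2 <- scnE$growth$substrate[[2]]
  expect_equal(gsub2$pars$freeze_at, 0.8)
  gl <- morphowrinkle:::growth_law_from_spec(gsub2)
  expect_identical(gl$fun(0.8), gl$fun(1.0))
})

test_that("volumetric registry: printed laws and schedules", {
  scn <- volume_scenario("single")
  expect_equal(scn$geometry$film, 1 / 41)
  expect_equal(scn$geometry$depth, 1)
  expect_equal(scn$geometry$width, 0.1)
  g <- lapply(scn$growth$film, morphowrinkle:::growth_law_from_spec)
  expect_equal(g[[1]]$fun(0.25), 1.25)   # g_f1 = 1 + t
  expect_equal(g[[3]]$fun(0.25), 1)      # film thickness does not grow
  gs <- lapply(scn$growth$substrate, morphowrinkle:::growth_law_from_spec)
  expect_equal(gs[[3]]$fun(0.25), 1.25)  # substrate thickens as 1 + t
  expect_identical(gs[[1]]$fun(0.2), gs[[1]]$fun(0.25))  # frozen at 0.2

  scn3 <- volume_scenario("three")
  # substrate in-plane growth still active at t = 0.2 (< 2 tau = 0.24):
  # 1 + 1.5 * 0.2 = 1.30
  gs3 <- morphowrinkle:::growth_law_from_spec(scn3$growth$substrate[[1]])
  expect_equal(gs3$fun(0.2), 1.30)
  # turgor ramp capped at tau = 0.12: r(0.2) = 0.2 * 0.12 = 0.024
  expect_equal(morphowrinkle:::ramp_at(scn3$boundary$pars$rate,
                                       scn3$boundary$pars$cap, 0.2),
               0.024)
  expect_equal(scn3$boundary$pars$kx_factor, 3)
})

test_that("every registry scenario round-trips through a config file", {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  for (nm in list_scenarios()) {
    scn <- get_scenario(nm)
    write_scenario(scn, tmp)
    back <- read_scenario(tmp)
    expect_equal(back, scn, tolerance = 1e-12, label = nm)
  }
})

test_that("scenario describe surfaces the oracle predictions", {
  out <- capture.output(describe_scenario(cross_section_scenario("flat")))
  expect_true(any(grepl("lambda_c", out)))
  expect_true(any(grepl("R = 10", out)))
})
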