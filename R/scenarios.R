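#' Build a runnable scenario
#'
#' A scenario is a complete, declarative description of one simulation:
#' geometry, material, growth schedule, boundary schedule, time grid, mesh
#' resolution and imperfection seed. Scenarios hold no closures, so they
#' serialize losslessly to JSON configs ([write_scenario()]) and are
#' materialized into meshes and schedules only when run.
#'
#' @param name Scenario name.
#' @param dim 2 (cross-section, plane strain) or 3 (volumetric).
#' @param geometry List with `width`, `depth`, `film` and (3D) `length`.
#' @param material List with `R`, `nu` and optionally `E_s`.
#' @param growth List with `film` and `substrate`, each a list of
#'   [growth_laws] objects (2 entries in 2D, 3 in 3D).
#' @param boundary A [boundary_schedules] object.
#' @param time List with `t_end` and `steps`.
#' @param mesh List of meshing controls: `resolution` (elements per
#'   predicted wavelength), `n_film_layers`, `n_substrate_layers`, `ny`
#'   (3D), optional `nx` / `wavelength` overrides.
#' @param imperfection List with `magnitude` (fraction of h) and `seed`.
#' @param numerics List with Newton `tol` and `maxit`.
#' @param onset_threshold Amplitude fraction of h defining onset.
#' @param regions Optional named list of reference-x intervals (or lists
#'   of pooled intervals) over which amplitudes are tracked separately.
#' @param y_section 3D only: length-coordinate of the metrics section.
#' @param note Free-text description of where the parameter set comes
#'   from.
#' @return A `wrinkle_scenario`.
#' @export
scenario <- function(name, dim, geometry, material, growth, boundary,
                     time = list(t_end = 1, steps = 200L),
                     mesh = list(), imperfection = list(magnitude = 1e-4,
                                                        seed = 0L),
                     numerics = list(tol = 1e-8, maxit = 25L),
                     onset_threshold = 0.05, regions = NULL,
                     y_section = NULL, note = "") {
  stopifnot(dim %in% c(2L, 3L))
  stopifnot(geometry$film > 0, geometry$film < geometry$depth)
  if (dim == 3L && is.null(geometry$length))
    stop("3D scenario needs geometry$length")
  nlaw <- if (dim == 2L) 2L else 3L
  growth$film <- lapply(growth$film, law_to_spec)
  growth$substrate <- lapply(growth$substrate, law_to_spec)
  stopifnot(length(growth$film) == nlaw, length(growth$substrate) == nlaw)
  # canonicalize through the schedule constructor so scenarios built in
  # code and scenarios parsed from configs are structurally identical
  boundary <- boundary_to_spec(boundary_from_spec(boundary))
  mesh <- utils::modifyList(list(resolution = 8, n_film_layers = 2L,
                                 n_substrate_layers = if (dim == 2L) 8L
                                                      else 5L,
                                 ny = 8L), mesh)
  structure(list(name = name, dim = dim, geometry = geometry,
                 material = material, growth = growth, boundary = boundary,
                 time = time, mesh = mesh, imperfection = imperfection,
                 numerics = numerics, onset_threshold = onset_threshold,
                 regions = regions, y_section = y_section, note = note),
            class = "wrinkle_scenario")
}

# ---- declarative <-> live forms ------------------------------------------

law_to_spec <- function(l) {
  if (!inherits(l, "growth_law")) return(l)  # already declarative
  pars <- Filter(function(p) !(is.numeric(p) && !is.finite(p)), l$pars)
  list(law = l$law, pars = pars)
}

boundary_to_spec <- function(b) {
  if (!inherits(b, "boundary_schedule")) return(b)
  pars <- b$pars
  if (!is.null(pars$stretch)) pars$stretch <- law_to_spec(pars$stretch)
  if (!is.null(pars$cap) && !is.finite(pars$cap)) pars$cap <- NULL
  list(type = b$type, pars = pars)
}

boundary_from_spec <- function(spec) {
  if (inherits(spec, "boundary_schedule")) return(spec)
  p <- spec$pars
  switch(spec$type,
    flat = boundary_flat(),
    parabola = boundary_parabola(rate = p$rate, cap = p$cap %||% Inf),
    segments = {
      seg <- p$segments
      if (!is.data.frame(seg))  # from a parsed config: list of row lists
        seg <- do.call(rbind, lapply(seg, as.data.frame))
      boundary_segments(seg, cap = p$cap %||% Inf)
    },
    sine_product = boundary_sine_product(
      rate = p$rate, cap = p$cap %||% Inf,
      kx_factor = p$kx_factor, ky_factor = p$ky_factor,
      power = p$power,
      stretch = if (!is.null(p$stretch)) growth_law_from_spec(p$stretch)),
    stop("unknown boundary type: ", spec$type))
}

# Turn a declarative scenario into live objects (geometry, material,
# schedules, and -- unless mesh = FALSE -- the imperfection-seeded mesh).
materialize_scenario <- function(scn, mesh = TRUE) {
  geom <- bilayer_geometry(width = scn$geometry$width,
                           depth = scn$geometry$depth,
                           film = scn$geometry$film,
                           length = scn$geometry$length)
  mat <- material(R = scn$material$R, nu = scn$material$nu,
                  E_s = scn$material$E_s %||% 1)
  gs <- growth_schedule(film = lapply(scn$growth$film, growth_law_from_spec),
                        substrate = lapply(scn$growth$substrate,
                                           growth_law_from_spec),
                        t_max = scn$time$t_end)
  bnd <- boundary_from_spec(scn$boundary)
  lam_pred <- scn$mesh$wavelength %||%
    (if (scn$material$R > 1)
       critical_wavelength(geom$film, scn$material$R, scn$material$nu)
     else stop("R <= 1 has no predicted wavelength; ",
               "set mesh$wavelength (or mesh$nx) explicitly"))
  out <- list(geometry = geom, material = mat, growth = gs, boundary = bnd,
              lambda_pred = lam_pred)
  if (mesh) {
    m <- if (scn$dim == 2L)
      build_cross_section_mesh(geom, wavelength = lam_pred,
                               resolution = scn$mesh$resolution,
                               n_film_layers = scn$mesh$n_film_layers,
                               n_substrate_layers = scn$mesh$n_substrate_layers,
                               nx = scn$mesh$nx)
    else
      build_volume_mesh(geom, wavelength = lam_pred,
                        resolution = scn$mesh$resolution,
                        ny = scn$mesh$ny,
                        n_film_layers = scn$mesh$n_film_layers,
                        n_substrate_layers = scn$mesh$n_substrate_layers,
                        nx = scn$mesh$nx)
    out$mesh <- seed_imperfection(m, scn$imperfection$magnitude %||% 1e-4,
                                  scn$imperfection$seed %||% 0L)
  }
  out
}

# ---- canonical registry ---------------------------------------------------

#' Canonical cross-section scenario: single growing cell, flat or bulged
#' base
#'
#' The reference cross-section parameter set: in-plane extent 2.0, depth
#' 0.2, film thickness ratio h/H_o = 0.008, stiffness mismatch R = 10,
#' nu = 0.45. The film expands with the accelerating laws
#' `g_f,k(t) = 1 + (C_k/2) t^2` (C_1 = 1 in-plane, C_2 = 10 through the
#' thickness); the substrate does not grow. With `base = "curved"` the base
#' bulges as `u(x) = r(t) x (x - w_o)`, `r(t) = 0.2 t` capped at t = 0.65,
#' emulating turgor pressure; bulging lengthens the base and delays onset
#' relative to the flat case. With `thickness_freeze = TRUE` the film stops
#' thickening at t = 0.5 (before onset), which isolates the effect of the
#' thickness at threshold on the selected wavelength.
#'
#' @param base `"flat"` or `"curved"`.
#' @param thickness_freeze Freeze g_f,2 at t = 0.5?
#' @param R,nu Material parameters.
#' @param width,depth,film_ratio Geometry (film thickness = `film_ratio *
#'   depth`).
#' @param C1,C2,prefactor Growth-law constants g = 1 + prefactor * C t^2.
#' @param freeze_time Freeze time when `thickness_freeze`.
#' @param rate,cap Bulge ramp r(t) = rate * min(t, cap).
#' @param t_end,steps Pseudo-time grid.
#' @param resolution Elements per predicted wavelength.
#' @param imperfection,seed Film imperfection magnitude (fraction of h)
#'   and seed.
#' @param ... Passed to [scenario()].
#' @export
cross_section_scenario <- function(base = c("flat", "curved"),
                                   thickness_freeze = FALSE,
                                   R = 10, nu = 0.45,
                                   width = 2.0, depth = 0.2,
                                   film_ratio = 0.008,
                                   C1 = 1, C2 = 10, prefactor = 0.5,
                                   freeze_time = 0.5,
                                   rate = 0.2, cap = 0.65,
                                   t_end = 1, steps = 200L,
                                   resolution = 8,
                                   imperfection = 1e-4, seed = 0L, ...) {
  base <- match.arg(base)
  g2 <- quadratic_growth_law(C2, prefactor,
                             freeze_at = if (thickness_freeze) freeze_time
                                         else Inf)
  scenario(
    name = paste0("cross_section_", base,
                  if (thickness_freeze) "_freeze" else ""),
    dim = 2L,
    geometry = list(width = width, depth = depth, film = film_ratio * depth),
    material = list(R = R, nu = nu),
    growth = list(film = list(quadratic_growth_law(C1, prefactor), g2),
                  substrate = list(constant_growth_law(),
                                   constant_growth_law())),
    boundary = if (base == "flat") boundary_flat()
               else boundary_parabola(rate = rate, cap = cap),
    time = list(t_end = t_end, steps = as.integer(steps)),
    mesh = list(resolution = resolution),
    imperfection = list(magnitude = imperfection, seed = as.integer(seed)),
    note = paste("canonical single-cell cross-section parameter set;",
                 "film-only growth, turgor-bulged or flat base"),
    ...)
}

#' Scaled cross-section study scenario
#'
#' The same physics as [cross_section_scenario()] but with the in-plane
#' extent set to a fixed number of expected wrinkle wavelengths (`waves`),
#' so sweeps over R stay affordable while the film still hosts enough
#' waves for wavelength statistics. Because the film thickens while it
#' grows, the wavelength selected at onset scales with the thickness *at
#' threshold*; the domain and mesh are therefore sized by the effective
#' wavelength `lambda_c(h) * g_f2(t*)`, with the onset time t* predicted
#' a priori by the stability oracle for the flat base (so flat and curved
#' variants share identical meshes). The bulge ramp is rescaled to
#' preserve the canonical maximum base slope (rate * w_o), keeping the
#' turgor-induced arc-length stretch -- and hence the onset delay --
#' geometrically similar to the canonical run. For R <= 1 (no wrinkling
#' branch) the R = 10 sizing is reused so runs remain comparable.
#'
#' @inheritParams cross_section_scenario
#' @param waves Domain width in units of the effective onset wavelength.
#' @export
wrinkle_study_scenario <- function(R = 10, base = c("flat", "curved"),
                                   thickness_freeze = FALSE,
                                   waves = 8, nu = 0.45, depth = 0.2,
                                   film_ratio = 0.008, steps = 100L,
                                   resolution = 16, C1 = 1, C2 = 10,
                                   prefactor = 0.5, freeze_time = 0.5,
                                   seed = 0L, ...) {
  base <- match.arg(base)
  h <- film_ratio * depth
  Rref <- if (R > 1) R else 10
  lam_c <- critical_wavelength(h, Rref, nu)
  # flat-base onset predicted by the oracle: eps_c = 1 - 1/g1(t*)
  g1_star <- 1 / (1 - critical_strain(Rref, nu))
  t_star <- sqrt((g1_star - 1) / (prefactor * C1))
  g2_star <- 1 + prefactor * C2 *
    min(t_star, if (thickness_freeze) freeze_time else Inf)^2
  lam_eff <- lam_c * g2_star
  width <- waves * lam_eff
  scn <- cross_section_scenario(base = base,
                                thickness_freeze = thickness_freeze,
                                R = R, nu = nu, width = width,
                                depth = depth, film_ratio = film_ratio,
                                C1 = C1, C2 = C2, prefactor = prefactor,
                                freeze_time = freeze_time,
                                rate = 0.2 * 2.0 / width,
                                steps = steps, resolution = resolution,
                                seed = seed, ...)
  scn$name <- paste0("study_", base, "_R", R)
  scn$mesh$wavelength <- lam_eff
  scn$note <- paste("scaled study variant of the cross-section scenario:",
                    waves, "effective onset wavelengths of in-plane",
                    "extent, bulge slope matched to the canonical",
                    "geometry")
  scn
}

#' Scaled turgor-delay study: flat vs bulged base on a shallow slab
#'
#' Compares wrinkling onset between a flat and a turgor-bulged base under
#' identical growth. The base bulge only stretches the film if it carries
#' through the substrate, which requires a slab geometry (depth well
#' below the bulge's lateral scale, as in the canonical cross-section's
#' 10:1 aspect). This study keeps the canonical in-plane extent (2.0),
#' depth (0.2) and growth laws, and instead sizes the film thickness so
#' the domain hosts `waves` effective onset wavelengths -- trading the
#' canonical h/H_o for an affordable mesh while preserving the aspect
#' ratio that makes turgor bulging mechanically effective. The bulge
#' ramp rate is raised (default 0.35) so the onset delay spans several
#' pseudo-time steps.
#'
#' @inheritParams cross_section_scenario
#' @param waves Domain width in units of the effective onset wavelength.
#' @export
turgor_delay_scenario <- function(base = c("flat", "curved"),
                                  thickness_freeze = FALSE, R = 10,
                                  nu = 0.45, waves = 8, rate = 0.35,
                                  t_end = 0.75, steps = 75L, C1 = 1,
                                  C2 = 10, prefactor = 0.5,
                                  freeze_time = 0.5, seed = 0L, ...) {
  base <- match.arg(base)
  width <- 2.0; depth <- 0.2
  g1_star <- 1 / (1 - critical_strain(R, nu))
  t_star <- sqrt((g1_star - 1) / (prefactor * C1))
  g2_star <- 1 + prefactor * C2 *
    min(t_star, if (thickness_freeze) freeze_time else Inf)^2
  lam_eff <- width / waves
  h <- lam_eff / (2 * pi * (R / 3)^(1 / 3) * g2_star)
  scn <- cross_section_scenario(base = base,
                                thickness_freeze = thickness_freeze,
                                R = R, nu = nu, width = width,
                                depth = depth, film_ratio = h / depth,
                                C1 = C1, C2 = C2, prefactor = prefactor,
                                freeze_time = freeze_time,
                                rate = rate, t_end = t_end, steps = steps,
                                resolution = 16, seed = seed, ...)
  scn$name <- paste0("turgor_delay_", base,
                     if (thickness_freeze) "_freeze" else "")
  scn$mesh$wavelength <- lam_eff
  scn$note <- paste("turgor-delay study: canonical slab aspect and growth",
                    "laws, film sized for", waves, "waves; bulge rate",
                    rate)
  scn
}

#' Canonical multi-cell scenario: three cells of different widths
#'
#' Three base segments of widths 1.48, 2.4 and 1.84 (left, middle, right)
#' inside a domain of width 6.0, separated by four equal clamped junction
#' intervals (the printed segment widths leave 0.28 of clamped length,
#' split evenly). Depth H_o = 0.15 (0.07 for case E), h/H_o = 0.0066,
#' R = 20, nu = 0.48. Each segment bulges with its own parabolic turgor
#' rule; the clamped junctions stay put, so wrinkles appear there and in
#' flat segments first.
#'
#' Cases: `A` in-plane film growth only, middle cell flat; `B` as A with
#' every cell bulged; `C` biaxial film growth, middle flat; `D` as C with
#' faster film thickening; `E` thinner domain with substrate thickening
#' tied to film thickening until t = 0.8 (deposition then stops). The
#' per-case growth-rate constants reproduce the described qualitative
#' orderings (the source prints the laws only graphically), and are
#' exposed as arguments.
#'
#' @param case `"A"` to `"E"`.
#' @param scale Geometric scale factor on widths (bulge rates scale as
#'   1/scale to preserve slopes; used by the scaled study variant).
#' @param R,nu,t_end,steps,resolution,seed As elsewhere.
#' @param C1,C2_slow,C2_fast Growth-rate constants (in-plane; slow/fast
#'   thickening).
#' @param rate Bulge ramp rate per segment before scaling.
#' @param ... Passed to [scenario()].
#' @export
three_cell_scenario <- function(case = c("A", "B", "C", "D", "E"),
                                scale = 1, R = 20, nu = 0.48,
                                t_end = 1, steps = 200L, resolution = 8,
                                C1 = 1, C2_slow = 1, C2_fast = 10,
                                rate = 0.2, seed = 0L, ...) {
  case <- match.arg(case)
  # geometric similarity under scaling: in-plane widths AND depth shrink
  # together (the turgor bulge must carry through the substrate, which
  # needs the canonical slab aspect); the film thickness stays at its
  # canonical absolute value so the wrinkle wavelength is unchanged
  depth0 <- if (case == "E") 0.07 else 0.15
  depth <- depth0 * scale
  film <- 0.0066 * depth0
  width <- 6.0 * scale
  segw <- c(1.48, 2.4, 1.84) * scale
  clamp <- (width - sum(segw)) / 4
  x0 <- c(clamp, clamp + segw[1] + clamp, clamp + segw[1] + clamp +
            segw[2] + clamp)
  rr <- rate / scale
  seg_rate <- switch(case,
                     A = c(rr, 0, rr), B = c(rr, rr, rr),
                     C = c(rr, 0, rr), D = c(rr, 0, rr),
                     E = c(rr, rr, rr))
  segments <- data.frame(x0 = x0, width = segw, rate = seg_rate)

  film_g2 <- switch(case,
                    A = constant_growth_law(),
                    B = constant_growth_law(),
                    C = quadratic_growth_law(C2_slow),
                    D = quadratic_growth_law(C2_fast),
                    E = quadratic_growth_law(C2_slow))
  sub_g2 <- if (case == "E")
    quadratic_growth_law(C2_slow, freeze_at = 0.8) else constant_growth_law()

  lam <- critical_wavelength(film, R, nu)
  jc <- c(x0[2] - clamp / 2, x0[3] - clamp / 2)  # interior junction centres
  regions <- list(
    cell_L = x0[1] + c(0.25, 0.75) * segw[1],
    cell_M = x0[2] + c(0.25, 0.75) * segw[2],
    cell_R = x0[3] + c(0.25, 0.75) * segw[3],
    junctions = lapply(jc, function(c0) c0 + c(-1.5, 1.5) * lam))

  scenario(
    name = paste0("three_cell_", case, if (scale != 1)
      paste0("_scale", scale) else ""),
    dim = 2L,
    geometry = list(width = width, depth = depth, film = film),
    material = list(R = R, nu = nu),
    growth = list(film = list(quadratic_growth_law(C1), film_g2),
                  substrate = list(constant_growth_law(), sub_g2)),
    boundary = boundary_segments(segments, cap = 0.65),
    time = list(t_end = t_end, steps = as.integer(steps)),
    mesh = list(resolution = resolution, wavelength = lam),
    imperfection = list(magnitude = 1e-4, seed = as.integer(seed)),
    regions = regions,
    note = paste("canonical three-cell base with clamped junctions;",
                 "per-case growth constants reconstructed from the",
                 "described orderings (laws printed only graphically)"),
    ...)
}

#' Scaled three-cell study scenario
#'
#' [three_cell_scenario()] scaled down geometrically (in-plane widths and
#' depth together, so turgor bulges still carry through the substrate;
#' the film thickness stays canonical so the wrinkle wavelength is
#' unchanged). At the default scale each cell hosts 6-10 predicted
#' wavelengths. Bulge rates scale inversely to preserve the base slopes,
#' and the run stops at t = 0.7, well past the last sub-domain's onset.
#'
#' @inheritParams three_cell_scenario
#' @export
three_cell_study_scenario <- function(case = "B", scale = 0.05,
                                      t_end = 0.7, steps = 70L,
                                      resolution = 12, ...) {
  three_cell_scenario(case = case, scale = scale, t_end = t_end,
                      steps = steps, resolution = resolution, ...)
}

#' Canonical volumetric scenarios: single cell and three-cell base
#'
#' The printed volumetric parameter sets: reference block
#' `[0, w_o] x [0, l_o] x [0, H_o]` with `l_o = w_o = H_o/10`, `H_o = 1`,
#' film thickness `h = H_o/41`. The single-cell base bulges as
#' `0.1 t sin(pi x / w_o) sin(pi y / l_o)`; film grows in-plane and the
#' substrate through the thickness (`1 + t`), substrate in-plane growth
#' frozen at t = 0.2, and the length direction is stretched with the
#' substrate's in-plane growth. The three-cell base bulges as
#' `r(t) sin^2(3 pi x / w_o) sin^2(pi y / l_o)` with `r(t) = 0.2 t` capped at
#' tau = 0.12, growth rate b = 1.5 (substrate in-plane frozen at 2 tau),
#' and length stretch `1 + 0.5 b t`, over t from 0 to 0.25. The stiffness
#' mismatch and Poisson ratio are not part of the printed set; R = 20 and
#' nu = 0.45 are adopted here.
#'
#' Note these printed in-plane extents are smaller than the predicted
#' wrinkle wavelength at moderate R; see the package vignette. The scaled
#' [volume_study_scenario()] uses a geometry that hosts several waves.
#'
#' @param cells `"single"` or `"three"`.
#' @param R,nu Material parameters (adopted, not printed).
#' @param steps Pseudo-time steps.
#' @param ... Passed to [scenario()].
#' @export
volume_scenario <- function(cells = c("single", "three"), R = 20,
                            nu = 0.45, steps = 50L, ...) {
  cells <- match.arg(cells)
  if (cells == "single") {
    scenario(
      name = "volume_single_cell", dim = 3L,
      geometry = list(width = 0.1, length = 0.1, depth = 1, film = 1 / 41),
      material = list(R = R, nu = nu),
      growth = list(
        film = list(linear_growth_law(1), linear_growth_law(1),
                    constant_growth_law()),
        substrate = list(linear_growth_law(1, freeze_at = 0.2),
                         linear_growth_law(1, freeze_at = 0.2),
                         linear_growth_law(1))),
      boundary = boundary_sine_product(rate = 0.1, kx_factor = 1,
                                       ky_factor = 1, power = 1,
                                       stretch = linear_growth_law(
                                         1, freeze_at = 0.2)),
      time = list(t_end = 0.25, steps = as.integer(steps)),
      note = paste("canonical volumetric single-cell set; length stretch",
                   "follows the substrate in-plane growth"),
      ...)
  } else {
    b <- 1.5; tau <- 0.12
    scenario(
      name = "volume_three_cell", dim = 3L,
      geometry = list(width = 0.1, length = 0.1, depth = 1, film = 1 / 41),
      material = list(R = R, nu = nu),
      growth = list(
        film = list(linear_growth_law(b), linear_growth_law(b),
                    constant_growth_law()),
        substrate = list(linear_growth_law(b, freeze_at = 2 * tau),
                         linear_growth_law(b, freeze_at = 2 * tau),
                         constant_growth_law())),
      boundary = boundary_sine_product(rate = 0.2, cap = tau,
                                       kx_factor = 3, ky_factor = 1,
                                       power = 2,
                                       stretch = linear_growth_law(0.5 * b)),
      time = list(t_end = 0.25, steps = as.integer(steps)),
      note = "canonical volumetric three-cell set",
      ...)
  }
}

#' Scaled volumetric study scenario (three bulges)
#'
#' A coarse, affordable volumetric run with the three-cell turgor base:
#' in-plane extent sized to host ~14 predicted wavelengths across the
#' bulge direction, length direction elongated and stretched so ridges
#' align along it, growth laws as in the canonical three-cell volumetric
#' set. Regions over the bulge tops (`dome`) and between bulges
#' (`junction`) are tracked separately: the pattern initiates between
#' bulges and at junctions before the dome tops.
#'
#' @param R,nu,steps,ny As elsewhere.
#' @param ... Passed to [scenario()].
#' @export
volume_study_scenario <- function(R = 20, nu = 0.45, steps = 30L,
                                  ny = 4L, ...) {
  b <- 1.5; tau <- 0.12
  # shallow slab: the three turgor bulges (lateral scale w/3) must carry
  # through the substrate depth to delay onset over the domes
  width <- 0.7; len <- 0.3; depth <- 0.05; film <- 0.006
  lam <- critical_wavelength(film, R, nu)
  centers_dome <- width * c(1, 3, 5) / 6
  centers_junc <- width * c(1, 2) / 3
  scenario(
    name = "volume_three_cell_study", dim = 3L,
    geometry = list(width = width, length = len, depth = depth,
                    film = film),
    material = list(R = R, nu = nu),
    growth = list(
      film = list(linear_growth_law(b), linear_growth_law(b),
                  constant_growth_law()),
      substrate = list(linear_growth_law(b, freeze_at = 2 * tau),
                       linear_growth_law(b, freeze_at = 2 * tau),
                       constant_growth_law())),
    boundary = boundary_sine_product(rate = 0.4, cap = tau, kx_factor = 3,
                                     ky_factor = 1, power = 2,
                                     stretch = linear_growth_law(0.5 * b)),
    time = list(t_end = 0.15, steps = as.integer(steps)),
    mesh = list(resolution = 8, ny = as.integer(ny),
                n_substrate_layers = 4L, wavelength = lam),
    regions = list(
      dome = lapply(centers_dome, function(c0) c0 + c(-1, 1) * lam),
      junction = lapply(centers_junc, function(c0) c0 + c(-1, 1) * lam)),
    y_section = len / 2,
    note = paste("scaled volumetric study: three turgor bulges across the",
                 "width, elongation along the length; qualitative pattern",
                 "ordering study"),
    ...)
}

#' Names of the canonical scenarios in the registry
#' @return Character vector of scenario names accepted by
#'   [get_scenario()].
#' @export
list_scenarios <- function() {
  c("cross_section_flat", "cross_section_curved",
    "cross_section_flat_freeze", "cross_section_curved_freeze",
    paste0("three_cell_", c("A", "B", "C", "D", "E")),
    "volume_single_cell", "volume_three_cell", "volume_three_cell_study")
}

#' Fetch a canonical scenario by name
#' @param name One of [list_scenarios()].
#' @param ... Overrides passed to the underlying constructor.
#' @export
get_scenario <- function(name, ...) {
  switch(name,
    cross_section_flat = cross_section_scenario("flat", ...),
    cross_section_curved = cross_section_scenario("curved", ...),
    cross_section_flat_freeze =
      cross_section_scenario("flat", thickness_freeze = TRUE, ...),
    cross_section_curved_freeze =
      cross_section_scenario("curved", thickness_freeze = TRUE, ...),
    three_cell_A = three_cell_scenario("A", ...),
    three_cell_B = three_cell_scenario("B", ...),
    three_cell_C = three_cell_scenario("C", ...),
    three_cell_D = three_cell_scenario("D", ...),
    three_cell_E = three_cell_scenario("E", ...),
    volume_single_cell = volume_scenario("single", ...),
    volume_three_cell = volume_scenario("three", ...),
    volume_three_cell_study = volume_study_scenario(...),
    stop("unknown scenario: ", name))
}

# ---- config files ---------------------------------------------------------

#' Write / read a scenario as a JSON config
#'
#' Scenarios are fully declarative and round-trip losslessly (full double
#' precision) through these configs.
#'
#' @param scn A `wrinkle_scenario`.
#' @param file Path to the config file.
#' @export
write_scenario <- function(scn, file) {
  stopifnot(inherits(scn, "wrinkle_scenario"))
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("scenario configs need the jsonlite package")
  jsonlite::write_json(unclass(scn), file, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(file)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(file) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("scenario configs need the jsonlite package")
  x <- jsonlite::read_json(file, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  regions <- x$regions
  if (!is.null(regions))
    regions <- lapply(regions, function(r) {
      if (is.matrix(r))       # pooled intervals simplified to a matrix
        lapply(seq_len(nrow(r)), function(i) as.numeric(r[i, ]))
      else if (is.list(r)) lapply(r, as.numeric)
      else as.numeric(r)
    })
  scenario(name = x$name, dim = as.integer(x$dim), geometry = x$geometry,
           material = x$material,
           growth = list(film = x$growth$film,
                         substrate = x$growth$substrate),
           boundary = x$boundary,
           time = x$time, mesh = as.list(x$mesh),
           imperfection = x$imperfection, numerics = x$numerics,
           onset_threshold = x$onset_threshold, regions = regions,
           y_section = x$y_section, note = x$note %||% "")
}
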