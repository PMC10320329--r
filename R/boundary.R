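#' Boundary schedules: turgor-bulged bases and lateral confinement
#'
#' The base of the bilayer follows a prescribed, pseudo-time-dependent
#' displacement that emulates turgor pressure bulging the underlying cell
#' wall; the lateral faces confine the in-plane extent (the "larger volume
#' into a smaller one" constraint); the free surface is traction-free.
#'
#' * `boundary_flat()`: the base stays put.
#' * `boundary_parabola(rate, cap)`: single-cell bulge, the parabolic
#'   profile `r(t) x (x - w_o)` (ramp `r(t) = rate * min(t, cap)`)
#'   applied towards the free surface -- turgor pushes the cell wall
#'   outward, which arcs and stretches the film above it.
#' * `boundary_segments(segments, cap)`: multi-cell base. Each row of
#'   `segments` (columns `x0`, `width`, `rate`) bulges as
#'   `f_k = r_k(t) (x - x0_k)(x - (x0_k + width_k))` on its own interval;
#'   the gaps between segments are clamped cell junctions (zero
#'   displacement).
#' * `boundary_sine_product(rate, cap, kx_factor, ky_factor, power,
#'   stretch)`: volumetric bulges,
#'   `u_z = r(t) sin(k_1 x)^power sin(k_2 y)^power` with
#'   `k_1 = kx_factor pi / w_o`, `k_2 = ky_factor pi / l_o`, plus a uniform
#'   stretch of the length (y) direction by the factor `stretch(t)` (a
#'   [growth_laws] object) applied to the base and the two width-normal
#'   faces, emulating cell elongation. The length-normal faces are free.
#'
#' In 2D the lateral faces x = 0 and x = w_o are pinned horizontally
#' (vertical motion free) and the base is pinned horizontally with the
#' scheduled depth displacement.
#'
#' @param rate Ramp rate of the bulge parameter r(t).
#' @param cap Pseudo-time at which the ramp stops (r is held constant
#'   afterwards); default `Inf`.
#' @param segments Data frame with columns `x0`, `width`, `rate`.
#' @param kx_factor,ky_factor Multiples of pi/w_o and pi/l_o in the bulge
#'   wavenumbers.
#' @param power Power of the sine factors (2 for cell-like bulges, 1 for a
#'   single smooth dome).
#' @param stretch A [growth_laws] object giving the length-direction
#'   stretch factor k(t) (default: none).
#' @return A `boundary_schedule`.
#' @name boundary_schedules
NULL

new_boundary <- function(type, pars) {
  structure(list(type = type, pars = pars), class = "boundary_schedule")
}

#' @rdname boundary_schedules
#' @export
boundary_flat <- function() new_boundary("flat", list())

#' @rdname boundary_schedules
#' @export
boundary_parabola <- function(rate = 0.2, cap = 0.65)
  new_boundary("parabola", list(rate = rate, cap = cap))

#' @rdname boundary_schedules
#' @export
boundary_segments <- function(segments, cap = 0.65) {
  segments <- as.data.frame(segments)
  stopifnot(all(c("x0", "width", "rate") %in% names(segments)))
  new_boundary("segments", list(segments = segments, cap = cap))
}

#' @rdname boundary_schedules
#' @export
boundary_sine_product <- function(rate = 0.2, cap = Inf, kx_factor = 3,
                                  ky_factor = 1, power = 2,
                                  stretch = NULL) {
  if (!is.null(stretch) && !inherits(stretch, "growth_law"))
    stretch <- growth_law_from_spec(stretch)
  new_boundary("sine_product",
               list(rate = rate, cap = cap, kx_factor = kx_factor,
                    ky_factor = ky_factor, power = power, stretch = stretch))
}

# ramp r(t) with cap
ramp_at <- function(rate, cap, t) rate * min(t, cap %||% Inf)

#' Base depth displacement prescribed by a schedule
#'
#' @param schedule A [boundary_schedules] object.
#' @param x,y In-plane reference coordinates of base points (`y` for 3D
#'   schedules only).
#' @param t Pseudo-time.
#' @param geom The [bilayer_geometry()] (supplies w_o and l_o).
#' @return Depth displacements, one per point.
#' @export
base_displacement <- function(schedule, x, t, geom, y = NULL) {
  stopifnot(inherits(schedule, "boundary_schedule"))
  p <- schedule$pars
  switch(schedule$type,
    flat = rep(0, length(x)),
    parabola = {
      # turgor bulges the base towards the free surface: the parabola
      # r x (x - w_o) is applied with depth increasing downwards, i.e.
      # upward displacement r x (w_o - x) in this package's coordinates
      # (a downward dip would Poisson-compress the film and advance
      # onset instead of delaying it)
      r <- ramp_at(p$rate, p$cap, t)
      r * x * (geom$width - x)
    },
    segments = {
      u <- rep(0, length(x))
      for (k in seq_len(nrow(p$segments))) {
        s <- p$segments[k, ]
        r <- ramp_at(s$rate, p$cap, t)
        inside <- x >= s$x0 & x <= s$x0 + s$width
        u[inside] <- r * (x[inside] - s$x0) *
          ((s$x0 + s$width) - x[inside])
      }
      u
    },
    sine_product = {
      if (is.null(y)) stop("sine-product schedule needs y coordinates")
      r <- ramp_at(p$rate, p$cap, t)
      k1 <- p$kx_factor * pi / geom$width
      k2 <- p$ky_factor * pi / geom$length
      r * sin(k1 * x)^p$power * sin(k2 * y)^p$power
    },
    stop("unknown boundary schedule type: ", schedule$type))
}

# length-direction stretch factor k(t) (3D schedules; 1 otherwise)
stretch_factor <- function(schedule, t) {
  s <- schedule$pars$stretch
  if (is.null(s)) 1 else s$fun(t)
}

#' Arc length of the deformed base curve
#'
#' Used by [growth_to_strain()]: the bulged base is longer than the flat
#' reference width, which relieves part of the growth-induced film
#' compression and delays onset.
#'
#' @inheritParams base_displacement
#' @param n Quadrature points.
#' @export
base_arc_length <- function(schedule, t, geom, n = 4001L) {
  x <- seq(0, geom$width, length.out = n)
  u <- base_displacement(schedule, x, t, geom,
                         y = if (schedule$type == "sine_product")
                           rep(geom$length / 2, n) else NULL)
  du <- diff(u); dx <- diff(x)
  sum(sqrt(dx^2 + du^2))
}

#' Dirichlet constraint set for a mesh at pseudo-time t
#'
#' Translates a boundary schedule into prescribed displacement values on
#' the tagged node sets of a mesh: lateral pinning, base motion (and, in
#' 3D, the length-direction stretch). The top surface is always
#' traction-free and receives no constraints.
#'
#' @param mesh A `bilayer_mesh`.
#' @param schedule A [boundary_schedules] object.
#' @param t Pseudo-time.
#' @return Data frame with columns `dof` (global dof index, node-major
#'   interleaved) and `value`.
#' @export
apply_boundary_conditions <- function(mesh, schedule, t) {
  stopifnot(inherits(mesh, "bilayer_mesh"),
            inherits(schedule, "boundary_schedule"))
  d <- mesh$dim
  if (d == 2L && schedule$type == "sine_product")
    stop("sine-product schedule references length-direction facets ",
         "that a cross-section mesh does not have")
  if (d == 3L && schedule$type %in% c("parabola", "segments"))
    stop("planar base schedule applied to a volume mesh")
  dof_of <- function(nodes, comp) (nodes - 1L) * d + comp
  geom <- mesh$geom

  if (d == 2L) {
    base <- mesh$sets$base
    ub <- base_displacement(schedule, mesh$coords[base, 1], t, geom)
    lateral <- union(mesh$sets$left, mesh$sets$right)
    out <- rbind(
      data.frame(dof = dof_of(base, 1L), value = 0),
      data.frame(dof = dof_of(base, 2L), value = ub),
      data.frame(dof = dof_of(lateral, 1L), value = 0))
  } else {
    base <- mesh$sets$base
    k <- stretch_factor(schedule, t)
    ub <- base_displacement(schedule, mesh$coords[base, 1], t, geom,
                            y = mesh$coords[base, 2])
    sides <- union(mesh$sets$left, mesh$sets$right)
    out <- rbind(
      data.frame(dof = dof_of(base, 1L), value = 0),
      data.frame(dof = dof_of(base, 2L),
                 value = (k - 1) * mesh$coords[base, 2]),
      data.frame(dof = dof_of(base, 3L), value = ub),
      data.frame(dof = dof_of(sides, 1L), value = 0),
      data.frame(dof = dof_of(sides, 2L),
                 value = (k - 1) * mesh$coords[sides, 2]))
  }
  out[!duplicated(out$dof), , drop = FALSE]
}

#' @export
print.boundary_schedule <- function(x, ...) {
  cat("boundary schedule <", x$type, ">\n", sep = "")
  if (x$type == "segments") print(x$pars$segments)
  invisible(x)
}
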