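#' Extract the deformed free-surface profile
#'
#' Samples the top (traction-free) surface of a solved state in the current
#' configuration, ordered along the surface. For volume meshes a section at
#' constant length-coordinate is taken (default: mid-length, through the
#' bulge maxima), so the profile runs perpendicular to the wrinkle ridges.
#'
#' @param mesh A `bilayer_mesh`.
#' @param u Nodal displacement vector (zero vector for the reference
#'   state).
#' @param y Section coordinate for 3D meshes (nearest node line is used);
#'   default mid-length.
#' @return A `surface_profile` data frame with columns `s` (arc length),
#'   `x` (current in-plane coordinate) and `height` (current depth
#'   coordinate), plus attribute `x_ref` (reference in-plane coordinate of
#'   each sample).
#' @export
extract_top_profile <- function(mesh, u, y = NULL) {
  stopifnot(inherits(mesh, "bilayer_mesh"))
  d <- mesh$dim
  top <- mesh$sets$top
  if (d == 3L) {
    yy <- mesh$coords[top, 2]
    ytarget <- y %||% (mesh$geom$length / 2)
    ysel <- unique(yy)[which.min(abs(unique(yy) - ytarget))]
    top <- top[abs(yy - ysel) < 1e-9 * max(mesh$geom$length, 1)]
  }
  ord <- order(mesh$coords[top, 1])
  top <- top[ord]
  um <- matrix(u, ncol = d, byrow = TRUE)
  xcur <- mesh$coords[top, 1] + um[top, 1]
  zcur <- mesh$coords[top, d] + um[top, d]
  s <- c(0, cumsum(sqrt(diff(xcur)^2 + diff(zcur)^2)))
  out <- data.frame(s = s, x = xcur, height = zcur)
  attr(out, "x_ref") <- mesh$coords[top, 1]
  class(out) <- c("surface_profile", "data.frame")
  out
}

#' Separate the cell-scale trend from the wrinkle oscillation
#'
#' Local quadratic regression (Gaussian weights, sd = `window`/4) of the
#' surface height against arc length. The smooth trend captures the
#' cell-scale bulge (a quadratic reproduces a parabolic bulge exactly);
#' the remainder is the wrinkle oscillation, about which amplitude is
#' measured. `trend + oscillation` reconstructs the input heights exactly
#' by construction.
#'
#' @param profile A [extract_top_profile()] result (or any data frame with
#'   `s` and `height`).
#' @param window Smoothing scale; must exceed the wrinkle wavelength so
#'   the oscillation is not absorbed into the trend (3 x the predicted
#'   wavelength is a good default), and must exceed the sample spacing.
#' @param passes Smoothing passes. With strongly bulged trends a single
#'   pass leaks a smooth residual of the (non-parabolic) deformed bulge
#'   into the oscillation; a second pass removes that leak while
#'   attenuating the wavelength-scale oscillation negligibly (default 2).
#' @return A `detrended_profile`: list with `profile`, `trend`,
#'   `oscillation`.
#' @export
detrend_profile <- function(profile, window, passes = 2L) {
  s <- profile$s; hgt <- profile$height
  spacing <- stats::median(diff(s))
  if (!is.finite(window) || window <= spacing)
    stop("smoothing window (", format(window),
         ") must exceed the sample spacing (", format(spacing), ")")
  osc <- hgt
  for (p in seq_len(max(1L, passes)))
    osc <- osc - local_quadratic_trend(s, osc, window)
  structure(list(profile = profile, trend = hgt - osc,
                 oscillation = osc),
            class = "detrended_profile")
}

# Gaussian-weighted local quadratic regression (sd = window/4); exact for
# quadratic trends, absorbs < 5% of a sinusoid of period window/2.
local_quadratic_trend <- function(s, v, window) {
  sigma <- window / 4
  n <- length(s)
  trend <- numeric(n)
  half <- 3 * sigma
  for (i in seq_len(n)) {
    sel <- which(abs(s - s[i]) <= half)
    ds <- s[sel] - s[i]
    w <- exp(-0.5 * (ds / sigma)^2)
    X <- cbind(1, ds, ds^2)
    XtW <- t(X * w)
    beta <- tryCatch(solve(XtW %*% X, XtW %*% v[sel]),
                     error = function(e) NULL)
    trend[i] <- if (is.null(beta)) sum(w * v[sel]) / sum(w) else beta[1]
  }
  trend
}

# interior local extrema of a series, with quadratic sub-sample refinement;
# returns data.frame(index, pos, value, kind) with kind +1 max / -1 min
find_extrema <- function(s, v) {
  n <- length(v)
  if (n < 5L) return(data.frame(index = integer(), pos = numeric(),
                                value = numeric(), kind = integer()))
  dv <- diff(v)
  sgn <- sign(dv)
  idx <- which(sgn[-1] * sgn[-(n - 1)] < 0) + 1L  # interior sign change
  idx <- idx[idx > 1L & idx < n]
  if (!length(idx)) return(data.frame(index = integer(), pos = numeric(),
                                      value = numeric(), kind = integer()))
  kind <- ifelse(v[idx] > (v[idx - 1L] + v[idx + 1L]) / 2, 1L, -1L)
  pos <- s[idx]; val <- v[idx]
  for (j in seq_along(idx)) {
    i <- idx[j]
    # quadratic through the three samples around the discrete extremum
    x0 <- s[i - 1L] - s[i]; x2 <- s[i + 1L] - s[i]
    y0 <- v[i - 1L]; y1 <- v[i]; y2 <- v[i + 1L]
    den <- x0 * x2 * (x0 - x2)
    if (abs(den) > 0) {
      a <- (x2 * (y0 - y1) - x0 * (y2 - y1)) / den
      b <- (x0^2 * (y2 - y1) - x2^2 * (y0 - y1)) / den
      if (abs(a) > 0) {
        xs <- -b / (2 * a)
        if (xs > x0 && xs < x2) {
          pos[j] <- s[i] + xs
          val[j] <- y1 + b * xs + a * xs^2
        }
      }
    }
  }
  data.frame(index = idx, pos = pos, value = val, kind = kind)
}

#' Wrinkle amplitude of a detrended oscillation
#'
#' Half the typical peak-to-trough excursion over interior waves (the
#' amplitude annotation of a ridge cross-section): the median over the
#' alternating peak/trough pairs, which equals the mean on clean periodic
#' profiles but is robust against the small spurious extremum pairs that
#' measurement noise introduces. 0 when the profile carries no interior
#' peak/trough pair.
#'
#' @param oscillation A [detrend_profile()] result, or a bare numeric
#'   vector of detrended heights.
#' @export
measure_amplitude <- function(oscillation) {
  v <- if (inherits(oscillation, "detrended_profile"))
    oscillation$oscillation else as.numeric(oscillation)
  s <- if (inherits(oscillation, "detrended_profile"))
    oscillation$profile$s else seq_along(v)
  ex <- find_extrema(s, v)
  if (nrow(ex) < 2L) return(0)
  dv <- abs(diff(ex$value))
  alt <- diff(ex$kind) != 0L   # only alternating max/min pairs
  if (!any(alt)) return(0)
  stats::median(dv[alt]) / 2
}

#' Per-wave wrinkle wavelengths of a surface profile
#'
#' Crests are located on the detrended oscillation (sign change of the
#' discrete derivative with quadratic sub-sample refinement), then each
#' wavelength is the Euclidean distance between consecutive crest points of
#' the actual surface, i.e. `lambda_n = |u_{n+1} - u_n|` on the current
#' configuration. On a curved base this exceeds the flat-projected spacing
#' (see [curved_wavelength_map()]).
#'
#' @param profile A [extract_top_profile()] result.
#' @param window Detrending window; default `3 * lambda_hint`.
#' @param lambda_hint Expected wavelength (used only for the default
#'   window).
#' @param detrended Optionally a precomputed [detrend_profile()] result.
#' @return List with `mean`, `sd`, `per_wave`, `n_waves`, and `undefined`
#'   (TRUE when fewer than 2 crests exist, i.e. onset not reached -- this
#'   is a state, not an error).
#' @export
measure_wavelength <- function(profile, window = NULL, lambda_hint = NULL,
                               detrended = NULL) {
  if (is.null(detrended)) {
    if (is.null(window)) {
      if (is.null(lambda_hint))
        stop("supply `window`, `lambda_hint`, or a precomputed `detrended`")
      window <- 3 * lambda_hint
    }
    detrended <- detrend_profile(profile, window)
  }
  s <- profile$s
  ex <- find_extrema(s, detrended$oscillation)
  pk <- ex[ex$kind == 1L, , drop = FALSE]
  # the first and last crest sit in the smoother's edge zone where the
  # truncated window distorts positions; drop them when enough remain
  if (nrow(pk) >= 5L) pk <- pk[2:(nrow(pk) - 1L), , drop = FALSE]
  if (nrow(pk) < 2L)
    return(list(mean = NA_real_, sd = NA_real_, per_wave = numeric(),
                positions = numeric(), n_waves = nrow(pk),
                undefined = TRUE))
  # surface point at each refined crest arc-length position
  px <- stats::approx(s, profile$x, xout = pk$pos)$y
  pz <- stats::approx(s, profile$height, xout = pk$pos)$y
  lam <- sqrt(diff(px)^2 + diff(pz)^2)
  list(mean = mean(lam), sd = if (length(lam) > 1L) sd(lam) else 0,
       per_wave = lam, positions = px, n_waves = nrow(pk),
       undefined = FALSE)
}

#' Exact crest-to-crest distances of a wrinkle mapped onto a curved base
#'
#' A flat periodic wrinkle `(x, A cos(kx))` carried onto a curved base
#' curve `(x, g(x))` by the normal offset `u = g + h(x) N-hat`,
#' `N-hat = (-t_y, t_x)`, places its crests at
#' `u_n = (x_n - A t_y(x_n), g(x_n) + A t_x(x_n))`, `x_n = 2 pi n / k`.
#' The squared crest spacing expands exactly as
#' `lambda_n^2 = lambda^2 + (dg_n)^2 + A^2 (dt_x^2 + dt_y^2)
#'  + 2 A (dg_n dt_x - lambda dt_y)`
#' with `lambda = 2 pi / k` and `d` the difference between consecutive
#' crests: the first two terms are the hypotenuse spanned by the height
#' difference, the rest is the amplitude-dependent spreading of crests on
#' a convex base. Wavelengths on a curved base are therefore not constant
#' even for a perfectly periodic wrinkle.
#'
#' @param base_curve Function g(x) describing the base (twice
#'   differentiable on the domain).
#' @param amplitude,wavenumber Wrinkle amplitude A and wavenumber k.
#' @param domain Interval `c(xmin, xmax)` containing the crests.
#' @param deriv Optional derivative g'(x); numerically differenced
#'   otherwise.
#' @return Data frame with crest positions `x` and spacings `lambda_n`
#'   (one row per consecutive crest pair).
#' @export
curved_wavelength_map <- function(base_curve, amplitude, wavenumber, domain,
                                  deriv = NULL) {
  stopifnot(wavenumber > 0, length(domain) == 2L)
  lam <- 2 * pi / wavenumber
  n0 <- ceiling(domain[1] / lam - 1e-9)
  n1 <- floor(domain[2] / lam + 1e-9)
  if (n1 - n0 < 1L) {
    warning("fewer than two crests fall inside the domain")
    return(data.frame(x = numeric(), lambda_n = numeric()))
  }
  xn <- (n0:n1) * lam
  g <- base_curve(xn)
  gp <- if (!is.null(deriv)) deriv(xn) else {
    eps <- 1e-6 * max(1, diff(domain))
    (base_curve(xn + eps) - base_curve(xn - eps)) / (2 * eps)
  }
  nrm <- sqrt(1 + gp^2)
  tx <- 1 / nrm; ty <- gp / nrm
  dg <- diff(g); dtx <- diff(tx); dty <- diff(ty)
  lam2 <- lam^2 + dg^2 + amplitude^2 * (dtx^2 + dty^2) +
    2 * amplitude * (dg * dtx - lam * dty)
  data.frame(x = xn[-length(xn)], lambda_n = sqrt(lam2))
}

#' Detect wrinkling onset from an amplitude trajectory
#'
#' The onset pseudo-time t* is the first time the amplitude exceeds
#' `threshold * h` and stays above it for two consecutive steps (a
#' sustained crossing, robust against a single noisy step).
#'
#' @param summary A data frame with columns `t` and an amplitude column
#'   (as produced by [run_quasistatic()]).
#' @param h Film thickness.
#' @param threshold Fraction of `h` defining onset (default 0.05: above
#'   the imperfection floor, below mature amplitudes).
#' @param column Amplitude column to use (a per-region column may be
#'   given).
#' @return The onset pseudo-time, or `NA` if onset is never reached.
#' @export
detect_onset <- function(summary, h, threshold = 0.05,
                         column = "amplitude") {
  a <- summary[[column]]
  if (is.null(a)) stop("no column `", column, "` in summary")
  above <- a > threshold * h
  sustained <- which(above[-length(above)] & above[-1])
  if (!length(sustained)) return(NA_real_)
  summary$t[sustained[1]]
}
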