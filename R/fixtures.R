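#' Synthetic surface-profile fixtures with known ground truth
#'
#' Deterministic generator of wrinkled surface profiles used as ground
#' truth for the pattern metrics: a base curve (flat or parabolic bulge)
#' carries a periodic wrinkle `h(x) = A cos(kx)` by the normal-offset
#' construction `u = (x, g(x)) + h(x) N-hat`, `N-hat = (-t_y, t_x)`,
#' optionally with seeded Gaussian height noise. The true amplitude,
#' wavenumber and the exact per-wave crest spacings (via
#' [curved_wavelength_map()]) are attached as attributes, so metric
#' estimators can be checked against a known answer without any external
#' data.
#'
#' @param base `"flat"` or `"parabola"` (`g(x) = rate * x * (x - width)`).
#' @param width Domain width.
#' @param rate Parabola coefficient (ignored for flat bases).
#' @param amplitude,wavenumber Wrinkle amplitude A and wavenumber k.
#' @param n_per_wave Samples per wavelength (>= 16; the metrics assume at
#'   least that density).
#' @param noise_sd Gaussian noise sd added to heights (keep below ~0.1 A
#'   so crest topology is preserved).
#' @param seed RNG seed for the noise.
#' @return A `surface_profile` with attributes `amplitude`, `wavenumber`,
#'   `lambda` (= 2 pi / k), and `lambda_n` (exact crest spacings).
#' @export
make_profile <- function(base = c("flat", "parabola"), width = 1,
                         rate = 0.5, amplitude = 0.01,
                         wavenumber = 2 * pi / 0.1, n_per_wave = 16,
                         noise_sd = 0, seed = 1L) {
  base <- match.arg(base)
  stopifnot(noise_sd >= 0)
  if (n_per_wave < 16)
    stop("under-sampled fixture: need >= 16 samples per wave")
  lam <- 2 * pi / wavenumber
  x <- seq(0, width, by = lam / n_per_wave)
  if (base == "flat") {
    g <- rep(0, length(x)); gp <- rep(0, length(x))
    gfun <- function(z) rep(0, length(z))
    dfun <- function(z) rep(0, length(z))
  } else {
    g <- rate * x * (x - width); gp <- rate * (2 * x - width)
    gfun <- function(z) rate * z * (z - width)
    dfun <- function(z) rate * (2 * z - width)
  }
  nrm <- sqrt(1 + gp^2)
  tx <- 1 / nrm; ty <- gp / nrm
  hosc <- amplitude * cos(wavenumber * x)
  px <- x - hosc * ty
  pz <- g + hosc * tx
  if (noise_sd > 0)
    pz <- pz + with_seed(seed, rnorm(length(pz), 0, noise_sd))
  s <- c(0, cumsum(sqrt(diff(px)^2 + diff(pz)^2)))
  out <- data.frame(s = s, x = px, height = pz)
  attr(out, "x_ref") <- x
  attr(out, "amplitude") <- amplitude
  attr(out, "wavenumber") <- wavenumber
  attr(out, "lambda") <- lam
  attr(out, "lambda_n") <-
    curved_wavelength_map(gfun, amplitude, wavenumber, c(0, width),
                          deriv = dfun)
  class(out) <- c("surface_profile", "data.frame")
  out
}

#' Random, well-conditioned kinematic states for constitutive tests
#'
#' Reproducible random deformation gradient and diagonal growth tensor
#' with comfortably positive determinants (det F > 0.3), decomposed via
#' [elastic_decomposition()].
#'
#' @param seed RNG seed.
#' @param dim 2 or 3.
#' @export
make_random_kinematic_state <- function(seed = 1L, dim = 3L) {
  stopifnot(dim %in% c(2L, 3L))
  with_seed(seed, {
    repeat {
      F <- diag(dim) + 0.25 * matrix(runif(dim * dim, -1, 1), dim)
      if (det(F) > 0.3) break
    }
    G <- diag(runif(dim, 0.85, 1.5), dim)
    elastic_decomposition(F, G)
  })
}
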