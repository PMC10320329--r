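#' Lamé parameters from Young's modulus and Poisson ratio
#'
#' mu = E / (2 (1 + nu)), lambda = E nu / ((1 + nu)(1 - 2 nu)). Both layers
#' share nu, so mu_f/mu_s = lambda_f/lambda_s = E_f/E_s = R.
#'
#' @param E Young's modulus (> 0; the substrate modulus is 1 by convention).
#' @param nu Poisson ratio, 0 < nu < 0.5 (lambda diverges at 0.5).
#' @return Named vector `c(mu = , lambda = )`.
#' @export
lame_parameters <- function(E, nu) {
  stopifnot(E > 0)
  if (!(nu > 0 && nu < 0.5))
    stop("Poisson ratio must lie in (0, 0.5); lambda is undefined at 0.5")
  c(mu = E / (2 * (1 + nu)),
    lambda = E * nu / ((1 + nu) * (1 - 2 * nu)))
}

#' Bilayer material: stiffness mismatch and shared Poisson ratio
#'
#' @param R Stiffness mismatch E_f/E_s (> 0). Wrinkling requires R > 1.
#' @param nu Shared Poisson ratio (0 < nu < 0.5).
#' @param E_s Substrate modulus (default 1, the nondimensional convention).
#' @return A `bilayer_material` with per-layer Lamé parameters.
#' @export
material <- function(R, nu, E_s = 1) {
  stopifnot(R > 0, E_s > 0)
  lf <- lame_parameters(R * E_s, nu)
  ls <- lame_parameters(E_s, nu)
  structure(list(R = R, nu = nu, E_f = R * E_s, E_s = E_s,
                 mu_f = lf[["mu"]], lambda_f = lf[["lambda"]],
                 mu_s = ls[["mu"]], lambda_s = ls[["lambda"]]),
            class = "bilayer_material")
}

#' @export
print.bilayer_material <- function(x, ...) {
  cat("bilayer material: R = E_f/E_s =", format(x$R), ", nu =",
      format(x$nu), "\n")
  cat("  film:      mu =", format(x$mu_f), ", lambda =",
      format(x$lambda_f), "\n")
  cat("  substrate: mu =", format(x$mu_s), ", lambda =",
      format(x$lambda_s), "\n")
  invisible(x)
}

# Embed a 2x2 in-plane tensor as plane strain (out-of-plane entry `a33`).
embed3 <- function(M, a33 = 1) {
  if (all(dim(M) == c(3L, 3L))) return(M)
  out <- diag(c(1, 1, a33))
  out[1:2, 1:2] <- M
  out
}

#' Multiplicative elastic/growth decomposition of the deformation gradient
#'
#' Splits F = A G into the elastic response A = F G^-1 and the prescribed
#' growth G, and computes the kinematic quantities the energy needs:
#' C_e = A^T A, its first invariant I_1, the elastic volume ratio
#' J_e = det A and the grown volume ratio J_g = det G. 2x2 input tensors
#' are treated as the in-plane block of a plane-strain state (out-of-plane
#' stretch 1, out-of-plane growth 1).
#'
#' @param F Deformation gradient (2x2 or 3x3, det F > 0).
#' @param G Growth tensor (same size, det G > 0; diagonal in all scenarios
#'   this package runs, but any invertible tensor is accepted here).
#' @return A `kinematic_state` with fields `F`, `G`, `A`, `Ce`, `I1`, `Je`,
#'   `Jg`.
#' @export
elastic_decomposition <- function(F, G) {
  F <- as.matrix(F); G <- as.matrix(G)
  stopifnot(all(dim(F) == dim(G)), nrow(F) %in% c(2L, 3L))
  dG <- det(G)
  if (!is.finite(dG) || abs(dG) < 1e-14) stop("growth tensor is singular")
  if (det(F) <= 0) stop("deformation gradient must have positive determinant")
  if (dG <= 0) stop("growth tensor must have positive determinant")
  A <- F %*% solve(G)
  A3 <- embed3(A);
  Ce <- t(A3) %*% A3
  structure(list(F = F, G = G, A = A, Ce = Ce,
                 I1 = sum(diag(Ce)), Je = det(A3), Jg = det(embed3(G))),
            class = "kinematic_state")
}

#' Compressible neo-Hookean strain energy density
#'
#' Psi = mu/2 (I_1 - 3) - mu ln J_e + lambda/2 ln^2 J_e, per unit reference
#' volume of the elastically relaxed (grown) configuration. Psi >= 0 with
#' equality iff the elastic part is a rotation.
#'
#' @param state A [elastic_decomposition()] result.
#' @param mu,lambda Lamé parameters of the layer.
#' @export
strain_energy_density <- function(state, mu, lambda) {
  stopifnot(inherits(state, "kinematic_state"))
  if (state$Je <= 0) stop("elastic volume ratio J_e must be positive")
  lnJ <- log(state$Je)
  mu / 2 * (state$I1 - 3) - mu * lnJ + lambda / 2 * lnJ^2
}

#' Nominal (first Piola-Kirchhoff) stress of the morphoelastic stack
#'
#' The stress conjugate to F of the total reference energy density
#' W(F) = J_g Psi(F G^-1):
#'   P = J_g (mu A + (lambda ln J_e - mu) A^-T) G^-T.
#' This is the energy-consistent growth pull-back (equivalently
#' P = F S-bar with S-bar = J_g G^-1 S_e G^-T); a compatible homogeneous
#' grown state (A = I) is exactly stress-free. For 2x2 input the in-plane
#' plane-strain block is returned.
#'
#' @inheritParams strain_energy_density
#' @export
nominal_stress <- function(state, mu, lambda) {
  stopifnot(inherits(state, "kinematic_state"))
  if (state$Je <= 0) stop("elastic volume ratio J_e must be positive")
  d <- nrow(state$F)
  A3 <- embed3(state$A); G3 <- embed3(state$G)
  lnJ <- log(state$Je)
  Pe <- mu * A3 + (lambda * lnJ - mu) * t(solve(A3))
  P <- state$Jg * Pe %*% t(solve(G3))
  P[seq_len(d), seq_len(d), drop = FALSE]
}

#' @export
print.kinematic_state <- function(x, ...) {
  cat("kinematic state (", nrow(x$F), "x", nrow(x$F), "): I1 =",
      format(x$I1), ", Je =", format(x$Je), ", Jg =", format(x$Jg), "\n")
  invisible(x)
}
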