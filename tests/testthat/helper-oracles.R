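# Independent oracles used across the test files. These deliberately avoid
# the package's closed-form / assembled implementations: crest spacings are
# measured by brute-force point mapping, stresses by finite differences of
# the energy.

# Brute-force crest spacing: map the crests of A cos(kx) onto the base
# curve by the normal offset and measure |u_{n+1} - u_n| directly.
brute_crest_distances <- function(gfun, A, k, domain, deriv = NULL) {
  lam <- 2 * pi / k
  n0 <- ceiling(domain[1] / lam - 1e-9)
  n1 <- floor(domain[2] / lam + 1e-9)
  xn <- (n0:n1) * lam
  g <- gfun(xn)
  gp <- if (!is.null(deriv)) deriv(xn) else {
    eps <- 1e-7 * max(1, diff(domain))
    (gfun(xn + eps) - gfun(xn - eps)) / (2 * eps)
  }
  nrm <- sqrt(1 + gp^2)
  tx <- 1 / nrm
  ty <- gp / nrm
  ux <- xn - A * ty
  uz <- g + A * tx
  sqrt(diff(ux)^2 + diff(uz)^2)
}

# Finite-difference nominal stress: central differences of the total
# reference energy J_g * Psi(F G^-1) with respect to the components of F.
fd_nominal_stress <- function(F, G, mu, lambda, eps = 1e-6) {
  d <- nrow(F)
  W <- function(Fm) {
    st <- elastic_decomposition(Fm, G)
    st$Jg * strain_energy_density(st, mu, lambda)
  }
  P <- matrix(0, d, d)
  for (i in seq_len(d)) for (j in seq_len(d)) {
    Fp <- F; Fp[i, j] <- Fp[i, j] + eps
    Fm <- F; Fm[i, j] <- Fm[i, j] - eps
    P[i, j] <- (W(Fp) - W(Fm)) / (2 * eps)
  }
  P
}

# Uniformly random proper rotation (QR of a Gaussian matrix, det +1).
random_rotation <- function(d) {
  qr_ <- qr(matrix(rnorm(d * d), d))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Evaluate under a fixed seed without disturbing the session RNG.
with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Small cross-section test assembly: mesh, material and a film-growth
# schedule on a coarse domain, used by the solver unit tests.
tiny_problem <- function(R = 10, nu = 0.45) {
  geom <- bilayer_geometry(width = 0.1, depth = 0.05, film = 0.01)
  mesh <- build_cross_section_mesh(geom, wavelength = 0.05, resolution = 8,
                                   n_film_layers = 2,
                                   n_substrate_layers = 3)
  list(geom = geom, mesh = mesh, mat = material(R, nu),
       growth = growth_schedule(
         film = list(quadratic_growth_law(1), quadratic_growth_law(10)),
         substrate = list(constant_growth_law(), constant_growth_law())),
       nogrowth = growth_schedule(
         film = list(constant_growth_law(), constant_growth_law()),
         substrate = list(constant_growth_law(), constant_growth_law())))
}
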