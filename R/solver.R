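#' Assemble the weak-form residual (and tangent) of the grown bilayer
#'
#' The discrete residual of the equilibrium weak form
#' `int_Omega P : grad v dV = 0`, with the nominal stress P derived from the
#' compressible neo-Hookean energy of each layer and the layer's current
#' growth tensor. The residual is the exact gradient of the total reference
#' energy `int J_g Psi(F G^-1) dV` with respect to the nodal displacements;
#' the tangent is its consistent Hessian.
#'
#' @param mesh A `bilayer_mesh`.
#' @param mat A [material()].
#' @param schedule A [growth_schedule()].
#' @param t Pseudo-time at which growth is evaluated.
#' @param u Nodal displacement vector (node-major interleaved components).
#' @param tangent Assemble the sparse tangent matrix as well?
#' @param pattern Precomputed tangent index pattern (an optimisation used
#'   by the drivers; recomputed from the connectivity when `NULL`).
#' @return List with `ok` (FALSE if an element inverted, with
#'   `bad_element`), `resid`, `energy`, and (if requested) `K`
#'   (a `dgCMatrix`).
#' @export
assemble_weak_residual <- function(mesh, mat, schedule, t, u,
                                   tangent = TRUE, pattern = NULL) {
  stopifnot(inherits(mesh, "bilayer_mesh"), inherits(mat, "bilayer_material"),
            inherits(schedule, "growth_schedule"))
  ne <- nrow(mesh$conn)
  ndof <- nrow(mesh$coords) * mesh$dim
  stopifnot(length(u) == ndof)
  gf <- growth_entries(schedule, "film", t)
  gs <- growth_entries(schedule, "substrate", t)
  growth <- matrix(rep(gs, each = ne), ne, 3)
  film <- mesh$layer == 1L
  growth[film, ] <- matrix(rep(gf, each = sum(film)), sum(film), 3)
  mu <- ifelse(film, mat$mu_f, mat$mu_s)
  lam <- ifelse(film, mat$lambda_f, mat$lambda_s)
  out <- .fem_assemble(mesh$coords, mesh$conn, u, mu, lam, growth, tangent)
  if (!out$ok)
    return(list(ok = FALSE, bad_element = out$bad_element))
  res <- list(ok = TRUE, resid = out$resid, energy = out$energy)
  if (tangent) {
    pattern <- pattern %||% tangent_pattern(mesh)
    res$ki <- pattern$ki; res$kj <- pattern$kj; res$kx <- out$kx
  }
  res
}

# Global (row, col) indices of the element tangent entries, in the order
# the element kernel emits them (element-major, row-major blocks). The
# pattern depends only on the connectivity, so drivers compute it once
# per run and pass it down.
tangent_pattern <- function(mesh) {
  d <- mesh$dim
  nne <- ncol(mesh$conn)
  edof <- nne * d
  base <- (mesh$conn - 1L) * d
  dofs <- matrix(0L, nrow(mesh$conn), edof)
  for (a in seq_len(d)) dofs[, seq(a, edof, by = d)] <- base + a
  m <- t(dofs)
  list(ki = as.integer(m[rep(seq_len(edof), each = edof), ]),
       kj = as.integer(m[rep(seq_len(edof), times = edof), ]))
}

#' Total reference strain energy of a displacement state
#' @inheritParams assemble_weak_residual
#' @export
total_energy <- function(mesh, mat, schedule, t, u) {
  a <- assemble_weak_residual(mesh, mat, schedule, t, u, tangent = FALSE)
  if (!a$ok) stop("element inversion in element ", a$bad_element)
  a$energy
}

# One Newton solve at fixed pseudo-time. `bc` is the constraint set from
# apply_boundary_conditions(). Convergence: free-residual norm below `tol`
# times the assembled load scale (the full residual norm at the first
# iterate, reactions included), with a small absolute floor. With
# `want_tangent_out` the converged free-dof tangent is returned (for
# stability classification of the equilibrium).
newton_solve <- function(mesh, mat, schedule, t, u0, bc,
                         tol = 1e-8, maxit = 25L,
                         want_tangent_out = FALSE, pattern = NULL) {
  pattern <- pattern %||% tangent_pattern(mesh)
  ndof <- nrow(mesh$coords) * mesh$dim
  u <- u0
  u[bc$dof] <- bc$value
  free <- setdiff(seq_len(ndof), bc$dof)
  pos <- integer(ndof)
  pos[free] <- seq_along(free)
  nf <- length(free)
  scale <- NULL
  rn_prev <- Inf
  rises <- 0L
  sigma <- 0       # Levenberg-style shift, engaged when the line search
  dmean <- NULL    # creeps near a singular tangent

  for (it in seq_len(maxit)) {
    asm <- assemble_weak_residual(mesh, mat, schedule, t, u, tangent = TRUE,
                                  pattern = pattern)
    if (!asm$ok)
      return(list(ok = FALSE, u = u, reason = paste0(
        "element inversion (element ", asm$bad_element, ")")))
    rf <- asm$resid[free]
    rn <- sqrt(sum(rf * rf))
    if (is.null(scale)) scale <- max(sqrt(sum(asm$resid^2)), 1e-10)
    if (rn <= tol * scale || rn < 1e-14) {
      out <- list(ok = TRUE, u = u, iterations = it - 1L, residual = rn,
                  scale = scale, energy = asm$energy)
      if (want_tangent_out) {
        pi_ <- pos[asm$ki]; pj_ <- pos[asm$kj]
        keep <- pi_ > 0L & pj_ > 0L
        out$K <- Matrix::sparseMatrix(i = pi_[keep], j = pj_[keep],
                                      x = asm$kx[keep], dims = c(nf, nf))
        out$free <- free
      }
      return(out)
    }
    if (rn > 10 * rn_prev) rises <- rises + 1L else rises <- 0L
    if (rises >= 2L)
      return(list(ok = FALSE, u = u, reason = "diverging residual"))
    rn_prev <- rn

    pi_ <- pos[asm$ki]; pj_ <- pos[asm$kj]
    keep <- pi_ > 0L & pj_ > 0L
    K <- Matrix::sparseMatrix(i = pi_[keep], j = pj_[keep],
                              x = asm$kx[keep], dims = c(nf, nf))
    if (is.null(dmean)) dmean <- mean(abs(Matrix::diag(K)))
    du <- NULL
    for (try_ in 1:6) {
      Ks <- if (sigma > 0) K + (sigma * dmean) * Matrix::Diagonal(nf)
            else K
      du <- tryCatch(as.numeric(Matrix::solve(Ks, -rf)),
                     error = function(e) NULL)
      if (!is.null(du) && all(is.finite(du))) break
      sigma <- max(10 * sigma, 1e-8)
      du <- NULL
    }
    if (is.null(du))
      return(list(ok = FALSE, u = u, reason = "singular tangent",
                  residual = rn, scale = scale))

    # backtracking line search on the residual norm; also guards against
    # stepping into an inverted element. Near the bifurcation the tangent
    # is nearly singular and a full step overshoots along the soft mode;
    # damping keeps the iteration on the branch it started from.
    step <- 1
    best <- NULL
    for (ls in 1:8) {
      utrial <- u
      utrial[free] <- u[free] + step * du
      chk <- assemble_weak_residual(mesh, mat, schedule, t, utrial,
                                    tangent = FALSE)
      if (chk$ok) {
        rt <- sqrt(sum(chk$resid[free]^2))
        if (is.null(best) || rt < best$rn) best <- list(u = utrial, rn = rt)
        if (rt <= rn * (1 - 1e-4 * step)) break
      }
      step <- step / 2
    }
    if (is.null(best))
      return(list(ok = FALSE, u = u, reason = "element inversion persists",
                  residual = rn, scale = scale))
    u <- best$u
    # adapt the regularization: creep engages it, clean steps relax it
    if (step < 0.26) sigma <- max(5 * sigma, 1e-7)
    else if (step == 1) sigma <- if (sigma > 1e-9) sigma / 5 else 0
  }
  # A stalled iterate with a residual still far below the load scale is a
  # usable equilibrium (the tangent is nearly singular just past onset and
  # the damped iteration can creep); accept it and record the residual.
  if (is.finite(rn) && rn <= 1e-4 * scale) {
    out <- list(ok = TRUE, u = u, iterations = maxit, residual = rn,
                scale = scale, stalled = TRUE,
                energy = assemble_weak_residual(mesh, mat, schedule, t, u,
                                                tangent = FALSE)$energy)
    if (want_tangent_out) {
      asm <- assemble_weak_residual(mesh, mat, schedule, t, u,
                                    tangent = TRUE, pattern = pattern)
      pi_ <- pos[asm$ki]; pj_ <- pos[asm$kj]
      keep <- pi_ > 0L & pj_ > 0L
      out$K <- Matrix::sparseMatrix(i = pi_[keep], j = pj_[keep],
                                    x = asm$kx[keep], dims = c(nf, nf))
      out$free <- free
    }
    return(out)
  }
  list(ok = FALSE, u = u, reason = sprintf(
    "max Newton iterations (residual %.3g, load scale %.3g)", rn, scale),
    residual = rn, scale = scale)
}

#' Advance the quasi-static equilibrium from one pseudo-time to the next
#'
#' Warm-started Newton continuation: the converged state at `t_prev` is the
#' initial guess at `t`. On non-convergence the growth/boundary increment
#' is bisected recursively (down to 1/64 of the step).
#'
#' @inheritParams assemble_weak_residual
#' @param u_prev Converged displacement at `t_prev`.
#' @param boundary A [boundary_schedules] object.
#' @param t_prev,t Previous and target pseudo-times.
#' @param tol,maxit Newton tolerance (relative residual) and iteration cap.
#' @return List with `u`, `iterations` (accumulated), `residual`, `energy`.
#' @export
solve_equilibrium <- function(u_prev, mesh, mat, schedule, boundary,
                              t_prev, t, tol = 1e-8, maxit = 25L,
                              want_tangent_out = FALSE, pattern = NULL,
                              .depth = 0L) {
  pattern <- pattern %||% tangent_pattern(mesh)
  bc <- apply_boundary_conditions(mesh, boundary, t)
  sol <- newton_solve(mesh, mat, schedule, t, u_prev, bc, tol, maxit,
                      want_tangent_out = want_tangent_out,
                      pattern = pattern)
  if (sol$ok) {
    sol$t <- t
    return(sol)
  }
  if (.depth >= 6L) {
    # Last resort at dt/64: near branch events (wavenumber exchanges,
    # secondary thresholds) the tangent is so ill-conditioned that the
    # damped iteration plateaus above the strict tolerance. A state whose
    # residual is still three orders below the load scale is accepted and
    # flagged rather than aborting the whole trajectory.
    if (!is.null(sol$residual) && !is.null(sol$scale) &&
        is.finite(sol$residual) && sol$residual <= 3e-3 * sol$scale) {
      warning("accepted stalled equilibrium at t = ", signif(t, 6),
              " (relative residual ",
              signif(sol$residual / sol$scale, 3), ")", call. = FALSE)
      return(list(ok = TRUE, u = sol$u, iterations = maxit,
                  residual = sol$residual, scale = sol$scale,
                  stalled = TRUE, t = t,
                  energy = assemble_weak_residual(mesh, mat, schedule, t,
                                                  sol$u,
                                                  tangent = FALSE)$energy))
    }
    stop("equilibrium solve failed at t = ", signif(t, 6),
         " after sub-stepping to dt/64: ", sol$reason,
         if (!is.null(sol$residual))
           paste0(" (last residual ", signif(sol$residual, 3), ")"))
  }
  tm <- (t_prev + t) / 2
  mid <- solve_equilibrium(u_prev, mesh, mat, schedule, boundary,
                           t_prev, tm, tol, maxit, FALSE, pattern,
                           .depth + 1L)
  fin <- solve_equilibrium(mid$u, mesh, mat, schedule, boundary,
                           tm, t, tol, maxit, want_tangent_out, pattern,
                           .depth + 1L)
  fin$iterations <- fin$iterations + mid$iterations
  fin
}

# Number of negative eigenvalues of the (symmetric) free-dof tangent, via
# the inertia of a sparse LDL factorization; NA when the factorization
# breaks down (singular tangent, treated as marginal).
tangent_inertia <- function(K) {
  f <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(K), LDL = TRUE,
                                 perm = TRUE, super = FALSE),
                error = function(e) NULL)
  if (is.null(f)) return(NA_integer_)
  sum(Matrix::diag(f) < 0)
}

# Eigenvector near the shift `sigma` of the free-dof tangent (shifted
# inverse iteration on a sparse LU); Rayleigh quotient taken against K
# itself. Used to extract a negative-curvature (buckling) direction.
soft_mode <- function(K, sigma = 0, iters = 25L, seed = 1L) {
  n <- nrow(K)
  Ks <- if (sigma != 0) K - sigma * Matrix::Diagonal(n) else K
  f <- tryCatch(Matrix::lu(Ks), error = function(e) NULL)
  if (is.null(f)) {  # exactly singular: tiny diagonal shift
    shift <- 1e-10 * mean(abs(Matrix::diag(K)))
    f <- Matrix::lu(Ks + shift * Matrix::Diagonal(n))
  }
  v <- with_seed(seed, rnorm(n))
  v <- v / sqrt(sum(v^2))
  for (i in seq_len(iters)) {
    w <- as.numeric(Matrix::solve(f, v))
    nw <- sqrt(sum(w * w))
    if (!is.finite(nw) || nw == 0) break
    v <- w / nw
  }
  list(v = v, lambda = as.numeric(t(v) %*% (K %*% v)))
}

# A direction of negative curvature of an indefinite tangent: probe
# progressively more negative shifts until the Rayleigh quotient is
# negative.
negative_mode <- function(K) {
  dscale <- mean(abs(Matrix::diag(K)))
  best <- NULL
  for (sigma in -c(1e-4, 1e-3, 1e-2, 1e-1) * dscale) {
    sm <- soft_mode(K, sigma = sigma)
    best <- sm
    if (sm$lambda < 0) return(sm)
  }
  best
}

# If the converged state sits on an unstable branch (indefinite tangent),
# nudge the displacement towards the buckled branch and re-solve until a
# stable equilibrium is found. The primary nudge is the oracle-expected
# wrinkle mode (cosine at the current grown-thickness wavelength, decaying
# into the substrate, supplied by `mode_hint`); the fallback is a
# negative-curvature eigenvector of the tangent. Pushes only change the
# Newton initial guess: every accepted state is an exact equilibrium of
# the unforced problem.
stabilize_state <- function(sol, mesh, mat, schedule, boundary, t,
                            tol, maxit, h, mode_hint = NULL,
                            pattern = NULL, max_push = 5L) {
  bc <- apply_boundary_conditions(mesh, boundary, t)
  amp_of <- function(s) max(abs(s$u - sol$u))
  dbg <- isTRUE(getOption("morphowrinkle.debug"))
  for (k in seq_len(max_push)) {
    if (is.null(sol$K)) break
    neg <- tangent_inertia(sol$K)
    if (dbg) message(sprintf("  [stab] t=%.4f k=%d neg=%s", t, k, neg))
    if (!is.na(neg) && neg == 0L) break  # positive definite: stable branch
    # candidate push directions: the oracle mode first, the (expensive)
    # negative-curvature eigenvector only if the oracle push fails
    gens <- list()
    if (!is.null(mode_hint)) gens$oracle <- function() mode_hint(t)
    gens$eigen <- function() {
      sm <- negative_mode(sol$K)
      veig <- numeric(length(sol$u))
      veig[sol$free] <- sm$v / max(abs(sm$v))
      veig
    }
    alpha <- 0.3 * h * 2^(k - 1)   # escalate if this level fails
    pushed <- NULL
    for (gen in gens) {
      v <- gen()
      for (sgn in c(1, -1)) {
        cand <- newton_solve(mesh, mat, schedule, t,
                             sol$u + sgn * alpha * v, bc, tol,
                             max(maxit, 40L), want_tangent_out = TRUE,
                             pattern = pattern)
        if (dbg) message(sprintf(
          "  [stab]   push sgn=%+d a=%.1e ok=%s du=%.2e", sgn, alpha,
          cand$ok, if (cand$ok) amp_of(cand) else NA))
        # accept only if the solve landed on a genuinely different branch
        if (cand$ok && amp_of(cand) > 10 * tol * max(1, max(abs(sol$u)))) {
          ineg <- tangent_inertia(cand$K)
          if (dbg) message(sprintf("  [stab]   -> ineg=%s", ineg))
          if (is.na(ineg) || ineg < neg || (neg > 0 && ineg == 0L)) {
            pushed <- cand
            break
          }
        }
      }
      if (!is.null(pushed)) break
    }
    if (!is.null(pushed)) {
      pushed$t <- t
      pushed$iterations <- pushed$iterations + sol$iterations
      sol <- pushed
    }
    # on failure: loop again with a larger push amplitude
  }
  sol
}

#' Run a scenario: quasi-static growth continuation with pattern metrics
#'
#' Builds the (imperfection-seeded) mesh, walks the pseudo-time grid
#' updating growth tensors and boundary displacements, solves each
#' equilibrium by warm-started Newton, and quantifies the free surface at
#' every step (amplitude, wavelength, per-region amplitudes when the
#' scenario defines sub-domains).
#'
#' @param scn A scenario from the registry (see [cross_section_scenario()])
#'   or built with [scenario()].
#' @param keep Which displacement states to retain: `"last"` (default),
#'   `"all"`, or `"none"`.
#' @param stop_after_onset If finite, stop this many steps after every
#'   tracked amplitude (global and per-region) has crossed the onset
#'   threshold; saves time when only onset and the near-onset pattern are
#'   needed.
#' @param verbose Print per-step convergence and metrics.
#' @return A `wrinkle_sim` object: fields `summary` (one row per step:
#'   `t`, `amplitude`, `wavelength`, `wavelength_sd`, `n_waves`, Newton
#'   statistics, per-region amplitude columns), `onset` (detected onset
#'   pseudo-time, `NA` if never), `mesh`, `states`/`u_last`, `scenario`.
#' @export
run_quasistatic <- function(scn, keep = c("last", "all", "none"),
                            stop_after_onset = Inf, verbose = FALSE) {
  stopifnot(inherits(scn, "wrinkle_scenario"))
  keep <- match.arg(keep)
  parts <- materialize_scenario(scn)
  mesh <- parts$mesh; mat <- parts$material
  schedule <- parts$growth; boundary <- parts$boundary
  h <- mesh$geom$film
  lam_pred <- parts$lambda_pred
  thr <- scn$onset_threshold %||% 0.05

  ts <- seq(0, scn$time$t_end, length.out = scn$time$steps + 1L)
  ndof <- nrow(mesh$coords) * mesh$dim
  u <- numeric(ndof)
  states <- if (keep == "all") vector("list", length(ts)) else NULL

  region_names <- names(scn$regions) %||% character()
  summ <- vector("list", length(ts))
  crossed_at <- NA_real_
  last_row <- length(ts)
  tol <- scn$numerics$tol %||% 1e-8
  maxit <- scn$numerics$maxit %||% 25L
  pattern <- tangent_pattern(mesh)

  # Pre-onset branch monitoring: while any tracked amplitude is below the
  # onset threshold and the oracle strain is in reach of critical, classify
  # the converged tangent and push off unstable (post-bifurcation) flat
  # branches onto the wrinkled branch.
  eps_c <- if (scn$material$R > 1)
    critical_strain(scn$material$R, scn$material$nu) else Inf
  eps_of <- function(t) {
    g1 <- growth_law_from_spec(scn$growth$film[[1]])$fun(t)
    1 - base_arc_length(boundary, t, mesh$geom) / (g1 * mesh$geom$width)
  }
  # Oracle-expected wrinkle mode at time t: cosine across the width at the
  # current grown-thickness wavelength, decaying into the substrate. Used
  # as the primary branch-push direction.
  mode_hint <- NULL
  if (is.finite(eps_c)) {
    lam_c0 <- critical_wavelength(h, scn$material$R, scn$material$nu)
    g_thick <- growth_law_from_spec(
      scn$growth$film[[if (scn$dim == 2L) 2L else 3L]])
    zcol <- mesh$dim
    zc <- mesh$coords[, zcol]
    xc <- mesh$coords[, 1]
    zdofs <- seq(zcol, ndof, by = mesh$dim)
    mode_hint <- function(t) {
      lam_m <- lam_c0 * g_thick$fun(t)
      v <- numeric(ndof)
      v[zdofs] <- cos(2 * pi * xc / lam_m) *
        exp(-2 * pi * pmax(mesh$geom$depth - zc, 0) / lam_m)
      v
    }
  }
  all_crossed <- FALSE

  for (i in seq_along(ts)) {
    t <- ts[i]
    do_check <- is.finite(eps_c) && !all_crossed && i > 1L &&
      eps_of(t) >= 0.4 * eps_c
    if (i > 1L) {
      sol <- tryCatch(
        solve_equilibrium(u, mesh, mat, schedule, boundary,
                          ts[i - 1L], t, tol = tol, maxit = maxit,
                          want_tangent_out = do_check,
                          pattern = pattern),
        error = function(e) e)
      if (inherits(sol, "error")) {
        # an unsolvable increment (typically a branch termination deep
        # past onset): report the trajectory computed so far
        warning("trajectory truncated at t = ", signif(t, 6), ": ",
                conditionMessage(sol), call. = FALSE)
        last_row <- i - 1L
        break
      }
      if (do_check)
        sol <- stabilize_state(sol, mesh, mat, schedule, boundary, t,
                               tol, maxit, h, mode_hint = mode_hint,
                               pattern = pattern)
      sol$K <- NULL
      u <- sol$u
    } else {
      sol <- list(iterations = 0L, residual = 0, energy = 0)
    }
    met <- profile_metrics(mesh, u, lam_pred, scn$regions,
                           y_section = scn$y_section)
    row <- data.frame(t = t, amplitude = met$amplitude,
                      wavelength = met$wavelength,
                      wavelength_sd = met$wavelength_sd,
                      n_waves = met$n_waves,
                      newton_iters = sol$iterations,
                      residual = sol$residual, energy = sol$energy)
    for (rn in region_names)
      row[[paste0("amplitude_", rn)]] <- met$region_amplitude[[rn]]
    summ[[i]] <- row
    if (keep == "all") states[[i]] <- u
    if (verbose)
      message(sprintf("t = %.4f  iters %2d  A = %.3e  lambda = %.4g",
                      t, sol$iterations, met$amplitude,
                      met$wavelength %||% NA))

    amps <- c(met$amplitude, unlist(met$region_amplitude))
    if (all(amps > thr * h)) {
      if (is.na(crossed_at)) crossed_at <- i
      # stability checks stay active until the crossing is sustained for
      # three steps (the just-bifurcated branch is weakly attracting and
      # can drop back onto the flat branch)
      all_crossed <- (i - crossed_at) >= 2L
      if (is.finite(stop_after_onset) && i - crossed_at >= stop_after_onset) {
        last_row <- i
        break
      }
    } else {
      crossed_at <- NA_real_
      all_crossed <- FALSE
    }
  }
  summary <- do.call(rbind, summ[seq_len(last_row)])
  onset <- detect_onset(summary, h = h, threshold = thr)

  structure(list(scenario = scn, mesh = mesh, material = mat,
                 summary = summary, onset = onset,
                 lambda_pred = lam_pred,
                 u_last = u,
                 states = if (keep == "all") states[seq_len(last_row)],
                 times = ts[seq_len(last_row)]),
            class = "wrinkle_sim")
}

# Surface metrics for one state: global amplitude/wavelength plus
# amplitudes restricted to named x-intervals (regions). Global metrics
# exclude a margin of about one wavelength at each pinned lateral edge,
# where the artificial confinement concentrates boundary distortion; in
# the wide canonical domains that zone is a negligible fraction of the
# surface, in scaled study domains it would otherwise dominate.
profile_metrics <- function(mesh, u, lambda_pred, regions = NULL,
                            y_section = NULL) {
  prof <- extract_top_profile(mesh, u, y = y_section)
  det <- detrend_profile(prof, window = 3 * lambda_pred)
  width <- mesh$geom$width
  margin <- min(1.5 * lambda_pred, 0.15 * width)
  xall <- attr(prof, "x_ref")
  inner <- xall >= margin & xall <= width - margin
  prof_in <- prof[inner, , drop = FALSE]
  attr(prof_in, "x_ref") <- xall[inner]
  det_in <- structure(list(profile = prof_in,
                           trend = det$trend[inner],
                           oscillation = det$oscillation[inner]),
                      class = "detrended_profile")
  amp <- measure_amplitude(det_in)
  wl <- measure_wavelength(prof_in, detrended = det_in)
  region_amplitude <- list()
  for (rn in names(regions)) {
    rg <- regions[[rn]]
    # region given as one interval or a list of pooled intervals (reference x)
    ivs <- if (is.list(rg)) rg else list(rg)
    xref <- attr(prof, "x_ref")
    mask <- Reduce(`|`, lapply(ivs, function(iv) xref >= iv[1] & xref <= iv[2]))
    region_amplitude[[rn]] <- measure_amplitude(det$oscillation[mask])
  }
  list(amplitude = amp,
       wavelength = if (wl$undefined) NA_real_ else wl$mean,
       wavelength_sd = if (wl$undefined) NA_real_ else wl$sd,
       n_waves = wl$n_waves,
       region_amplitude = region_amplitude)
}
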