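#' Analytic wrinkling-onset predictions for a stiff film on a compliant
#' substrate
#'
#' Classical scaling rules for the primary wrinkling instability of a thin
#' stiff film bonded to a deep compliant substrate, used as the independent
#' oracle against which the finite-element results are checked:
#'
#' * critical wavelength `lambda_c = 2 pi h (E-bar_f / (3 E-bar_s))^(1/3)`,
#'   i.e. `gamma_1 h R^(1/3)` with `gamma_1 = 2 pi / 3^(1/3)` when the
#'   layers share a Poisson ratio (the plane-strain moduli
#'   `E-bar = E/(1 - nu^2)` then cancel to R);
#' * critical compressive strain `eps_c = (1/4) (3 E-bar_s / E-bar_f)^(2/3)`,
#'   i.e. `gamma_2 R^(-2/3)` with `gamma_2 = 3^(2/3)/4`.
#'
#' The exponents 1/3 and -2/3 are exact for this class of bilayers; the
#' prefactors are the stiff-film-on-half-space values and shift somewhat
#' for finite substrate depth, so comparisons against simulations should
#' lean on the exponents. Both require R > 1: with no stiffness mismatch
#' there is no wrinkling branch.
#'
#' @param h Film thickness (> 0).
#' @param R Film/substrate stiffness ratio (> 1).
#' @param nu Shared Poisson ratio (retained in the interface for clarity;
#'   it cancels when the layers share it).
#' @return `critical_wavelength()`: the wavelength selected at onset;
#'   `critical_strain()`: the in-plane compressive strain at onset.
#' @name stability_oracle
NULL

#' @rdname stability_oracle
#' @export
critical_wavelength <- function(h, R, nu = 0.45) {
  stopifnot(all(h > 0))
  if (any(R <= 1)) stop("no wrinkling branch for R <= 1")
  2 * pi * h * (R / 3)^(1 / 3)
}

#' @rdname stability_oracle
#' @export
critical_strain <- function(R, nu = 0.45) {
  if (any(R <= 1)) stop("no wrinkling branch for R <= 1")
  0.25 * (3 / R)^(2 / 3)
}

#' Effective in-plane film strain induced by growth against confinement
#'
#' The film grows in-plane by the factor `g_f1(t)` while the available
#' in-plane extent is the (possibly bulged, hence elongated) base length
#' L(t); the mismatch is the effective compressive strain
#' `eps(t) = 1 - L(t) / (g_f1(t) * w_o)`. On a flat, fixed-width base this
#' reduces to `1 - 1/g_f1(t)`. Base bulging lengthens L(t) and so delays
#' the time at which `eps` reaches the critical strain.
#'
#' @param scn A scenario (see [cross_section_scenario()]).
#' @param t Pseudo-time(s).
#' @return Effective strain values, one per `t`.
#' @export
growth_to_strain <- function(scn, t) {
  stopifnot(inherits(scn, "wrinkle_scenario"))
  parts <- materialize_scenario(scn, mesh = FALSE)
  g1 <- parts$growth$film[[1]]$fun
  geom <- parts$geometry
  vapply(t, function(ti) {
    L <- base_arc_length(parts$boundary, ti, geom)
    1 - L / (g1(ti) * geom$width)
  }, numeric(1))
}

#' Onset time predicted by the analytic oracle
#'
#' Solves `eps(t) = eps_c` for the scenario's growth and boundary
#' schedules; `NA` when the critical strain is never reached in the run
#' interval.
#'
#' @inheritParams growth_to_strain
#' @export
predict_onset_time <- function(scn) {
  eps_c <- critical_strain(scn$material$R, scn$material$nu)
  f <- function(t) growth_to_strain(scn, t) - eps_c
  t_end <- scn$time$t_end
  if (f(t_end) < 0) return(NA_real_)
  uniroot(f, c(0, t_end), tol = 1e-10)$root
}

#' Least-squares scaling exponent in log-log space
#'
#' Fits `log y = a + p log x` and returns the exponent p, for verifying
#' power-law behaviour (e.g. wavelength ~ R^(1/3), strain ~ R^(-2/3)).
#'
#' @param x,y Positive vectors (>= 3 points).
#' @return A `scaling_fit`: list with `exponent`, `se`, `intercept`,
#'   `r_squared`, `residuals`.
#' @examples
#' fit_scaling_exponent(1:5, 7 * (1:5)^(1 / 3))$exponent  # 1/3
#' @export
fit_scaling_exponent <- function(x, y) {
  if (length(x) < 3L || length(y) != length(x))
    stop("need at least 3 (x, y) pairs")
  if (any(x <= 0) || any(y <= 0))
    stop("power-law fit needs strictly positive values")
  fit <- lm(log(y) ~ log(x))
  sm <- suppressWarnings(summary(fit))  # exact power laws fit perfectly
  structure(list(exponent = unname(coef(fit)[2]),
                 se = sm$coefficients[2, 2],
                 intercept = unname(coef(fit)[1]),
                 r_squared = sm$r.squared,
                 residuals = unname(fit$residuals)),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat("log-log scaling fit: exponent =", format(x$exponent),
      "+/-", format(x$se), " (R^2 =", format(x$r_squared), ")\n")
  invisible(x)
}
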