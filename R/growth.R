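#' Growth laws for the diagonal growth-tensor entries
#'
#' Each entry g(t) of a layer's growth tensor follows a named scalar law of
#' the pseudo-time parameter t, with g(0) = 1 (the reference configuration
#' is stress-free) and an optional freeze time after which the entry holds
#' its value exactly:
#'
#' * `quadratic_growth_law(C)`: g(t) = 1 + prefactor * C * min(t, freeze)^2,
#'   the accelerating in-plane film expansion law of the cross-section
#'   scenarios (prefactor 1/2 by default).
#' * `linear_growth_law(b)`: g(t) = 1 + b * min(t, freeze), used by the
#'   volumetric scenarios.
#' * `constant_growth_law()`: g(t) = 1 (no growth).
#'
#' A freeze models abrupt arrest of deposition (e.g. film thickening that
#' stops mid-run); it is exact, with no drift past the freeze time.
#'
#' @param C,b Non-negative rate constants.
#' @param prefactor Multiplier of `C t^2` (default 1/2).
#' @param freeze_at Pseudo-time after which the entry stays frozen
#'   (default `Inf`, never).
#' @return A `growth_law` object, callable as a function of t.
#' @examples
#' g <- quadratic_growth_law(10, freeze_at = 0.5)
#' g(0.7)  # frozen at its t = 0.5 value, 2.25
#' @name growth_laws
NULL

new_growth_law <- function(law, pars, fun) {
  structure(list(law = law, pars = pars, fun = fun), class = "growth_law")
}

#' @rdname growth_laws
#' @export
quadratic_growth_law <- function(C, prefactor = 0.5, freeze_at = Inf) {
  stopifnot(C >= 0, prefactor >= 0)
  new_growth_law("quadratic",
                 list(C = C, prefactor = prefactor, freeze_at = freeze_at),
                 function(t) 1 + prefactor * C * pmin(t, freeze_at)^2)
}

#' @rdname growth_laws
#' @export
linear_growth_law <- function(b, freeze_at = Inf) {
  stopifnot(b >= 0)
  new_growth_law("linear", list(b = b, freeze_at = freeze_at),
                 function(t) 1 + b * pmin(t, freeze_at))
}

#' @rdname growth_laws
#' @export
constant_growth_law <- function() {
  new_growth_law("constant", list(), function(t) rep(1, length(t)))
}

# rebuild a law from its declarative form (list(law = ..., pars))
growth_law_from_spec <- function(spec) {
  if (inherits(spec, "growth_law")) return(spec)
  switch(spec$law,
         quadratic = quadratic_growth_law(spec$pars$C,
                                          spec$pars$prefactor %||% 0.5,
                                          spec$pars$freeze_at %||% Inf),
         linear    = linear_growth_law(spec$pars$b,
                                       spec$pars$freeze_at %||% Inf),
         constant  = constant_growth_law(),
         stop("unknown growth law: ", spec$law))
}

#' @export
print.growth_law <- function(x, ...) {
  ps <- if (length(x$pars))
    paste(names(x$pars), vapply(x$pars, format, ""), sep = " = ",
          collapse = ", ") else ""
  cat("growth law <", x$law, ">", if (nzchar(ps)) paste0(" (", ps, ")"),
      "\n", sep = "")
  invisible(x)
}

#' Layerwise growth schedule
#'
#' Collects the per-layer growth laws: one law per diagonal entry of the
#' growth tensor, two entries per layer for cross-section runs (in-plane,
#' thickness) and three for volumetric runs (width, length, thickness).
#'
#' @param film,substrate Lists of [growth_laws] objects, one per diagonal
#'   entry (length 2 or 3, equal between layers).
#' @param t_max Upper end of the run interval used for validation
#'   (default `Inf`).
#' @return A `growth_schedule`.
#' @export
growth_schedule <- function(film, substrate, t_max = Inf) {
  stopifnot(length(film) %in% c(2L, 3L), length(film) == length(substrate))
  film <- lapply(film, growth_law_from_spec)
  substrate <- lapply(substrate, growth_law_from_spec)
  structure(list(film = film, substrate = substrate,
                 dim = length(film), t_max = t_max),
            class = "growth_schedule")
}

#' Evaluate a layer's growth tensor
#'
#' @param schedule A [growth_schedule()].
#' @param layer `"film"` or `"substrate"`.
#' @param t Pseudo-time within the run interval.
#' @return The diagonal growth tensor G_k(t) as a matrix.
#' @examples
#' sch <- growth_schedule(
#'   film = list(quadratic_growth_law(1), quadratic_growth_law(10)),
#'   substrate = list(constant_growth_law(), constant_growth_law()))
#' evaluate_growth(sch, "film", 1)  # diag(1.5, 6)
#' @export
evaluate_growth <- function(schedule, layer = c("film", "substrate"), t) {
  stopifnot(inherits(schedule, "growth_schedule"), length(t) == 1L)
  layer <- match.arg(layer)
  if (t < 0 || t > schedule$t_max)
    stop("t = ", t, " is outside the run interval [0, ",
         schedule$t_max, "]")
  g <- vapply(schedule[[layer]], function(l) l$fun(t), numeric(1))
  if (any(g <= 0)) stop("growth entries must stay positive")
  diag(g, nrow = length(g))
}

# entries as a plain vector, padded with g3 = 1 for cross-section runs
growth_entries <- function(schedule, layer, t) {
  g <- diag(evaluate_growth(schedule, layer, t))
  if (length(g) == 2L) c(g, 1) else g
}
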