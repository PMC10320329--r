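#' @export
print.wrinkle_scenario <- function(x, ...) {
  cat("wrinkle scenario <", x$name, "> (", x$dim, "D)\n", sep = "")
  g <- x$geometry
  cat("  geometry: width ", format(g$width),
      if (!is.null(g$length)) paste0(" x length ", format(g$length)),
      " x depth ", format(g$depth), ", film h = ", format(g$film),
      " (h/H_o = ", format(g$film / g$depth), ")\n", sep = "")
  cat("  material: R =", format(x$material$R), ", nu =",
      format(x$material$nu), "\n")
  fmt_law <- function(l) {
    ps <- l$pars
    paste0(l$law, if (length(ps))
      paste0("(", paste(names(ps), vapply(ps, format, ""), sep = "=",
                        collapse = ", "), ")"))
  }
  cat("  growth film:     ",
      paste(vapply(x$growth$film, fmt_law, ""), collapse = " | "), "\n")
  cat("  growth substrate:",
      paste(vapply(x$growth$substrate, fmt_law, ""), collapse = " | "),
      "\n")
  cat("  boundary:", x$boundary$type, "\n")
  cat("  time: t in [0, ", format(x$time$t_end), "], ",
      x$time$steps, " steps\n", sep = "")
  cat("  imperfection: ", format(x$imperfection$magnitude),
      " x h, seed ", x$imperfection$seed, "\n", sep = "")
  if (nzchar(x$note %||% "")) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Describe a scenario's full parameter set
#'
#' Prints every numeric parameter of a scenario, including the derived
#' film thickness, predicted wavelength and strain threshold from the
#' stability oracle.
#' @param scn A `wrinkle_scenario`.
#' @export
describe_scenario <- function(scn) {
  print(scn)
  if (scn$material$R > 1) {
    lam <- critical_wavelength(scn$geometry$film, scn$material$R,
                               scn$material$nu)
    cat("  oracle: lambda_c =", format(lam), ", eps_c =",
        format(critical_strain(scn$material$R, scn$material$nu)), "\n")
  } else {
    cat("  oracle: R <= 1, no wrinkling branch\n")
  }
  invisible(scn)
}

#' @export
print.wrinkle_sim <- function(x, ...) {
  n <- nrow(x$summary)
  cat("wrinkle simulation <", x$scenario$name, ">: ", n, " states, t in [0, ",
      format(max(x$summary$t)), "]\n", sep = "")
  cat("  onset t* =", if (is.na(x$onset)) "not reached"
      else format(x$onset), "\n")
  fin <- x$summary[n, ]
  cat("  final: amplitude ", format(fin$amplitude, digits = 4),
      ", mean wavelength ", format(fin$wavelength, digits = 4),
      " (predicted ", format(x$lambda_pred, digits = 4), ")\n", sep = "")
  invisible(x)
}

#' @export
summary.wrinkle_sim <- function(object, ...) {
  s <- object$summary
  out <- list(name = object$scenario$name,
              onset = object$onset,
              lambda_pred = object$lambda_pred,
              final = s[nrow(s), ],
              amplitude_range = range(s$amplitude),
              newton_total = sum(s$newton_iters),
              max_residual = max(s$residual))
  class(out) <- "summary.wrinkle_sim"
  out
}

#' @export
print.summary.wrinkle_sim <- function(x, ...) {
  cat("run <", x$name, ">\n", sep = "")
  cat("  onset t* :", if (is.na(x$onset)) "not reached"
      else format(x$onset), "\n")
  cat("  final amplitude :", format(x$final$amplitude, digits = 4), "\n")
  cat("  final wavelength:", format(x$final$wavelength, digits = 4),
      "  predicted:", format(x$lambda_pred, digits = 4), "\n")
  cat("  Newton iterations (total):", x$newton_total,
      ", worst residual:", format(x$max_residual, digits = 3), "\n")
  invisible(x)
}

#' Plot a simulated wrinkle run
#'
#' `type = "profile"` draws the deformed free surface at the final kept
#' state; `type = "amplitude"` and `type = "wavelength"` draw their
#' trajectories against pseudo-time with the onset marked.
#'
#' @param x A `wrinkle_sim`.
#' @param type What to draw.
#' @param ... Passed to the underlying base-graphics call.
#' @export
plot.wrinkle_sim <- function(x, type = c("profile", "amplitude",
                                         "wavelength"), ...) {
  type <- match.arg(type)
  s <- x$summary
  if (type == "profile") {
    u <- x$u_last
    prof <- extract_top_profile(x$mesh, u, y = x$scenario$y_section)
    plot(prof$x, prof$height, type = "l", xlab = "in-plane position",
         ylab = "surface height", main = x$scenario$name, ...)
  } else if (type == "amplitude") {
    plot(s$t, s$amplitude, type = "l", xlab = "pseudo-time t",
         ylab = "wrinkle amplitude", main = x$scenario$name, ...)
    if (!is.na(x$onset)) abline(v = x$onset, lty = 2)
  } else {
    plot(s$t, s$wavelength, type = "l", xlab = "pseudo-time t",
         ylab = "mean wavelength", main = x$scenario$name, ...)
    abline(h = x$lambda_pred, lty = 3)
    if (!is.na(x$onset)) abline(v = x$onset, lty = 2)
  }
  invisible(x)
}
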