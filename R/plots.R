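#' Plot a psychometric fit
#'
#' Per-level accuracy with binomial standard errors and the fitted Weibull
#' curve, on a logarithmic evidence axis.
#'
#' @param fit a [psychometric_fit()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot_psychometric <- function(fit, ...) {
  tab <- fit$table
  eps <- tab$epsilon
  eps_plot <- ifelse(eps == 0, min(eps[eps > 0]) / 2, eps)
  graphics::plot(eps_plot, tab$accuracy, log = "x", ylim = c(0.4, 1),
                 xlab = "evidence quality (%)", ylab = "accuracy",
                 pch = 19, ...)
  graphics::arrows(eps_plot, tab$accuracy - tab$sem,
                   eps_plot, tab$accuracy + tab$sem,
                   length = 0.02, angle = 90, code = 3)
  xs <- exp(seq(log(min(eps_plot)), log(max(eps)), length.out = 200))
  graphics::lines(xs, 1 - 0.5 * exp(-(xs / fit$alpha)^fit$beta))
  invisible(fit)
}

#' Plot a chronometric summary
#'
#' Mean response time against evidence quality, correct and error trials
#' as separate lines.
#'
#' @param tab result of [chronometric_summary()].
#' @param ... passed to [graphics::plot()].
#' @export
plot_chronometric <- function(tab, ...) {
  cx <- tab[tab$outcome == "correct", ]
  ex <- tab[tab$outcome == "error", ]
  rng <- range(c(cx$mean_rt, ex$mean_rt), na.rm = TRUE)
  graphics::plot(cx$epsilon, cx$mean_rt, type = "b", pch = 19,
                 ylim = rng, xlab = "evidence quality (%)",
                 ylab = "response time (ms)", ...)
  graphics::lines(ex$epsilon, ex$mean_rt, type = "b", pch = 1,
                  col = "grey40")
  graphics::legend("topright", c("correct", "error"), pch = c(19, 1),
                   col = c("black", "grey40"), bty = "n")
  invisible(tab)
}

#' Plot the change-of-mind probability curve
#'
#' @param curve a [com_probability_curve()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot_com_curve <- function(curve, ...) {
  graphics::plot(curve$epsilon, curve$p_any, type = "b", pch = 19,
                 col = "grey50", xlab = "evidence quality (%)",
                 ylab = "P(change-of-mind)",
                 ylim = c(0, max(curve$p_any, 1e-3) * 1.1), ...)
  graphics::lines(curve$epsilon, curve$p_to_correct, type = "b",
                  pch = 19)
  graphics::lines(curve$epsilon, curve$p_to_error, type = "b", pch = 1,
                  lty = 2)
  graphics::legend("topright", c("any", "to correct", "to error"),
                   pch = c(19, 19, 1), lty = c(1, 1, 2),
                   col = c("grey50", "black", "black"), bty = "n")
  invisible(curve)
}

#' Phase-plane plot of the reduced sensorimotor subsystem
#'
#' Nullclines, fixed points (filled: stable; open: saddle/unstable) and an
#' optional trajectory overlay in the (S1, S2) unit square.
#'
#' @inheritParams find_fixed_points
#' @param trajectory optional matrix from [reduced_trajectory()].
#' @export
plot_phase_plane <- function(epsilon = 0, I_fb = 0, params,
                             trajectory = NULL) {
  nc <- nullclines(epsilon, I_fb, params, resolution = 151)
  fps <- find_fixed_points(epsilon, I_fb, params)
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "S1",
                 ylab = "S2", asp = 1)
  graphics::points(nc$S1_nullcline$S1, nc$S1_nullcline$S2, pch = ".",
                   col = "orange")
  graphics::points(nc$S2_nullcline$S1, nc$S2_nullcline$S2, pch = ".",
                   col = "steelblue")
  if (!is.null(trajectory))
    graphics::lines(trajectory[, "S1"], trajectory[, "S2"], lty = 3)
  if (nrow(fps)) {
    stable <- startsWith(fps$stability, "stable")
    graphics::points(fps$S1[stable], fps$S2[stable], pch = 19, cex = 1.2)
    graphics::points(fps$S1[!stable], fps$S2[!stable], pch = 21,
                     bg = "grey", cex = 1.2)
  }
  invisible(fps)
}

#' Plot a bifurcation diagram
#'
#' Steady-state `S1` (or its firing rate `H1`) against the constant
#' feedback current, stable branches as filled points, saddles as open.
#'
#' @param diagram a [bifurcation_scan()] result.
#' @param ordinate `"S1"` or `"H1"`.
#' @export
plot_bifurcation <- function(diagram, ordinate = c("S1", "H1")) {
  ordinate <- match.arg(ordinate)
  b <- diagram$branches
  stable <- startsWith(b$stability, "stable")
  graphics::plot(b$I_fb[stable], b[[ordinate]][stable], pch = 19,
                 cex = 0.4, xlab = "feedback current (nA)",
                 ylab = ordinate,
                 ylim = range(b[[ordinate]]))
  graphics::points(b$I_fb[!stable], b[[ordinate]][!stable], pch = 21,
                   cex = 0.4, bg = "white")
  if (length(diagram$critical_currents))
    graphics::abline(v = diagram$critical_currents, lty = 3)
  invisible(diagram)
}
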