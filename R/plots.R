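#' Phase portrait with nullclines
#'
#' Draws the cubic and quadratic nullclines of the autonomous model,
#' marks the equilibria by stability class, and optionally overlays
#' trajectories.
#'
#' @param params a [cq_params()] object (autonomous variant).
#' @param W_range range of membrane potential to display.
#' @param trajectories optional list of `cq_trajectory` objects.
#' @param ... further arguments passed to [graphics::plot()].
#' @return Invisibly, the equilibrium table.
#' @export
cq_phase_portrait <- function(params, W_range = c(-8, 8),
                              trajectories = NULL, ...) {
  W <- seq(W_range[1], W_range[2], length.out = 400)
  nc <- cq_nullclines(params, W)
  ylim <- range(c(nc$Z_W_nullcline, nc$Z_Z_nullcline))
  graphics::plot(nc$W, nc$Z_W_nullcline, type = "l", col = "steelblue",
                 xlab = "W (membrane potential)",
                 ylab = "Z (recovery variable)",
                 ylim = ylim, ...)
  graphics::lines(nc$W, nc$Z_Z_nullcline, col = "firebrick")
  if (!is.null(trajectories)) {
    for (tr in trajectories) graphics::lines(tr$W, tr$Z, col = "grey40")
  }
  eqs <- as.data.frame(cq_find_equilibria(params))
  stable <- grepl("^stable", eqs$stability)
  graphics::points(eqs$W, eqs$Z, pch = ifelse(stable, 19, 21), bg = "white",
                   cex = 1.3)
  graphics::legend("topright", bty = "n", lty = c(1, 1, NA, NA),
                   pch = c(NA, NA, 19, 21),
                   col = c("steelblue", "firebrick", "black", "black"),
                   legend = c("W-nullcline", "Z-nullcline",
                              "stable equilibrium", "unstable equilibrium"))
  invisible(eqs)
}

#' Plot method for stroboscopic sweep diagrams
#'
#' Top panel: stroboscopic samples of `W` against the swept parameter
#' (the bifurcation diagram); bottom panel: the largest Lyapunov
#' exponent, with the zero line marked.
#'
#' @param x a `cq_sweep_diagram`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.cq_sweep_diagram <- function(x, ...) {
  d <- as.data.frame(x)
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(d$param, d$W_sample, pch = ".", cex = 0.8,
                 xlab = x$parameter, ylab = "stroboscopic W", ...)
  graphics::plot(x$grid, x$lle, type = "l", xlab = x$parameter,
                 ylab = "largest Lyapunov exponent")
  graphics::abline(h = 0, lty = 2, col = "grey50")
  invisible(x)
}

#' Plot method for trajectories
#'
#' @param x a `cq_trajectory`.
#' @param what `"time"` for W(t) or `"phase"` for the (W, Z) orbit.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.cq_trajectory <- function(x, what = c("time", "phase"), ...) {
  what <- match.arg(what)
  if (what == "time") {
    graphics::plot(x$t, x$W, type = "l", xlab = "t", ylab = "W", ...)
  } else {
    graphics::plot(x$W, x$Z, type = "l", xlab = "W", ylab = "Z", ...)
  }
  invisible(x)
}
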