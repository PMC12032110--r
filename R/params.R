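#' Parameter set for the cubic-quadratic neuron model
#'
#' Builds and validates the parameter set of the planar cubic-quadratic
#' (C-Q) spiking-neuron model.  The autonomous system is
#' \deqn{dW/dt = -W^3 + 30W - Z + E, \qquad \tau\, dZ/dt = 5(W+v)^2 - Z,}
#' where \eqn{W} is the membrane potential, \eqn{Z} the recovery variable,
#' \eqn{E} the external input current, \eqn{v} shifts the recovery
#' nullcline horizontally and \eqn{\tau > 0} sets the recovery time scale.
#' All quantities are dimensionless.
#'
#' The periodically forced variant uses a rescaled recovery variable and a
#' sinusoidal input \eqn{E(t) = F\sin(\omega t) + 70}:
#' \deqn{dW/dt = -W^3 + 30W - 10Z + F\sin(\omega t), \qquad
#'       dZ/dt = 5(W+3)^2 - 10Z - 70,}
#' which is the \eqn{v = 3} model with the resting input level 70 folded
#' into the constant term (\code{drive = "rescaled"}, the default; at
#' \eqn{F = 0} it sits on the tonic-spiking limit cycle).  With
#' \code{drive = "printed"} the baseline is added a second time in the
#' \eqn{W} equation, giving a system whose \eqn{F = 0} state is a strongly
#' stable focus near \eqn{W \approx 3.37}; see the package vignette for why
#' both forms are provided.
#'
#' @param E external input current (autonomous variant only).
#' @param v recovery-offset parameter (autonomous variant only).
#' @param tau recovery time constant, must be positive (autonomous only;
#'   the forced variant has no free time constant).
#' @param variant `"autonomous"` or `"forced"`.
#' @param F forcing amplitude, required (and `>= 0`) for the forced variant.
#' @param omega forcing angular frequency, required (and `> 0`) for the
#'   forced variant.
#' @param drive `"rescaled"` (default) or `"printed"`; how the baseline
#'   input level enters the forced equations (see Details).
#' @return An object of class `cq_params`.
#' @examples
#' cq_params(E = 70, v = 3)
#' cq_params(variant = "forced", F = 10, omega = 5.75)
#' @export
cq_params <- function(E = 70, v = 3, tau = 1,
                      variant = c("autonomous", "forced"),
                      F = NULL, omega = NULL,
                      drive = c("rescaled", "printed")) {
  variant <- match.arg(variant)
  drive <- match.arg(drive)
  if (variant == "autonomous") {
    if (!is.numeric(E) || length(E) != 1L || !is.finite(E))
      stop("`E` must be a single finite number")
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("`v` must be a single finite number")
    if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
      stop("`tau` must be a single positive number")
    if (!is.null(F) && !identical(F, 0)) {
      stop("the autonomous variant takes no forcing amplitude `F`")
    }
    if (!is.null(omega)) {
      stop("the autonomous variant takes no forcing frequency `omega`")
    }
    p <- list(variant = "autonomous", E = E, v = v, tau = tau)
  } else {
    if (is.null(F) || is.null(omega))
      stop("the forced variant requires both `F` and `omega`")
    if (!is.numeric(F) || length(F) != 1L || !is.finite(F) || F < 0)
      stop("`F` must be a single finite number >= 0")
    if (!is.numeric(omega) || length(omega) != 1L || !is.finite(omega) ||
        omega <= 0)
      stop("`omega` must be a single finite number > 0")
    if (!missing(tau) && !identical(tau, 1))
      stop("the forced variant has no recovery time constant `tau`")
    p <- list(variant = "forced", F = F, omega = omega, drive = drive,
              e0 = if (drive == "printed") 70 else 0)
  }
  class(p) <- "cq_params"
  p
}

#' @export
print.cq_params <- function(x, ...) {
  if (x$variant == "autonomous") {
    cat(sprintf("C-Q model parameters (autonomous): E = %g, v = %g, tau = %g\n",
                x$E, x$v, x$tau))
  } else {
    cat(sprintf(
      "C-Q model parameters (forced, %s drive): F = %g, omega = %g\n",
      x$drive, x$F, x$omega))
  }
  invisible(x)
}

is_cq_params <- function(x) inherits(x, "cq_params")

assert_autonomous <- function(params, what) {
  if (!is_cq_params(params)) stop("`params` must be built by cq_params()")
  if (params$variant != "autonomous")
    stop(sprintf("%s is defined for the autonomous variant only", what))
  invisible(params)
}

# parameter list handed to the compiled integrator
params_for_cpp <- function(params) {
  if (params$variant == "autonomous") {
    list(variant = 0L, E = params$E, v = params$v, tau = params$tau)
  } else {
    list(variant = 1L, F = params$F, omega = params$omega, e0 = params$e0)
  }
}
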