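#' Vector field of the C-Q model
#'
#' Evaluates the two time-derivatives of the cubic-quadratic model at a
#' given state.  Pure and deterministic; see [cq_params()] for the two
#' system variants.
#'
#' @param state numeric vector `c(W, Z)` (optionally named).
#' @param params a [cq_params()] object.
#' @param t time, needed by the forced variant (default 0).
#' @return Named numeric vector `c(dW, dZ)`.
#' @examples
#' cq_vector_field(c(W = 1, Z = 0), cq_params(E = 0, v = 0))
#' @export
cq_vector_field <- function(state, params, t = 0) {
  if (!is_cq_params(params)) stop("`params` must be built by cq_params()")
  state <- as.numeric(state)
  if (length(state) != 2L || any(!is.finite(state)))
    stop("`state` must be two finite numbers (W, Z); non-finite state ",
         "indicates a diverged trajectory")
  W <- state[1L]; Z <- state[2L]
  if (params$variant == "autonomous") {
    c(dW = -W^3 + 30 * W - Z + params$E,
      dZ = (5 * (W + params$v)^2 - Z) / params$tau)
  } else {
    c(dW = -W^3 + 30 * W - 10 * Z + params$F * sin(params$omega * t) +
        params$e0,
      dZ = 5 * (W + 3)^2 - 10 * Z - 70)
  }
}

#' Nullclines of the autonomous C-Q model
#'
#' The \eqn{W}-nullcline is the cubic \eqn{Z = -W^3 + 30W + E} and the
#' \eqn{Z}-nullcline the parabola \eqn{Z = 5(W+v)^2}; equilibria sit at
#' their intersections.
#'
#' @param params a [cq_params()] object (autonomous variant).
#' @param W_grid numeric vector of membrane-potential values.
#' @return `data.frame` with columns `W`, `Z_W_nullcline`, `Z_Z_nullcline`.
#' @examples
#' cq_nullclines(cq_params(E = 70, v = 3), W_grid = c(-3, 0, 3))
#' @export
cq_nullclines <- function(params, W_grid) {
  assert_autonomous(params, "cq_nullclines()")
  W_grid <- as.numeric(W_grid)
  data.frame(W = W_grid,
             Z_W_nullcline = -W_grid^3 + 30 * W_grid + params$E,
             Z_Z_nullcline = 5 * (W_grid + params$v)^2)
}

#' Jacobian matrix of the C-Q model
#'
#' For the autonomous variant the Jacobian at \eqn{(W, Z)} is
#' \deqn{J = \begin{pmatrix} -3W^2 + 30 & -1 \\
#'   (10W + 10v)/\tau & -1/\tau \end{pmatrix}.}
#' The recovery time constant divides the whole second row because
#' \eqn{\tau} multiplies \eqn{dZ/dt}.  For the forced variant the entries
#' `-1` become `-10` and the second row is `10(W+3), -10`.
#'
#' @inheritParams cq_vector_field
#' @return A 2x2 numeric matrix.
#' @examples
#' cq_jacobian(c(0, 0), cq_params(E = 70, v = 0))
#' @export
cq_jacobian <- function(state, params) {
  if (!is_cq_params(params)) stop("`params` must be built by cq_params()")
  W <- as.numeric(state)[1L]
  if (!is.finite(W)) stop("`state` must be finite")
  if (params$variant == "autonomous") {
    matrix(c(-3 * W^2 + 30, (10 * W + 10 * params$v) / params$tau,
             -1, -1 / params$tau), nrow = 2L)
  } else {
    matrix(c(-3 * W^2 + 30, 10 * (W + 3), -10, -10), nrow = 2L)
  }
}
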