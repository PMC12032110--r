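#' Steady-state cubic of the autonomous C-Q model
#'
#' Eliminating \eqn{Z} between the two nullclines gives the steady-state
#' cubic \deqn{h(W) = -W^3 - 5W^2 + (30 - 10v)W + (E - 5v^2),} whose real
#' roots are the equilibrium membrane potentials.
#'
#' @param params a [cq_params()] object (autonomous variant).
#' @return An object of class `cq_cubic`: list with `coefficients`
#'   (degree order, constant first), and `alpha = E + 45`, the shifted
#'   input used when the cubic is organised by branches of \eqn{E}.
#' @examples
#' cq_steady_state_cubic(cq_params(E = 70, v = 3))
#' @export
cq_steady_state_cubic <- function(params) {
  assert_autonomous(params, "cq_steady_state_cubic()")
  structure(list(
    coefficients = c(params$E - 5 * params$v^2, 30 - 10 * params$v, -5, -1),
    alpha = params$E + 45,
    E = params$E, v = params$v), class = "cq_cubic")
}

# h(W) and h'(W) without constructing the full object
h_eval <- function(W, E, v) -W^3 - 5 * W^2 + (30 - 10 * v) * W + E - 5 * v^2
h_prime <- function(W, v) -3 * W^2 - 10 * W + 30 - 10 * v

#' Real roots of the steady-state cubic
#'
#' Roots are computed with the Jenkins-Traub solver ([base::polyroot()]);
#' a root where the derivative \eqn{h'(W)} also (numerically) vanishes is
#' reported once with multiplicity 2, which is the degenerate equilibrium
#' of a saddle-node.  At the tolerance boundary the generic (distinct
#' roots) interpretation is preferred.
#'
#' @inheritParams cq_steady_state_cubic
#' @param dprime_tol scaled tolerance on \eqn{|h'(W)|} below which a root
#'   is flagged as a double root.
#' @return Sorted numeric vector of the real roots (ascending), with an
#'   integer attribute `"multiplicity"` of equal length.
#' @examples
#' cq_steady_state_roots(cq_params(E = 45, v = 3)) # double root at W = 0
#' @export
cq_steady_state_roots <- function(params, dprime_tol = 1e-6) {
  assert_autonomous(params, "cq_steady_state_roots()")
  E <- params$E; v <- params$v
  z <- polyroot(c(E - 5 * v^2, 30 - 10 * v, -5, -1))
  real <- sort(Re(z[abs(Im(z)) < 1e-6 * (1 + Mod(z))]))
  if (length(real) == 0L) {
    # a real cubic always has one real root; fall back to the least-Im one
    real <- Re(z[which.min(abs(Im(z)))])
  }
  # scale for the derivative criterion: sum of term magnitudes at the root
  mult <- rep(1L, length(real))
  if (length(real) == 3L) {
    scale3 <- function(W) max(1, 3 * W^2 + 10 * abs(W) + abs(30 - 10 * v))
    dp <- abs(h_prime(real, v)) / vapply(real, scale3, numeric(1))
    # a double root shows up as two nearly coincident roots with tiny h'
    for (i in 1:2) {
      if (diff(real[i:(i + 1)]) < 1e-4 && all(dp[i:(i + 1)] < dprime_tol)) {
        real <- c(real[-(i:(i + 1))], mean(real[i:(i + 1)]))
        mult <- c(1L, 2L)
        ord <- order(real)
        real <- real[ord]; mult <- mult[ord]
        break
      }
    }
  }
  structure(real, multiplicity = mult)
}

#' Jacobian eigenvalues along the equilibrium manifold
#'
#' Eigenvalues of the autonomous Jacobian at abscissa `W`, obtained from
#' the quadratic formula on the trace and determinant so that complex
#' conjugacy is preserved exactly.  Ordered by descending real part, then
#' descending imaginary part (so a conjugate pair is reported with the
#' positive imaginary part first).
#'
#' @param W equilibrium membrane potential (any real value is accepted).
#' @inheritParams cq_steady_state_cubic
#' @return Complex vector of length 2.
#' @examples
#' cq_eigenvalues_at(1.9030, cq_params(E = 70, v = 3))
#' @export
cq_eigenvalues_at <- function(W, params) {
  assert_autonomous(params, "cq_eigenvalues_at()")
  td <- trace_det(W, params$v, params$tau)
  disc <- td[["tr"]]^2 - 4 * td[["det"]]
  if (disc >= 0) {
    r <- sqrt(disc)
    lam <- complex(real = c(td[["tr"]] + r, td[["tr"]] - r) / 2,
                   imaginary = c(0, 0))
  } else {
    im <- sqrt(-disc) / 2
    lam <- complex(real = rep(td[["tr"]] / 2, 2), imaginary = c(im, -im))
  }
  lam
}

trace_det <- function(W, v, tau) {
  a11 <- -3 * W^2 + 30
  c(tr = a11 - 1 / tau, det = (-a11 + 10 * W + 10 * v) / tau)
}

#' Linear stability class from an eigenvalue pair
#'
#' @param eigenvalues complex (or numeric) vector of length 2, the
#'   eigenvalues of a real 2x2 matrix: either two reals or a conjugate
#'   pair.
#' @param zero_tol real parts within `zero_tol` of zero make the point
#'   non-hyperbolic.
#' @return One of `"stable_node"`, `"unstable_node"`, `"stable_focus"`,
#'   `"unstable_focus"`, `"saddle"`, `"non_hyperbolic"`.
#' @examples
#' cq_classify_stability(c(-674.3637, -0.6240))
#' cq_classify_stability(complex(real = 0.45, imaginary = c(7, -7)))
#' @export
cq_classify_stability <- function(eigenvalues, zero_tol = 1e-6) {
  lam <- as.complex(eigenvalues)
  if (length(lam) != 2L) stop("`eigenvalues` must have length 2")
  im <- Im(lam); re <- Re(lam)
  complex_pair <- any(abs(im) > 0)
  if (complex_pair) {
    ok <- abs(re[1] - re[2]) <= 1e-8 * (1 + max(abs(re))) &&
      abs(im[1] + im[2]) <= 1e-8 * (1 + max(abs(im)))
    if (!ok) stop("complex eigenvalues of a real 2x2 matrix must be a ",
                  "conjugate pair")
  }
  if (any(abs(re) <= zero_tol)) return("non_hyperbolic")
  if (complex_pair) {
    if (re[1] < 0) "stable_focus" else "unstable_focus"
  } else if (prod(sign(re)) < 0) {
    "saddle"
  } else if (re[1] < 0) "stable_node" else "unstable_node"
}

#' Equilibria of the autonomous C-Q model
#'
#' Solves the steady-state cubic, lifts each real root to the phase plane
#' through \eqn{Z = 5(W+v)^2}, and classifies its linear stability from
#' the Jacobian eigenvalues.
#'
#' @inheritParams cq_steady_state_roots
#' @param zero_tol passed to [cq_classify_stability()].
#' @return An object of class `cq_equilibria`: a list of `cq_equilibrium`
#'   records (fields `W`, `Z`, `eigenvalues`, `stability`, `multiplicity`,
#'   `params`), ordered by ascending `W`.  Use [as.data.frame()] for the
#'   tabular form.
#' @examples
#' eq <- cq_find_equilibria(cq_params(E = 70, v = 3))
#' as.data.frame(eq)
#' @export
cq_find_equilibria <- function(params, zero_tol = 1e-6) {
  assert_autonomous(params, "cq_find_equilibria()")
  W <- cq_steady_state_roots(params)
  mult <- attr(W, "multiplicity")
  out <- lapply(seq_along(W), function(i) {
    lam <- cq_eigenvalues_at(W[i], params)
    structure(list(W = W[i], Z = 5 * (W[i] + params$v)^2,
                   eigenvalues = lam,
                   stability = cq_classify_stability(lam, zero_tol),
                   multiplicity = mult[i], params = params),
              class = "cq_equilibrium")
  })
  structure(out, class = "cq_equilibria")
}

#' @export
as.data.frame.cq_equilibria <- function(x, ...) {
  do.call(rbind, lapply(x, function(e) {
    data.frame(E = e$params$E, v = e$params$v, tau = e$params$tau,
               W = e$W, Z = e$Z,
               re_lambda1 = Re(e$eigenvalues[1]),
               im_lambda1 = Im(e$eigenvalues[1]),
               re_lambda2 = Re(e$eigenvalues[2]),
               im_lambda2 = Im(e$eigenvalues[2]),
               stability = e$stability)
  }))
}

#' @export
print.cq_equilibria <- function(x, ...) {
  cat(sprintf("%d equilibrium point(s) of the autonomous C-Q model\n",
              length(x)))
  print(as.data.frame(x), digits = 6)
  invisible(x)
}

#' Export an equilibrium table as CSV
#'
#' @param x a `cq_equilibria` object.
#' @param file path of the CSV file to write.
#' @return The file path, invisibly.
#' @export
cq_write_equilibria_csv <- function(x, file) {
  utils::write.csv(as.data.frame(x), file, row.names = FALSE)
  invisible(file)
}
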