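#' @title Codimension-one bifurcations of the autonomous C-Q model
#' @description Saddle-node points, Andronov-Hopf points and focus/node
#'   eigenvalue-type boundaries along one-parameter sweeps in `v` or `E`.
#'   The trace, determinant and steady-state conditions of this model
#'   reduce to low-order polynomial systems, so critical values are
#'   obtained from polynomial root solving and then verified by
#'   back-substitution; the focus/node boundary, which lives on a branch,
#'   is located by bracketing and bisection along the continued branch.
#' @name cq_bifurcation
NULL

new_bifpoint <- function(kind, parameter, critical_value, W_star, Z_star,
                         conditions, fixed) {
  structure(list(kind = kind, parameter = parameter,
                 critical_value = critical_value,
                 W_star = W_star, Z_star = Z_star,
                 conditions = conditions, fixed = fixed),
            class = "cq_bifpoint")
}

#' @export
print.cq_bifpoint <- function(x, ...) {
  cat(sprintf("%s at %s = %.6g  (W*, Z*) = (%.6g, %.6g)\n",
              x$kind, x$parameter, x$critical_value, x$W_star, x$Z_star))
  invisible(x)
}

bif_list <- function(points) {
  points <- points[order(vapply(points, `[[`, numeric(1), "critical_value"))]
  structure(points, class = "cq_bifurcations")
}

#' @export
print.cq_bifurcations <- function(x, ...) {
  cat(sprintf("%d bifurcation point(s)\n", length(x)))
  for (p in x) print(p)
  invisible(x)
}

#' @export
as.data.frame.cq_bifurcations <- function(x, ...) {
  do.call(rbind, lapply(x, function(p) {
    data.frame(kind = p$kind, parameter = p$parameter,
               critical_value = p$critical_value,
               W_star = p$W_star, Z_star = p$Z_star)
  }))
}

real_roots <- function(coefs, tol = 1e-7) {
  # real roots of a polynomial given coefficients in increasing degree
  z <- polyroot(coefs)
  sort(Re(z[abs(Im(z)) < tol * (1 + Mod(z))]))
}

#' Saddle-node bifurcations along a one-parameter sweep
#'
#' Solves the simultaneous system \eqn{h(W) = 0,\ \partial h/\partial W = 0}
#' for the sweep parameter.  For a sweep in `E` the fold abscissae come
#' from the quadratic \eqn{h'(W) = 0}; for a sweep in `v` elimination of
#' `v` leaves a quartic in `W`.  Each returned point carries the residuals
#' of the non-hyperbolicity, non-degeneracy (second derivative of `h`)
#' and transversality conditions.
#'
#' @param sweep `"v"` or `"E"`, the parameter that is varied.
#' @param fixed a [cq_params()] object providing the parameter that is
#'   held fixed (and `tau`).
#' @param bracket numeric length-2 interval of sweep-parameter values.
#' @return A `cq_bifurcations` list (possibly empty), sorted by critical
#'   value.  Points are labelled `"saddle_node"`; whether a point lies on
#'   an invariant circle is a global question answered by
#'   [cq_classify_saddle_node_globality()].
#' @examples
#' cq_find_saddle_node("E", cq_params(v = 3), c(0, 200))
#' @export
cq_find_saddle_node <- function(sweep = c("v", "E"), fixed, bracket) {
  sweep <- match.arg(sweep)
  assert_autonomous(fixed, "cq_find_saddle_node()")
  stopifnot(length(bracket) == 2L, bracket[1] <= bracket[2])
  pts <- list()
  if (sweep == "E") {
    v <- fixed$v
    Wc <- real_roots(c(30 - 10 * v, -10, -3))     # h'(W) = 0
    for (W in Wc) {
      E <- W^3 + 5 * W^2 - (30 - 10 * v) * W + 5 * v^2
      if (E < bracket[1] || E > bracket[2]) next
      pts[[length(pts) + 1L]] <- saddle_node_point("E", E, W, E, v, fixed$tau)
    }
  } else {
    E <- fixed$E
    # eliminate v = (30 - 3W^2 - 10W)/10 from h = 0:
    # 20 h(W, v(W)) = -9W^4 - 20W^3 + 180W^2 + 600W + 20E - 900
    Wc <- real_roots(c(20 * E - 900, 600, 180, -20, -9))
    for (W in Wc) {
      v <- (30 - 3 * W^2 - 10 * W) / 10
      if (v < bracket[1] || v > bracket[2]) next
      pts[[length(pts) + 1L]] <- saddle_node_point("v", v, W, E, v, fixed$tau)
    }
  }
  bif_list(pts)
}

saddle_node_point <- function(parameter, critical, W, E, v, tau) {
  lam <- cq_eigenvalues_at(W, cq_params(E = E, v = v, tau = tau))
  new_bifpoint(
    kind = "saddle_node", parameter = parameter, critical_value = critical,
    W_star = W, Z_star = 5 * (W + v)^2,
    conditions = list(
      h_residual = h_eval(W, E, v),
      dh_residual = h_prime(W, v),
      zero_eigenvalue = min(abs(Re(lam))),
      nondegeneracy = -3 * W - 5,               # (1/2) h''(W)
      transversality = if (parameter == "v") -10 * (W + v) else 1),
    fixed = if (parameter == "v") list(E = E, tau = tau)
            else list(v = v, tau = tau))
}

#' Andronov-Hopf bifurcations along a one-parameter sweep
#'
#' At an equilibrium the Jacobian trace is \eqn{-3W^2 + 30 - 1/\tau}, so
#' the Hopf condition fixes the abscissa
#' \eqn{W_\star = \pm\sqrt{(30 - 1/\tau)/3}} and the critical parameter
#' follows from \eqn{h(W_\star) = 0} in closed form; candidates with
#' non-positive Jacobian determinant (saddles) are discarded.
#' Transversality, the speed of the trace zero-crossing along the branch,
#' is reported with each point.
#'
#' @inheritParams cq_find_saddle_node
#' @return A `cq_bifurcations` list of points labelled `"hopf"`.
#' @examples
#' cq_find_hopf("v", cq_params(E = 70), c(3, 6))
#' @export
cq_find_hopf <- function(sweep = c("v", "E"), fixed, bracket) {
  sweep <- match.arg(sweep)
  assert_autonomous(fixed, "cq_find_hopf()")
  stopifnot(length(bracket) == 2L, bracket[1] <= bracket[2])
  tau <- fixed$tau
  if (30 - 1 / tau <= 0) return(bif_list(list()))   # trace never vanishes
  W_star <- c(-1, 1) * sqrt((30 - 1 / tau) / 3)
  pts <- list()
  for (W in W_star) {
    if (sweep == "E") {
      v <- fixed$v
      E <- W^3 + 5 * W^2 - (30 - 10 * v) * W + 5 * v^2
      cand <- if (E >= bracket[1] && E <= bracket[2]) list(c(E = E, v = v))
              else list()
    } else {
      E <- fixed$E
      # h(W, v) = 0 is quadratic in v: 5v^2 + 10Wv + (W^3 + 5W^2 - 30W - E)
      disc <- 100 * W^2 - 20 * (W^3 + 5 * W^2 - 30 * W - E)
      cand <- list()
      if (disc >= 0) {
        for (v in (-10 * W + c(-1, 1) * sqrt(disc)) / 10) {
          if (v >= bracket[1] && v <= bracket[2])
            cand[[length(cand) + 1L]] <- c(E = E, v = v)
        }
      }
    }
    for (cv in cand) {
      td <- trace_det(W, cv[["v"]], tau)
      if (td[["det"]] <= 0) next                    # saddle, not a Hopf
      crit <- if (sweep == "E") cv[["E"]] else cv[["v"]]
      # d(tr)/d(param) along the branch: tr depends on W only
      dW_dparam <- if (sweep == "E") -1 / h_prime(W, cv[["v"]]) else
        (10 * W + 10 * cv[["v"]]) / h_prime(W, cv[["v"]])
      pts[[length(pts) + 1L]] <- new_bifpoint(
        kind = "hopf", parameter = sweep, critical_value = crit,
        W_star = W, Z_star = 5 * (W + cv[["v"]])^2,
        conditions = list(trace = td[["tr"]], det = td[["det"]],
                          transversality = -6 * W * dW_dparam),
        fixed = if (sweep == "E") list(v = cv[["v"]], tau = tau)
                else list(E = cv[["E"]], tau = tau))
    }
  }
  bif_list(pts)
}

# equilibrium of `params` whose W is nearest `W_ref` (branch continuation)
nearest_branch_W <- function(E, v, tau, W_ref) {
  W <- cq_steady_state_roots(cq_params(E = E, v = v, tau = tau))
  W[which.min(abs(W - W_ref))]
}

branch_disc <- function(param_value, sweep, fixed, W_ref) {
  E <- if (sweep == "E") param_value else fixed$E
  v <- if (sweep == "v") param_value else fixed$v
  W <- nearest_branch_W(E, v, fixed$tau, W_ref)
  td <- trace_det(W, v, fixed$tau)
  list(disc = td[["tr"]]^2 - 4 * td[["det"]], W = W)
}

#' Focus/node boundaries along a one-parameter sweep
#'
#' Locates parameter values where the eigenvalue discriminant
#' \eqn{\mathrm{tr}(J)^2 - 4\det(J)} vanishes along an equilibrium branch,
#' i.e. where a node turns into a focus or vice versa.  Branches are
#' continued through the sweep by nearest-`W` matching and each sign
#' change is refined by bisection.
#'
#' @inheritParams cq_find_saddle_node
#' @param n_grid number of grid points used to scan each branch.
#' @return A `cq_bifurcations` list of points labelled
#'   `"focus_node_boundary"`; each point's `conditions` records the branch
#'   (`"lower"`, `"middle"`, `"upper"` or `"only"`) it lies on.
#' @examples
#' cq_find_focus_node_boundary("E", cq_params(v = 3), c(64, 123))
#' @export
cq_find_focus_node_boundary <- function(sweep = c("v", "E"), fixed, bracket,
                                        n_grid = 2001) {
  sweep <- match.arg(sweep)
  assert_autonomous(fixed, "cq_find_focus_node_boundary()")
  stopifnot(length(bracket) == 2L, bracket[1] <= bracket[2])
  grid <- seq(bracket[1], bracket[2], length.out = n_grid)
  eqs <- lapply(grid, function(p) {
    E <- if (sweep == "E") p else fixed$E
    v <- if (sweep == "v") p else fixed$v
    W <- cq_steady_state_roots(cq_params(E = E, v = v, tau = fixed$tau))
    td <- vapply(W, function(w) {
      x <- trace_det(w, v, fixed$tau); x[["tr"]]^2 - 4 * x[["det"]]
    }, numeric(1))
    list(W = as.numeric(W), disc = td)
  })
  pts <- list()
  seen <- numeric(0)
  for (i in seq_len(n_grid - 1L)) {
    a <- eqs[[i]]; b <- eqs[[i + 1L]]
    for (j in seq_along(a$W)) {
      k <- which.min(abs(b$W - a$W[j]))
      if (abs(b$W[k] - a$W[j]) > 0.5 * (1 + abs(a$W[j]))) next  # branch ends
      if (a$disc[j] == 0 || a$disc[j] * b$disc[k] > 0) next
      lo <- grid[i]; hi <- grid[i + 1L]
      W_ref <- a$W[j]; d_lo <- a$disc[j]
      for (it in 1:60) {
        mid <- (lo + hi) / 2
        res <- branch_disc(mid, sweep, fixed, W_ref)
        W_ref <- res$W
        if (res$disc * d_lo <= 0) hi <- mid else { lo <- mid; d_lo <- res$disc }
        if (hi - lo < 1e-11 * (1 + abs(mid))) break
      }
      crit <- (lo + hi) / 2
      if (any(abs(seen - crit) < 1e-6 * (1 + abs(crit)))) next
      seen <- c(seen, crit)
      res <- branch_disc(crit, sweep, fixed, W_ref)
      E <- if (sweep == "E") crit else fixed$E
      v <- if (sweep == "v") crit else fixed$v
      n_br <- length(a$W)
      branch <- if (n_br == 1L) "only" else
        c("lower", "middle", "upper")[j]
      pts[[length(pts) + 1L]] <- new_bifpoint(
        kind = "focus_node_boundary", parameter = sweep,
        critical_value = crit, W_star = res$W,
        Z_star = 5 * (res$W + v)^2,
        conditions = list(disc_residual = res$disc, branch = branch),
        fixed = if (sweep == "E") list(v = fixed$v, tau = fixed$tau)
                else list(E = fixed$E, tau = fixed$tau))
    }
  }
  bif_list(pts)
}

#' Equilibrium branch diagram over a parameter grid
#'
#' Tabulates every equilibrium (with its stability class) over a grid of
#' the sweep parameter and attaches the saddle-node, Hopf and focus/node
#' boundary points detected inside the grid range.
#'
#' @inheritParams cq_find_saddle_node
#' @param grid ascending numeric vector of sweep-parameter values.
#' @return An object of class `cq_branch_diagram`: list with `parameter`,
#'   `grid`, `branches` (data frame: `param`, `W`, `Z`, `stability`,
#'   `branch`), and `points` (a `cq_bifurcations` list).
#' @examples
#' bd <- cq_branch_diagram("v", cq_params(E = 70), grid = c(-11, 0, 3))
#' table(bd$branches$param)
#' @export
cq_branch_diagram <- function(sweep = c("v", "E"), fixed, grid) {
  sweep <- match.arg(sweep)
  assert_autonomous(fixed, "cq_branch_diagram()")
  grid <- as.numeric(grid)
  if (is.unsorted(grid, strictly = TRUE)) stop("`grid` must be ascending")
  rows <- lapply(grid, function(p) {
    E <- if (sweep == "E") p else fixed$E
    v <- if (sweep == "v") p else fixed$v
    eq <- cq_find_equilibria(cq_params(E = E, v = v, tau = fixed$tau))
    d <- as.data.frame(eq)
    n <- nrow(d)
    branch <- if (n == 1L) "only" else c("lower", "middle", "upper")[seq_len(n)]
    data.frame(param = p, W = d$W, Z = d$Z, stability = d$stability,
               branch = branch)
  })
  bracket <- range(grid)
  pts <- c(unclass(cq_find_saddle_node(sweep, fixed, bracket)),
           unclass(cq_find_hopf(sweep, fixed, bracket)),
           unclass(cq_find_focus_node_boundary(sweep, fixed, bracket)))
  structure(list(parameter = sweep, grid = grid,
                 branches = do.call(rbind, rows), points = bif_list(pts)),
            class = "cq_branch_diagram")
}

#' @export
print.cq_branch_diagram <- function(x, ...) {
  cat(sprintf("C-Q branch diagram over %s in [%g, %g] (%d grid points)\n",
              x$parameter, min(x$grid), max(x$grid), length(x$grid)))
  print(x$points)
  invisible(x)
}

#' Export a branch diagram as CSV plus a JSON sidecar
#'
#' Writes the branch samples as CSV (`param`, `W`, `Z`, `stability`,
#' `branch`) and the detected bifurcation points as a JSON file next to
#' it.
#'
#' @param x a `cq_branch_diagram`.
#' @param file CSV path; the sidecar replaces the extension with `.json`.
#' @return The CSV path, invisibly.
#' @export
cq_write_branch_diagram <- function(x, file) {
  utils::write.csv(x$branches, file, row.names = FALSE)
  sidecar <- sub("\\.[^.]*$", ".json", file)
  if (identical(sidecar, file)) sidecar <- paste0(file, ".json")
  jsonlite::write_json(lapply(x$points, function(p) {
    list(kind = p$kind, parameter = p$parameter,
         critical_value = p$critical_value,
         W_star = p$W_star, Z_star = p$Z_star)
  }), sidecar, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
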