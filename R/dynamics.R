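#' Integrate a trajectory of the C-Q model
#'
#' Fixed-step classical Runge-Kutta (RK4) integration in compiled code,
#' the package default, or adaptive integration through
#' [deSolve::ode()] (`method = "adaptive"`, useful for very small
#' recovery time constants).  Integration is deterministic for fixed
#' inputs.  A trajectory whose membrane potential passes `blowup` is
#' treated as divergent: the integration stops and an error of class
#' `"cq_divergence"` is signalled, carrying the last valid state in its
#' `last_state` / `last_time` fields.
#'
#' @param params a [cq_params()] object.
#' @param initial numeric `c(W, Z)` initial state.
#' @param t_end final time (`t_end = 0` returns the initial sample only).
#' @param dt integration step.
#' @param t0 initial time.
#' @param record_every record every n-th step (thins the output, not the
#'   integration).
#' @param method `"rk4"` (default) or `"adaptive"`.
#' @param blowup membrane-potential magnitude treated as divergence.
#' @return A `cq_trajectory`: data frame with columns `t`, `W`, `Z` and
#'   attributes `params`, `initial` and `integrator` (method, step,
#'   tolerances).
#' @examples
#' tr <- cq_integrate(cq_params(E = 70, v = 3), c(0, 0), t_end = 5)
#' range(tr$W)
#' @export
cq_integrate <- function(params, initial, t_end, dt = 1e-3, t0 = 0,
                         record_every = 1L, method = c("rk4", "adaptive"),
                         blowup = 1e3) {
  method <- match.arg(method)
  if (!is_cq_params(params)) stop("`params` must be built by cq_params()")
  initial <- as.numeric(initial)
  if (length(initial) != 2L || any(!is.finite(initial)))
    stop("`initial` must be two finite numbers (W, Z)")
  if (dt <= 0) stop("`dt` must be positive")
  if (t_end < t0) stop("`t_end` must be >= `t0`")
  if (method == "rk4") {
    res <- cq_rk4_cpp(params_for_cpp(params), initial, t0, t_end, dt,
                      as.integer(record_every), blowup)
    if (isTRUE(res$diverged)) {
      stop(errorCondition(
        sprintf("trajectory diverged near t = %.6g (|W| > %g)",
                res$last_t, blowup),
        class = "cq_divergence",
        last_state = c(W = res$last_W, Z = res$last_Z),
        last_time = res$last_t))
    }
    traj <- data.frame(t = res$t, W = res$W, Z = res$Z)
  } else {
    times <- unique(c(seq(t0, t_end, by = dt * record_every), t_end))
    rhs <- function(t, y, parms) list(cq_vector_field(y, params, t))
    sol <- deSolve::ode(y = c(W = initial[1], Z = initial[2]), times = times,
                        func = rhs, parms = NULL, method = "lsoda",
                        rtol = 1e-10, atol = 1e-10)
    traj <- data.frame(t = sol[, "time"], W = sol[, "W"], Z = sol[, "Z"])
    if (any(!is.finite(traj$W)) || max(abs(traj$W), na.rm = TRUE) > blowup) {
      ok <- which(is.finite(traj$W) & abs(traj$W) <= blowup)
      last <- if (length(ok)) traj[max(ok), ] else traj[1, ]
      stop(errorCondition("trajectory diverged (adaptive mode)",
                          class = "cq_divergence",
                          last_state = c(W = last$W, Z = last$Z),
                          last_time = last$t))
    }
  }
  structure(traj, params = params, initial = initial,
            integrator = list(method = method, dt = dt,
                              record_every = record_every, blowup = blowup),
            class = c("cq_trajectory", "data.frame"))
}

#' @export
`[.cq_trajectory` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "params") <- attr(x, "params")
    attr(out, "initial") <- attr(x, "initial")
    attr(out, "integrator") <- attr(x, "integrator")
    class(out) <- class(x)
  }
  out
}

#' The ten standard initial conditions
#'
#' The fixed set of phase-plane initial states used wherever "all initial
#' conditions" are examined; it spans both attraction basins of the
#' bistable regime.
#'
#' @return A 10x2 matrix with columns `W`, `Z`.
#' @export
cq_standard_ics <- function() {
  m <- rbind(c(-6, 0), c(-3, 0), c(0, 0), c(3, 0), c(6, 0),
             c(0, 50), c(0, 150), c(3, 150), c(-3, 100), c(5, 100))
  colnames(m) <- c("W", "Z")
  m
}

# linearly interpolated upward crossings of W = level
upward_crossings <- function(t, W, level) {
  i <- which(W[-length(W)] < level & W[-1] >= level)
  if (!length(i)) return(numeric(0))
  frac <- (level - W[i]) / (W[i + 1] - W[i])
  t[i] + frac * (t[i + 1] - t[i])
}

#' Detect a stable limit cycle
#'
#' Integrates from `initial`, discards a transient, and measures the
#' orbit period from successive upward crossings of the Poincare section
#' `W = W_section` (by default the equilibrium abscissa nearest the
#' post-transient orbit mean).  Returns `NULL` when the trajectory
#' settles on an equilibrium or the crossing amplitudes keep shrinking
#' (a damped focus), so only genuinely periodic attractors are reported.
#'
#' @inheritParams cq_integrate
#' @param t_end,dt integration horizon and step.
#' @param transient_frac fraction of the horizon discarded as transient.
#' @param rel_tol relative agreement required between successive periods
#'   (and cycle amplitudes) for the cycle to be flagged converged.
#' @param W_section optional Poincare-section abscissa override.
#' @return A `cq_limit_cycle` (fields `period`, `W_min`, `W_max`,
#'   `Z_min`, `Z_max`, `mean_orbit`, `converged`, `n_periods`,
#'   `W_section`) or `NULL` when no cycle is found.
#' @examples
#' cyc <- cq_detect_limit_cycle(cq_params(E = 70, v = 3), c(0, 0))
#' cyc$period
#' @export
cq_detect_limit_cycle <- function(params, initial = c(0, 0), t_end = 200,
                                  dt = 1e-3, transient_frac = 0.5,
                                  rel_tol = 1e-4, W_section = NULL) {
  assert_autonomous(params, "cq_detect_limit_cycle()")
  traj <- cq_integrate(params, initial, t_end = t_end, dt = dt)
  post <- traj[traj$t >= transient_frac * t_end, ]
  eqs <- cq_find_equilibria(params)
  eq_W <- vapply(eqs, `[[`, numeric(1), "W")
  eq_Z <- vapply(eqs, `[[`, numeric(1), "Z")
  # settled on an equilibrium?
  tail_n <- max(1L, nrow(post) - 200L)
  last <- post[nrow(post), ]
  d_eq <- sqrt((eq_W - last$W)^2 + ((eq_Z - last$Z) / 30)^2)
  if (min(d_eq) < 1e-3 &&
      max(post$W[tail_n:nrow(post)]) - min(post$W[tail_n:nrow(post)]) < 1e-3)
    return(NULL)
  if (is.null(W_section)) {
    W_section <- eq_W[which.min(abs(eq_W - mean(post$W)))]
  }
  tc <- upward_crossings(post$t, post$W, W_section)
  if (length(tc) < 3L) return(NULL)   # at least two full returns
  periods <- diff(tc)
  # per-cycle W amplitude, to reject slowly damped spirals
  amp <- vapply(seq_len(length(tc) - 1L), function(k) {
    seg <- post$W[post$t >= tc[k] & post$t <= tc[k + 1]]
    if (length(seg) < 2L) return(NA_real_)
    diff(range(seg))
  }, numeric(1))
  n <- length(periods)
  per_ok <- abs(periods[n] - periods[n - 1]) <= rel_tol * periods[n]
  amp_ok <- is.finite(amp[n]) && amp[n] > 0.1 &&
    abs(amp[n] - amp[n - 1]) <= max(10 * rel_tol, 1e-3) * amp[n]
  if (!amp_ok) return(NULL)
  one <- post[post$t >= tc[n] & post$t <= tc[n + 1], c("t", "W", "Z")]
  if (nrow(one) > 1000L)
    one <- one[unique(round(seq(1, nrow(one), length.out = 1000L))), ]
  Wseg <- one$W; Zseg <- one$Z
  structure(list(period = periods[n],
                 W_min = min(Wseg), W_max = max(Wseg),
                 Z_min = min(Zseg), Z_max = max(Zseg),
                 mean_orbit = one, converged = per_ok && amp_ok,
                 n_periods = n, W_section = W_section),
            class = "cq_limit_cycle")
}

#' @export
print.cq_limit_cycle <- function(x, ...) {
  cat(sprintf(
    "limit cycle: period %.6g, W in [%.4g, %.4g], converged: %s\n",
    x$period, x$W_min, x$W_max, x$converged))
  invisible(x)
}

#' Winding number of a closed orbit around a point
#'
#' Total signed angle swept by the orbit around `point`, divided by
#' \eqn{2\pi}.  A stable cycle born around an unstable focus winds once.
#'
#' @param orbit data frame with columns `W`, `Z` sampling one closed loop
#'   (e.g. the `mean_orbit` of a [cq_detect_limit_cycle()] result).
#' @param point numeric `c(W, Z)`.
#' @return The (rounded) integer winding number.
#' @export
cq_winding_number <- function(orbit, point) {
  th <- atan2(orbit$Z - point[2], orbit$W - point[1])
  dth <- diff(th)
  dth <- dth - 2 * pi * round(dth / (2 * pi))
  close_th <- (th[1] - th[length(th)])
  close_th <- close_th - 2 * pi * round(close_th / (2 * pi))
  round((sum(dth) + close_th) / (2 * pi))
}

#' Numerically verify a trapping region for a limit cycle
#'
#' A stable limit cycle is guaranteed inside a closed region that (i)
#' contains exactly one equilibrium, which is unstable, (ii) has the
#' vector field pointing strictly inward everywhere on its boundary, and
#' (iii) carries no equilibrium on the boundary itself.  This routine
#' checks the three conditions on an axis-aligned rectangle by sampling
#' the boundary and recording the worst inward margin (the most positive
#' outward normal component of the field; negative margins mean inward).
#'
#' @inheritParams cq_integrate
#' @param region numeric `c(W_min, W_max, Z_min, Z_max)`.
#' @param n_boundary_samples number of boundary sample points.
#' @return A `cq_trapping_report`: list with logical `conditions`
#'   (`one_unstable_inside`, `inward_everywhere`, `boundary_clear`),
#'   `pass`, `worst_margin`, and the interior equilibria found.
#' @examples
#' cq_verify_trapping_region(cq_params(E = 70, v = 3),
#'                           region = c(-9, 6.5, -5, 500))
#' @export
cq_verify_trapping_region <- function(params, region,
                                      n_boundary_samples = 400) {
  assert_autonomous(params, "cq_verify_trapping_region()")
  stopifnot(length(region) == 4L)
  W1 <- region[1]; W2 <- region[2]; Z1 <- region[3]; Z2 <- region[4]
  degenerate <- !(W2 > W1 && Z2 > Z1)
  eqs <- cq_find_equilibria(params)
  eq_W <- vapply(eqs, `[[`, numeric(1), "W")
  eq_Z <- vapply(eqs, `[[`, numeric(1), "Z")
  stab <- vapply(eqs, `[[`, character(1), "stability")
  tol <- 1e-9 * (1 + max(abs(c(W1, W2, Z1, Z2))))
  inside <- eq_W > W1 + tol & eq_W < W2 - tol &
            eq_Z > Z1 + tol & eq_Z < Z2 - tol
  on_boundary <- !inside &
    eq_W >= W1 - tol & eq_W <= W2 + tol &
    eq_Z >= Z1 - tol & eq_Z <= Z2 + tol
  cond1 <- !degenerate && sum(inside) == 1L &&
    stab[inside] %in% c("unstable_node", "unstable_focus", "saddle")
  cond3 <- !any(on_boundary)
  worst <- -Inf; cond2 <- FALSE
  if (!degenerate) {
    perim <- 2 * (W2 - W1) + 2 * (Z2 - Z1)
    n_w <- max(2L, round(n_boundary_samples * (W2 - W1) / perim))
    n_z <- max(2L, round(n_boundary_samples * (Z2 - Z1) / perim))
    Ws <- seq(W1, W2, length.out = n_w)
    Zs <- seq(Z1, Z2, length.out = n_z)
    margins <- c(
      vapply(Ws, function(w)  cq_vector_field(c(w, Z2), params)[2], 0), # top
      vapply(Ws, function(w) -cq_vector_field(c(w, Z1), params)[2], 0), # bottom
      vapply(Zs, function(z)  cq_vector_field(c(W2, z), params)[1], 0), # right
      vapply(Zs, function(z) -cq_vector_field(c(W1, z), params)[1], 0)) # left
    worst <- max(margins)
    cond2 <- worst < 0
  }
  structure(list(conditions = c(one_unstable_inside = cond1,
                                inward_everywhere = cond2,
                                boundary_clear = cond3),
                 pass = cond1 && cond2 && cond3,
                 worst_margin = worst,
                 interior_equilibria = data.frame(W = eq_W[inside],
                                                  Z = eq_Z[inside],
                                                  stability = stab[inside]),
                 region = region), class = "cq_trapping_report")
}

#' @export
print.cq_trapping_report <- function(x, ...) {
  cat("trapping-region check:",
      if (x$pass) "PASS" else "FAIL", "\n")
  print(x$conditions)
  cat(sprintf("worst outward margin on boundary: %.4g (negative = inward)\n",
              x$worst_margin))
  invisible(x)
}

#' Classify a saddle-node bifurcation as on or off an invariant circle
#'
#' A saddle-node on an invariant circle (SNIC) destroys the only
#' attractor-limiting equilibria and the emerging limit cycle threads
#' through the locus of the vanished saddle-node pair; a saddle-node off
#' the cycle leaves a limit cycle that already coexisted with the node
#' and saddle before the bifurcation.  The classification therefore
#' checks, just before the critical parameter, whether a periodic
#' attractor coexists with the equilibria (label `"off_cycle"`), and
#' otherwise, just past the critical parameter, whether the periodic
#' attractor passes through a neighbourhood of the former saddle-node
#' location (label `"on_invariant_circle"`); distances are measured in
#' `(W, Z/30)` scaled coordinates because the recovery variable spans a
#' roughly thirtyfold wider range than the potential.
#'
#' @param fixed a [cq_params()] object with the non-swept parameter and
#'   `tau`.
#' @param critical a `cq_bifpoint` of kind `"saddle_node"` (from
#'   [cq_find_saddle_node()]).
#' @param offset parameter offset used on either side of the critical
#'   value.
#' @param radius neighbourhood radius in scaled coordinates.
#' @param t_end,dt integration settings for the cycle searches.
#' @return List with `label` (`"on_invariant_circle"`, `"off_cycle"` or
#'   `"inconclusive"`) and `evidence`.
#' @export
cq_classify_saddle_node_globality <- function(fixed, critical,
                                              offset = 1e-2, radius = 0.5,
                                              t_end = 600, dt = 1e-3) {
  assert_autonomous(fixed, "cq_classify_saddle_node_globality()")
  if (!inherits(critical, "cq_bifpoint") || critical$kind != "saddle_node")
    stop("`critical` must be a saddle-node cq_bifpoint")
  sweep <- critical$parameter
  vc <- critical$critical_value
  at <- function(p) {
    if (sweep == "v") cq_params(E = fixed$E, v = p, tau = fixed$tau)
    else cq_params(E = p, v = fixed$v, tau = fixed$tau)
  }
  count_roots <- function(p) length(cq_steady_state_roots(at(p)))
  # the "past" side is the one where the pair has annihilated (fewer roots)
  dir <- if (count_roots(vc + offset) < count_roots(vc - offset)) 1 else -1
  before <- at(vc - dir * offset)
  past <- at(vc + dir * offset)

  scaled_min_dist <- function(orbit)
    min(sqrt((orbit$W - critical$W_star)^2 +
             ((orbit$Z - critical$Z_star) / 30)^2))

  # coexisting periodic attractor before the bifurcation?
  eqs_before <- cq_find_equilibria(before)
  ics <- rbind(cq_standard_ics(),
               t(vapply(eqs_before, function(e) c(e$W + 0.1, e$Z),
                        numeric(2))))
  cycle_before <- NULL
  for (i in seq_len(nrow(ics))) {
    cyc <- tryCatch(
      cq_detect_limit_cycle(before, ics[i, ], t_end = t_end, dt = dt),
      cq_divergence = function(e) NULL)
    if (!is.null(cyc) && cyc$converged) { cycle_before <- cyc; break }
  }
  if (!is.null(cycle_before)) {
    return(list(label = "off_cycle",
                evidence = list(coexisting_cycle = TRUE,
                                period_before = cycle_before$period)))
  }
  # past the bifurcation: does the cycle thread the saddle-node ghost?
  cyc <- tryCatch(
    cq_detect_limit_cycle(past, c(critical$W_star + 0.05, critical$Z_star),
                          t_end = t_end, dt = dt),
    cq_divergence = function(e) NULL)
  if (is.null(cyc)) {
    return(list(label = "inconclusive",
                evidence = list(coexisting_cycle = FALSE,
                                cycle_past = FALSE)))
  }
  d <- scaled_min_dist(cyc$mean_orbit)
  list(label = if (d <= radius) "on_invariant_circle" else "off_cycle",
       evidence = list(coexisting_cycle = FALSE, cycle_past = TRUE,
                       ghost_distance = d, radius = radius,
                       period_past = cyc$period))
}

#' Export a trajectory as CSV
#'
#' @param x a `cq_trajectory`.
#' @param file CSV path.
#' @return The path, invisibly.
#' @export
cq_write_trajectory_csv <- function(x, file) {
  utils::write.csv(as.data.frame(x)[, c("t", "W", "Z")], file,
                   row.names = FALSE)
  invisible(file)
}
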