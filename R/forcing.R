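#' Simulate the periodically forced C-Q model
#'
#' Convenience wrapper around [cq_integrate()] for the forced variant
#' (see [cq_params()] for the two drive conventions).
#'
#' @param F forcing amplitude (`>= 0`).
#' @param omega forcing angular frequency (`> 0`).
#' @param initial numeric `c(W, Z)` initial state.
#' @param t_end,dt integration horizon and step.
#' @param drive `"rescaled"` (default) or `"printed"`.
#' @param ... further arguments passed to [cq_integrate()].
#' @return A `cq_trajectory`.
#' @examples
#' tr <- cq_forced_simulate(F = 10, omega = 5.75, t_end = 20)
#' @export
cq_forced_simulate <- function(F, omega, initial = c(0, 0), t_end = 400,
                               dt = 5e-4, drive = "rescaled", ...) {
  params <- cq_params(variant = "forced", F = F, omega = omega,
                      drive = drive)
  cq_integrate(params, initial, t_end = t_end, dt = dt, ...)
}

#' Largest Lyapunov exponent of the forced C-Q model
#'
#' Benettin two-trajectory estimate: after a transient, a companion
#' trajectory offset by `d0` is integrated alongside the fiducial one,
#' renormalised back to separation `d0` every `renorm_interval` time
#' units, and the average logarithmic growth rate is accumulated.  Both
#' copies share the drive phase, so growth along the time direction is
#' excluded.  The estimate is flagged converged when the running
#' estimate's final 20 percent has spread below
#' `0.05 * max(1, |value|)`.
#'
#' @inheritParams cq_forced_simulate
#' @param transient time discarded before measuring.
#' @param horizon measuring time.
#' @param renorm_interval time between renormalisations.
#' @param d0 perturbation magnitude.
#' @param initial initial state of the fiducial trajectory.
#' @return A `cq_lyapunov`: list with `value` (per unit model time),
#'   `series` (running estimates at each renormalisation), `converged`,
#'   `spread` and `settings`.
#' @examples
#' \donttest{
#' cq_largest_lyapunov(F = 10, omega = 15.02, horizon = 500)
#' }
#' @export
cq_largest_lyapunov <- function(F, omega, transient = 200, horizon = 2000,
                                dt = 5e-4, renorm_interval = 0.5, d0 = 1e-8,
                                initial = c(0, 0), drive = "rescaled") {
  params <- cq_params(variant = "forced", F = F, omega = omega,
                      drive = drive)
  res <- cq_lyapunov_cpp(params_for_cpp(params), as.numeric(initial),
                         transient, horizon, dt, renorm_interval, d0, 1e3)
  if (isTRUE(res$diverged))
    stop(errorCondition("trajectory diverged during Lyapunov estimation",
                        class = "cq_divergence"))
  series <- res$series
  n <- length(series)
  tail20 <- series[seq.int(max(1L, ceiling(0.8 * n)), n)]
  spread <- diff(range(tail20))
  structure(list(value = res$value, series = series,
                 converged = spread < 0.05 * max(1, abs(res$value)),
                 spread = spread,
                 settings = list(F = F, omega = omega, transient = transient,
                                 horizon = horizon, dt = dt,
                                 renorm_interval = renorm_interval, d0 = d0,
                                 drive = drive, initial = as.numeric(initial))),
            class = "cq_lyapunov")
}

#' @export
print.cq_lyapunov <- function(x, ...) {
  cat(sprintf("largest Lyapunov exponent: %.5g (%s, spread %.3g)\n",
              x$value, if (x$converged) "converged" else "NOT converged",
              x$spread))
  invisible(x)
}

#' Spike times of a trajectory
#'
#' Spikes are upward crossings of `threshold` with hysteresis: after a
#' spike the detector re-arms only once the potential has fallen below
#' `rearm`.  The defaults suit the C-Q orbit geometry (spikes exceed
#' \eqn{W \approx 4}, rest sits near \eqn{W \approx -4}).
#'
#' @param traj a `cq_trajectory` (or data frame with `t` and `W`).
#' @param threshold spike detection level.
#' @param rearm re-arming level.
#' @return Numeric vector of spike times.
#' @export
cq_detect_spikes <- function(traj, threshold = 2, rearm = 0) {
  t <- traj$t; W <- traj$W
  armed <- TRUE
  out <- numeric(0)
  up <- which(W[-length(W)] < threshold & W[-1] >= threshold)
  down <- which(W[-length(W)] >= rearm & W[-1] < rearm)
  events <- rbind(if (length(up)) cbind(up, 1L),
                  if (length(down)) cbind(down, 0L))
  if (is.null(events) || nrow(events) == 0L) return(numeric(0))
  events <- events[order(events[, 1L]), , drop = FALSE]
  for (i in seq_len(nrow(events))) {
    if (events[i, 2L] == 1L && armed) {
      j <- events[i, 1L]
      frac <- (threshold - W[j]) / (W[j + 1] - W[j])
      out <- c(out, t[j] + frac * (t[j + 1] - t[j]))
      armed <- FALSE
    } else if (events[i, 2L] == 0L) {
      armed <- TRUE
    }
  }
  out
}

#' Classify the firing regime of a forced trajectory
#'
#' Decision rule: no spikes after the transient gives `"quiescent"`; a
#' converged, positive largest Lyapunov exponent (exceeding its own
#' convergence spread) gives `"chaotic"`; otherwise a bimodal
#' interspike-interval distribution (largest gap ratio between sorted
#' ISIs at least `gap_ratio`) gives `"bursting"`, and a unimodal one
#' `"spiking"`.
#'
#' @param traj a post-transient `cq_trajectory` of the forced variant
#'   covering at least 10 forcing periods.
#' @param lle optional `cq_lyapunov` for the same parameters.
#' @param threshold,rearm spike detector settings
#'   (see [cq_detect_spikes()]).
#' @param gap_ratio ISI gap ratio separating intra- from inter-burst
#'   intervals.
#' @return A `cq_regime`: list with `label` (one of `"quiescent"`,
#'   `"spiking"`, `"bursting"`, `"chaotic"`) and `evidence` (spike
#'   count, ISI statistics, LLE).
#' @export
cq_classify_regime <- function(traj, lle = NULL, threshold = 2, rearm = 0,
                               gap_ratio = 3) {
  params <- attr(traj, "params")
  if (is.null(params) || params$variant != "forced")
    stop("`traj` must be a trajectory of the forced variant")
  span <- diff(range(traj$t))
  if (span < 10 * 2 * pi / params$omega)
    stop("trajectory must cover at least 10 forcing periods")
  sp <- cq_detect_spikes(traj, threshold, rearm)
  isi <- diff(sp)
  ev <- list(n_spikes = length(sp),
             isi_mean = if (length(isi)) mean(isi) else NA_real_,
             isi_cv = if (length(isi) > 1) stats::sd(isi) / mean(isi)
                      else NA_real_,
             isi_max_gap_ratio = NA_real_,
             lle = if (!is.null(lle)) lle$value else NA_real_)
  label <- if (length(sp) == 0L) {
    "quiescent"
  } else if (!is.null(lle) && lle$converged && lle$value > 0 &&
             lle$value > lle$spread) {
    "chaotic"
  } else if (length(isi) >= 5L) {
    s <- sort(isi)
    ratios <- s[-1] / s[-length(s)]
    ev$isi_max_gap_ratio <- max(ratios)
    if (max(ratios) >= gap_ratio) "bursting" else "spiking"
  } else {
    "spiking"
  }
  structure(list(label = label, evidence = ev), class = "cq_regime")
}

#' @export
print.cq_regime <- function(x, ...) {
  cat(sprintf("firing regime: %s (spikes: %d, ISI CV: %.3g, LLE: %.3g)\n",
              x$label, x$evidence$n_spikes, x$evidence$isi_cv,
              x$evidence$lle))
  invisible(x)
}

#' Stroboscopic bifurcation diagram with Lyapunov exponents
#'
#' For each grid value of the swept forcing parameter the system is
#' integrated past a transient and sampled stroboscopically at the
#' forcing period (`n_strobe` samples of `W`), and the largest Lyapunov
#' exponent is estimated.  The final state of each grid point seeds the
#' next one (continuation warm start).  Grid points whose trajectory
#' diverges are recorded as `NA` and the sweep continues.
#'
#' @param sweep `"F"` or `"omega"`.
#' @param fixed_other the value of the non-swept forcing parameter.
#' @param grid strictly increasing numeric vector of swept values.
#' @param n_strobe stroboscopic samples kept per grid point.
#' @param transient discarded time before sampling.
#' @param lle_transient,lle_horizon,dt,renorm_interval,d0 Lyapunov
#'   settings per grid point (shorter than the single-point defaults to
#'   keep sweeps desk-scale).
#' @param drive `"rescaled"` (default) or `"printed"`.
#' @param initial initial state of the first grid point.
#' @return A `cq_sweep_diagram`: list with `parameter`, `grid`,
#'   `samples` (list of numeric vectors), `lle`, `lle_converged`.
#' @examples
#' \donttest{
#' sw <- cq_sweep_diagram("F", fixed_other = 15.02, grid = seq(0, 2, 0.5))
#' }
#' @export
cq_sweep_diagram <- function(sweep = c("F", "omega"), fixed_other, grid,
                             n_strobe = 200, transient = 100,
                             lle_transient = 50, lle_horizon = 300,
                             dt = 5e-4, renorm_interval = 0.5, d0 = 1e-8,
                             drive = "rescaled", initial = c(0, 0)) {
  sweep <- match.arg(sweep)
  grid <- as.numeric(grid)
  if (is.unsorted(grid, strictly = TRUE))
    stop("`grid` must be strictly increasing")
  samples <- vector("list", length(grid))
  lle <- rep(NA_real_, length(grid))
  conv <- rep(NA, length(grid))
  state <- as.numeric(initial)
  for (i in seq_along(grid)) {
    F <- if (sweep == "F") grid[i] else fixed_other
    omega <- if (sweep == "omega") grid[i] else fixed_other
    params <- cq_params(variant = "forced", F = F, omega = omega,
                        drive = drive)
    st <- cq_strobe_cpp(params_for_cpp(params), state, transient,
                        as.integer(n_strobe), dt, 1e3)
    if (isTRUE(st$diverged)) {
      samples[[i]] <- NA_real_
      next
    }
    samples[[i]] <- st$samples
    est <- tryCatch(
      cq_largest_lyapunov(F, omega, transient = lle_transient,
                          horizon = lle_horizon, dt = dt,
                          renorm_interval = renorm_interval, d0 = d0,
                          initial = state, drive = drive),
      cq_divergence = function(e) NULL)
    if (!is.null(est)) {
      lle[i] <- est$value
      conv[i] <- est$converged
    }
    state <- c(st$last_W, st$last_Z)
  }
  structure(list(parameter = sweep, fixed_other = fixed_other, grid = grid,
                 samples = samples, lle = lle, lle_converged = conv,
                 settings = list(n_strobe = n_strobe, transient = transient,
                                 lle_transient = lle_transient,
                                 lle_horizon = lle_horizon, dt = dt,
                                 drive = drive)),
            class = "cq_sweep_diagram")
}

#' @export
as.data.frame.cq_sweep_diagram <- function(x, ...) {
  do.call(rbind, lapply(seq_along(x$grid), function(i) {
    s <- x$samples[[i]]
    data.frame(param = x$grid[i], sample_index = seq_along(s),
               W_sample = s, lle = x$lle[i])
  }))
}

#' @export
print.cq_sweep_diagram <- function(x, ...) {
  cat(sprintf(
    "stroboscopic sweep over %s (%d points), %s fixed at %g; LLE in [%.3g, %.3g]\n",
    x$parameter, length(x$grid),
    if (x$parameter == "F") "omega" else "F", x$fixed_other,
    min(x$lle, na.rm = TRUE), max(x$lle, na.rm = TRUE)))
  invisible(x)
}

#' Export a sweep diagram as CSV
#'
#' Columns `param`, `sample_index`, `W_sample`, `lle`.
#'
#' @param x a `cq_sweep_diagram`.
#' @param file CSV path.
#' @return The path, invisibly.
#' @export
cq_write_sweep_csv <- function(x, file) {
  utils::write.csv(as.data.frame(x), file, row.names = FALSE)
  invisible(file)
}

#' Number of distinct stroboscopic values (orbit period detection)
#'
#' Counts distinct values among stroboscopic samples after rounding to
#' `digits`; a period-n orbit yields n distinct values, a chaotic or
#' quasiperiodic band many.
#'
#' @param samples numeric vector of stroboscopic `W` samples.
#' @param digits rounding used to merge equal values.
#' @return Integer count.
#' @export
cq_strobe_period <- function(samples, digits = 3) {
  length(unique(round(samples, digits)))
}
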