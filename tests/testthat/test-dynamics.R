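test_that("integration respects identity, invariance and RK4 order", {
  p <- cq_params(E = 70, v = -10)
  # t_end = 0 returns the single initial sample
  tr0 <- cq_integrate(p, c(1, 2), t_end = 0)
  expect_equal(nrow(tr0), 1L)
  expect_equal(unlist(tr0[1, ]), c(t = 0, W = 1, Z = 2))
  # a trajectory started at the stable node stays there
  eq <- cq_find_equilibria(p)[[1]]
  tr <- cq_integrate(p, c(eq$W, eq$Z), t_end = 50, dt = 1e-3,
                     record_every = 100L)
  expect_lt(max(abs(tr$W - eq$W)), 1e-3)
  expect_lt(max(abs(tr$Z - eq$Z)), 1e-3)
  # observed convergence order of the integrator is ~4
  p3 <- cq_params(E = 70, v = 3)
  ref <- cq_integrate(p3, c(0, 0), t_end = 1, dt = 1e-5)
  err <- vapply(c(2e-3, 1e-3), function(dt) {
    tr <- cq_integrate(p3, c(0, 0), t_end = 1, dt = dt)
    f <- tr[nrow(tr), ]; r <- ref[nrow(ref), ]
    sqrt((f$W - r$W)^2 + (f$Z - r$Z)^2)
  }, numeric(1))
  expect_gt(log2(err[1] / err[2]), 3.5)
})

test_that("divergence raises a typed error carrying the last state", {
  err <- tryCatch(
    cq_integrate(cq_params(E = 70, v = 3), c(40, 0), t_end = 1, dt = 0.05),
    cq_divergence = function(e) e)
  expect_s3_class(err, "cq_divergence")
  expect_true(all(is.finite(err$last_state)))
  expect_true(is.finite(err$last_time))
})

test_that("the adaptive mode agrees with fixed-step RK4", {
  p <- cq_params(E = 70, v = 3)
  a <- cq_integrate(p, c(0, 0), t_end = 5, dt = 1e-3, method = "adaptive",
                    record_every = 100L)
  b <- cq_integrate(p, c(0, 0), t_end = 5, dt = 1e-3, record_every = 100L)
  i <- nrow(a)
  expect_lt(abs(a$W[i] - b$W[i]), 1e-4)
})

test_that("the tonic-firing regime has a limit cycle around its focus", {
  cyc <- cq_detect_limit_cycle(cq_params(E = 70, v = 3), c(0, 0))
  expect_false(is.null(cyc))
  expect_true(cyc$converged)
  expect_equal(cq_winding_number(cyc$mean_orbit, c(1.903, 120.198)), 1)
  # period is invariant under halving the step
  cyc2 <- cq_detect_limit_cycle(cq_params(E = 70, v = 3), c(0, 0),
                                dt = 5e-4)
  expect_lt(abs(cyc$period - cyc2$period) / cyc$period, 1e-3)
})

test_that("no cycle survives past the subcritical side of the Hopf", {
  p <- cq_params(E = 70, v = 4.3)
  ics <- cq_standard_ics()
  for (i in seq_len(nrow(ics))) {
    expect_null(cq_detect_limit_cycle(p, ics[i, ]))
  }
})

test_that("cycles near the Hopf grow with distance from it", {
  amps <- vapply(c(0.01, 0.05, 0.1), function(d) {
    cyc <- cq_detect_limit_cycle(cq_params(E = 70, v = 4.2737 - d),
                                 c(-3, 6))
    expect_false(is.null(cyc))
    cyc$W_max - cyc$W_min
  }, numeric(1))
  expect_true(all(diff(amps) > 0))
  expect_null(cq_detect_limit_cycle(cq_params(E = 70, v = 4.2737 + 0.05),
                                    c(-3, 6)))
})

test_that("the mono-instability window past the fold has a global cycle", {
  cyc <- cq_detect_limit_cycle(cq_params(E = 70, v = 2.35), c(0, 0))
  expect_false(is.null(cyc))
  expect_equal(cq_winding_number(cyc$mean_orbit, c(2.7874, 131.9644)), 1)
})

test_that("the bistable regime parks different states on both equilibria", {
  p <- cq_params(E = 70, v = 1)
  eqs <- as.data.frame(cq_find_equilibria(p))
  stable <- eqs[eqs$stability %in% c("stable_node", "stable_focus"), ]
  expect_equal(nrow(stable), 2L)
  finals <- t(vapply(seq_len(nrow(cq_standard_ics())), function(i) {
    tr <- cq_integrate(p, cq_standard_ics()[i, ], t_end = 100,
                       record_every = 1000L)
    unlist(tr[nrow(tr), c("W", "Z")])
  }, numeric(2)))
  hits <- vapply(seq_len(nrow(stable)), function(k) {
    any(abs(finals[, 1] - stable$W[k]) < 1e-3 &
        abs(finals[, 2] - stable$Z[k]) < 1e-1)
  }, logical(1))
  expect_true(all(hits))
})

test_that("trapping-region verification checks all three conditions", {
  p <- cq_params(E = 70, v = 3)
  rep1 <- cq_verify_trapping_region(p, c(-9, 6.5, -5, 500))
  expect_true(rep1$pass)
  expect_lt(rep1$worst_margin, 0)
  expect_equal(nrow(rep1$interior_equilibria), 1L)
  # a rectangle pierced by the fast outflow fails the inward condition
  rep2 <- cq_verify_trapping_region(p, c(-8, 8, 0, 260))
  expect_true(rep2$conditions[["one_unstable_inside"]])
  expect_false(rep2$conditions[["inward_everywhere"]])
  # equilibrium far outside the box: condition (i) fails, no exception
  rep3 <- cq_verify_trapping_region(cq_params(E = 70, v = -10),
                                    c(-9, 6.5, -5, 500))
  expect_false(rep3$conditions[["one_unstable_inside"]])
  # degenerate rectangle
  rep4 <- cq_verify_trapping_region(p, c(2, 2, 0, 0))
  expect_false(rep4$conditions[["one_unstable_inside"]])
  expect_false(rep4$pass)
})

test_that("the upper fold at tau = 1 is a saddle-node on invariant circle", {
  fixed <- cq_params(E = 70)
  sn <- cq_find_saddle_node("v", fixed, c(0, 6))[[1]]
  res <- cq_classify_saddle_node_globality(fixed, sn)
  expect_identical(res$label, "on_invariant_circle")
  expect_lt(res$evidence$ghost_distance, 0.5)
  expect_error(cq_classify_saddle_node_globality(fixed, "not a point"),
               "saddle-node")
})

test_that("the fold-born cycle has the hallmarks of an infinite-period onset", {
  # period scales like offset^(-1/2): quartering the offset doubles it
  fixed <- cq_params(E = 70)
  sn <- cq_find_saddle_node("v", fixed, c(0, 6))[[1]]
  T_at <- function(off) {
    cyc <- cq_detect_limit_cycle(
      cq_params(E = 70, v = sn$critical_value + off),
      c(sn$W_star + 0.05, sn$Z_star), t_end = 600)
    cyc$period
  }
  ratio <- T_at(0.0025) / T_at(0.01)
  expect_gt(ratio, 1.7)
  expect_lt(ratio, 2.3)
})

test_that("fast-recovery cycles past the fold grow with v", {
  amps <- vapply(c(2.34, 2.36, 2.40, 2.45, 2.50), function(v) {
    cyc <- cq_detect_limit_cycle(cq_params(E = 70, v = v, tau = 0.152),
                                 c(-3.85, 12.4), t_end = 400)
    expect_false(is.null(cyc))
    cyc$W_max - cyc$W_min
  }, numeric(1))
  expect_true(all(diff(amps) >= 0))
})

test_that("trajectories export as t/W/Z CSV", {
  tr <- cq_integrate(cq_params(E = 70, v = 3), c(0, 0), t_end = 1,
                     record_every = 100L)
  f <- tempfile(fileext = ".csv")
  cq_write_trajectory_csv(tr, f)
  d <- utils::read.csv(f)
  expect_identical(names(d), c("t", "W", "Z"))
  expect_equal(nrow(d), nrow(tr))
})
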