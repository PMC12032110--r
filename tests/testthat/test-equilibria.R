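test_that("steady-state cubic coefficients and roots match hand values", {
  cub <- cq_steady_state_cubic(cq_params(E = 70, v = 3))
  expect_equal(cub$coefficients, c(25, 0, -5, -1))
  expect_equal(cub$alpha, 115)

  r <- cq_steady_state_roots(cq_params(E = 70, v = -10))
  expect_length(r, 1)
  expect_lt(abs(as.numeric(r) + 15.3187), 1e-4)

  # h = -W^2 (W + 5) at v = 3, E = 45: double root at 0
  r <- cq_steady_state_roots(cq_params(E = 45, v = 3))
  expect_lt(max(abs(as.numeric(r) - c(-5, 0))), 1e-6)
  expect_equal(attr(r, "multiplicity"), c(1L, 2L))

  r <- cq_steady_state_roots(cq_params(E = 70, v = 1.5))
  expect_lt(max(abs(as.numeric(r) - c(-5.8469, -2.7745, 3.6215))), 1e-4)
})

test_that("roots agree with an independent companion-matrix solve", {
  set.seed(1)
  for (i in 1:1000) {
    v <- runif(1, -12, 6); E <- runif(1, 0, 200)
    mine <- as.numeric(cq_steady_state_roots(cq_params(E = E, v = v)))
    ref <- companion_real_roots(E, v)
    expect_length(mine, length(ref))
    expect_lt(max(abs(mine - ref)), 1e-7)
  }
})

test_that("roots agree with the closed-form radical branches at E = 70", {
  set.seed(2)
  for (i in 1:100) {
    v <- runif(1, -12, 6)
    mine <- as.numeric(cq_steady_state_roots(cq_params(E = 70, v = v)))
    ref <- cardano_roots_E70(v)
    expect_length(mine, length(ref))
    expect_lt(max(abs(mine - ref)), 1e-6)
  }
})

test_that("the root count follows the fold structure of the v-sweep", {
  sn <- cq_find_saddle_node("v", cq_params(E = 70), c(-12, 6))
  v1 <- sn[[1]]$critical_value  # ~ -9.359
  v4 <- sn[[2]]$critical_value  # ~  2.3304
  count <- function(v) length(cq_steady_state_roots(cq_params(E = 70, v = v)))
  expect_equal(count(v1 - 1e-3), 1L)
  expect_equal(count(v1 + 1e-3), 3L)
  expect_equal(count(v4 - 1e-3), 3L)
  expect_equal(count(v4 + 1e-3), 1L)
  # at the endpoints themselves: two entries, one a double root
  r <- cq_steady_state_roots(cq_params(E = 70, v = v4))
  expect_length(r, 2)
  expect_equal(sort(attr(r, "multiplicity")), c(1L, 2L))
})

test_that("every printed equilibrium instance reproduces", {
  for (case in printed_instances()) {
    eqs <- cq_find_equilibria(cq_params(E = 70, v = case$v))
    eq <- eqs[[case$idx]]
    # the root itself at the printed precision (absolute)
    expect_lt(abs(eq$W - case$W), 1e-3)
    # Z and eigenvalues evaluated AT the printed root match the printed
    # values (the quoted values inherit the four-decimal rounding of W;
    # Z values quoted to one decimal get the matching coarser band)
    Z_tol <- if (case$Z > 1000) 5e-2 else 2e-3
    expect_lt(abs(5 * (case$W + case$v)^2 - case$Z), Z_tol)
    lam <- cq_eigenvalues_at(case$W, cq_params(E = 70, v = case$v))
    if (case$v == -5 && case$idx == 1) {
      # published as +404.5919; truly negative (sign typo): assert ours
      expect_lt(Re(lam[2]), 0)
      expect_lt(abs(Re(lam[2]) + 404.5919), 5e-3)
      expect_lt(abs(Re(lam[1]) + 0.578), 1e-3)
    } else {
      expect_lt(max(Mod(sort(lam) - sort(as.complex(case$lambda)))), 1e-3)
    }
    expect_identical(eq$stability, case$stability)
    # full-precision values stay within the rounding-amplified envelope
    expect_lt(abs(eq$Z - case$Z), 5e-2)
  }
})

test_that("equilibria satisfy their defining residuals", {
  set.seed(3)
  for (i in 1:50) {
    p <- cq_params(E = runif(1, 0, 200), v = runif(1, -12, 6),
                   tau = runif(1, 0.2, 5))
    for (eq in cq_find_equilibria(p)) {
      f <- cq_vector_field(c(eq$W, eq$Z), p)
      expect_lt(max(abs(f)), 1e-9 * (1 + abs(p$E) + 5 * p$v^2))
      expect_equal(eq$Z, 5 * (eq$W + p$v)^2)
      # eigenvalues solve the characteristic polynomial
      J <- cq_jacobian(c(eq$W, eq$Z), p)
      for (lam in eq$eigenvalues) {
        res <- lam^2 - sum(diag(J)) * lam + det(J)
        expect_lt(Mod(res), 1e-8 * (1 + Mod(lam)^2))
      }
    }
  }
})

test_that("eigenvalues satisfy trace/determinant identities", {
  set.seed(4)
  for (i in 1:1000) {
    W <- runif(1, -16, 8); v <- runif(1, -12, 6); tau <- runif(1, 0.1, 10)
    p <- cq_params(E = 70, v = v, tau = tau)
    lam <- cq_eigenvalues_at(W, p)
    J <- cq_jacobian(c(W, 0), p)
    tr <- sum(diag(J)); dt <- det(J)
    expect_lt(Mod(sum(lam) - tr), 1e-10 * max(1, abs(tr)))
    expect_lt(Mod(prod(lam) - dt), 1e-10 * max(1, abs(dt)))
    # ordering: descending real part, then descending imaginary part
    expect_true(Re(lam[1]) > Re(lam[2]) ||
                (Re(lam[1]) == Re(lam[2]) && Im(lam[1]) >= Im(lam[2])))
  }
})

test_that("stability classification covers all classes and rejects junk", {
  expect_identical(cq_classify_stability(c(-674.3637, -0.6240)),
                   "stable_node")
  expect_identical(cq_classify_stability(c(16.3020, 1.8338)),
                   "unstable_node")
  expect_identical(cq_classify_stability(c(29.8102, -2.3875)), "saddle")
  expect_identical(
    cq_classify_stability(complex(real = c(0.4509, 0.4509),
                                  imaginary = c(7.0355, -7.0355))),
    "unstable_focus")
  expect_identical(
    cq_classify_stability(complex(real = c(-5.17, -5.17),
                                  imaginary = c(5.81, -5.81))),
    "stable_focus")
  expect_identical(cq_classify_stability(c(0, -1), zero_tol = 1e-6),
                   "non_hyperbolic")
  expect_error(
    cq_classify_stability(complex(real = c(1, 2), imaginary = c(3, 1))),
    "conjugate")
})

test_that("the equilibrium table exports with the documented columns", {
  eqs <- cq_find_equilibria(cq_params(E = 70, v = 1.5))
  d <- as.data.frame(eqs)
  expect_identical(names(d), c("E", "v", "tau", "W", "Z", "re_lambda1",
                               "im_lambda1", "re_lambda2", "im_lambda2",
                               "stability"))
  expect_equal(nrow(d), 3)
  f <- tempfile(fileext = ".csv")
  cq_write_equilibria_csv(eqs, f)
  expect_equal(nrow(utils::read.csv(f)), 3)
})
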