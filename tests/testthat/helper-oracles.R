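# Independent oracles used across the test files.

# Real roots of the steady-state cubic via the companion matrix of the
# monic polynomial -- fully independent of the polyroot-based solver.
companion_real_roots <- function(E, v, tol = 1e-6) {
  # -W^3 - 5W^2 + (30 - 10v)W + (E - 5v^2) = 0, monic form
  b <- c(5, -(30 - 10 * v), -(E - 5 * v^2))  # W^3 + b1 W^2 + b2 W + b3
  C <- rbind(c(-b[1], -b[2], -b[3]),
             c(1, 0, 0),
             c(0, 1, 0))
  z <- eigen(C, only.values = TRUE)$values
  sort(Re(z[abs(Im(z)) < tol * (1 + Mod(z))]))
}

# Closed-form (Cardano) equilibrium branches at E = 70, transcribed from
# the published radical expressions and evaluated in complex arithmetic;
# returns the real roots.
cardano_roots_E70 <- function(v, tol = 1e-6) {
  q2 <- 25 * v / 3 - 5 * v^2 / 2 + 145 / 27          # -q/2
  p3 <- 10 * v / 3 - 115 / 9                          # p/3
  s <- sqrt(as.complex(p3^3 + q2^2))
  P1 <- (q2 + s)^(1 / 3)
  P2 <- p3 / P1
  W1 <- P1 - P2 - 5 / 3
  W2 <- (P2 - P1) / 2 - 5 / 3 - sqrt(3) * (P1 + P2) * 1i / 2
  W3 <- (P2 - P1) / 2 - 5 / 3 + sqrt(3) * (P1 + P2) * 1i / 2
  W <- c(W1, W2, W3)
  sort(Re(W[abs(Im(W)) < tol * (1 + Mod(W))]))
}

# Centered finite-difference Jacobian of the vector field.
fd_jacobian <- function(state, params, h = 1e-4) {
  J <- matrix(0, 2, 2)
  for (j in 1:2) {
    e <- c(0, 0); e[j] <- h
    J[, j] <- (cq_vector_field(state + e, params) -
               cq_vector_field(state - e, params)) / (2 * h)
  }
  J
}

# Printed equilibrium instances of the autonomous model at E = 70: the
# coordinates and eigenvalues quoted to four decimals, with the published
# sign typo at (v = -5, lower branch) corrected to the computed sign.
printed_instances <- function() {
  list(
    list(v = -10, idx = 1, W = -15.3187, Z = 3205.2,
         lambda = c(-0.6240, -674.3637), stability = "stable_node"),
    list(v = -5, idx = 1, W = -12.0301, Z = 1450.1,
         lambda = c(-0.578, -404.5919), stability = "stable_node"),
    list(v = -5, idx = 2, W = 0.7251, Z = 91.3739,
         lambda = c(29.8102, -2.3875), stability = "saddle"),
    list(v = -5, idx = 3, W = 6.3049, Z = 8.5138,
         lambda = c(-1.1481, -89.1072), stability = "stable_node"),
    list(v = 1.5, idx = 1, W = -5.8469, Z = 94.4777,
         lambda = c(-0.3976, -73.1611), stability = "stable_node"),
    list(v = 1.5, idx = 2, W = -2.7745, Z = 8.1218,
         lambda = c(8.2799, -2.3734), stability = "saddle"),
    list(v = 1.5, idx = 3, W = 3.6215, Z = 131.1488,
         lambda = complex(real = c(-5.1729, -5.1729),
                          imaginary = c(5.8139, -5.8139)),
         stability = "stable_focus"),
    list(v = 2.1, idx = 1, W = -4.7882, Z = 36.1321,
         lambda = c(-0.3014, -39.4792), stability = "stable_node"),
    list(v = 2.1, idx = 2, W = -3.2722, Z = 6.8703,
         lambda = c(1.9084, -5.0303), stability = "saddle"),
    list(v = 2.1, idx = 3, W = 3.0604, Z = 133.1486,
         lambda = complex(real = c(0.4509, 0.4509),
                          imaginary = c(7.0355, -7.0355)),
         stability = "unstable_focus"),
    list(v = 2.35, idx = 1, W = 2.7874, Z = 131.9644,
         lambda = complex(real = c(2.8456, 2.8456),
                          imaginary = c(6.0486, -6.0486)),
         stability = "unstable_focus"),
    list(v = 3, idx = 1, W = 1.9030, Z = 120.1970,
         lambda = c(16.3020, 1.8338), stability = "unstable_node"),
    list(v = 4.5, idx = 1, W = -3.3178, Z = 6.9880,
         lambda = complex(real = c(-2.0117, -2.0117),
                          imaginary = c(3.2861, -3.2861)),
         stability = "stable_focus"),
    list(v = 5, idx = 1, W = -3.6494, Z = 9.1206,
         lambda = c(-2.9200, -8.0344), stability = "stable_node"))
}
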