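# Independent oracles and random fixtures for the property tests.

# Nonzero-equilibrium oracle: real roots of the therapy quadratic
# (t1+t2) x^2 - (t1+2t2+e) x + t2 = 0 via base R's polyroot (companion-matrix
# eigenvalues), independent of the package's closed-form solver.
oracle_quad_roots <- function(t1, t2, e) {
  s <- t1 + t2
  if (s == 0) {
    b <- t1 + 2 * t2 + e
    if (b == 0) return(numeric(0))
    return(t2 / b)
  }
  r <- polyroot(c(t2, -(t1 + 2 * t2 + e), s))
  sort(Re(r[abs(Im(r)) < 1e-8]))
}

# Bracketing oracle: sign scan of the quadratic on a uniform grid followed by
# bisection refinement of each bracket.
oracle_scan_roots <- function(t1, t2, e, lo = -50, hi = 50, step = 1e-4) {
  s <- t1 + t2
  f <- function(x) s * x^2 - (t1 + 2 * t2 + e) * x + t2
  grid <- seq(lo, hi, by = step)
  vals <- f(grid)
  idx <- which(vals[-length(vals)] * vals[-1L] < 0)
  exact <- grid[vals == 0]
  refined <- vapply(idx, function(i) {
    uniroot(f, c(grid[i], grid[i + 1L]), tol = 1e-12)$root
  }, numeric(1))
  sort(c(exact, refined))
}

# Reduced on-simplex flow under therapy and its derivative (hand-expanded,
# independent of the package internals).
oracle_flow <- function(x, t1, t2, e = 0) {
  x * ((1 - x) * (t2 - (t1 + t2) * x) - e * x)
}

oracle_flow_deriv <- function(x, t1, t2, e = 0, h = 1e-6) {
  (oracle_flow(x + h, t1, t2, e) - oracle_flow(x - h, t1, t2, e)) / (2 * h)
}

random_payoff <- function() {
  payoff_matrix(runif(1, -5, 5), runif(1, -5, 5), runif(1, -5, 5),
    runif(1, -5, 5))
}

expect_converges_to <- function(x0, t, therapy, x_expected, tol,
                                control = sim_control()) {
  traj <- simulate_game(x0, t, therapy = therapy, control = control)
  expect_true(traj$converged)
  expect_lt(abs(steady_state_value(traj)[["x"]] - x_expected), tol)
  invisible(traj)
}
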