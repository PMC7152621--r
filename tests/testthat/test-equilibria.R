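test_that("baseline equilibria and their stability follow the cubic", {
  a1 <- baseline_equilibria(t_params(-1, 2))
  expect_equal(a1$equilibria$x, c(0, 1, 2))
  expect_identical(a1$equilibria$stability, c("unstable", "stable", "unstable"))

  a3 <- baseline_equilibria(t_params(1, 2))
  expect_equal(a3$equilibria$x, c(0, 2 / 3, 1), tolerance = 1e-12)
  expect_identical(a3$equilibria$stability, c("unstable", "stable", "unstable"))

  b3 <- baseline_equilibria(t_params(-3, -1))
  expect_equal(b3$equilibria$x, c(0, 0.25, 1))
  expect_identical(b3$equilibria$stability, c("stable", "unstable", "stable"))

  # derivative-sign oracle across random parameters
  set.seed(9)
  for (i in 1:200) {
    t1 <- runif(1, -8, 8); t2 <- runif(1, -8, 8)
    if (abs(t1 + t2) < 0.05 || abs(t1) < 1e-3 || abs(t2) < 1e-3) next
    eq <- baseline_equilibria(t_params(t1, t2))
    for (k in seq_len(nrow(eq$equilibria))) {
      d <- oracle_flow_deriv(eq$equilibria$x[k], t1, t2)
      expected <- if (d < 0) "stable" else "unstable"
      expect_identical(eq$equilibria$stability[k], expected)
    }
  }
})

test_that("degenerate parameter sums drop the interior equilibrium with a flag", {
  eq <- baseline_equilibria(t_params(1, -1))
  expect_equal(eq$equilibria$x, c(0, 1))
  expect_match(eq$flags, "degenerate")
})

test_that("therapy equilibria match the reference scenarios", {
  a1 <- therapy_equilibria(t_params(-1, 2), 18)
  nz <- a1$equilibria[a1$equilibria$source == "therapy_quadratic", ]
  expect_equal(nz$x, c(0.0957, 20.904), tolerance = 1e-3)
  expect_equal(nz$z, nz$x) # z_eq = (j/l) x_eq with j = l = 1
  expect_identical(nz$stability, c("stable", "saddle"))

  a3 <- therapy_equilibria(t_params(1, 2), 16)
  nz <- a3$equilibria[a3$equilibria$source == "therapy_quadratic", ]
  expect_equal(nz$x, c(0.0965, 6.904), tolerance = 1e-3)

  # e = 0 reduces to the nonzero baseline equilibria
  e0 <- therapy_equilibria(t_params(-1, 2), 0)
  expect_equal(e0$equilibria$x[e0$equilibria$source == "therapy_quadratic"],
    c(1, 2))
})

test_that("the quasi-steady state z scales with j/l", {
  eq <- therapy_equilibria(t_params(-1, 2),
    therapy_params(w = 9, j = 4, l = 2)) # e = 18 again
  nz <- eq$equilibria[eq$equilibria$source == "therapy_quadratic", ]
  expect_equal(nz$x, sort(oracle_quad_roots(-1, 2, 18)), tolerance = 1e-10)
  expect_equal(nz$z, 2 * nz$x, tolerance = 1e-12)
})

test_that("a complex root pair leaves only the origin, flagged", {
  eq <- therapy_equilibria(t_params(-3, -1), 2)
  expect_equal(eq$equilibria$x, 0)
  expect_match(eq$flags, "complex pair")
})

test_that("origin stability is set by t2 alone, with or without therapy", {
  expect_identical(origin_stability(t_params(3, -1)), "stable")
  expect_identical(origin_stability(t_params(-1, 2)), "unstable")
  expect_identical(origin_stability(t_params(1, 0)), "marginal")
  # flip happens exactly at t2 = 0
  for (t2 in c(-1e-12, 1e-12)) {
    expect_identical(origin_stability(t_params(1, t2)),
      if (t2 < 0) "stable" else "unstable")
  }
  # the linearization coefficient at x = 0 equals t2 for every e
  set.seed(14)
  for (i in 1:100) {
    t2 <- runif(1, -5, 5); e <- runif(1, -20, 20)
    d <- oracle_flow_deriv(0, runif(1, -5, 5), t2, e)
    expect_lt(abs(d - t2), 1e-6)
  }
})

test_that("Vieta product and sum match the closed forms and the roots", {
  expect_equal(vieta_diagnostics(t_params(-1, 2), 0), c(P = 2, S = 3))
  expect_equal(vieta_diagnostics(t_params(-1, 2), 18), c(P = 2, S = 21))
  set.seed(23)
  for (i in 1:200) {
    t1 <- runif(1, -8, 8); t2 <- runif(1, -8, 8)
    if (abs(t1 + t2) < 0.1) next
    e <- runif(1, -20, 20)
    v <- vieta_diagnostics(t_params(t1, t2), e)
    roots <- oracle_quad_roots(t1, t2, e)
    if (length(roots) == 2L && all(abs(roots) < 100)) {
      expect_lt(abs(prod(roots) - v[["P"]]), 1e-9 * max(1, abs(v[["P"]])))
      expect_lt(abs(sum(roots) - v[["S"]]), 1e-9 * max(1, abs(v[["S"]])))
    }
  }
})

test_that("the root product is invariant in e", {
  for (t in list(t_params(-1, 2), t_params(1, 2), t_params(-4, 1))) {
    products <- vapply(seq(-25, 25, length.out = 50), function(e) {
      eq <- therapy_equilibria(t, e)
      nz <- eq$equilibria$x[eq$equilibria$source == "therapy_quadratic"]
      if (length(nz) == 2L) prod(nz) else NA_real_
    }, numeric(1))
    products <- products[!is.na(products)]
    expect_gte(length(products), 35)
    expect_lt(max(products) - min(products), 1e-9 * max(1, abs(products[1])))
  }
})

test_that("closed-form roots agree with the sign-scan bracketing oracle", {
  set.seed(31)
  n_checked <- 0L
  for (i in 1:100) {
    t1 <- runif(1, -10, 10); t2 <- runif(1, -10, 10)
    if (abs(t1 + t2) < 0.05) next
    e <- runif(1, -20, 20)
    scanned <- oracle_scan_roots(t1, t2, e, lo = -50, hi = 50, step = 1e-3)
    eq <- therapy_equilibria(t_params(t1, t2), e)
    computed <- eq$equilibria$x[eq$equilibria$source == "therapy_quadratic"]
    for (r in scanned) {
      expect_lt(min(abs(computed - r)), 1e-8)
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 100)
})

test_that("Jacobian stability relates exactly to the reduced-map derivative", {
  # det(J) = -l * h'(x*) identically, so a saddle <=> h' > 0; with h' < 0 the
  # equilibrium can still lose stability through a positive trace when the
  # stem-cell compartment relaxes slowly.
  set.seed(37)
  disagreements <- 0L
  n <- 0L
  for (i in 1:500) {
    t1 <- runif(1, -10, 10); t2 <- runif(1, -10, 10)
    if (abs(t1 + t2) < 0.05) next
    e <- runif(1, -15, 15)
    eq <- therapy_equilibria(t_params(t1, t2), e)
    nz <- eq$equilibria[eq$equilibria$source == "therapy_quadratic", ]
    for (k in seq_len(nrow(nz))) {
      x <- nz$x[k]
      if (abs(x) > 50) next
      hprime <- oracle_flow_deriv(x, t1, t2, e)
      scale <- max(1, abs(x))^2
      if (abs(hprime) < 1e-4 * scale) next # too close to non-hyperbolic
      n <- n + 1L
      if (hprime > 0) {
        expect_identical(nz$stability[k], "saddle")
      } else if (nz$stability[k] != "stable") {
        # must be the slow-z destabilization: trace > 0
        fx <- oracle_flow_deriv(x, t1, t2, 0) - e * x # d/dx at fixed z
        expect_gt(fx - 1, 0) # trace of [[fx, -xe], [1, -1]]
        disagreements <- disagreements + 1L
      }
    }
  }
  expect_gt(n, 400)
  # the reduction is reliable for most of the sampled space
  expect_lt(disagreements / n, 0.2)
})

test_that("the interior-root exclusion condition clears the bistable interval", {
  t <- t_params(-3, -1)
  expect_equal(interior_exclusion_threshold(t), 1) # -2*sqrt(4) - (-5)
  above <- no_interior_root_condition(t, 2)
  expect_true(as.logical(above))
  expect_length(attr(above, "roots"), 0) # complex pair at e just above
  below <- no_interior_root_condition(t, 0.5)
  expect_false(as.logical(below))
  expect_gt(length(attr(below, "roots_in_01")), 0)
  far <- no_interior_root_condition(t, 10)
  expect_true(as.logical(far))
  expect_equal(attr(far, "roots"), c(-1, -0.25), tolerance = 1e-9)
  expect_length(attr(far, "roots_in_01"), 0)

  # negative radicand t2*(t1+t2) outside the bistable-compatible regions
  expect_error(no_interior_root_condition(t_params(-4, 1), 5), "bistable")
})

test_that("the equilibrium JSON report carries the full analysis", {
  eq <- therapy_equilibria(t_params(-3, -1), 2)
  path <- tempfile(fileext = ".json")
  equilibrium_report(eq, path)
  rep <- jsonlite::read_json(path)
  expect_equal(rep$t1, -3)
  expect_equal(rep$e, 2)
  expect_true(rep$exclusion_condition)
  expect_equal(length(rep$equilibria), 1)
  expect_identical(rep$equilibria[[1]]$stability, "stable")

  # where the radicand is negative the condition is null
  rep2 <- equilibrium_report(therapy_equilibria(t_params(-4, 1), 12))
  expect_null(rep2$exclusion_condition)
  unlink(path)
})
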