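# Closed-form equilibria, stability classification, Vieta diagnostics and the
# interior-root exclusion condition for the bistable regime.

# Roots of A x^2 + B x + C = 0 with the cancellation-safe formulation
# (sign-matched numerator); needed because the therapy quadratic is routinely
# solved at e values where one root is within ~1e-2 of zero.
solve_quadratic <- function(A, B, C) {
  if (A == 0) {
    if (B == 0) return(numeric(0))
    return(-C / B)
  }
  disc <- B^2 - 4 * A * C
  if (disc < 0) return(numeric(0))
  if (B == 0) {
    r <- sqrt(-C / A)
    return(sort(c(-r, r)))
  }
  q <- -(B + sign(B) * sqrt(disc)) / 2
  roots <- if (q == 0) c(0, -B / A) else c(q / A, C / q)
  sort(unique(roots))
}

stability_from_deriv <- function(d, tol = 0) {
  if (d < -tol) "stable" else if (d > tol) "unstable" else "marginal"
}

new_equilibrium_set <- function(df, t, e, therapy = NULL, flags = character(0)) {
  P <- if (t$sum != 0) t$t2 / t$sum else NA_real_
  S <- if (t$sum != 0) (t$t1 + 2 * t$t2 + e) / t$sum else NA_real_
  nz <- df$x[df$source != "origin"]
  structure(
    list(
      equilibria = df, t = t, e = e, therapy = therapy,
      vieta = c(P = P, S = S),
      product_check = if (length(nz) == 2L) abs(prod(nz) - P) else NA_real_,
      sum_check = if (length(nz) == 2L) abs(sum(nz) - S) else NA_real_,
      flags = flags
    ),
    class = "equilibrium_set"
  )
}

#' @export
print.equilibrium_set <- function(x, ...) {
  cat(sprintf("Equilibria for t1 = %g, t2 = %g, e = %g:\n", x$t$t1, x$t$t2, x$e))
  print(x$equilibria, row.names = FALSE)
  if (!anyNA(x$vieta)) {
    cat(sprintf("Vieta: root product P = %g, root sum S = %g\n",
      x$vieta[["P"]], x$vieta[["S"]]))
  }
  for (f in x$flags) cat("note:", f, "\n")
  invisible(x)
}

#' Equilibria of the baseline replicator dynamics
#'
#' The on-simplex baseline flow is the cubic
#' `x (1 - x) (t2 - (t1 + t2) x)`, with fixed points at x = 0, x = 1 and the
#' coexistence point `x3 = t2/(t1+t2)` (omitted when `t1 + t2 = 0`). Each
#' fixed point is classified from the sign of the flow derivative there:
#' x = 0 is stable iff `t2 < 0`, x = 1 iff `t1 < 0`, and a feasible x3 iff
#' `t1 + t2 > 0`. Non-hyperbolic points (zero derivative) are reported as
#' `"marginal"`, never silently as stable.
#'
#' @param t reduced parameters ([t_params()] or a [payoff_matrix()]).
#'
#' @return An object of class `equilibrium_set` whose `equilibria` data frame
#'   has columns `x`, `z` (all zero here), `stability`, `source`.
#' @export
#' @examples
#' baseline_equilibria(t_params(-1, 2))  # x = 1 attracts; x3 = 2 infeasible
#' baseline_equilibria(t_params(-3, -1)) # bistable with separatrix at 0.25
baseline_equilibria <- function(t) {
  t <- as_t_params(t)
  xs <- c(0, 1)
  sources <- c("origin", "baseline_cubic")
  flags <- character(0)
  if (t$sum != 0) {
    xs <- c(xs, t$t2 / t$sum)
    sources <- c(sources, "baseline_cubic")
  } else {
    flags <- "degenerate: t1 + t2 = 0, interior equilibrium undefined"
  }
  ord <- order(xs)
  xs <- xs[ord]
  sources <- sources[ord]
  stab <- vapply(xs, function(x) {
    stability_from_deriv(reduced_flow_deriv(x, t))
  }, character(1))
  df <- data.frame(x = xs, z = 0, stability = stab, source = sources,
    stringsAsFactors = FALSE)
  new_equilibrium_set(df, t, e = 0, flags = flags)
}

# 2-D (x, z) Jacobian of the therapy system with y eliminated via x + y = 1.
therapy_jacobian <- function(x, z, t, therapy) {
  fx <- (1 - 2 * x) * (t$t2 - t$sum * x) - t$sum * x * (1 - x) - z * therapy$w
  matrix(c(fx, therapy$j, -x * therapy$w, -therapy$l), 2, 2)
}

classify_jacobian <- function(J, tol = 1e-10) {
  ev <- Re(eigen(J, only.values = TRUE)$values)
  scale <- max(abs(J), 1)
  if (any(abs(ev) <= tol * scale)) return("marginal")
  if (all(ev < 0)) return("stable")
  if (all(ev > 0)) return("unstable")
  "saddle"
}

#' Equilibria of the therapy-augmented system
#'
#' Under stem-cell injection the origin (x = 0, z = 0) remains a fixed point
#' and the nonzero equilibria are the real roots of the quadratic
#' `(t1 + t2) x^2 - (t1 + 2 t2 + e) x + t2 = 0`, each paired with the
#' stem-cell quasi-steady state `z = (j/l) x`. When the quadratic has a
#' complex pair the set contains the origin only, flagged accordingly.
#' Stability is classified from the eigenvalues of the 2-D (x, z) Jacobian
#' (y is eliminated via x + y = 1).
#'
#' @param t reduced parameters ([t_params()] or a [payoff_matrix()]).
#' @param therapy a [therapy_params()] or a single number interpreted as the
#'   composite parameter `e` (expanded as `w = e, j = 1, l = 1`).
#'
#' @return An object of class `equilibrium_set`; roots are listed ascending
#'   in x. `vieta` holds the closed-form root product and sum, and
#'   `product_check` / `sum_check` their deviations from the computed roots.
#' @export
#' @examples
#' therapy_equilibria(t_params(-1, 2), therapy = 18)
therapy_equilibria <- function(t, therapy) {
  t <- as_t_params(t)
  therapy <- as_therapy_params(therapy)
  e <- therapy$e
  flags <- character(0)

  roots <- solve_quadratic(t$sum, -(t$t1 + 2 * t$t2 + e), t$t2)
  if (t$sum == 0) {
    flags <- c(flags, "degenerate: t1 + t2 = 0, quadratic reduces to linear")
  }
  if (length(roots) == 0L && t$sum != 0) {
    flags <- c(flags, "no nonzero equilibria: quadratic roots are a complex pair")
  }
  roots <- setdiff(roots, 0)

  xs <- c(0, roots)
  sources <- c("origin", rep("therapy_quadratic", length(roots)))
  zs <- (therapy$j / therapy$l) * xs
  ord <- order(xs)
  xs <- xs[ord]; zs <- zs[ord]; sources <- sources[ord]
  stab <- vapply(seq_along(xs), function(i) {
    classify_jacobian(therapy_jacobian(xs[i], zs[i], t, therapy))
  }, character(1))
  df <- data.frame(x = xs, z = zs, stability = stab, source = sources,
    stringsAsFactors = FALSE)
  new_equilibrium_set(df, t, e = e, therapy = therapy, flags = flags)
}

#' Stability of the cancer-free state
#'
#' The linearization coefficient of the on-simplex flow at x = 0 equals `t2`
#' with and without therapy, so the cancer-free state is stable iff `t2 < 0`,
#' unstable iff `t2 > 0`, and marginal (non-hyperbolic) at `t2 = 0` — therapy
#' cannot change the local stability of x = 0, only relocate the other
#' equilibria.
#'
#' @param t reduced parameters ([t_params()] or a [payoff_matrix()]).
#'
#' @return `"stable"`, `"unstable"` or `"marginal"`.
#' @export
origin_stability <- function(t) {
  t <- as_t_params(t)
  stability_from_deriv(t$t2)
}

#' Vieta diagnostics for the nonzero equilibria
#'
#' Product and sum of the two roots of the therapy quadratic by Vieta's
#' formulas: `P = t2/(t1+t2)` and `S = (t1 + 2 t2 + e)/(t1+t2)`. The product
#' does not depend on e: therapy shifts the root sum but leaves the product
#' fixed, which is the lever the therapy analysis rests on.
#'
#' @param t reduced parameters ([t_params()] or a [payoff_matrix()]).
#' @param e composite therapy parameter (0 for the baseline system).
#'
#' @return Named numeric vector `c(P, S)`.
#' @export
#' @examples
#' vieta_diagnostics(t_params(-1, 2), e = 18) # P = 2 regardless of e
vieta_diagnostics <- function(t, e = 0) {
  t <- as_t_params(t)
  e <- check_finite_scalar(e, "e")
  if (t$sum == 0) {
    stop("degenerate case: t1 + t2 = 0, Vieta formulas undefined", call. = FALSE)
  }
  c(P = t$t2 / t$sum, S = (t$t1 + 2 * t$t2 + e) / t$sum)
}

#' Threshold of the interior-root exclusion condition
#'
#' In the bistable regime (t1 < 0, t2 < 0) the therapy quadratic loses its
#' roots in (0, 1) once `e` exceeds
#' `-2 sqrt(t2 (t1 + t2)) - (t1 + 2 t2)`; the whole interval (0, 1) then
#' becomes the basin of the cancer-free state. The radicand `t2 (t1 + t2)`
#' must be non-negative, which holds throughout the bistable regime.
#'
#' @param t reduced parameters ([t_params()] or a [payoff_matrix()]).
#'
#' @return The threshold value of e.
#' @export
#' @examples
#' interior_exclusion_threshold(t_params(-3, -1)) # 1
interior_exclusion_threshold <- function(t) {
  t <- as_t_params(t)
  rad <- t$t2 * t$sum
  if (rad < 0) {
    stop(paste(
      "negative radicand t2*(t1+t2): the exclusion condition applies to the",
      "bistable regime (t1 < 0, t2 < 0, t1 + t2 < 0)"), call. = FALSE)
  }
  -2 * sqrt(rad) - (t$t1 + 2 * t$t2)
}

#' Interior-root exclusion condition
#'
#' Tests whether `e` strictly exceeds [interior_exclusion_threshold()]. In
#' the bistable regime this guarantees the therapy quadratic has no root in
#' (0, 1), so every interior trajectory converges to the cancer-free state.
#' The condition as stated is a lower bound only; because large e can also
#' produce real roots that lie outside (0, 1), the returned value carries
#' attributes `threshold`, `roots` (real roots of the quadratic, possibly
#' empty) and `roots_in_01` so callers can inspect the full picture.
#'
#' @param t reduced parameters ([t_params()] or a [payoff_matrix()]).
#' @param e composite therapy parameter.
#'
#' @return Logical scalar with attributes `threshold`, `roots`,
#'   `roots_in_01`.
#' @export
#' @examples
#' no_interior_root_condition(t_params(-3, -1), e = 2)   # TRUE
#' no_interior_root_condition(t_params(-3, -1), e = 0.5) # FALSE
no_interior_root_condition <- function(t, e) {
  t <- as_t_params(t)
  e <- check_finite_scalar(e, "e")
  threshold <- interior_exclusion_threshold(t)
  roots <- solve_quadratic(t$sum, -(t$t1 + 2 * t$t2 + e), t$t2)
  structure(
    e > threshold,
    threshold = threshold,
    roots = roots,
    roots_in_01 = roots[roots > 0 & roots < 1]
  )
}

#' JSON report of an equilibrium analysis
#'
#' Assembles (and optionally writes) the structured report
#' `{t1, t2, e, equilibria: [{x, z, stability, source}], vieta: {P, S},
#' exclusion_condition}`; the exclusion condition is `null` outside the
#' bistable regime where its radicand is negative.
#'
#' @param eqset an `equilibrium_set` from [baseline_equilibria()] or
#'   [therapy_equilibria()].
#' @param path optional output path; when given the report is written as JSON.
#'
#' @return The report as a list, invisibly when `path` is given.
#' @export
equilibrium_report <- function(eqset, path = NULL) {
  stopifnot(inherits(eqset, "equilibrium_set"))
  cond <- tryCatch(
    as.logical(no_interior_root_condition(eqset$t, eqset$e)),
    error = function(err) NULL
  )
  report <- list(
    t1 = eqset$t$t1, t2 = eqset$t$t2, e = eqset$e,
    equilibria = lapply(seq_len(nrow(eqset$equilibria)), function(i) {
      as.list(eqset$equilibria[i, c("x", "z", "stability", "source")])
    }),
    vieta = list(P = eqset$vieta[["P"]], S = eqset$vieta[["S"]]),
    exclusion_condition = cond,
    flags = as.list(eqset$flags)
  )
  if (!is.null(path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
      null = "null")
    return(invisible(report))
  }
  report
}
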