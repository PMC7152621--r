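# Domain types and case taxonomy for the two-strategy cancer/healthy cell game.

check_finite_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  as.numeric(x)
}

#' Payoff matrix of the cancer-healthy cell game
#'
#' Constructs the 2x2 payoff matrix of the evolutionary game between
#' cancerous (C) and healthy (H) cells. Payoffs are dimensionless and may be
#' benefits (positive) or costs (negative); they encode, among other things,
#' the immune system's response and the tumour type, and are expected to vary
#' from patient to patient.
#'
#' @param a payoff of a C cell interacting with another C cell.
#' @param b payoff of a C cell interacting with an H cell.
#' @param c payoff of an H cell interacting with a C cell.
#' @param d payoff of an H cell interacting with another H cell.
#'
#' @return An object of class `payoff_matrix`.
#' @seealso [derive_t_params()] for the reduced parameters the dynamics
#'   actually depend on.
#' @export
#' @examples
#' pm <- payoff_matrix(a = 1, b = 3, c = 0, d = 1)
#' derive_t_params(pm)
payoff_matrix <- function(a, b, c, d) {
  structure(
    list(
      a = check_finite_scalar(a, "a"),
      b = check_finite_scalar(b, "b"),
      c = check_finite_scalar(c, "c"),
      d = check_finite_scalar(d, "d")
    ),
    class = "payoff_matrix"
  )
}

#' @export
print.payoff_matrix <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
    dimnames = list(c("C", "H"), c("C", "H"))
  )
  cat("Payoff matrix (row strategy vs column strategy):\n")
  print(m)
  invisible(x)
}

#' Reduced game parameters
#'
#' The replicator dynamics of the two-strategy game depend on the payoffs only
#' through two differences: `t1 = c - a` (advantage of healthy over cancerous
#' cells when meeting a cancerous cell) and `t2 = b - d` (advantage of
#' cancerous over healthy cells when meeting a healthy cell). `t_params()`
#' builds the pair directly; [derive_t_params()] computes it from a payoff
#' matrix.
#'
#' @param t1,t2 finite reduced parameters.
#'
#' @return An object of class `t_params` with fields `t1`, `t2` and their
#'   `sum`.
#' @export
#' @examples
#' t_params(-1, 2)
t_params <- function(t1, t2) {
  t1 <- check_finite_scalar(t1, "t1")
  t2 <- check_finite_scalar(t2, "t2")
  structure(list(t1 = t1, t2 = t2, sum = t1 + t2), class = "t_params")
}

#' @export
print.t_params <- function(x, ...) {
  cat(sprintf("Reduced game parameters: t1 = %g, t2 = %g (t1 + t2 = %g)\n",
    x$t1, x$t2, x$sum))
  invisible(x)
}

#' @rdname t_params
#' @param payoff a [payoff_matrix()].
#' @export
derive_t_params <- function(payoff) {
  stopifnot(inherits(payoff, "payoff_matrix"))
  t_params(payoff$c - payoff$a, payoff$b - payoff$d)
}

# Coerce payoff_matrix / t_params / length-2 numeric to t_params.
as_t_params <- function(t) {
  if (inherits(t, "t_params")) return(t)
  if (inherits(t, "payoff_matrix")) return(derive_t_params(t))
  if (is.numeric(t) && length(t) == 2L) return(t_params(t[[1L]], t[[2L]]))
  stop("expected a `t_params`, a `payoff_matrix`, or two numbers", call. = FALSE)
}

# Canonical payoff matrix realizing given reduced parameters
# (a = 0, b = t2, c = t1, d = 0), used when only (t1, t2) are supplied.
payoff_from_t <- function(t) {
  t <- as_t_params(t)
  payoff_matrix(a = 0, b = t$t2, c = t$t1, d = 0)
}

#' Interior equilibrium of the baseline game
#'
#' The baseline replicator dynamics have fixed points at x = 0 (no cancerous
#' cells), x = 1 (only cancerous cells) and the coexistence point
#' `x3 = t2 / (t1 + t2)`, which may lie outside the feasible interval
#' \[0, 1\]; its location determines the case taxonomy (see
#' [classify_case()]).
#'
#' @param t reduced parameters ([t_params()] or a [payoff_matrix()]).
#'
#' @return The coexistence fixed point as a single number.
#' @export
#' @examples
#' interior_equilibrium(t_params(-1, 2)) # 2, outside [0, 1]
#' interior_equilibrium(t_params(1, 2))  # 2/3, a feasible coexistence point
interior_equilibrium <- function(t) {
  t <- as_t_params(t)
  if (t$sum == 0) {
    stop("degenerate case: t1 + t2 = 0, the interior equilibrium is undefined",
      call. = FALSE)
  }
  t$t2 / t$sum
}

#' Classify the dynamical regime of the baseline game
#'
#' Partitions the reduced parameter plane into six hyperbolic cases plus a
#' degenerate boundary. The family is set by the sign of `t1 + t2` (A for
#' positive, B for negative) and the sub-case by the location of the interior
#' fixed point `x3 = t2/(t1+t2)`:
#'
#' * A1: x3 > 1 (all-cancer state x = 1 attracts the whole interior),
#' * A2: x3 < 0 (cancer-free state x = 0 attracts),
#' * A3: 0 < x3 < 1 (stable coexistence at x3),
#' * B1: x3 < 0 (x = 1 attracts the whole interior),
#' * B2: x3 > 1 (x = 0 attracts),
#' * B3: 0 < x3 < 1 (bistable: x3 is unstable and separates the basins of
#'   x = 0 and x = 1).
#'
#' Boundary parameter sets (`t1 + t2 = 0`, `t1 = 0` or `t2 = 0`, i.e. x3
#' undefined or exactly on 0/1) are labelled `DEGENERATE` rather than forced
#' into a sub-case. Classification uses exact sign tests, not a floating
#' tolerance, since the inputs are user-supplied parameters. The sign pattern
#' of (t1, t2) implied by the classification is recorded alongside the label.
#'
#' @param t reduced parameters ([t_params()] or a [payoff_matrix()]).
#'
#' @return An object of class `case_label`: a list with `label` (one of
#'   `"A1"`, `"A2"`, `"A3"`, `"B1"`, `"B2"`, `"B3"`, `"DEGENERATE"`), `x3`
#'   (`NA` when undefined), `x3_location` (one of `"below_zero"`,
#'   `"interior"`, `"above_one"`, `"undefined"`) and `t_signs`.
#' @export
#' @examples
#' classify_case(t_params(-1, 2))  # A1
#' classify_case(t_params(-3, -1)) # B3, bistable
classify_case <- function(t) {
  t <- as_t_params(t)
  sign_str <- function(v) if (v > 0) ">0" else if (v < 0) "<0" else "=0"
  t_signs <- sprintf("t1%s, t2%s", sign_str(t$t1), sign_str(t$t2))

  if (t$sum == 0 || t$t1 == 0 || t$t2 == 0) {
    x3 <- if (t$sum == 0) NA_real_ else t$t2 / t$sum
    out <- list(label = "DEGENERATE", x3 = x3, x3_location = "undefined",
      t_signs = t_signs, t = t)
    return(structure(out, class = "case_label"))
  }

  x3 <- t$t2 / t$sum
  location <- if (x3 < 0) {
    "below_zero"
  } else if (x3 > 1) {
    "above_one"
  } else {
    "interior"
  }
  label <- if (t$sum > 0) {
    switch(location, above_one = "A1", below_zero = "A2", interior = "A3")
  } else {
    switch(location, below_zero = "B1", above_one = "B2", interior = "B3")
  }
  structure(
    list(label = label, x3 = x3, x3_location = location, t_signs = t_signs,
      t = t),
    class = "case_label"
  )
}

#' @export
print.case_label <- function(x, ...) {
  cat(sprintf("Case %s (%s)", x$label, x$t_signs))
  if (is.na(x$x3)) {
    cat("; interior equilibrium undefined (t1 + t2 = 0)\n")
  } else {
    cat(sprintf("; x3 = %g (%s)\n", x$x3, gsub("_", " ", x$x3_location)))
  }
  invisible(x)
}

#' @export
format.case_label <- function(x, ...) x$label
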