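# Replicator dynamics: right-hand sides, numerical integration, steady states.

#' Stem-cell therapy parameters
#'
#' The therapy couples a stem-cell compartment z to the game: injected stem
#' cells depress the per-capita growth of cancerous cells at rate `w` per unit
#' of z, the cancerous-cell frequency x drives injection at rate `j`, and the
#' standing stem-cell level is cleared (and damps further injection) at rate
#' `l`. At any equilibrium z settles at `(j/l) x`, so the equilibrium
#' structure depends on the three rates only through the composite control
#' parameter `e = w j / l`.
#'
#' Either supply all of `(w, j, l)`, or supply `e` alone, which is expanded to
#' the canonical triple `w = e, j = 1, l = 1` (any triple with the same
#' `w j / l` has the same equilibria).
#'
#' @param w effect of z on the cancerous/healthy growth rates (per unit z).
#' @param j effect of x on the injection rate of stem cells.
#' @param l decay rate of the stem-cell level; must be positive.
#' @param e composite control parameter; shortcut for `w = e, j = 1, l = 1`.
#'
#' @return An object of class `therapy_params` with fields `w`, `j`, `l`, `e`.
#' @export
#' @examples
#' therapy_params(e = 18)
#' therapy_params(w = 9, j = 2, l = 1) # same e = 18, same equilibria
therapy_params <- function(w = NULL, j = 1, l = 1, e = NULL) {
  if (is.null(w) && is.null(e)) {
    stop("supply either `w` (with `j`, `l`) or the composite parameter `e`",
      call. = FALSE)
  }
  if (is.null(w)) {
    e <- check_finite_scalar(e, "e")
    w <- e
    j <- 1
    l <- 1
  } else {
    w <- check_finite_scalar(w, "w")
    j <- check_finite_scalar(j, "j")
    l <- check_finite_scalar(l, "l")
    if (l <= 0) {
      stop("invalid therapy: `l` must be > 0 for a finite stem-cell steady state",
        call. = FALSE)
    }
    e_from_rates <- w * j / l
    if (!is.null(e)) {
      e <- check_finite_scalar(e, "e")
      if (abs(e - e_from_rates) > 1e-12 * max(1, abs(e))) {
        stop("inconsistent therapy: `e` must equal w*j/l when both are given",
          call. = FALSE)
      }
    }
    e <- e_from_rates
  }
  if (l <= 0) stop("invalid therapy: `l` must be > 0", call. = FALSE)
  structure(list(w = w, j = j, l = l, e = e), class = "therapy_params")
}

#' @export
print.therapy_params <- function(x, ...) {
  cat(sprintf("Therapy parameters: w = %g, j = %g, l = %g (e = wj/l = %g)\n",
    x$w, x$j, x$l, x$e))
  invisible(x)
}

as_therapy_params <- function(therapy) {
  if (is.null(therapy)) return(therapy_params(w = 0, j = 0, l = 1))
  if (inherits(therapy, "therapy_params")) return(therapy)
  if (is.numeric(therapy) && length(therapy) == 1L) {
    return(therapy_params(e = therapy))
  }
  stop("expected a `therapy_params`, a single number `e`, or NULL", call. = FALSE)
}

#' Average fitnesses of the two strategies
#'
#' Frequency-weighted average payoffs: `fC = x a + y b` for cancerous cells,
#' `fH = x c + y d` for healthy cells, and the population mean
#' `fCH = x fC + y fH`. A strategy whose fitness exceeds the population mean
#' increases in frequency under the replicator dynamics.
#'
#' @param x,y frequencies of cancerous and healthy cells.
#' @param payoff a [payoff_matrix()].
#'
#' @return Named numeric vector `c(fC, fH, fCH)`.
#' @export
#' @examples
#' fitnesses(0.5, 0.5, payoff_matrix(1, 3, 0, 1))
fitnesses <- function(x, y, payoff) {
  stopifnot(inherits(payoff, "payoff_matrix"))
  x <- check_finite_scalar(x, "x")
  y <- check_finite_scalar(y, "y")
  fC <- x * payoff$a + y * payoff$b
  fH <- x * payoff$c + y * payoff$d
  c(fC = fC, fH = fH, fCH = x * fC + y * fH)
}

#' Baseline replicator right-hand side
#'
#' Time derivatives of the cancerous and healthy frequencies without therapy:
#' `dx = x (fC - fCH)`, `dy = y (fH - fCH)`. On the simplex `x + y = 1` the
#' two derivatives sum to zero and `dx` reduces to the cubic
#' `x (1 - x) (t2 - (t1 + t2) x)`, whose roots are the baseline equilibria.
#'
#' @param x,y frequencies of cancerous and healthy cells.
#' @param payoff a [payoff_matrix()].
#'
#' @return Named numeric vector `c(dx, dy)`.
#' @export
baseline_rhs <- function(x, y, payoff) {
  f <- fitnesses(x, y, payoff)
  c(dx = x * (f[["fC"]] - f[["fCH"]]), dy = y * (f[["fH"]] - f[["fCH"]]))
}

# Reduced (on-simplex) baseline flow and its derivative; used for equilibria.
reduced_flow <- function(x, t, e = 0) {
  x * ((1 - x) * (t$t2 - t$sum * x) - e * x)
}

reduced_flow_deriv <- function(x, t, e = 0) {
  (1 - 2 * x) * (t$t2 - t$sum * x) - t$sum * x * (1 - x) - 2 * e * x
}

#' Therapy-augmented right-hand side
#'
#' Time derivatives of `(x, y, z)` under stem-cell injection:
#' `dx = x (fC - fCH - z w)`, `dy = y (fH - fCH) + (1 - y) z w`,
#' `dz = x j - z l`. With `w = 0` the `(dx, dy)` components reduce exactly to
#' [baseline_rhs()]; on the simplex `dx + dy = 0` for every z.
#'
#' @param state numeric vector `c(x, y, z)` (names optional).
#' @param payoff a [payoff_matrix()].
#' @param therapy a [therapy_params()], a single number interpreted as `e`,
#'   or `NULL` for no therapy.
#'
#' @return Named numeric vector `c(dx, dy, dz)`.
#' @export
therapy_rhs <- function(state, payoff, therapy) {
  therapy <- as_therapy_params(therapy)
  state <- unlist(state, use.names = FALSE)
  stopifnot(length(state) == 3L, all(is.finite(state)))
  x <- state[[1L]]; y <- state[[2L]]; z <- state[[3L]]
  f <- fitnesses(x, y, payoff)
  c(
    dx = x * (f[["fC"]] - f[["fCH"]] - z * therapy$w),
    dy = y * (f[["fH"]] - f[["fCH"]]) + (1 - y) * z * therapy$w,
    dz = x * therapy$j - z * therapy$l
  )
}

#' Integration settings for [simulate_game()]
#'
#' Defaults reflect that equilibria are approached exponentially, so tight
#' tolerances keep simulated steady states comparable with the closed-form
#' equilibria: relative tolerance 1e-9, absolute 1e-11, convergence declared
#' when the max-norm of the right-hand side falls below 1e-8. The horizon is
#' doubled automatically (up to `max_doublings` times) when a run has not
#' converged.
#'
#' @param rtol,atol relative/absolute integration tolerances.
#' @param conv_tol declare convergence when `max |RHS| < conv_tol`.
#' @param horizon initial integration horizon (time units are arbitrary).
#' @param max_doublings number of automatic horizon doublings.
#' @param dt_out output time step of the recorded trajectory.
#'
#' @return A list of settings.
#' @export
sim_control <- function(rtol = 1e-9, atol = 1e-11, conv_tol = 1e-8,
                        horizon = 500, max_doublings = 4, dt_out = 0.5) {
  stopifnot(rtol > 0, atol > 0, conv_tol > 0, horizon > 0, max_doublings >= 0,
    dt_out > 0)
  list(rtol = rtol, atol = atol, conv_tol = conv_tol, horizon = horizon,
    max_doublings = max_doublings, dt_out = dt_out)
}

#' Simulate the replicator dynamics
#'
#' Integrates the baseline or therapy-augmented system from a point on the
#' simplex until the right-hand side max-norm falls below the convergence
#' tolerance or the (automatically extended) horizon is exhausted. Integration
#' uses a stiff-capable adaptive solver (`deSolve::lsodar`) with root-based
#' stopping at the convergence criterion.
#'
#' States are not clipped: a small negative excursion beyond -1e-10 raises a
#' warning and beyond -1e-6 an error, to distinguish genuine model escape
#' from round-off. The stem-cell level starts at `z0 = 0` by default (therapy
#' begins with no stem cells present); it is not bounded above by 1, and a
#' warning is issued if it exceeds 1.
#'
#' @param x0 initial frequency of cancerous cells, in \[0, 1\].
#' @param t game parameters: a [t_params()] or a [payoff_matrix()].
#' @param therapy a [therapy_params()], a single number interpreted as the
#'   composite parameter `e` (expanded as `w = e, j = 1, l = 1`), or `NULL`
#'   for the baseline system.
#' @param y0 initial healthy-cell frequency; defaults to `1 - x0` and must
#'   complete the simplex within 1e-8.
#' @param z0 initial stem-cell level (>= 0).
#' @param control a [sim_control()] list.
#'
#' @return An object of class `game_trajectory`: a list with `states`
#'   (data frame with columns `time`, `x`, `y`, `z`), `converged`,
#'   `steady_state` (named vector, `NULL` if not converged), and the inputs.
#' @export
#' @examples
#' traj <- simulate_game(0.5, t_params(-1, 2))        # case A1: x -> 1
#' steady_state_value(traj)["x"]
#' traj <- simulate_game(0.5, t_params(-1, 2), therapy = 18)
#' steady_state_value(traj)["x"]                       # suppressed near 0.096
simulate_game <- function(x0, t, therapy = NULL, y0 = NULL, z0 = 0,
                          control = sim_control()) {
  payoff <- if (inherits(t, "payoff_matrix")) t else payoff_from_t(t)
  tp <- as_therapy_params(therapy)
  x0 <- check_finite_scalar(x0, "x0")
  z0 <- check_finite_scalar(z0, "z0")
  if (is.null(y0)) y0 <- 1 - x0
  y0 <- check_finite_scalar(y0, "y0")
  if (x0 < 0 || y0 < 0 || z0 < 0) {
    stop("initial frequencies must be non-negative", call. = FALSE)
  }
  if (abs(x0 + y0 - 1) > 1e-8) {
    stop("initial condition must lie on the simplex: x0 + y0 = 1", call. = FALSE)
  }

  derivs <- function(time, state, parms) {
    list(therapy_rhs(state, payoff, tp))
  }
  rootfun <- function(time, state, parms) {
    max(abs(therapy_rhs(state, payoff, tp))) - control$conv_tol
  }

  state <- c(x = x0, y = y0, z = z0)
  pieces <- list()
  t_start <- 0
  horizon <- control$horizon
  converged <- max(abs(therapy_rhs(state, payoff, tp))) < control$conv_tol

  attempt <- 0
  while (!converged && attempt <= control$max_doublings) {
    times <- seq(t_start, t_start + horizon,
      length.out = max(2L, ceiling(horizon / control$dt_out) + 1L))
    sol <- deSolve::lsodar(
      y = state, times = times, func = derivs, parms = NULL,
      rootfunc = rootfun, rtol = control$rtol, atol = control$atol
    )
    if (attr(sol, "istate")[1L] < 0) {
      stop(sprintf(
        "integrator failure (istate = %d) at t ~ %g; state = (%s)",
        attr(sol, "istate")[1L], utils::tail(sol[, "time"], 1),
        paste(signif(utils::tail(sol, 1)[-1], 6), collapse = ", ")
      ), call. = FALSE)
    }
    pieces[[length(pieces) + 1L]] <- as.data.frame(unclass(sol))
    last <- utils::tail(as.data.frame(unclass(sol)), 1L)
    state <- c(x = last$x, y = last$y, z = last$z)
    t_start <- last$time
    converged <- !is.null(attr(sol, "troot")) && length(attr(sol, "troot")) > 0
    if (!converged) {
      horizon <- horizon * 2
      attempt <- attempt + 1
    }
  }

  if (length(pieces) == 0L) {
    # already at (numerical) equilibrium at t = 0
    pieces <- list(data.frame(time = 0, x = x0, y = y0, z = z0))
  }
  states <- do.call(rbind, pieces)
  names(states)[1L] <- "time"
  states <- states[!duplicated(states$time), , drop = FALSE]
  rownames(states) <- NULL

  min_val <- min(states$x, states$y, states$z)
  if (min_val < -1e-6) {
    stop(sprintf(
      "trajectory escaped the feasible region (minimum component %.3g)",
      min_val), call. = FALSE)
  }
  if (min_val < -1e-10) {
    warning(sprintf(
      "small negative excursion (minimum component %.3g); treated as round-off",
      min_val), call. = FALSE)
  }
  if (max(states$z) > 1) {
    warning("stem-cell level z exceeded 1; z is a level, not a bounded frequency",
      call. = FALSE)
  }

  steady <- NULL
  if (converged) {
    steady <- c(x = state[["x"]], y = state[["y"]], z = state[["z"]],
      t = t_start)
  }
  structure(
    list(
      states = states, converged = converged, steady_state = steady,
      t = as_t_params(derive_t_params(payoff)), therapy = tp,
      payoff = payoff, control = control
    ),
    class = "game_trajectory"
  )
}

#' @export
print.game_trajectory <- function(x, ...) {
  last <- utils::tail(x$states, 1L)
  cat(sprintf(
    "Replicator trajectory: %d points over t = [0, %g], %s\n",
    nrow(x$states), last$time,
    if (x$converged) "converged" else "NOT converged"
  ))
  cat(sprintf("  final state: x = %.6g, y = %.6g, z = %.6g\n",
    last$x, last$y, last$z))
  invisible(x)
}

#' @export
as.data.frame.game_trajectory <- function(x, ...) x$states

#' Extract the steady state of a converged trajectory
#'
#' @param traj a [simulate_game()] result.
#'
#' @return Named numeric vector `c(x, y, z, t)` of the converged state and the
#'   time at which convergence was declared.
#' @export
steady_state_value <- function(traj) {
  stopifnot(inherits(traj, "game_trajectory"))
  if (!traj$converged) {
    stop(paste(
      "trajectory has not converged; increase the horizon or",
      "`max_doublings` in sim_control()"), call. = FALSE)
  }
  traj$steady_state
}

#' Write a trajectory to CSV (and optional JSON run metadata)
#'
#' The CSV has columns `time`, `x`, `y`, `z` with values written to 12
#' significant digits. The optional JSON sidecar records the parameters,
#' tolerances and convergence flag of the run.
#'
#' @param traj a [simulate_game()] result.
#' @param csv_path output CSV path.
#' @param meta_path optional path for a JSON metadata file.
#'
#' @return `csv_path`, invisibly.
#' @export
write_trajectory <- function(traj, csv_path, meta_path = NULL) {
  stopifnot(inherits(traj, "game_trajectory"))
  out <- traj$states
  out[] <- lapply(out, function(col) formatC(col, digits = 12, format = "g"))
  utils::write.csv(out, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(meta_path)) {
    meta <- list(
      t1 = traj$t$t1, t2 = traj$t$t2,
      therapy = traj$therapy[c("w", "j", "l", "e")],
      payoff = traj$payoff[c("a", "b", "c", "d")],
      control = traj$control,
      converged = traj$converged,
      steady_state = as.list(traj$steady_state)
    )
    jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
      null = "null")
  }
  invisible(csv_path)
}
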