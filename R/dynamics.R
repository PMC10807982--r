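# deSolve-compatible derivative function
.ode_func <- function(t, y, parms) {
  n <- y[1L]; i <- y[2L]; e <- y[3L]
  mu <- parms[1L]; m <- parms[2L]; cc <- parms[3L]
  se <- parms[4L]; si <- parms[5L]
  dn <- m * i + m * e - n * e * se - n * i * si
  di <- -mu * i - m * i + n * i * si + (1 - cc) * e * i * si -
    (1 - cc) * i * e * se
  de <- mu * i - m * e + n * e * se - (1 - cc) * e * i * si +
    (1 - cc) * i * e * se
  list(c(dn, di, de))
}

.parms_vec <- function(params) {
  c(params$mu, params$m, params$c, params$se, params$si)
}

.traj_drift_tol <- 1e-7

new_trajectory <- function(times, states, params) {
  colnames(states) <- c("n", "i", "e")
  structure(list(times = times, states = states, params = params),
            class = "culture_trajectory")
}

#' Integrate the model forward in time
#'
#' Solves the three-compartment system with an adaptive solver
#' (`deSolve::lsoda`, relative tolerance 1e-8, absolute tolerance 1e-10)
#' from a given initial state. The state is never renormalized during
#' integration; instead the simplex-sum drift of the final state is checked
#' against 1e-7 so solver problems surface rather than being masked.
#'
#' @param params A [model_params()] object.
#' @param initial Initial [simplex_state()]. The configuration used
#'   throughout the model's analyses is the all-inefficient start
#'   `simplex_state(0, 1, 0)`.
#' @param t_max Integration horizon (> 0), model time units.
#' @param resolution Number of equally spaced output points (>= 2),
#'   including `t = 0`.
#' @param rtol,atol Solver tolerances.
#' @return A `culture_trajectory`: list with `times`, a `states` matrix with
#'   columns `n`, `i`, `e`, and the `params` used.
#' @examples
#' p <- model_params(m = 0.1, c = 0.75, se = 0.5)
#' traj <- integrate_culture(p, simplex_state(0, 1, 0), t_max = 100)
#' head(as.data.frame(traj))
#' @export
integrate_culture <- function(params, initial, t_max, resolution = 201L,
                              rtol = 1e-8, atol = 1e-10) {
  stopifnot(t_max > 0, resolution >= 2)
  y0 <- as_state(initial, slack = 0)
  times <- seq(0, t_max, length.out = resolution)
  sol <- deSolve::lsoda(y = unname(y0), times = times, func = .ode_func,
                        parms = .parms_vec(params), rtol = rtol, atol = atol)
  diagn <- attr(sol, "istate")
  if (!is.null(diagn) && diagn[1L] < 0) {
    last <- sol[nrow(sol), ]
    stop(structure(class = c("turnlearn_integration_error", "error",
                             "condition"),
                   list(message = sprintf(
                     "ODE integration failed at t = %g", last[1L]),
                     call = sys.call(),
                     last_state = last[-1L])))
  }
  states <- unname(sol[, 2:4, drop = FALSE])
  drift <- abs(rowSums(states) - 1)
  if (max(drift) > .traj_drift_tol) {
    stop(sprintf("simplex-sum drift %.3g exceeds tolerance %.1g",
                 max(drift), .traj_drift_tol), call. = FALSE)
  }
  new_trajectory(sol[, 1L], states, params)
}

#' Fixed-step reference integration
#'
#' Integrates the model with a fixed-step forward Euler or classical
#' fourth-order Runge-Kutta scheme (no error control). This is a
#' deliberately simple brute-force reference used to cross-check the
#' adaptive solver; it is orders of magnitude slower at comparable accuracy
#' and not meant for production runs.
#'
#' @inheritParams integrate_culture
#' @param h Fixed step size (default 1e-4).
#' @param method `"rk4"` or `"euler"`.
#' @return A `culture_trajectory`.
#' @export
fixed_step_integrate <- function(params, initial, t_max, h = 1e-4,
                                 resolution = 101L,
                                 method = c("rk4", "euler")) {
  stopifnot(t_max > 0, h > 0, resolution >= 2)
  method <- match.arg(method)
  y0 <- as_state(initial, slack = 0)
  times <- seq(0, t_max, length.out = resolution)
  states <- .fixed_step_cpp(unname(y0), params$mu, params$m, params$c,
                            params$se, params$si, times, h,
                            if (method == "euler") 1L else 4L)
  new_trajectory(times, states, params)
}

#' @export
print.culture_trajectory <- function(x, ...) {
  cat(sprintf("Culture trajectory: %d points on [0, %g]\n",
              length(x$times), max(x$times)))
  fin <- x$states[nrow(x$states), ]
  cat(sprintf("  final state: n = %.6g, i = %.6g, e = %.6g\n",
              fin[1L], fin[2L], fin[3L]))
  invisible(x)
}

#' @export
as.data.frame.culture_trajectory <- function(x, ...) {
  data.frame(t = x$times, n = x$states[, "n"], i = x$states[, "i"],
             e = x$states[, "e"])
}

#' Time for the efficient solution to reach a target fraction
#'
#' Finds the first time `t_h` at which the efficient fraction `e(t)` reaches
#' a threshold (default one half of the population), using the solver's root
#' detection (`deSolve::lsodar`), which locates the crossing far more
#' tightly than the 1e-6 time tolerance required of it.
#'
#' A threshold the system never attains is distinguished from a horizon that
#' is merely too short using the closed-form equilibrium: if `e` has not
#' crossed by `t_max` and the equilibrium efficient fraction is at or below
#' the threshold, the threshold is genuinely unreachable (`reached = FALSE`,
#' `t_h = NA`); if the equilibrium lies strictly above the threshold, an
#' error asks for a larger `t_max` instead of silently mislabelling the
#' run. At the knife-edge where the equilibrium equals the threshold the
#' approach is asymptotic, so this case is classified unreachable.
#'
#' @param x A [model_params()] object, or a `culture_trajectory` (whose
#'   `params` and first state are then used).
#' @param initial Initial [simplex_state()] (ignored when `x` is a
#'   trajectory).
#' @param threshold Target efficient fraction, in (0, 1); a threshold at or
#'   below the initial efficient fraction yields `t_h = 0`.
#' @param t_max Search horizon.
#' @return A `threshold_result`: list with `threshold`, `t_h` (`NA` when not
#'   reached) and logical `reached`.
#' @examples
#' p <- model_params(m = 0.1, c = 0.75, se = 0.5)
#' time_to_threshold(p, simplex_state(0, 1, 0))
#' @export
time_to_threshold <- function(x, initial = simplex_state(0, 1, 0),
                              threshold = 0.5, t_max = 1e5) {
  if (inherits(x, "culture_trajectory")) {
    initial <- as_state(x$states[1L, ])
    params <- x$params
  } else {
    params <- x
  }
  stopifnot(threshold < 1, t_max > 0)
  y0 <- as_state(initial)
  if (y0[["e"]] >= threshold || threshold <= 0) {
    return(structure(list(threshold = threshold, t_h = 0, reached = TRUE),
                     class = "threshold_result"))
  }
  rootfun <- function(t, y, p) y[3L] - threshold
  sol <- deSolve::lsodar(y = unname(y0), times = c(0, t_max),
                         func = .ode_func, parms = .parms_vec(params),
                         rootfunc = rootfun, rtol = 1e-8, atol = 1e-10)
  troot <- attr(sol, "troot")
  if (length(troot) > 0 && is.finite(troot[1L])) {
    return(structure(list(threshold = threshold, t_h = troot[1L],
                          reached = TRUE),
                     class = "threshold_result"))
  }
  e_star <- equilibrium_analytic(params)$e_star
  if (e_star > threshold) {
    stop(structure(class = c("turnlearn_horizon_error", "error", "condition"),
                   list(message = sprintf(
                     paste0("equilibrium e* = %g exceeds threshold %g but no",
                            " crossing by t_max = %g: increase t_max"),
                     e_star, threshold, t_max),
                     call = sys.call())))
  }
  structure(list(threshold = threshold, t_h = NA_real_, reached = FALSE),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  if (x$reached) {
    cat(sprintf("e(t) reaches %g at t_h = %.6f\n", x$threshold, x$t_h))
  } else {
    cat(sprintf("e(t) never reaches %g (equilibrium below threshold)\n",
                x$threshold))
  }
  invisible(x)
}

#' Long-time equilibrium by integration
#'
#' Integrates from `initial` with an adaptive horizon (starting at `t = 1e3`
#' and doubling up to a cap of `1e7`) until the maximum absolute component
#' of the right-hand side at the endpoint falls below `residual_tol`
#' (default 1e-9). The endpoint and achieved residual are returned; hitting
#' the cap without convergence is an error, never a silent truncation.
#'
#' @inheritParams integrate_culture
#' @param residual_tol Convergence criterion on `max |rhs|` at the endpoint.
#' @param t_start,t_cap Initial and maximal integration horizon.
#' @return An `equilibrium_result` with `source = "numeric"`; see
#'   [equilibrium_analytic()] for the fields.
#' @examples
#' p <- model_params(m = 0.1, c = 0.75, se = 0.5)
#' equilibrium_numeric(p, simplex_state(0, 1, 0))
#' @export
equilibrium_numeric <- function(params, initial, residual_tol = 1e-9,
                                t_start = 1e3, t_cap = 1e7) {
  y <- as_state(initial, slack = 0)
  all_naive_start <- y[["i"]] + y[["e"]] == 0
  t_done <- 0
  horizon <- t_start
  repeat {
    resid <- max(abs(culture_rhs(y, params)))
    if (resid < residual_tol) break
    if (t_done >= t_cap) {
      stop(structure(class = c("turnlearn_convergence_error", "error",
                               "condition"),
                     list(message = sprintf(
                       "no equilibrium by t = %g (residual %.3g)",
                       t_cap, resid),
                       call = sys.call(), residual = resid)))
    }
    seg_end <- min(horizon, t_cap)
    sol <- deSolve::lsoda(y = unname(y), times = c(0, seg_end - t_done),
                          func = .ode_func, parms = .parms_vec(params),
                          rtol = 1e-10, atol = 1e-12)
    y <- as_state(sol[nrow(sol), 2:4], slack = 1e-9)
    t_done <- seg_end
    horizon <- horizon * 2
  }
  # solver round-off can leave harmless tiny negatives; clamp for reporting
  y <- pmin(pmax(y, 0), 1)
  new_equilibrium_result(state = y, params = params, residual = resid,
                         source = "numeric",
                         all_naive_start = all_naive_start)
}
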