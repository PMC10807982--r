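.extinct_tol <- 1e-6

new_equilibrium_result <- function(state, params, residual, source,
                                   all_naive_start = FALSE) {
  e_star <- unname(state[["e"]])
  regime <- if (all_naive_start && e_star < .extinct_tol &&
                state[["i"]] < .extinct_tol) {
    "degenerate_all_naive"
  } else if (e_star < .extinct_tol && params$m > 0) {
    "extinction"
  } else {
    "persistence"
  }
  structure(list(state = state, e_star = e_star, regime = regime,
                 residual = residual, source = source, params = params),
            class = "equilibrium_result")
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat(sprintf("Equilibrium (%s): n = %.6g, i = %.6g, e = %.6g\n",
              x$source, x$state[["n"]], x$state[["i"]], x$state[["e"]]))
  cat(sprintf("  regime: %s; residual max|rhs| = %.3g\n", x$regime,
              x$residual))
  invisible(x)
}

#' Closed-form equilibrium
#'
#' Returns the equilibrium the system reaches from any start containing at
#' least some knowledgeable individuals. With innovation present
#' (`mu > 0`) the inefficient solution always goes extinct, so the
#' equilibrium has `i = 0` as a structural fact. The efficient fraction at
#' equilibrium is
#' \deqn{e^* = 1 - m / s_e \quad (m \le s_e),}
#' with `n = m / se` naive individuals maintained by turnover; when
#' `m >= se` (and `m > 0`) naive newcomers arrive faster than they adopt
#' the efficient solution, the pool of experience erodes, and only naive
#' individuals remain (`e* = 0`, extinction regime). Without turnover
#' (`m = 0`) the efficient solution fixes (`e* = 1`). The boundary
#' `m = se` belongs to the extinction regime: the formula gives exactly 0
#' there and the dynamics for all `m >= se` end all-naive.
#'
#' With `mu = 0` the model has a continuum of equilibria, so the analytic
#' branch refuses `mu = 0` with an explanatory error rather than guessing.
#'
#' The returned state is verified by substitution into [culture_rhs()]
#' (residual below 1e-12).
#'
#' @param params A [model_params()] object with `mu > 0`.
#' @return An `equilibrium_result`: list with `state` (a simplex triple),
#'   `e_star`, `regime` (one of `"persistence"`, `"extinction"`,
#'   `"degenerate_all_naive"`), `residual`, `source = "analytic"`, and the
#'   `params`.
#' @examples
#' equilibrium_analytic(model_params(m = 0.1, c = 0.75, se = 0.5))$e_star
#' @export
equilibrium_analytic <- function(params) {
  if (params$mu <= 0) {
    stop(paste0("equilibrium_analytic requires mu > 0: with mu = 0 the ",
                "system has a continuum of equilibria and no single ",
                "closed-form target"), call. = FALSE)
  }
  state <- if (params$m == 0) {
    c(n = 0, i = 0, e = 1)
  } else if (params$se > 0 && params$m < params$se) {
    c(n = params$m / params$se, i = 0, e = 1 - params$m / params$se)
  } else {
    c(n = 1, i = 0, e = 0)
  }
  residual <- max(abs(culture_rhs(state, params)))
  stopifnot(residual < 1e-12)
  new_equilibrium_result(state = state, params = params, residual = residual,
                         source = "analytic")
}

#' Classify the long-run regime of a parameter set
#'
#' Labels the equilibrium regime and reports whether efficient individuals
#' can form half or more of the population at equilibrium, which holds
#' exactly when `m <= se / 2` (the boundary `m = se / 2` gives
#' `e* = 1/2`, counted as a majority under "half or more").
#'
#' @inheritParams equilibrium_analytic
#' @return A list with `regime`, `e_star` and logical `majority`.
#' @examples
#' classify_regime(model_params(m = 0.25, c = 0.75, se = 0.5))
#' @export
classify_regime <- function(params) {
  eq <- equilibrium_analytic(params)
  list(regime = eq$regime, e_star = eq$e_star, majority = eq$e_star >= 0.5)
}

#' Equilibrium robustness to starting conditions
#'
#' Verifies numerically that the equilibrium does not depend on where the
#' population starts, except for the degenerate all-naive start (which is a
#' fixed point: nobody knows either solution, so there is nothing to learn
#' or to innovate from). Draws `n_starts` points uniformly on the simplex
#' (symmetric Dirichlet(1,1,1)), rejecting near-pure-naive draws
#' (`i0 + e0 < 0.01`), runs [equilibrium_numeric()] from each, and checks
#' that the spread of the efficient component and its deviation from the
#' closed form are both below `tol`. A violation is an error: this
#' operation is a verification, not a survey.
#'
#' @inheritParams equilibrium_analytic
#' @param n_starts Number of random starts (>= 2).
#' @param seed Integer RNG seed (mandatory, for reproducibility).
#' @param tol Agreement tolerance on the efficient component.
#' @return Invisibly, a list with the drawn `starts` (matrix), the
#'   equilibrium `e_values`, `max_spread`, `max_deviation` from the closed
#'   form, and `e_analytic`.
#' @examples
#' \donttest{
#' p <- model_params(m = 0.1, c = 0.75, se = 0.5)
#' rep <- robustness_to_initial_conditions(p, n_starts = 5, seed = 1)
#' rep$max_spread
#' }
#' @export
robustness_to_initial_conditions <- function(params, n_starts = 20L, seed,
                                             tol = 1e-4) {
  stopifnot(n_starts >= 2, params$mu > 0)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  set.seed(seed)
  starts <- matrix(NA_real_, nrow = n_starts, ncol = 3,
                   dimnames = list(NULL, c("n", "i", "e")))
  k <- 0L
  while (k < n_starts) {
    g <- stats::rexp(3)
    x <- g / sum(g)
    if (x[2L] + x[3L] < 0.01) next
    k <- k + 1L
    starts[k, ] <- x
  }
  e_values <- vapply(seq_len(n_starts), function(r) {
    equilibrium_numeric(params, simplex_state(starts[r, 1L], starts[r, 2L],
                                              starts[r, 3L]))$e_star
  }, numeric(1))
  e_analytic <- equilibrium_analytic(params)$e_star
  max_spread <- diff(range(e_values))
  max_deviation <- max(abs(e_values - e_analytic))
  if (max_spread >= tol || max_deviation >= tol) {
    stop(sprintf(
      "equilibrium not robust: spread %.3g, deviation from closed form %.3g",
      max_spread, max_deviation), call. = FALSE)
  }
  invisible(list(starts = starts, e_values = e_values,
                 max_spread = max_spread, max_deviation = max_deviation,
                 e_analytic = e_analytic))
}
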