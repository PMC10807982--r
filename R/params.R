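#' Model parameters
#'
#' Construct and validate the five parameters of the turnover/social-learning
#' model: the innovation rate `mu` (inefficient individuals independently
#' discover the efficient solution), the population turnover rate `m`
#' (individuals of any state are replaced by naive newcomers), the behavioral
#' conservatism probability `c` (a knowledgeable individual ignores a
#' social-learning opportunity with probability `c`), and the per-encounter
#' success rates of learning from an efficient (`se`) or inefficient (`si`)
#' individual. All rates are per unit model time; `c` is a probability.
#'
#' The model's standing assumption is `se > si` (the efficient solution is
#' more likely to be copied once encountered). Violating it is permitted --
#' the boundary `se = si` is useful for symmetry checks -- but triggers a
#' warning rather than an error.
#'
#' @param mu Innovation rate, `mu >= 0`. Default 0.01.
#' @param m Turnover rate, `m >= 0`.
#' @param c Behavioral conservatism, `0 <= c <= 1`.
#' @param se Success rate of learning from an efficient individual, `se >= 0`.
#' @param si Success rate of learning from an inefficient individual,
#'   `si >= 0`. Default 0.1.
#'
#' @return An object of class `model_params`: a named list with components
#'   `mu`, `m`, `c`, `se`, `si`.
#' @examples
#' p <- model_params(m = 0.1, c = 0.75, se = 0.5)
#' p
#' @seealso [validate_params()] for construction from a raw named list,
#'   [culture_rhs()] for the differential equations the parameters enter.
#' @export
model_params <- function(mu = 0.01, m, c, se, si = 0.1) {
  validate_params(list(mu = mu, m = m, c = c, se = se, si = si))
}

#' Validate a raw parameter mapping
#'
#' Checks that all five model parameters are present, numeric, finite and
#' within their admissible ranges, and returns a `model_params` object.
#' Emits a warning (not an error) when `se <= si`, since the model's
#' qualitative results assume efficient individuals attract more learners.
#'
#' @param raw A named list or named numeric vector containing `mu`, `m`,
#'   `c`, `se`, `si`.
#' @return A validated `model_params` object.
#' @examples
#' validate_params(list(mu = 0.01, m = 0.1, c = 0.75, se = 0.5, si = 0.1))
#' @export
validate_params <- function(raw) {
  required <- c("mu", "m", "c", "se", "si")
  raw <- as.list(raw)
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop("missing model parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  p <- lapply(raw[required], function(x) {
    x <- as.numeric(x)
    if (length(x) != 1L || !is.finite(x)) {
      stop("model parameters must be single finite numbers", call. = FALSE)
    }
    x
  })
  for (nm in c("mu", "m", "se", "si")) {
    if (p[[nm]] < 0) {
      stop(sprintf("parameter '%s' must be >= 0 (got %g)", nm, p[[nm]]),
           call. = FALSE)
    }
  }
  if (p$c < 0 || p$c > 1) {
    stop(sprintf("parameter 'c' must lie in [0, 1] (got %g)", p$c),
         call. = FALSE)
  }
  if (p$se <= p$si) {
    warning(sprintf(
      "se (%g) <= si (%g): the model's standing assumption se > si is violated",
      p$se, p$si), call. = FALSE)
  }
  structure(p, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Model parameters (per unit time; c is a probability)\n")
  cat(sprintf("  mu = %g  m = %g  c = %g  se = %g  si = %g\n",
              x$mu, x$m, x$c, x$se, x$si))
  invisible(x)
}

# tolerance constants shared across the package
.simplex_sum_tol <- 1e-9
.simplex_slack <- 1e-12

#' Compartment state on the simplex
#'
#' Construct a population state as fractions of naive (`n`), inefficient
#' (`i`) and efficient (`e`) individuals. Population size is constant, so the
#' three fractions must sum to 1 (tolerance 1e-9) and each must lie in
#' \[0, 1\]. States produced by the integrator may carry tiny negative
#' round-off (within 1e-12); user-supplied states must be exactly in range.
#'
#' @param n,i,e Fractions of naive, inefficient and efficient individuals.
#' @return A named numeric vector `c(n, i, e)` of class `simplex_state`.
#' @examples
#' simplex_state(0, 1, 0)  # the all-inefficient start used throughout
#' @export
simplex_state <- function(n, i, e) {
  x <- c(n = as.numeric(n), i = as.numeric(i), e = as.numeric(e))
  if (any(!is.finite(x))) stop("state fractions must be finite", call. = FALSE)
  if (any(x < 0 | x > 1)) {
    bad <- names(x)[x < 0 | x > 1][1L]
    stop(sprintf("state fraction '%s' must lie in [0, 1] (got %g)",
                 bad, x[[bad]]), call. = FALSE)
  }
  assert_simplex(x)
  structure(x, class = c("simplex_state", "numeric"))
}

# internal: check the simplex invariant on a bare numeric triple; `slack`
# admits solver round-off below 0 / above 1
assert_simplex <- function(x, slack = 0, sum_tol = .simplex_sum_tol) {
  if (abs(sum(x) - 1) > sum_tol) {
    stop(sprintf("state fractions must sum to 1 (sum = %.12g)", sum(x)),
         call. = FALSE)
  }
  if (any(x < -slack) || any(x > 1 + slack)) {
    stop("state fraction outside [0, 1] beyond the allowed round-off slack",
         call. = FALSE)
  }
  invisible(x)
}

# internal: coerce a length-3 vector (possibly from the solver) to a plain
# named triple after a slack-tolerant simplex check
as_state <- function(x, slack = .simplex_slack) {
  x <- as.numeric(x)
  names(x) <- c("n", "i", "e")
  assert_simplex(x, slack = slack)
  x
}

#' @export
print.simplex_state <- function(x, ...) {
  cat(sprintf("Simplex state: n = %g, i = %g, e = %g\n", x[1L], x[2L], x[3L]))
  invisible(x)
}
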