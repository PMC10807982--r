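new_sweep_grid <- function(axis1_name, axis1_values, axis2_name,
                           axis2_values, values, reachable, fixed,
                           quantity) {
  stopifnot(all(diff(axis1_values) > 0), all(diff(axis2_values) > 0),
            identical(dim(values),
                      c(length(axis1_values), length(axis2_values))))
  structure(list(axis1 = list(name = axis1_name, values = axis1_values),
                 axis2 = list(name = axis2_name, values = axis2_values),
                 values = values, reachable = reachable, fixed = fixed,
                 quantity = quantity),
            class = "sweep_grid")
}

#' @export
print.sweep_grid <- function(x, ...) {
  cat(sprintf("Sweep of %s over %d x %d grid (%s x %s)\n", x$quantity,
              length(x$axis1$values), length(x$axis2$values),
              x$axis1$name, x$axis2$name))
  n_un <- sum(!x$reachable)
  if (n_un > 0) cat(sprintf("  %d cell(s) unreachable/unconverged\n", n_un))
  invisible(x)
}

# fill fixed-parameter defaults shared by the sweep operations
.fill_fixed <- function(fixed, defaults) {
  fixed <- as.list(fixed)
  for (nm in names(defaults)) {
    if (is.null(fixed[[nm]])) fixed[[nm]] <- defaults[[nm]]
  }
  fixed
}

#' Sweep the half-adoption time over turnover and conservatism
#'
#' Computes the time `t_h` at which the efficient fraction first reaches
#' `threshold` for every cell of an `(m, c)` grid, holding `mu`, `se`, `si`
#' fixed. Cells whose equilibrium efficient fraction does not exceed the
#' threshold can never cross it and are marked unreachable (value `NA`,
#' `reachable = FALSE`) -- never given a sentinel number. Each cell is a
#' pure function of its coordinates, so recomputing any single cell
#' reproduces the grid value exactly.
#'
#' @param m_values,c_values Strictly increasing grid axes.
#' @param fixed Named list of the held-fixed parameters `mu`, `se`, `si`
#'   (`mu` defaults to 0.01, `si` to 0.1; `se` is required).
#' @param initial Initial state (default all-inefficient).
#' @param threshold Target efficient fraction (default 0.5).
#' @param t_max Search horizon passed to [time_to_threshold()].
#' @return A `sweep_grid` with `quantity = "t_h"`.
#' @examples
#' \donttest{
#' g <- sweep_th(c(0, 0.1), c(0.5, 0.75), fixed = list(se = 0.5))
#' g$values
#' }
#' @export
sweep_th <- function(m_values, c_values, fixed,
                     initial = simplex_state(0, 1, 0), threshold = 0.5,
                     t_max = 1e5) {
  stopifnot(length(m_values) > 0, length(c_values) > 0)
  fixed <- .fill_fixed(fixed, list(mu = 0.01, si = 0.1))
  if (is.null(fixed$se)) stop("fixed$se is required", call. = FALSE)
  values <- matrix(NA_real_, length(m_values), length(c_values))
  reachable <- matrix(TRUE, length(m_values), length(c_values))
  for (a in seq_along(m_values)) {
    for (b in seq_along(c_values)) {
      params <- model_params(mu = fixed$mu, m = m_values[a],
                             c = c_values[b], se = fixed$se, si = fixed$si)
      res <- tryCatch(
        time_to_threshold(params, initial, threshold, t_max),
        error = function(err) {
          stop(sprintf("cell (m = %g, c = %g): %s", m_values[a],
                       c_values[b], conditionMessage(err)), call. = FALSE)
        })
      if (res$reached) {
        values[a, b] <- res$t_h
      } else {
        reachable[a, b] <- FALSE
      }
    }
  }
  new_sweep_grid("m", m_values, "c", c_values, values, reachable,
                 fixed, "t_h")
}

#' Sweep the equilibrium efficient fraction over turnover and learning rate
#'
#' Computes the equilibrium efficient fraction `e*` on an `(m, se)` grid,
#' either from the closed form (`mode = "analytic"`) or by long-horizon
#' integration from the all-inefficient start (`mode = "numeric"`). The two
#' agree to within 1e-4 in the persistence region. Numeric non-convergence
#' is marked per cell (value `NA`, `reachable = FALSE`) rather than raised.
#'
#' @param m_values,se_values Strictly increasing grid axes.
#' @param fixed Named list of held-fixed parameters `mu`, `c`, `si`
#'   (defaults `mu = 0.01`, `si = 0.1`; `c` is required).
#' @param mode `"analytic"` or `"numeric"`.
#' @return A `sweep_grid` with `quantity = "e_star"`.
#' @examples
#' g <- sweep_estar(c(0.1, 0.6), c(0.5, 0.8), fixed = list(c = 0.75))
#' g$values
#' @export
sweep_estar <- function(m_values, se_values, fixed,
                        mode = c("analytic", "numeric")) {
  stopifnot(length(m_values) > 0, length(se_values) > 0)
  mode <- match.arg(mode)
  fixed <- .fill_fixed(fixed, list(mu = 0.01, si = 0.1))
  if (is.null(fixed$c)) stop("fixed$c is required", call. = FALSE)
  values <- matrix(NA_real_, length(m_values), length(se_values))
  reachable <- matrix(TRUE, length(m_values), length(se_values))
  for (a in seq_along(m_values)) {
    for (b in seq_along(se_values)) {
      params <- suppressWarnings(
        model_params(mu = fixed$mu, m = m_values[a], c = fixed$c,
                     se = se_values[b], si = fixed$si))
      if (mode == "analytic") {
        values[a, b] <- equilibrium_analytic(params)$e_star
      } else {
        eq <- tryCatch(
          equilibrium_numeric(params, simplex_state(0, 1, 0)),
          turnlearn_convergence_error = function(err) NULL)
        if (is.null(eq)) {
          reachable[a, b] <- FALSE
        } else {
          values[a, b] <- eq$e_star
        }
      }
    }
  }
  new_sweep_grid("m", m_values, "se", se_values, values, reachable,
                 fixed, "e_star")
}

#' Sensitivity of the half-adoption time to turnover
#'
#' Finite-difference derivative of `t_h` with respect to the turnover rate
#' `m` at a point `(m, c)`: central difference with step `dm` (forward at
#' `m < dm`, where `m - dm` would be negative). A negative sensitivity
#' means increasing turnover accelerates the spread of the efficient
#' solution; positive means it slows it. The default step `dm = 1e-3` sits
#' far above the crossing-time tolerance and far below typical grid
#' spacings.
#'
#' @param m,c The evaluation point.
#' @param fixed Named list with `mu`, `se`, `si` as in [sweep_th()].
#' @inheritParams sweep_th
#' @param dm Finite-difference step in `m`.
#' @return Signed sensitivity `d t_h / d m` (time units per rate unit).
#' @examples
#' \donttest{
#' th_sensitivity(0.05, 0.75, fixed = list(se = 0.5))  # negative
#' }
#' @export
th_sensitivity <- function(m, c, fixed, initial = simplex_state(0, 1, 0),
                           threshold = 0.5, t_max = 1e5, dm = 1e-3) {
  fixed <- .fill_fixed(fixed, list(mu = 0.01, si = 0.1))
  if (is.null(fixed$se)) stop("fixed$se is required", call. = FALSE)
  th_at <- function(mm) {
    params <- model_params(mu = fixed$mu, m = mm, c = c, se = fixed$se,
                           si = fixed$si)
    res <- time_to_threshold(params, initial, threshold, t_max)
    if (!res$reached) {
      stop(sprintf(
        "threshold %g unreachable at stencil point m = %g (c = %g)",
        threshold, mm, c), call. = FALSE)
    }
    res$t_h
  }
  if (m >= dm) {
    (th_at(m + dm) - th_at(m - dm)) / (2 * dm)
  } else {
    (th_at(m + dm) - th_at(m)) / dm
  }
}

#' Critical curve where turnover neither accelerates nor slows adoption
#'
#' For each turnover rate in `m_values`, locates the conservatism value
#' `c(m)` at which the sensitivity of `t_h` to `m` vanishes, by scanning
#' `c` in \[0, 1\] for a sign change and bisecting the bracket to
#' `c_tolerance`. Above the curve (higher conservatism) increasing turnover
#' accelerates cultural evolution; below it, turnover slows it. Turnover
#' rates with no sign change in `c` are omitted from the curve with a
#' message, not an error. When several brackets exist, the root nearest the
#' previous turnover rate's root is kept so the curve is continuous.
#'
#' @param m_values Turnover rates at which to locate the curve.
#' @inheritParams th_sensitivity
#' @param c_tolerance Bisection tolerance on `c`.
#' @param n_scan Number of scan points over \[0, 1\] used to bracket the
#'   sign change.
#' @return A `critical_curve`: data frame with columns `m` and `c`, with
#'   the tolerance in attribute `"c_tolerance"`.
#' @examples
#' \donttest{
#' critical_curve(c(0.05, 0.1), fixed = list(se = 0.5))
#' }
#' @export
critical_curve <- function(m_values, fixed,
                           initial = simplex_state(0, 1, 0),
                           threshold = 0.5, t_max = 1e5, dm = 1e-3,
                           c_tolerance = 1e-4, n_scan = 11L) {
  fixed <- .fill_fixed(fixed, list(mu = 0.01, si = 0.1))
  if (is.null(fixed$se)) stop("fixed$se is required", call. = FALSE)
  sens <- function(m, c) {
    th_sensitivity(m, c, fixed, initial, threshold, t_max, dm)
  }
  out_m <- numeric(0)
  out_c <- numeric(0)
  prev_root <- NA_real_
  for (m in m_values) {
    c_scan <- seq(0, 1, length.out = n_scan)
    s_scan <- vapply(c_scan, function(cc) {
      tryCatch(sens(m, cc), error = function(e) NA_real_)
    }, numeric(1))
    ok <- which(!is.na(s_scan[-length(s_scan)]) & !is.na(s_scan[-1L]) &
                  s_scan[-length(s_scan)] * s_scan[-1L] <= 0 &
                  s_scan[-length(s_scan)] != 0)
    if (length(ok) == 0L) {
      message(sprintf(
        "critical_curve: no sign change of th_sensitivity in c at m = %g; point omitted",
        m))
      next
    }
    if (length(ok) > 1L) {
      message(sprintf(
        "critical_curve: %d brackets at m = %g; keeping the one nearest the previous root",
        length(ok), m))
      if (!is.na(prev_root)) {
        mids <- (c_scan[ok] + c_scan[ok + 1L]) / 2
        ok <- ok[which.min(abs(mids - prev_root))]
      } else {
        ok <- ok[1L]
      }
    }
    lo <- c_scan[ok]; hi <- c_scan[ok + 1L]
    s_lo <- s_scan[ok]
    while (hi - lo > c_tolerance) {
      mid <- (lo + hi) / 2
      s_mid <- sens(m, mid)
      if (s_lo * s_mid <= 0) hi <- mid else { lo <- mid; s_lo <- s_mid }
    }
    root <- (lo + hi) / 2
    prev_root <- root
    out_m <- c(out_m, m)
    out_c <- c(out_c, root)
  }
  structure(data.frame(m = out_m, c = out_c),
            class = c("critical_curve", "data.frame"),
            c_tolerance = c_tolerance, fixed = fixed,
            threshold = threshold)
}

#' Critical social-learning/turnover ratio for a majority
#'
#' Finds the ratio `se / m` at which the equilibrium efficient fraction
#' equals `threshold`, by bisecting on the turnover rate `m` with the
#' equilibrium evaluated by long-horizon integration
#' ([equilibrium_numeric()]). From the closed form `e* = 1 - m/se` the
#' ratio is `1 / (1 - threshold)` independently of `c` and `si`; for the
#' default threshold of one half it equals 2 -- social learning must run
#' more than twice as fast as turnover for the efficient solution to reach
#' a majority. The numerically bisected value is returned alongside the
#' analytic one so the agreement can be inspected.
#'
#' @param fixed Named list with `mu`, `c`, `si` (defaults `mu = 0.01`,
#'   `si = 0.1`; `c` is required).
#' @param se Social-learning success rate (> 0).
#' @param threshold Equilibrium efficient fraction to cross (default 0.5).
#' @param m_tol Bisection tolerance on `m`.
#' @return List with `ratio` (numeric, `se / m` at the crossing), `m` (the
#'   bisected turnover rate), `analytic_ratio = 1 / (1 - threshold)`, and
#'   `threshold`.
#' @examples
#' \donttest{
#' critical_ratio(fixed = list(c = 0.75), se = 0.5)$ratio  # ~2
#' }
#' @export
critical_ratio <- function(fixed, se, threshold = 0.5, m_tol = 1e-6) {
  stopifnot(se > 0, threshold > 0, threshold < 1)
  fixed <- .fill_fixed(fixed, list(mu = 0.01, si = 0.1))
  if (is.null(fixed$c)) stop("fixed$c is required", call. = FALSE)
  estar_at <- function(m) {
    params <- suppressWarnings(
      model_params(mu = fixed$mu, m = m, c = fixed$c, se = se,
                   si = fixed$si))
    equilibrium_numeric(params, simplex_state(0, 1, 0))$e_star
  }
  lo <- se * 1e-4            # e* near 1 here: above threshold
  hi <- se * (1 - 1e-4)      # e* near 0 here: below threshold
  stopifnot(estar_at(lo) > threshold, estar_at(hi) < threshold)
  while (hi - lo > m_tol) {
    mid <- (lo + hi) / 2
    if (estar_at(mid) > threshold) lo <- mid else hi <- mid
  }
  m_root <- (lo + hi) / 2
  list(ratio = se / m_root, m = m_root,
       analytic_ratio = 1 / (1 - threshold), threshold = threshold)
}
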