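#' Finite agent population
#'
#' Constructs the state of the finite-population stochastic counterpart of
#' the mean-field model: integer occupancies of the naive, inefficient and
#' efficient compartments. The default start mirrors the deterministic
#' analyses: everybody inefficient.
#'
#' @param N Population size (>= 1).
#' @param n,i,e Integer compartment counts summing to `N`; by default all
#'   `N` individuals are inefficient.
#' @return An `agent_population`: list with `N` and integer `counts`.
#' @examples
#' agent_population(100)
#' @export
agent_population <- function(N, n = 0L, i = N, e = 0L) {
  N <- as.integer(N)
  counts <- c(n = as.integer(n), i = as.integer(i), e = as.integer(e))
  stopifnot(N >= 1, all(counts >= 0L), sum(counts) == N)
  structure(list(N = N, counts = counts), class = "agent_population")
}

#' @export
print.agent_population <- function(x, ...) {
  cat(sprintf("Agent population, N = %d: n = %d, i = %d, e = %d\n",
              x$N, x$counts[1L], x$counts[2L], x$counts[3L]))
  invisible(x)
}

# signed incidence of the seven CTMC channels on the (n, i, e) counts;
# column order matches event_rates()
.ctmc_stoich <- cbind(
  innovation      = c(0, -1, +1),
  turnover_i      = c(+1, -1, 0),
  turnover_e      = c(+1, 0, -1),
  learn_from_i    = c(-1, +1, 0),
  learn_from_e    = c(-1, 0, +1),
  exchange_i_to_e = c(0, -1, +1),
  exchange_e_to_i = c(0, +1, -1))

#' Event-channel rates of the stochastic model
#'
#' Total firing rate of each of the seven event channels given the current
#' occupancy. Pairwise-encounter channels between classes with fractions
#' `x` and `y` and success rate `s` fire at total rate `N x y s`, so the
#' expected drift of the fractions `counts / N` equals [culture_rhs()]
#' exactly -- the finite-population model is a drift-exact lift of the ODE
#' and can serve as an independent oracle for it. Self-encounters carry no
#' `N/(N-1)` correction, keeping the drift identical by construction.
#'
#' @param pop An [agent_population()].
#' @param params A [model_params()] object.
#' @return Named numeric vector of channel rates (events per unit time).
#' @examples
#' event_rates(agent_population(100), model_params(m = 0.1, c = 0.75, se = 0.5))
#' @export
event_rates <- function(pop, params) {
  Nn <- pop$counts[[1L]]; Ni <- pop$counts[[2L]]; Ne <- pop$counts[[3L]]
  N <- pop$N
  c(innovation      = params$mu * Ni,
    turnover_i      = params$m * Ni,
    turnover_e      = params$m * Ne,
    learn_from_i    = Nn * Ni * params$si / N,
    learn_from_e    = Nn * Ne * params$se / N,
    exchange_i_to_e = (1 - params$c) * Ni * Ne * params$se / N,
    exchange_e_to_i = (1 - params$c) * Ne * Ni * params$si / N)
}

#' Expected drift of the compartment fractions
#'
#' Sums stoichiometry times rate over the channels, scaled to fractions:
#' the instantaneous expected rate of change of `counts / N`. Equals
#' [culture_rhs()] at the corresponding fractions, term by term.
#'
#' @inheritParams event_rates
#' @return Named numeric drift vector `c(n, i, e)` per unit time.
#' @export
ctmc_drift <- function(pop, params) {
  drift <- as.numeric(.ctmc_stoich %*% event_rates(pop, params)) / pop$N
  names(drift) <- c("n", "i", "e")
  drift
}

#' Exact stochastic simulation of the finite-population model
#'
#' Samples one path of the continuous-time Markov chain over the seven
#' event channels by the exact (Gillespie direct) method: no time
#' discretization, no assumed ordering of innovation, turnover and
#' learning events. Counts sum to `N` after every event; the path is
#' reproducible given `seed`.
#'
#' @inheritParams event_rates
#' @param t_max Simulation horizon (> 0).
#' @param seed Integer RNG seed (mandatory).
#' @param max_events Safety cap on the number of recorded events; exceeding
#'   it sets `truncated = TRUE` in the result.
#' @return A data frame with columns `time`, `n`, `i`, `e` (one row per
#'   event, starting at `time = 0`) carrying attribute `"truncated"`.
#' @examples
#' p <- model_params(m = 0.1, c = 0.75, se = 0.5)
#' path <- simulate_ctmc(agent_population(50), p, t_max = 10, seed = 1)
#' tail(path)
#' @export
simulate_ctmc <- function(pop, params, t_max, seed, max_events = 1e7) {
  stopifnot(t_max > 0)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  set.seed(seed)
  res <- .ctmc_path_cpp(unname(pop$counts), params$mu, params$m, params$c,
                        params$se, params$si, t_max, max_events)
  out <- data.frame(time = res$time, n = res$n, i = res$i, e = res$e)
  attr(out, "truncated") <- res$truncated
  out
}

#' Ensemble of stochastic replicates sampled on a time grid
#'
#' Runs `n_rep` independent CTMC replicates and records the compartment
#' counts at the requested output times, returning per-time ensemble means
#' and Monte Carlo standard errors of the fractions. This is the workhorse
#' for checking mean-field convergence: as `N` grows the ensemble-mean
#' fraction path approaches the ODE solution.
#'
#' @inheritParams simulate_ctmc
#' @param times Non-decreasing output times (>= 0).
#' @param n_rep Number of replicates (>= 2).
#' @return A `ctmc_ensemble`: list with `times`, `mean` and `se` (matrices
#'   with columns `n`, `i`, `e`, fractions), `n_rep`, `N`, and the raw
#'   per-replicate efficient-fraction matrix `e_paths`
#'   (times x replicates).
#' @examples
#' \donttest{
#' p <- model_params(m = 0.1, c = 0.75, se = 0.5)
#' ens <- ctmc_ensemble(agent_population(200), p, times = c(10, 25, 50),
#'                      n_rep = 20, seed = 1)
#' ens$mean
#' }
#' @export
ctmc_ensemble <- function(pop, params, times, n_rep, seed) {
  stopifnot(n_rep >= 2, all(times >= 0), !is.unsorted(times))
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  set.seed(seed)
  acc <- array(NA_real_, dim = c(length(times), 3L, n_rep))
  for (r in seq_len(n_rep)) {
    counts <- .ctmc_sample_cpp(unname(pop$counts), params$mu, params$m,
                               params$c, params$se, params$si, times)
    acc[, , r] <- counts / pop$N
  }
  mean_mat <- apply(acc, c(1, 2), mean)
  se_mat <- apply(acc, c(1, 2), stats::sd) / sqrt(n_rep)
  colnames(mean_mat) <- colnames(se_mat) <- c("n", "i", "e")
  structure(list(times = times, mean = mean_mat, se = se_mat,
                 n_rep = n_rep, N = pop$N,
                 e_paths = acc[, 3L, , drop = TRUE]),
            class = "ctmc_ensemble")
}

#' @export
print.ctmc_ensemble <- function(x, ...) {
  cat(sprintf("CTMC ensemble: N = %d, %d replicates, %d output times\n",
              x$N, x$n_rep, length(x$times)))
  invisible(x)
}
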