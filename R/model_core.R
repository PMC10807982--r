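#' Right-hand side of the compartmental model
#'
#' Evaluates the time derivatives of the naive, inefficient and efficient
#' fractions under innovation, population turnover and mass-action social
#' learning:
#' \deqn{n' = m i + m e - n e s_e - n i s_i}
#' \deqn{i' = -\mu i - m i + n i s_i + (1-c) e i s_i - (1-c) i e s_e}
#' \deqn{e' = \mu i - m e + n e s_e - (1-c) e i s_i + (1-c) i e s_e}
#' Naive individuals always attempt to learn on encounter; knowledgeable
#' individuals do so with probability `1 - c`. There is no cultural loss:
#' efficient individuals never revert spontaneously. The three derivatives
#' sum to zero (constant population size).
#'
#' @param state A `simplex_state` or numeric triple `(n, i, e)`.
#' @param params A [model_params()] object.
#' @return Named numeric vector `c(n, i, e)` of derivatives per unit time.
#' @examples
#' p <- model_params(m = 0.1, c = 0.75, se = 0.5)
#' culture_rhs(simplex_state(0, 1, 0), p)
#' @export
culture_rhs <- function(state, params) {
  s <- as_state(state)
  n <- s[["n"]]; i <- s[["i"]]; e <- s[["e"]]
  mu <- params$mu; m <- params$m; cc <- params$c
  se <- params$se; si <- params$si
  dn <- m * i + m * e - n * e * se - n * i * si
  di <- -mu * i - m * i + n * i * si + (1 - cc) * e * i * si -
    (1 - cc) * i * e * se
  de <- mu * i - m * e + n * e * se - (1 - cc) * e * i * si +
    (1 - cc) * i * e * se
  c(n = dn, i = di, e = de)
}

#' Per-process flow decomposition
#'
#' Splits the right-hand side into the seven directed flows of the model's
#' flow diagram: innovation (i to e), turnover of inefficient and efficient
#' individuals (to n), naive individuals learning from inefficient or
#' efficient individuals, and the conservatism-damped exchange between the
#' two knowledgeable compartments. Each flow is non-negative in its stated
#' direction, and the signed per-compartment sums reconstruct
#' [culture_rhs()] exactly.
#'
#' @inheritParams culture_rhs
#' @return Named numeric vector of flow magnitudes: `innovation`,
#'   `turnover_i`, `turnover_e`, `learn_from_i`, `learn_from_e`,
#'   `exchange_i_to_e`, `exchange_e_to_i`.
#' @examples
#' p <- model_params(m = 0.1, c = 0.75, se = 0.5)
#' flow_decomposition(simplex_state(0, 1, 0), p)
#' @export
flow_decomposition <- function(state, params) {
  s <- as_state(state)
  n <- s[["n"]]; i <- s[["i"]]; e <- s[["e"]]
  c(innovation      = params$mu * i,
    turnover_i      = params$m * i,
    turnover_e      = params$m * e,
    learn_from_i    = n * i * params$si,
    learn_from_e    = n * e * params$se,
    exchange_i_to_e = (1 - params$c) * i * e * params$se,
    exchange_e_to_i = (1 - params$c) * e * i * params$si)
}

# internal: signed incidence of each flow on (n, i, e); columns are the
# flows of flow_decomposition() in order
flow_incidence <- function() {
  m <- cbind(
    innovation      = c(0, -1, +1),
    turnover_i      = c(+1, -1, 0),
    turnover_e      = c(+1, 0, -1),
    learn_from_i    = c(-1, +1, 0),
    learn_from_e    = c(-1, 0, +1),
    exchange_i_to_e = c(0, -1, +1),
    exchange_e_to_i = c(0, +1, -1))
  rownames(m) <- c("n", "i", "e")
  m
}
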