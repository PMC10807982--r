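# reference configuration used throughout the analyses: all-inefficient
# start, mu = 0.01, si = 0.1, se = 0.5, c = 0.75, with m varied
ref_params <- function(m = 0.1, c = 0.75, se = 0.5, mu = 0.01, si = 0.1) {
  model_params(mu = mu, m = m, c = c, se = se, si = si)
}

all_inefficient <- function() simplex_state(0, 1, 0)

# uniform draw on the 2-simplex (symmetric Dirichlet(1,1,1))
random_simplex <- function() {
  g <- stats::rexp(3)
  g / sum(g)
}

# random admissible parameters respecting the standing assumption se > si
random_params <- function() {
  model_params(mu = stats::runif(1, 0, 0.05),
               m = stats::runif(1, 0, 0.5),
               c = stats::runif(1),
               se = stats::runif(1, 0.15, 1),
               si = stats::runif(1, 0, 0.1))
}
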