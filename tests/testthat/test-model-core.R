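test_that("parameter validation accepts admissible values and rejects bounds violations", {
  p <- validate_params(list(mu = 0.01, m = 0.1, c = 0.75, se = 0.5, si = 0.1))
  expect_s3_class(p, "model_params")
  expect_identical(unlist(p[c("mu", "m", "c", "se", "si")]),
                   c(mu = 0.01, m = 0.1, c = 0.75, se = 0.5, si = 0.1))

  # all-zero boundary is admissible, but se = si violates the standing
  # assumption and warns
  expect_warning(p0 <- validate_params(list(mu = 0, m = 0, c = 0, se = 0,
                                            si = 0)),
                 "se")
  expect_s3_class(p0, "model_params")

  expect_error(validate_params(list(mu = 0.01, m = 0.1, c = 1.5, se = 0.5,
                                    si = 0.1)), "'c'")
  expect_error(validate_params(list(mu = 0.01, m = -0.1, c = 0.5, se = 0.5,
                                    si = 0.1)), "'m'")
  expect_error(validate_params(list(mu = 0.01, m = 0.1, c = 0.5, se = 0.5)),
               "si")
})

test_that("simplex states are validated on construction", {
  s <- simplex_state(0.2, 0.3, 0.5)
  expect_equal(sum(s), 1)
  expect_error(simplex_state(0.5, 0.5, 0.5), "sum to 1")
  expect_error(simplex_state(-0.1, 0.6, 0.5), "\\[0, 1\\]")
})

test_that("the right-hand side matches hand substitution", {
  p <- ref_params(m = 0.1)
  expect_equal(culture_rhs(simplex_state(0, 1, 0), p),
               c(n = 0.1, i = -0.11, e = 0.01))

  # with c = 1 both exchange terms vanish
  p2 <- suppressWarnings(
    validate_params(list(mu = 0, m = 0, c = 1, se = 0.5, si = 0.1)))
  expect_equal(culture_rhs(simplex_state(1/3, 1/3, 1/3), p2),
               c(n = -1/15, i = 1/90, e = 1/18))

  p0 <- suppressWarnings(
    validate_params(list(mu = 0, m = 0, c = 0, se = 0, si = 0)))
  expect_equal(culture_rhs(simplex_state(0.2, 0.3, 0.5), p0),
               c(n = 0, i = 0, e = 0))
})

test_that("derivatives conserve population and fix the all-naive state", {
  set.seed(11)
  for (k in 1:100) {
    s <- random_simplex()
    p <- random_params()
    d <- culture_rhs(s, p)
    expect_lt(abs(sum(d)), 1e-14)
  }
  for (k in 1:20) {
    expect_equal(unname(culture_rhs(c(1, 0, 0), random_params())),
                 c(0, 0, 0))
  }
})

test_that("full conservatism reduces to the system without i-e exchange", {
  reduced_rhs <- function(s, p) {
    n <- s[1]; i <- s[2]; e <- s[3]
    c(p$m * (i + e) - n * e * p$se - n * i * p$si,
      -p$mu * i - p$m * i + n * i * p$si,
      p$mu * i - p$m * e + n * e * p$se)
  }
  set.seed(12)
  for (k in 1:50) {
    s <- random_simplex()
    p <- model_params(mu = runif(1, 0, 0.05), m = runif(1, 0, 0.5), c = 1,
                      se = runif(1, 0.15, 1), si = runif(1, 0, 0.1))
    expect_equal(unname(culture_rhs(s, p)), unname(reduced_rhs(s, p)),
                 tolerance = 1e-14)
  }
})

test_that("with se = si and mu = 0 the i and e equations are exchange-symmetric", {
  set.seed(13)
  for (k in 1:50) {
    s <- random_simplex()
    p <- suppressWarnings(validate_params(list(
      mu = 0, m = runif(1, 0, 0.5), c = runif(1), se = 0.3, si = 0.3)))
    d <- culture_rhs(c(s[1], s[2], s[3]), p)
    d_swapped <- culture_rhs(c(s[1], s[3], s[2]), p)
    expect_equal(unname(d[c("i", "e")]), unname(d_swapped[c("e", "i")]),
                 tolerance = 1e-14)
  }
})

test_that("flow decomposition reconstructs the derivatives and is directionally non-negative", {
  # signed incidence of each directed flow on (n, i, e), written out by hand
  incidence <- rbind(
    n = c(innovation = 0, turnover_i = 1, turnover_e = 1,
          learn_from_i = -1, learn_from_e = -1,
          exchange_i_to_e = 0, exchange_e_to_i = 0),
    i = c(-1, -1, 0, 1, 0, -1, 1),
    e = c(1, 0, -1, 0, 1, 1, -1))
  set.seed(14)
  for (k in 1:100) {
    s <- random_simplex()
    p <- random_params()
    fl <- flow_decomposition(s, p)
    expect_true(all(fl >= 0))
    expect_equal(as.numeric(incidence %*% fl),
                 unname(culture_rhs(s, p)), tolerance = 1e-14)
  }

  fl <- flow_decomposition(simplex_state(0, 1, 0), ref_params(m = 0.1))
  expect_equal(fl[["innovation"]], 0.01)
  expect_equal(fl[["turnover_i"]], 0.1)
  expect_true(all(fl[c("learn_from_i", "learn_from_e", "exchange_i_to_e",
                       "exchange_e_to_i")] == 0))

  # the all-naive state carries no flow at all
  expect_true(all(flow_decomposition(c(1, 0, 0), ref_params(m = 0.3)) == 0))
})
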