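test_that("the half-adoption time sweep reflects turnover acceleration and unreachability", {
  g <- sweep_th(c(0, 0.1, 0.3), c(0.5, 0.75), fixed = list(se = 0.5))
  expect_s3_class(g, "sweep_grid")
  # at c = 0.75, turnover m = 0.1 beats m = 0
  expect_lt(g$values[2, 2], g$values[1, 2])
  # m = 0.3 gives e* = 0.4 < 1/2: unreachable, marked, not a sentinel
  expect_false(g$reachable[3, 1])
  expect_false(g$reachable[3, 2])
  expect_true(is.na(g$values[3, 1]))
  expect_true(all(g$values[g$reachable] > 0))
})

test_that("a single-cell sweep equals the direct threshold computation", {
  g <- sweep_th(0.1, 0.75, fixed = list(se = 0.5))
  direct <- time_to_threshold(ref_params(m = 0.1), all_inefficient())
  expect_identical(g$values[1, 1], direct$t_h)
})

test_that("equilibrium sweeps agree between closed form and integration", {
  m_grid <- c(0, 0.1, 0.3, 0.7)
  se_grid <- c(0.2, 0.5, 0.9)
  g_an <- sweep_estar(m_grid, se_grid, fixed = list(c = 0.75))
  g_num <- sweep_estar(m_grid, se_grid, fixed = list(c = 0.75),
                       mode = "numeric")
  expect_equal(g_an$values[2, 2], 0.8)       # m = 0.1, se = 0.5
  expect_true(all(g_an$values[1, ] == 1))    # no turnover: fixation
  ext <- outer(m_grid, se_grid, ">")
  expect_true(all(g_an$values[ext] == 0))
  expect_true(all(g_num$reachable))
  expect_lt(max(abs(g_an$values - g_num$values)), 1e-4)
})

test_that("turnover sensitivity of t_h has the expected signs and is stencil-converged", {
  s_conservative <- th_sensitivity(0.05, 0.75, fixed = list(se = 0.5))
  expect_lt(s_conservative, 0)  # conservative group: turnover accelerates

  s_open <- th_sensitivity(0.05, 0, fixed = list(se = 0.5))
  expect_gt(s_open, 0)          # no conservatism: newcomers only dilute

  s_half <- th_sensitivity(0.05, 0.75, fixed = list(se = 0.5), dm = 5e-4)
  expect_lt(abs(s_half - s_conservative) / abs(s_conservative), 0.05)

  expect_error(th_sensitivity(0.3, 0.75, fixed = list(se = 0.5)),
               "unreachable")
})

test_that("the critical curve separates acceleration from deceleration and is reproducible", {
  m_vals <- c(0.03, 0.06, 0.1)
  curve <- critical_curve(m_vals, fixed = list(se = 0.5))
  expect_identical(curve$m, m_vals)
  expect_true(all(curve$c > 0 & curve$c < 1))
  # the curve rises with m, and c = 0.75 sits above it at small m
  expect_true(all(diff(curve$c) > 0))
  expect_gt(0.75, curve$c[curve$m == 0.06])

  # sign coherence on either side of the curve
  expect_lt(th_sensitivity(0.06, curve$c[2] + 0.1, fixed = list(se = 0.5)), 0)
  expect_gt(th_sensitivity(0.06, curve$c[2] - 0.1, fixed = list(se = 0.5)), 0)

  # bisection result independent of bracket refinement
  curve_fine <- critical_curve(m_vals, fixed = list(se = 0.5), n_scan = 21L)
  expect_lt(max(abs(curve$c - curve_fine$c)), 1e-4)

  # beyond the region where the line exists, points are omitted with a log
  # message, not an error
  expect_message(omitted <- critical_curve(0.2, fixed = list(se = 0.5)),
                 "omitted")
  expect_identical(nrow(omitted), 0L)
})

test_that("faster social learning enlarges the turnover-acceleration region", {
  c_at <- function(se) critical_curve(0.05, fixed = list(se = se))$c
  expect_lt(c_at(0.8), c_at(0.5))
})

test_that("the critical learning/turnover ratio is 1/(1 - threshold), independent of c and si", {
  cr <- critical_ratio(fixed = list(c = 0.75), se = 0.5)
  expect_lt(abs(cr$ratio - 2), 1e-3)
  expect_equal(cr$analytic_ratio, 2)

  cr9 <- critical_ratio(fixed = list(c = 0.75), se = 0.5, threshold = 0.9)
  expect_lt(abs(cr9$ratio - 10), 1e-3)

  cr_c <- critical_ratio(fixed = list(c = 0.2), se = 0.5)
  cr_si <- critical_ratio(fixed = list(c = 0.75, si = 0.02), se = 0.5)
  expect_lt(abs(cr_c$ratio - cr$ratio), 1e-3)
  expect_lt(abs(cr_si$ratio - cr$ratio), 1e-3)
})
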