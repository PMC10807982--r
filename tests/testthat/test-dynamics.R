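test_that("without turnover the efficient solution sweeps to fixation monotonically", {
  p <- ref_params(m = 0)
  traj <- integrate_culture(p, all_inefficient(), t_max = 1000,
                            resolution = 501)
  e <- traj$states[, "e"]
  expect_true(all(diff(e) >= -1e-10))
  expect_gt(e[length(e)], 0.999)
  expect_lt(max(traj$states[, "i"][501]), 1e-3)
  # no naive inflow when m = 0 and n0 = 0
  expect_lt(max(abs(traj$states[, "n"])), 1e-9)
})

test_that("trajectories preserve the simplex and the all-naive state is constant", {
  set.seed(21)
  for (k in 1:10) {
    p <- random_params()
    traj <- integrate_culture(p, all_inefficient(), t_max = 200,
                              resolution = 101)
    expect_lt(max(abs(rowSums(traj$states) - 1)), 1e-7)
    expect_true(all(traj$states > -1e-7 & traj$states < 1 + 1e-7))
  }
  traj <- integrate_culture(ref_params(m = 0.3), simplex_state(1, 0, 0),
                            t_max = 500, resolution = 51)
  expect_lt(max(abs(traj$states[, "n"] - 1)), 1e-9)
})

test_that("adaptive integration agrees with fixed-step Euler and RK4 references", {
  set.seed(22)
  configs <- c(list(ref_params(m = 0.1)),
               replicate(3, random_params(), simplify = FALSE))
  for (p in configs) {
    ad <- integrate_culture(p, all_inefficient(), t_max = 100,
                            resolution = 101)
    rk <- fixed_step_integrate(p, all_inefficient(), t_max = 100, h = 1e-4,
                               resolution = 101, method = "rk4")
    expect_lt(max(abs(ad$states - rk$states)), 1e-5)
    # Euler is first-order: its truncation error at h = 1e-4 caps the
    # achievable agreement around 1e-4
    eu <- fixed_step_integrate(p, all_inefficient(), t_max = 100, h = 1e-4,
                               resolution = 101, method = "euler")
    expect_lt(max(abs(ad$states - eu$states)), 1e-4)
  }
})

test_that("turnover m = 0.1 reaches half-adoption sooner than m = 0", {
  t_m0 <- time_to_threshold(ref_params(m = 0), all_inefficient())
  t_m01 <- time_to_threshold(ref_params(m = 0.1), all_inefficient())
  expect_true(t_m0$reached && t_m01$reached)
  expect_lt(t_m01$t_h, t_m0$t_h)
})

test_that("threshold crossing is located accurately and t_h = 0 below the start", {
  p <- ref_params(m = 0.1)
  res <- time_to_threshold(p, all_inefficient(), threshold = 0.5)
  traj <- integrate_culture(p, all_inefficient(), t_max = res$t_h,
                            resolution = 2)
  expect_lt(abs(traj$states[2, "e"] - 0.5), 1e-6)

  res0 <- time_to_threshold(p, simplex_state(0, 0.4, 0.6), threshold = 0.5)
  expect_identical(res0$t_h, 0)
  expect_true(res0$reached)

  # a trajectory object can stand in for (params, initial)
  traj2 <- integrate_culture(p, all_inefficient(), t_max = 100)
  res2 <- time_to_threshold(traj2)
  expect_equal(res2$t_h, res$t_h, tolerance = 1e-8)
})

test_that("unreachable thresholds are distinguished from too-small horizons", {
  # m = 0.3 > se/2: equilibrium e* = 0.4 can never cross one half
  res <- time_to_threshold(ref_params(m = 0.3), all_inefficient(),
                           threshold = 0.5)
  expect_false(res$reached)
  expect_true(is.na(res$t_h))

  # reachable in principle, but the horizon is too short: an error, not a
  # silent "never reached"
  expect_error(time_to_threshold(ref_params(m = 0.1), all_inefficient(),
                                 threshold = 0.5, t_max = 1),
               class = "turnlearn_horizon_error")
})

test_that("numerical equilibria match the known long-run states", {
  eq <- equilibrium_numeric(ref_params(m = 0.1), all_inefficient())
  expect_lt(abs(eq$e_star - 0.8), 1e-4)
  expect_lt(eq$state[["i"]], 1e-4)
  expect_equal(eq$regime, "persistence")
  expect_lt(eq$residual, 1e-9)

  eq_ext <- equilibrium_numeric(suppressWarnings(ref_params(m = 0.6)),
                                all_inefficient())
  expect_lt(abs(eq_ext$state[["n"]] - 1), 1e-4)
  expect_equal(eq_ext$regime, "extinction")

  eq_naive <- equilibrium_numeric(ref_params(m = 0.1),
                                  simplex_state(1, 0, 0))
  expect_identical(unname(eq_naive$state), c(1, 0, 0))
  expect_equal(eq_naive$regime, "degenerate_all_naive")
})

test_that("with innovation the inefficient solution goes extinct from any seeded start", {
  set.seed(23)
  for (k in 1:5) {
    s <- random_simplex()
    if (s[2] + s[3] < 0.01) next
    p <- random_params()
    eq <- equilibrium_numeric(p, simplex_state(s[1], s[2], s[3]))
    expect_lt(eq$state[["i"]], 1e-6)
  }
})
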