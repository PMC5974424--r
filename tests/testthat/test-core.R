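test_that("PLL profile follows injection and exponential decay", {
  p <- plateau()
  s1 <- dose_schedule(1, interval = 1)
  tr1 <- constant_trajectory(1, p$repair_rate0)
  # initial condition: one unit cohort per Gy per relative DNA content
  expect_equal(pll_profile(0, s1, tr1, p), 1)
  # one e-folding time later
  expect_equal(pll_profile(1 / 0.704, s1, tr1, p), exp(-1), tolerance = 1e-12)

  # two fractions: value just after the second injection (hand evaluation)
  s2 <- dose_schedule(c(1, 1), interval = 0.5)
  tr2 <- constant_trajectory(2, 0.704)
  expect_equal(pll_profile(0.5, s2, tr2, p), exp(-0.352) + 1,
               tolerance = 1e-12)

  expect_error(pll_profile(-1, s1, tr1, p), class = "imk_domain_error")
  expect_error(pll_profile(0, s2, tr1, p), class = "imk_config_error")
})

test_that("PLL profile matches the linearized-ODE oracle on random schedules", {
  skip_if_not_installed("deSolve")
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(2:5, 1)
    sched <- dose_schedule(runif(n, 0.5, 3), interval = runif(1, 0.2, 1.5))
    traj <- cell_state_trajectory(runif(n, 0.8, 1.4), runif(n, 0.8, 2),
                                  runif(n, 0.3, 2.5))
    p <- imk_parameters(0.15, 0.05, 1, a_rate = runif(1, 0, 0.05),
                        gamma = 0.9)
    # trajectory rate entries are c_n; engine adds a_rate itself
    t_eval <- sort(runif(4, 0, sched$delivery_time * 1.5))
    expect_equal(pll_profile(t_eval, sched, traj, p),
                 ode_pll_oracle(t_eval, sched, traj, p),
                 tolerance = 1e-8)
  }
})

test_that("state coefficients reduce and rescale correctly", {
  p <- plateau()
  tr_const <- constant_trajectory(3, p$repair_rate0)
  co <- state_coefficients(1, 2, tr_const, p)
  expect_equal(co$alpha_n, p$alpha0)
  expect_equal(co$beta_n, p$beta0)
  expect_equal(co$beta_nm, p$beta0)

  # plateau baseline with a later log-phase state: published converted values
  tr <- cell_state_trajectory(g_rel = c(1, 1.227), g2_rel = c(1, 1.457),
                              c_rates = c(0.704, 1.782))
  co2 <- state_coefficients(2, 2, tr, p)
  expect_equal(co2$alpha_n, 0.075, tolerance = 2e-2)
  expect_equal(co2$beta_n, 0.028, tolerance = 2e-2)

  expect_error(state_coefficients(0, 2, tr, p), class = "imk_config_error")
})

test_that("lethal-lesion yield reproduces hand-evaluated cases", {
  p <- plateau()
  # zero dose
  s0 <- dose_schedule(c(0, 0), interval = 1)
  t0 <- lethal_lesion_yield(s0, constant_trajectory(2, 0.704), p)
  expect_equal(t0$w_mean, 0)
  expect_equal(t0$survival, 1)

  # single acute fraction = LQ closed form: 2 Gy plateau
  s1 <- dose_schedule(2, interval = 1)
  t1 <- lethal_lesion_yield(s1, constant_trajectory(1, 0.704), p)
  expect_equal(t1$w_mean, (0.155 + 0.924 * 0.048) * 2 + 0.048 * 4,
               tolerance = 1e-12)
  expect_equal(t1$survival, 0.554, tolerance = 1e-3)

  # two fractions of 1.5 Gy at 0.5 h: hand evaluation of the full sum
  s2 <- dose_schedule(c(1.5, 1.5), interval = 0.5)
  t2 <- lethal_lesion_yield(s2, constant_trajectory(2, 0.704), p)
  expect_equal(t2$w_mean, 0.598056 + 0.216 + 0.216 * exp(-0.352),
               tolerance = 1e-9)

  expect_error(
    lethal_lesion_yield(s2, constant_trajectory(3, 0.704), p),
    class = "imk_config_error")
})

test_that("tally term groups are non-negative and sum exactly to the total", {
  p <- plateau()
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(1:6, 1)
    sched <- dose_schedule(runif(n, 0, 4), interval = runif(1, 0.1, 2))
    traj <- cell_state_trajectory(runif(n, 0.7, 1.5), runif(n, 0.7, 2.2),
                                  runif(n, 0.2, 3))
    tally <- lethal_lesion_yield(sched, traj, p)
    expect_gte(tally$linear, 0)
    expect_gte(tally$quadratic, 0)
    expect_gte(tally$cross, 0)
    expect_identical(tally$w_mean, tally$linear + tally$quadratic + tally$cross)
    expect_true(tally$survival > 0 && tally$survival <= 1)
  }
})

test_that("survival decreases with dose and increases when a fraction is split", {
  p <- plateau()
  s <- dose_schedule(c(2, 2, 2), interval = 0.5)
  tr <- constant_trajectory(3, 0.704)
  s_double <- dose_schedule(c(4, 4, 4), interval = 0.5)
  expect_lt(survival_fraction(s_double, tr, p), survival_fraction(s, tr, p))

  # splitting one acute dose into two separated halves never lowers survival
  acute <- survival_fraction(dose_schedule(4, 1), constant_trajectory(1, 0.704), p)
  for (tau in c(0.25, 1, 4)) {
    split <- survival_fraction(dose_schedule(c(2, 2), tau),
                               constant_trajectory(2, 0.704), p)
    expect_gte(split, acute)
  }
})

test_that("symmetric cross-rate convention coincides with the printed form when state is constant", {
  p <- plateau()
  s <- dose_schedule(c(1.5, 1.5, 1.5), interval = 0.5)
  tr_const <- constant_trajectory(3, 0.704)
  expect_equal(lethal_lesion_yield(s, tr_const, p, cross_rate = "symmetric")$w_mean,
               lethal_lesion_yield(s, tr_const, p, cross_rate = "earlier")$w_mean)
  tr_var <- cell_state_trajectory(rep(1, 3), rep(1, 3), c(0.5, 1, 2))
  expect_false(isTRUE(all.equal(
    lethal_lesion_yield(s, tr_var, p, cross_rate = "symmetric")$w_mean,
    lethal_lesion_yield(s, tr_var, p, cross_rate = "earlier")$w_mean)))
})
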