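test_that("Lea-Catcheside factor has correct limits and values", {
  expect_equal(lea_catcheside_factor(0.704, 0), 1)
  expect_equal(lea_catcheside_factor(0.704, 12), 0.2087, tolerance = 5e-4)
  # long-exposure asymptote 2 / (k T)
  expect_equal(lea_catcheside_factor(0.704, 1e5), 2 / (0.704 * 1e5),
               tolerance = 1e-4)
  expect_gt(lea_catcheside_factor(0.704, 6), lea_catcheside_factor(0.704, 12))
  expect_error(lea_catcheside_factor(-1, 5), class = "imk_domain_error")
  expect_error(lea_catcheside_factor(0.704, -1), class = "imk_domain_error")
})

test_that("protraction factor matches brute-force double integration and stays in (0,1]", {
  for (k in c(0.3, 0.704, 1.782)) {
    for (T in c(0.05, 1, 6, 12)) {
      q <- lea_catcheside_factor(k, T)
      expect_true(q > 0 && q <= 1)
      expect_equal(q, brute_force_q(k, T), tolerance = 1e-8)
    }
  }
})

test_that("acute LQ survival matches arithmetic from the packaged parameters", {
  p <- plateau()
  expect_equal(acute_lq(0, p), 1)
  # effective linear coefficient alpha0 + gamma*beta0 = 0.1994 Gy^-1
  expect_equal(-log(acute_lq(1, p)) - p$beta0, 0.155 + 0.924 * 0.048,
               tolerance = 1e-12)
  expect_equal(acute_lq(2, p), 0.554, tolerance = 1e-3)
})

test_that("continuous survival reduces to the acute limit and spares at low rates", {
  p <- plateau()
  expect_equal(continuous_survival(0, 1, p), 1)
  expect_equal(continuous_survival(4, 1e9, p), acute_lq(4, p),
               tolerance = 1e-9)
  # classic dose-rate sparing at constant cell state
  expect_gt(continuous_survival(6, 0.5, p), continuous_survival(6, 3, p))
  expect_gt(continuous_survival(6, 3, p), continuous_survival(6, 60, p))
  expect_error(continuous_survival(6, 0, p), class = "imk_domain_error")
})

test_that("continuous closed form is the fine-fractionation limit of the engine", {
  p <- plateau()
  # spec'd oracle case: 6 Gy at 3.0 Gy/h vs 1e4 micro-fractions
  s_cont <- continuous_survival(6, 3.0, p)
  n <- 1e4
  sched <- dose_schedule(rep(6 / n, n), interval = 2 / n)
  s_frac <- survival_fraction(sched, constant_trajectory(n, 0.704), p)
  expect_equal(log(s_frac), log(s_cont), tolerance = 1e-3)

  # property: convergence at N = 1000 across random parameter draws
  set.seed(11)
  for (rep in 1:3) {
    pr <- imk_parameters(runif(1, 0.05, 0.3), runif(1, 0.01, 0.08),
                         runif(1, 0.4, 2), gamma = runif(1, 0.5, 1.5))
    D <- runif(1, 2, 8); rate <- runif(1, 0.5, 6); n <- 1000
    sched <- dose_schedule(rep(D / n, n), interval = (D / rate) / n)
    w_frac <- lethal_lesion_yield(sched, constant_trajectory(n, pr$repair_rate0),
                                  pr)$w_mean
    expect_equal(w_frac, -log(continuous_survival(D, rate, pr)),
                 tolerance = 1e-3)
  }
})

test_that("effective LQ coefficients degrade with delivery time", {
  p <- plateau()
  co0 <- lq_coefficients(p, 0)
  expect_equal(co0$beta_eff, p$beta0)
  expect_equal(co0$alpha, 0.155 + 0.924 * 0.048)
  Ts <- c(0.5, 2, 6, 12, 24)
  betas <- vapply(Ts, function(T) lq_coefficients(p, T)$beta_eff, numeric(1))
  expect_true(all(diff(betas) < 0))
  expect_true(all(betas <= p$beta0 & betas > 0))
})

test_that("regimen designer reproduces the published equivalent regimens", {
  r3 <- design_equivalent_regimen(3.0, 1.5, 12)
  expect_equal(r3$interval, 0.5)
  expect_equal(r3$n_fractions, 24L)
  r6 <- design_equivalent_regimen(6.0, 2.0, 12)
  expect_equal(r6$interval, 1 / 3)
  expect_equal(r6$n_fractions, 36L)
  r1 <- design_equivalent_regimen(1.0, 1.0, 12)
  expect_equal(r1$interval, 1)
  expect_equal(r1$n_fractions, 12L)
  expect_error(design_equivalent_regimen(3.0, 1.5, 12.2),
               class = "imk_domain_error")
})

test_that("designed regimens emulate their continuous dose-rate to R^2 >= 0.999", {
  p <- plateau()
  expect_equal(r_squared(1:5, 1:5), 1)  # identical curves
  expect_gte(regimen_equivalence_r2(design_equivalent_regimen(3.0, 1.5, 12), p),
             0.999)
  expect_gte(regimen_equivalence_r2(design_equivalent_regimen(6.0, 2.0, 12), p),
             0.999)
  expect_error(regimen_equivalence_r2(dose_schedule(2, 1), p),
               class = "imk_domain_error")
})
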