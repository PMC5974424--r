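test_that("differential SLDR rate reproduces the two-phase anchor value", {
  pl <- cho_k1_phase_stats("plateau")
  lg <- cho_k1_phase_stats("log")
  expect_equal(differential_sldr_rate(pl, lg), (1.782 - 0.704) / (52.4 - 14.9),
               tolerance = 1e-12)
  expect_equal(differential_sldr_rate(pl, lg), 0.0287, tolerance = 2e-3)
  # order-invariant, zero for identical rates
  expect_equal(differential_sldr_rate(lg, pl), differential_sldr_rate(pl, lg))
  other <- cell_phase_stats(60, 28, 12, 1.1, 1.2, pl$c)
  expect_equal(differential_sldr_rate(pl, other), 0)
  expect_error(differential_sldr_rate(pl, pl), class = "imk_domain_error")
})

test_that("interpolation is exact at samples, bounded per segment, constant outside", {
  tc <- cell_cycle_timecourse(c(0, 2, 4, 6, 8), c(15, 16, 25, 30, 29),
                              c(1, 1.01, 1.06, 1.1, 1.09))
  expect_equal(interpolate_timecourse(tc, c(0, 2, 4, 6, 8)),
               c(15, 16, 25, 30, 29))
  # constant extrapolation outside the window
  expect_equal(interpolate_timecourse(tc, c(-3, 12)), c(15, 29))
  # monotone-segment interpolant stays within neighbouring sample values
  for (seg in 1:4) {
    t_dense <- seq(tc$time_h[seg], tc$time_h[seg + 1], length.out = 101)
    v <- interpolate_timecourse(tc, t_dense)
    lo <- min(tc$s_fraction_pct[seg + 0:1]); hi <- max(tc$s_fraction_pct[seg + 0:1])
    expect_true(all(v >= lo - 1e-9 & v <= hi + 1e-9))
  }
  flat <- cell_cycle_timecourse(c(0, 4, 8), rep(20, 3), rep(1, 3))
  expect_equal(interpolate_timecourse(flat, seq(0, 8, 0.5)), rep(20, 17))
  expect_error(cell_cycle_timecourse(0, 15, 1), class = "imk_data_error")
})

test_that("S-phase-dependent SLDR rate follows the differential law", {
  tc <- generate_synthetic_timecourse(magnitude = 37.5, t_max = 12)
  expect_equal(sldr_rate_at(0, tc, 0.704, 0.0287), 0.704)
  # full plateau-to-log S-phase shift reproduces the log-phase rate
  c_end <- sldr_rate_at(12, tc, 0.704, 0.0287)
  expect_equal(c_end, 0.704 + 0.0287 * 37.5, tolerance = 1e-6)
  expect_equal(c_end, 1.780, tolerance = 1e-3)
  # flat time course leaves the rate at c0 everywhere
  flat <- generate_synthetic_timecourse(pattern = "flat", t_max = 12)
  expect_equal(sldr_rate_at(c(0, 3, 7, 12), flat, 0.704, 0.0287), rep(0.704, 4))
  # nonphysical negative rates are clamped with a warning
  expect_warning(ct <- sldr_rate_at(12, tc, 0.1, -0.1), "clamped")
  expect_gte(ct, 1e-6)
})

test_that("trajectories built from time courses sample the fraction grid", {
  p <- plateau()
  sched <- design_equivalent_regimen(3.0, 1.5, 12)
  flat <- generate_synthetic_timecourse(pattern = "flat", t_max = 12)
  tr_flat <- build_trajectory(sched, flat, p, dc_dns = 0.0287)
  expect_equal(tr_flat$g_rel, rep(1, 24))
  expect_equal(tr_flat$c_rates, rep(0.704, 24))
  # flat state: IMK model reduces to the constant-rate model
  expect_equal(survival_fraction(sched, tr_flat, p),
               survival_fraction(sched, constant_trajectory(24, 0.704), p),
               tolerance = 1e-12)

  # schedule outrunning the measured window keeps the last sample
  long <- dose_schedule(rep(1, 30), interval = 1)  # 30 h vs 12 h window
  tc <- generate_synthetic_timecourse(magnitude = 20, t_max = 12)
  tr_long <- build_trajectory(long, tc, p, dc_dns = 0.0287)
  expect_equal(tr_long$c_rates[14:30], rep(tr_long$c_rates[13], 17))

  # g2 conventions: square by default, anchor interpolation on request
  tr_sq <- build_trajectory(sched, tc, p, dc_dns = 0.0287, g2_mode = "square")
  expect_equal(tr_sq$g2_rel, tr_sq$g_rel^2)
  anchors <- list(cho_k1_phase_stats("plateau"), cho_k1_phase_stats("log"))
  tr_an <- build_trajectory(sched, tc, p, dc_dns = 0.0287,
                            g2_mode = "anchor", anchors = anchors)
  expect_true(all(tr_an$g2_rel >= 1 - 1e-9 & tr_an$g2_rel <= 1.457 + 1e-9))
  expect_error(build_trajectory(sched, tc, p, 0.0287, g2_mode = "anchor"),
               class = "imk_config_error")
})

test_that("trajectory endpoints reach the log-phase state coefficients", {
  # drive the S-phase fraction over the full plateau-to-log shift and check
  # that the final fraction's coefficients match the published conversion
  p <- plateau()
  tc <- generate_synthetic_timecourse(magnitude = 52.4 - 14.9, t_max = 12)
  sched <- dose_schedule(rep(1, 13), interval = 1)
  anchors <- list(cho_k1_phase_stats("plateau"), cho_k1_phase_stats("log"))
  dcdns <- differential_sldr_rate(anchors[[1]], anchors[[2]])
  tr <- build_trajectory(sched, tc, p, dc_dns = dcdns,
                         g2_mode = "anchor", anchors = anchors)
  co <- state_coefficients(13, 13, tr, p)
  expect_equal(co$alpha_n, 0.075, tolerance = 2e-2)
  expect_equal(co$beta_n, 0.028, tolerance = 2e-2)
})

test_that("phase parameter conversion matches the published set and round-trips", {
  p <- plateau()
  pl <- cho_k1_phase_stats("plateau")
  lg <- cho_k1_phase_stats("log")
  conv <- convert_phase_parameters(p, pl, lg)
  expect_equal(conv$alpha0, 0.075, tolerance = 1e-2)
  expect_equal(conv$beta0, 0.028, tolerance = 2e-2)
  expect_equal(conv$repair_rate0, 1.782)
  expect_equal(conv$gamma, p$gamma)

  ident <- convert_phase_parameters(p, pl, pl)
  expect_equal(ident$alpha0, p$alpha0)
  expect_equal(ident$beta0, p$beta0)

  back <- convert_phase_parameters(conv, lg, pl)
  expect_equal(back$alpha0, p$alpha0, tolerance = 1e-12)
  expect_equal(back$beta0, p$beta0, tolerance = 1e-12)
  expect_equal(back$repair_rate0, p$repair_rate0, tolerance = 1e-12)
})
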