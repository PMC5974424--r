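# Independent oracles used across the suite.  Each deliberately avoids the
# package's own closed forms: lesion kinetics are integrated as ODEs, the
# protraction factor as a brute-force double integral, and the LQ mean
# inactivation dose through the erfc closed form.

plateau <- function() load_parameters("cho-k1-plateau")
logphase <- function() load_parameters("cho-k1-log")

# PLL profile by numerical integration: each fraction's lesion cohort obeys
# dx/dt = -(a + c_n) x from its injection time; the profile is the cohort sum.
ode_pll_oracle <- function(t, schedule, trajectory, params) {
  rates <- params$a_rate + trajectory$c_rates
  vapply(t, function(ti) {
    total <- 0
    for (n in seq_len(schedule$n_fractions)) {
      t0 <- schedule$start_times[n]
      if (t0 > ti + 1e-12) next
      x0 <- trajectory$g_rel[n] * schedule$fraction_doses[n]
      if (ti - t0 < 1e-12) {
        total <- total + x0
      } else {
        sol <- deSolve::ode(
          y = c(x = x0), times = c(t0, ti),
          func = function(time, y, p) list(-p$k * y), parms = list(k = rates[n]),
          rtol = 1e-12, atol = 1e-14)
        total <- total + sol[nrow(sol), "x"]
      }
    }
    total
  }, numeric(1))
}

# Lea-Catcheside factor by brute-force double integration of the repair
# kernel over the delivery square: q = (2/T^2) Int_0^T Int_0^t e^{-k(t-s)} ds dt
brute_force_q <- function(k, T) {
  outer_f <- function(tv) {
    vapply(tv, function(t) {
      stats::integrate(function(s) exp(-k * (t - s)), 0, t,
                       rel.tol = 1e-11)$value
    }, numeric(1))
  }
  2 / T^2 * stats::integrate(outer_f, 0, T, rel.tol = 1e-10)$value
}

# Mean inactivation dose of exp(-(alpha D + beta D^2)) in closed form
lq_dbar_closed_form <- function(alpha, beta) {
  if (beta == 0) return(1 / alpha)
  erfc <- function(x) 2 * stats::pnorm(-x * sqrt(2))
  sqrt(pi / (4 * beta)) * exp(alpha^2 / (4 * beta)) * erfc(alpha / (2 * sqrt(beta)))
}

# Value the 0-1 h secant / 2 h plateau convention returns on an exact
# split-dose model curve with true composite rate k (hand-derived:
# numerator R(1-e^{-k}), denominator R(1-e^{-2k}))
secant_convention_value <- function(k) (1 - exp(-k)) / (1 - exp(-2 * k))

# Fractionated survival for a total dose D delivered as a uniform schedule
# approximating a constant dose-rate, with per-fraction dose z_ref
rate_schedule <- function(total_dose, dose_rate, fraction_dose) {
  n <- max(1L, ceiling(total_dose / fraction_dose - 1e-9))
  doses <- rep(fraction_dose, n)
  doses[n] <- total_dose - fraction_dose * (n - 1)
  dose_schedule(doses, fraction_dose / dose_rate)
}
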