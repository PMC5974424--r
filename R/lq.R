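#' Lea-Catcheside dose-protraction factor
#'
#' The multiplier `q` in (0, 1] applied to the quadratic coefficient of the
#' linear-quadratic model when a dose is delivered continuously over time
#' `T` with first-order sub-lethal damage repair at composite rate
#' `k = a + c`:
#' `q = 2 / (k T)^2 * (k T + exp(-k T) - 1)`.
#' `q -> 1` as `T -> 0` (acute limit) and `q ~ 2 / (k T)` as `T -> infinity`.
#'
#' @param repair_rate Composite repair rate `a + c` (h^-1), > 0.
#' @param T Delivery time (h), >= 0; vectorised.
#' @return `q` in (0, 1].
#' @examples
#' lea_catcheside_factor(0.704, 12)  # 0.2087
#' @export
lea_catcheside_factor <- function(repair_rate, T) {
  check_scalar(repair_rate, "repair_rate", lower = 0, strict_lower = TRUE)
  if (!is.numeric(T) || anyNA(T) || any(T < 0))
    stop_domain("'T' must be non-negative")
  x <- repair_rate * T
  q <- ifelse(x < 1e-6,
              # series: q = 1 - x/3 + x^2/12 - ..., avoids 0/0 at T = 0
              1 - x / 3 + x^2 / 12,
              2 / x^2 * (x + exp(-x) - 1))
  q
}

#' Survival under continuous exposure at a constant dose-rate
#'
#' Closed-form limit of the fractionated IMK model for infinitely fine
#' fractionation with constant cell state:
#' `-ln S = (alpha0 + gamma * beta0) D + q(a + c, T) * beta0 * D^2`
#' with `T = D / dose_rate` and `q` the Lea-Catcheside factor.  Delivery is
#' assumed to end at the last instant of `T`; no post-irradiation repair
#' term is added.
#'
#' @param dose Total absorbed dose D (Gy), >= 0; vectorised.
#' @param dose_rate Constant dose-rate (Gy/h), > 0 (may be `Inf` for the
#'   acute limit).
#' @param params An [imk_parameters()].
#' @return Surviving fraction(s) in (0, 1].
#' @examples
#' p <- load_parameters("cho-k1-plateau")
#' continuous_survival(6, 3.0, p)
#' @export
continuous_survival <- function(dose, dose_rate, params) {
  if (!is.numeric(dose) || anyNA(dose) || any(dose < 0))
    stop_domain("'dose' must be non-negative")
  if (!is.numeric(dose_rate) || length(dose_rate) != 1L || is.na(dose_rate) ||
      dose_rate <= 0)
    stop_domain("'dose_rate' must be a single positive rate (Gy/h)")
  T <- dose / dose_rate
  x <- params$repair_rate0 * T
  q <- ifelse(x < 1e-6, 1 - x / 3 + x^2 / 12, 2 / x^2 * (x + exp(-x) - 1))
  lnS <- (params$alpha0 + params$gamma * params$beta0) * dose +
    q * params$beta0 * dose^2
  safe_exp(-lnS)
}

#' Acute linear-quadratic survival
#'
#' The zero-delivery-time limit of the model:
#' `-ln S = (alpha0 + gamma * beta0) D + beta0 * D^2`; the microdosimetric
#' term `gamma * beta0` augments the effective linear coefficient.
#'
#' @param dose Absorbed dose (Gy), >= 0; vectorised.
#' @param params An [imk_parameters()].
#' @return Surviving fraction(s) in (0, 1].
#' @examples
#' acute_lq(2, load_parameters("cho-k1-plateau"))  # ~0.554
#' @export
acute_lq <- function(dose, params) {
  if (!is.numeric(dose) || anyNA(dose) || any(dose < 0))
    stop_domain("'dose' must be non-negative")
  lnS <- (params$alpha0 + params$gamma * params$beta0) * dose +
    params$beta0 * dose^2
  safe_exp(-lnS)
}

#' Effective LQ coefficients for a protracted delivery
#'
#' @param params An [imk_parameters()].
#' @param delivery_time Delivery time T (h), >= 0.
#' @return List with `alpha` (`alpha0 + gamma * beta0`, Gy^-1), `beta_eff`
#'   (`q(T) * beta0`, Gy^-2) and `delivery_time`.
#' @export
lq_coefficients <- function(params, delivery_time) {
  check_scalar(delivery_time, "delivery_time", lower = 0)
  q <- lea_catcheside_factor(params$repair_rate0, delivery_time)
  list(alpha = params$alpha0 + params$gamma * params$beta0,
       beta_eff = q * params$beta0,
       delivery_time = delivery_time)
}

#' Agreement between a fractionated regimen and its continuous equivalent
#'
#' Quantifies how well a uniform fractionated schedule emulates continuous
#' exposure at its mean dose-rate, under constant cell state.  At each
#' cumulative dose reached after `k = 2, ..., N` fractions, `-ln S` is
#' computed from the fractionated model and from the continuous closed form
#' (with `T = D_k / dose_rate`), and the coefficient of determination
#' between the two series is returned.  Well-designed regimens (e.g.
#' 1.5 Gy every 30 min for 3.0 Gy/h) give R^2 >= 0.999.
#'
#' @param schedule A [dose_schedule()] with at least 2 fractions.
#' @param params An [imk_parameters()].
#' @return R^2 between the fractionated and continuous `-ln S` series.
#' @examples
#' p <- load_parameters("cho-k1-plateau")
#' regimen_equivalence_r2(design_equivalent_regimen(3.0, 1.5, 12), p)
#' @export
regimen_equivalence_r2 <- function(schedule, params) {
  if (!inherits(schedule, "dose_schedule"))
    stop_config("'schedule' must be a dose_schedule")
  if (schedule$n_fractions < 2L)
    stop_domain("R^2 is undefined for single-point schedules")
  N <- schedule$n_fractions
  lnS_frac <- vapply(seq_len(N), function(k) {
    sub <- dose_schedule(schedule$fraction_doses[seq_len(k)],
                         schedule$interval)
    lethal_lesion_yield(sub, constant_trajectory(k, params$repair_rate0),
                        params)$w_mean
  }, numeric(1))
  cum_dose <- cumsum(schedule$fraction_doses)
  lnS_cont <- -log(continuous_survival(cum_dose, schedule$dose_rate, params))
  r_squared(lnS_frac, lnS_cont)
}
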