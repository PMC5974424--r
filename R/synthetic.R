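#' Generate a synthetic clonogenic survival curve
#'
#' Produces model survival at the requested doses and multiplies it by
#' mean-one lognormal noise with coefficient of variation `noise_cv`,
#' emulating the scatter of plating-ratio measurements in a clonogenic
#' assay (counting and plating-efficiency variation act multiplicatively
#' on survival).  The SD column is set to `noise_cv * S_model`, the known
#' generating dispersion.  Doses are acute (`dose_rate = Inf`) or delivered
#' continuously at a constant rate.
#'
#' @param params An [imk_parameters()].
#' @param doses Doses (Gy), strictly increasing, >= 0.
#' @param dose_rate Delivery rate (Gy/h); `Inf` (default) for acute
#'   exposure.
#' @param noise_cv Coefficient of variation of the multiplicative noise;
#'   0 returns the exact model curve.
#' @param seed Integer seed; the generator is deterministic for a fixed
#'   seed.  Defaults to 20180529.
#' @return A [survival_curve()] tagged `"measured"` (it plays the role of
#'   data) with attribute `model` holding the noise-free curve.
#' @examples
#' p <- load_parameters("cho-k1-plateau")
#' generate_synthetic_survival(p, doses = 1:6, noise_cv = 0.1, seed = 1)
#' @export
generate_synthetic_survival <- function(params, doses,
                                        dose_rate = Inf, noise_cv = 0.1,
                                        seed = 20180529) {
  if (any(doses < 0) || is.unsorted(doses, strictly = TRUE))
    stop_domain("'doses' must be non-negative and strictly increasing")
  check_scalar(noise_cv, "noise_cv", lower = 0)
  s_model <- if (is.infinite(dose_rate)) acute_lq(doses, params)
             else continuous_survival(doses, dose_rate, params)
  if (noise_cv > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed %% .Machine$integer.max))
    sigma <- sqrt(log(1 + noise_cv^2))
    s_obs <- s_model * exp(stats::rnorm(length(doses), 0, sigma) - sigma^2 / 2)
  } else {
    s_obs <- s_model
  }
  s_obs <- pmin(s_obs, 1)
  out <- survival_curve(doses, s_obs,
                        sd = if (noise_cv > 0) noise_cv * s_model else NULL,
                        provenance = "measured")
  attr(out, "model") <- s_model
  out
}

#' Generate a synthetic cell-cycle time course
#'
#' Emulates the S-phase redistribution seen during protracted exposure: a
#' smooth logistic rise of the S-phase fraction from a plateau-phase
#' baseline (14.9 %) by `magnitude` percentage points over the exposure,
#' with the relative mean DNA content per nucleus coupled linearly to the
#' S-phase fraction through the plateau/log-phase anchors (DNA 1 -> 1.227
#' as N_S goes 14.9 % -> 52.4 %).  Samples are drawn on the 2 h
#' flow-cytometry grid (0, 2, ..., t_max) with optional Gaussian sampling
#' noise.
#'
#' @param pattern `"s_rise"` (logistic rise, default) or `"flat"`.
#' @param magnitude Total rise of the S-phase fraction (percentage
#'   points); 0 gives a flat time course.
#' @param t_max End of the sampled window (h); sampling every 2 h.
#' @param baseline_s Starting S-phase fraction (%), default 14.9.
#' @param noise_sd_s,noise_sd_g Gaussian sampling SDs for the S-phase
#'   fraction (percentage points) and relative DNA; both default to 0
#'   (noise-free).
#' @param seed Integer seed, default 20180529.
#' @return A [cell_cycle_timecourse()].
#' @examples
#' generate_synthetic_timecourse(magnitude = 37.5, t_max = 12)
#' @export
generate_synthetic_timecourse <- function(pattern = c("s_rise", "flat"),
                                          magnitude = 20, t_max = 12,
                                          baseline_s = 14.9,
                                          noise_sd_s = 0, noise_sd_g = 0,
                                          seed = 20180529) {
  pattern <- match.arg(pattern)
  check_scalar(magnitude, "magnitude", lower = 0)
  check_scalar(t_max, "t_max", lower = 0, strict_lower = TRUE)
  times <- seq(0, t_max, by = 2)
  if (length(times) < 2L) times <- c(0, t_max)
  if (pattern == "flat" || magnitude == 0) {
    ns <- rep(baseline_s, length(times))
  } else {
    # logistic rise centred mid-exposure, normalised so the sampled window
    # spans exactly baseline_s -> baseline_s + magnitude
    mid <- t_max / 2
    rate <- 6 / t_max
    raw <- function(t) 1 / (1 + exp(-rate * (t - mid)))
    ns <- baseline_s + magnitude * (raw(times) - raw(0)) / (raw(t_max) - raw(0))
  }
  # couple DNA content to S-phase fraction via the CHO-K1 phase anchors
  g <- 1 + (1.227 - 1) * (ns - baseline_s) / (52.4 - 14.9)
  if (noise_sd_s > 0 || noise_sd_g > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed %% .Machine$integer.max))
    ns <- pmin(pmax(ns + stats::rnorm(length(times), 0, noise_sd_s), 0), 100)
    g <- pmax(g + stats::rnorm(length(times), 0, noise_sd_g), 1e-3)
  }
  cell_cycle_timecourse(times, ns, g,
                        sd_s = if (noise_sd_s > 0) rep(noise_sd_s, length(times)) else NULL,
                        sd_g = if (noise_sd_g > 0) rep(noise_sd_g, length(times)) else NULL)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
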