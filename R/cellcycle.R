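#' Cell-cycle phase composition with state summaries
#'
#' Summarises one culture condition: the percentages of cells in G0/G1, S
#' and G2/M (summing to ~100), the relative mean DNA content per nucleus
#' `g_rel`, the relative second moment `g2_rel`, and the sub-lethal damage
#' repair rate `c` (h^-1) of the condition.  Plateau-phase (density
#' arrested, mostly G0/G1) and logarithmic-growth cultures are the two
#' conditions anchoring the S-phase dependence of the repair rate.
#'
#' @param g0g1,s,g2m Phase percentages (each >= 0, sum within [99, 101]).
#' @param g_rel Relative mean DNA per nucleus, > 0.
#' @param g2_rel Relative second moment of DNA per nucleus, > 0.
#' @param c SLDR rate (h^-1), > 0.
#' @param label Optional name for printing.
#' @return An object of class `cell_phase_stats`.
#' @examples
#' cho_k1_phase_stats("plateau")
#' @export
cell_phase_stats <- function(g0g1, s, g2m, g_rel, g2_rel, c, label = NULL) {
  for (v in c(g0g1 = g0g1, s = s, g2m = g2m))
    if (!is.numeric(v) || length(v) != 1L || v < 0)
      stop_domain("phase percentages must be single non-negative numbers")
  tot <- g0g1 + s + g2m
  # +-1.5 absorbs rounding of published phase tables (e.g. 37.6+52.4+11.4)
  if (tot < 98.5 || tot > 101.5)
    stop_domain(sprintf("phase percentages sum to %.3g, not ~100", tot))
  check_scalar(g_rel, "g_rel", lower = 0, strict_lower = TRUE)
  check_scalar(g2_rel, "g2_rel", lower = 0, strict_lower = TRUE)
  check_scalar(c, "c", lower = 0, strict_lower = TRUE)
  structure(list(g0g1 = g0g1, s = s, g2m = g2m, g_rel = g_rel,
                 g2_rel = g2_rel, c = c, label = label),
            class = "cell_phase_stats")
}

#' @rdname cell_phase_stats
#' @param phase `"plateau"` or `"log"`: packaged CHO-K1 phase compositions
#'   (plateau: 72.7/14.9/12.4 %, c = 0.704 h^-1; log: 37.6/52.4/11.4 %,
#'   relative DNA 1.227 / second moment 1.457, c = 1.782 h^-1).
#' @export
cho_k1_phase_stats <- function(phase = c("plateau", "log")) {
  phase <- match.arg(phase)
  path <- system.file("extdata", "cho_k1_phases.csv", package = "imkmodel")
  df <- read_imk_csv(path, c("phase", "g0g1_pct", "s_pct", "g2m_pct",
                             "g_rel", "g2_rel", "c_per_h"))
  row <- df[df$phase == phase, ]
  cell_phase_stats(row$g0g1_pct, row$s_pct, row$g2m_pct, row$g_rel,
                   row$g2_rel, row$c_per_h, label = paste0("cho-k1-", phase))
}

#' @export
print.cell_phase_stats <- function(x, ...) {
  cat("Cell-phase stats", if (!is.null(x$label)) paste0("(", x$label, ")"), "\n")
  cat(sprintf("  G0/G1 %.3g%% | S %.3g%% | G2/M %.3g%%\n", x$g0g1, x$s, x$g2m))
  cat(sprintf("  g_rel %.4g | g2_rel %.4g | SLDR c %.4g h^-1\n",
              x$g_rel, x$g2_rel, x$c))
  invisible(x)
}

#' Cell-cycle time course during an exposure
#'
#' Samples of the S-phase fraction `N_S(t)` (percent) and the relative mean
#' DNA content per nucleus at times `t` (h) from the start of irradiation,
#' e.g. flow-cytometric measurements taken every 2 h.
#'
#' @param time_h Sample times (h), non-negative, strictly increasing,
#'   >= 2 samples.
#' @param s_fraction_pct S-phase percentages in [0, 100].
#' @param g_rel Relative mean DNA per nucleus, > 0.
#' @param sd_s,sd_g Optional measurement SDs.
#' @return An object of class `cell_cycle_timecourse`.
#' @export
cell_cycle_timecourse <- function(time_h, s_fraction_pct, g_rel,
                                  sd_s = NULL, sd_g = NULL) {
  n <- length(time_h)
  if (n < 2L) stop_data("a time course needs >= 2 samples")
  if (length(s_fraction_pct) != n || length(g_rel) != n)
    stop_data("time course columns must have equal length")
  if (any(time_h < 0) || is.unsorted(time_h, strictly = TRUE))
    stop_data("'time_h' must be non-negative and strictly increasing")
  if (any(s_fraction_pct < 0) || any(s_fraction_pct > 100))
    stop_data("'s_fraction_pct' must lie in [0, 100]")
  if (any(g_rel <= 0)) stop_data("'g_rel' must be positive")
  structure(list(time_h = as.numeric(time_h),
                 s_fraction_pct = as.numeric(s_fraction_pct),
                 g_rel = as.numeric(g_rel), sd_s = sd_s, sd_g = sd_g),
            class = "cell_cycle_timecourse")
}

#' @export
print.cell_cycle_timecourse <- function(x, ...) {
  cat(sprintf("Cell-cycle time course: %d samples over %g-%g h\n",
              length(x$time_h), min(x$time_h), max(x$time_h)))
  cat(sprintf("  S-phase %.3g-%.3g%% | g_rel %.4g-%.4g\n",
              min(x$s_fraction_pct), max(x$s_fraction_pct),
              min(x$g_rel), max(x$g_rel)))
  invisible(x)
}

#' Differential SLDR rate per percent of S-phase cells
#'
#' The two-condition finite difference `dc/dN_S = (c_b - c_a) /
#' (N_S_b - N_S_a)` (h^-1 per %), order-invariant by construction.  With the
#' CHO-K1 plateau and logarithmic-growth anchors this gives 0.0287 h^-1/%.
#'
#' @param phase_a,phase_b Two [cell_phase_stats()] with distinct S-phase
#'   fractions.
#' @return `dc/dN_S` (h^-1 per %).
#' @examples
#' differential_sldr_rate(cho_k1_phase_stats("plateau"),
#'                        cho_k1_phase_stats("log"))
#' @export
differential_sldr_rate <- function(phase_a, phase_b) {
  stopifnot(inherits(phase_a, "cell_phase_stats"),
            inherits(phase_b, "cell_phase_stats"))
  dns <- phase_b$s - phase_a$s
  if (abs(dns) < 1e-12)
    stop_domain("phases have equal S-phase fractions; dc/dN_S is undefined")
  (phase_b$c - phase_a$c) / dns
}

#' Interpolate a cell-cycle time course
#'
#' Shape-preserving monotone-segment cubic interpolation through the sampled
#' points: exact at samples, monotone and bounded by the neighbouring sample
#' values on each segment (Fritsch-Carlson slope limiting, with zero slope at
#' interior extrema so local maxima/minima are never overshot), and constant
#' extrapolation outside the sampled window.
#'
#' @param timecourse A [cell_cycle_timecourse()].
#' @param query_times Times (h) at which to evaluate.
#' @param what `"s_fraction"` or `"g_rel"`.
#' @return Interpolated values at `query_times`.
#' @export
interpolate_timecourse <- function(timecourse, query_times,
                                   what = c("s_fraction", "g_rel")) {
  stopifnot(inherits(timecourse, "cell_cycle_timecourse"))
  what <- match.arg(what)
  y <- switch(what, s_fraction = timecourse$s_fraction_pct,
              g_rel = timecourse$g_rel)
  x <- timecourse$time_h
  # clamp to the sampled window -> constant extrapolation at the ends
  monotone_hermite(x, y, pmin(pmax(query_times, min(x)), max(x)))
}

# Cubic Hermite interpolation with Fritsch-Carlson monotone slope limiting.
# Node slopes are zeroed where the secants change sign (local extrema) and
# clamped to 3x the smaller adjacent secant magnitude, which keeps every
# segment monotone between its endpoints (no overshoot anywhere).
monotone_hermite <- function(x, y, xq) {
  n <- length(x)
  d <- diff(y) / diff(x)                       # secant slopes
  m <- numeric(n)
  m[1] <- d[1]
  m[n] <- d[n - 1]
  if (n > 2) {
    for (i in 2:(n - 1)) {
      m[i] <- if (d[i - 1] * d[i] <= 0) 0 else (d[i - 1] + d[i]) / 2
    }
  }
  for (i in seq_len(n - 1)) {
    if (d[i] == 0) {
      m[i] <- m[i + 1] <- 0
    } else {
      m[i] <- sign(d[i]) * min(abs(m[i]), 3 * abs(d[i]))
      m[i + 1] <- sign(d[i]) * min(abs(m[i + 1]), 3 * abs(d[i]))
    }
  }
  idx <- pmin(pmax(findInterval(xq, x), 1L), n - 1L)
  h <- x[idx + 1L] - x[idx]
  t <- (xq - x[idx]) / h
  h00 <- (1 + 2 * t) * (1 - t)^2
  h10 <- t * (1 - t)^2
  h01 <- t^2 * (3 - 2 * t)
  h11 <- t^2 * (t - 1)
  h00 * y[idx] + h10 * h * m[idx] + h01 * y[idx + 1L] + h11 * h * m[idx + 1L]
}

#' S-phase-dependent SLDR rate at a given time
#'
#' `c(t) = c0 + dc/dN_S * (N_S(t) - N_S(0))`, with `N_S` taken from the
#' interpolated time course.  The result is floored at a small positive
#' rate (1e-6 h^-1, with a warning) since a non-positive repair rate is
#' unphysical.
#'
#' @param t Time(s) after the start of irradiation (h).
#' @param timecourse A [cell_cycle_timecourse()].
#' @param c0 SLDR rate at `t = 0` (h^-1).
#' @param dc_dns Differential SLDR rate (h^-1 per %).
#' @return SLDR rate(s) (h^-1).
#' @export
sldr_rate_at <- function(t, timecourse, c0, dc_dns) {
  check_scalar(c0, "c0", lower = 0, strict_lower = TRUE)
  check_scalar(dc_dns, "dc_dns")
  ns <- interpolate_timecourse(timecourse, t, "s_fraction")
  ns0 <- interpolate_timecourse(timecourse, 0, "s_fraction")
  ct <- c0 + dc_dns * (ns - ns0)
  if (any(ct < 1e-6)) {
    warning("SLDR rate clamped at 1e-6 h^-1 (non-positive rate implied)")
    ct <- pmax(ct, 1e-6)
  }
  ct
}

#' Build a per-fraction cell-state trajectory from a time course
#'
#' Samples the interpolated time course at the fraction start times
#' `t_n = (n - 1) * interval` of a schedule and assembles the per-fraction
#' state (relative DNA content, relative second moment, SLDR rate) used by
#' the lesion-yield engine.  DNA content is renormalised so that the first
#' fraction has `g_rel = 1`.  A time course measured under one dose-rate
#' may be applied to a schedule at another (transfer of cell-cycle
#' kinetics); schedules outrunning the measured window use the last sample
#' (constant extrapolation).
#'
#' Because the second moment of the DNA distribution is rarely measured,
#' two conventions are offered for `g2_rel`:
#' \describe{
#'   \item{`"square"` (default)}{`g2_rel = g_rel^2` — exact when the shape
#'     of the DNA distribution does not change during exposure.}
#'   \item{`"anchor"`}{Linear interpolation in `N_S` between two measured
#'     phase anchors (e.g. the plateau and log-phase second moments).}
#' }
#'
#' @param schedule A [dose_schedule()].
#' @param timecourse A [cell_cycle_timecourse()].
#' @param params An [imk_parameters()]; `repair_rate0` is the `c0` of the
#'   first fraction.
#' @param dc_dns Differential SLDR rate (h^-1 per %).
#' @param g2_mode `"square"` or `"anchor"`.
#' @param anchors For `"anchor"` mode: list of two [cell_phase_stats()]
#'   (ordered by S-phase fraction is not required).
#' @return A [cell_state_trajectory()] with one entry per fraction.
#' @examples
#' p <- load_parameters("cho-k1-plateau")
#' tc <- generate_synthetic_timecourse(magnitude = 20, t_max = 12)
#' build_trajectory(design_equivalent_regimen(3, 1.5, 12), tc, p,
#'                  dc_dns = 0.0287)
#' @export
build_trajectory <- function(schedule, timecourse, params, dc_dns,
                             g2_mode = c("square", "anchor"),
                             anchors = NULL) {
  if (!inherits(schedule, "dose_schedule"))
    stop_config("'schedule' must be a dose_schedule")
  g2_mode <- match.arg(g2_mode)
  t_n <- schedule$start_times
  g <- interpolate_timecourse(timecourse, t_n, "g_rel")
  g <- g / g[1]
  c_n <- sldr_rate_at(t_n, timecourse, params$repair_rate0, dc_dns)
  g2 <- switch(g2_mode,
    square = g^2,
    anchor = {
      if (is.null(anchors) || length(anchors) != 2L)
        stop_config("'anchor' mode needs a list of two cell_phase_stats")
      a <- anchors[[1]]; b <- anchors[[2]]
      if (abs(b$s - a$s) < 1e-12)
        stop_config("anchor phases must differ in S-phase fraction")
      ns <- interpolate_timecourse(timecourse, t_n, "s_fraction")
      g2a <- a$g2_rel / a$g2_rel        # anchor a is the baseline (= 1)
      g2b <- b$g2_rel / a$g2_rel
      pmax(g2a + (g2b - g2a) * (ns - a$s) / (b$s - a$s), 1e-6)
    })
  cell_state_trajectory(g, g2, c_n)
}

#' Convert baseline parameters between culture conditions
#'
#' Re-expresses a parameter set calibrated in one cell condition (e.g.
#' plateau phase) in another (e.g. logarithmic growth), under the
#' assumption that the microscopic lethal-conversion and pairing rates are
#' cell-specific constants: only the mean DNA content and the SLDR rate
#' differ between conditions, so
#' `alpha0' = alpha0 * (g_rel'/g_rel) * (k/k')`,
#' `beta0' = beta0 * (g2_rel'/g2_rel) * (k/k')`, `repair_rate0' = c'`,
#' `gamma` unchanged.  With the CHO-K1 anchors this converts
#' (0.155, 0.048, 0.704) for plateau into (0.075, 0.028, 1.782) for log
#' phase.
#'
#' @param params [imk_parameters()] calibrated in the `from` condition.
#' @param from,to [cell_phase_stats()] of the two conditions.
#' @return An [imk_parameters()] for the `to` condition.
#' @examples
#' convert_phase_parameters(load_parameters("cho-k1-plateau"),
#'                          cho_k1_phase_stats("plateau"),
#'                          cho_k1_phase_stats("log"))
#' @export
convert_phase_parameters <- function(params, from, to) {
  stopifnot(inherits(params, "imk_parameters"),
            inherits(from, "cell_phase_stats"),
            inherits(to, "cell_phase_stats"))
  k_from <- params$a_rate + from$c
  k_to <- params$a_rate + to$c
  imk_parameters(
    alpha0 = params$alpha0 * (to$g_rel / from$g_rel) * k_from / k_to,
    beta0 = params$beta0 * (to$g2_rel / from$g2_rel) * k_from / k_to,
    repair_rate0 = to$c,
    a_rate = params$a_rate,
    gamma = params$gamma,
    label = to$label
  )
}

#' Read / write a cell-cycle time course as CSV
#'
#' Columns `time_h,s_fraction_pct,g_rel` with optional `sd_s,sd_g`.
#'
#' @param path File path.
#' @return `read_timecourse_csv()` returns a [cell_cycle_timecourse()]; the
#'   writer returns `path` invisibly.
#' @export
read_timecourse_csv <- function(path) {
  df <- read_imk_csv(path, c("time_h", "s_fraction_pct", "g_rel"))
  cell_cycle_timecourse(
    df$time_h, df$s_fraction_pct, df$g_rel,
    sd_s = if ("sd_s" %in% names(df) && !all(is.na(df$sd_s))) df$sd_s else NULL,
    sd_g = if ("sd_g" %in% names(df) && !all(is.na(df$sd_g))) df$sd_g else NULL)
}

#' @rdname read_timecourse_csv
#' @param timecourse A [cell_cycle_timecourse()].
#' @export
write_timecourse_csv <- function(timecourse, path) {
  stopifnot(inherits(timecourse, "cell_cycle_timecourse"))
  df <- data.frame(time_h = timecourse$time_h,
                   s_fraction_pct = timecourse$s_fraction_pct,
                   g_rel = timecourse$g_rel,
                   sd_s = if (is.null(timecourse$sd_s)) NA else timecourse$sd_s,
                   sd_g = if (is.null(timecourse$sd_g)) NA else timecourse$sd_g)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
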