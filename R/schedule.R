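#' Fractionated dose-delivery schedule
#'
#' An ordered sequence of instantaneous dose fractions `z_1, ..., z_N` (Gy)
#' delivered at a uniform inter-fraction interval `interval` (h); fraction
#' `n` is delivered at time `(n - 1) * interval`, with the time origin at the
#' first fraction.  The uniform interval is a structural assumption of the
#' fractionated lesion-yield formula, so non-uniform timings are rejected
#' rather than silently generalised.
#'
#' @param fraction_doses Numeric vector of fraction doses (Gy), each >= 0.
#' @param interval Uniform inter-fraction interval (h), > 0.
#' @return An object of class `dose_schedule` with derived fields
#'   `n_fractions`, `total_dose` (Gy), `delivery_time` (h, `N * interval`)
#'   and `dose_rate` (mean rate, Gy/h).
#' @examples
#' dose_schedule(rep(1.5, 24), interval = 0.5)  # 3.0 Gy/h equivalent regimen
#' @export
dose_schedule <- function(fraction_doses, interval) {
  if (!is.numeric(fraction_doses) || length(fraction_doses) < 1L ||
      anyNA(fraction_doses))
    stop_domain("'fraction_doses' must be a non-empty numeric vector")
  if (any(fraction_doses < 0))
    stop_domain("fraction doses must be non-negative")
  check_scalar(interval, "interval", lower = 0, strict_lower = TRUE)
  n <- length(fraction_doses)
  total <- sum(fraction_doses)
  structure(
    list(fraction_doses = as.numeric(fraction_doses),
         interval = interval,
         n_fractions = n,
         start_times = (seq_len(n) - 1) * interval,
         total_dose = total,
         delivery_time = n * interval,
         dose_rate = total / (n * interval)),
    class = "dose_schedule"
  )
}

#' @export
print.dose_schedule <- function(x, ...) {
  cat(sprintf(
    "Dose schedule: %d fraction(s), %g Gy total over %g h (mean %.3g Gy/h)\n",
    x$n_fractions, x$total_dose, x$delivery_time, x$dose_rate))
  if (length(unique(x$fraction_doses)) == 1L) {
    cat(sprintf("  %g Gy per fraction every %g h\n",
                x$fraction_doses[1], x$interval))
  } else {
    cat("  doses (Gy):", paste(signif(x$fraction_doses, 4), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Design a fractionation regimen equivalent to a continuous dose-rate
#'
#' Builds the uniform schedule that delivers `fraction_dose` Gy per fraction
#' at the interval that reproduces a prescribed mean dose-rate over a total
#' delivery time: `interval = fraction_dose / dose_rate` and
#' `N = total_time / interval`.  Such regimens stand in for continuous
#' exposure in cell-irradiation experiments; e.g. 1.5 Gy every 30 min for
#' 12 h (24 fractions) is equivalent to continuous 3.0 Gy/h.
#'
#' @param dose_rate Target mean dose-rate (Gy/h), > 0.
#' @param fraction_dose Dose per fraction (Gy), > 0.
#' @param total_time Total delivery time (h), > 0.  Must be an integer
#'   multiple of the implied interval.
#' @return A [dose_schedule()].
#' @examples
#' design_equivalent_regimen(3.0, 1.5, 12)  # 24 x 1.5 Gy at 0.5 h
#' design_equivalent_regimen(6.0, 2.0, 12)  # 36 x 2.0 Gy at 20 min
#' @export
design_equivalent_regimen <- function(dose_rate, fraction_dose, total_time) {
  check_scalar(dose_rate, "dose_rate", lower = 0, strict_lower = TRUE)
  check_scalar(fraction_dose, "fraction_dose", lower = 0, strict_lower = TRUE)
  check_scalar(total_time, "total_time", lower = 0, strict_lower = TRUE)
  interval <- fraction_dose / dose_rate
  n_exact <- total_time / interval
  n <- round(n_exact)
  if (abs(n_exact - n) > 1e-9 * max(1, n_exact) || n < 1)
    stop_domain(sprintf(
      "total_time = %g h is not an integer number of %g h intervals",
      total_time, interval))
  dose_schedule(rep(fraction_dose, n), interval)
}

#' Read / write a dose schedule as CSV
#'
#' The schedule table has columns `fraction_index` (1-based),
#' `dose_Gy` and `start_time_h`; start times must lie on a uniform grid
#' `(n - 1) * interval`.
#'
#' @param path File path.
#' @return `read_schedule_csv()` returns a [dose_schedule()];
#'   `write_schedule_csv()` returns `path` invisibly.
#' @export
read_schedule_csv <- function(path) {
  df <- read_imk_csv(path, c("fraction_index", "dose_Gy", "start_time_h"))
  df <- df[order(df$fraction_index), , drop = FALSE]
  if (!identical(as.integer(df$fraction_index), seq_len(nrow(df))))
    stop_data(sprintf("%s: fraction_index must be 1..N without gaps", path))
  if (nrow(df) > 1L) {
    steps <- diff(df$start_time_h)
    if (any(abs(steps - steps[1]) > 1e-9 * max(steps[1], 1)))
      stop_data(sprintf("%s: start times are not uniformly spaced", path))
    interval <- steps[1]
  } else {
    interval <- if (df$start_time_h[1] > 0) df$start_time_h[1] else 1
  }
  if (abs(df$start_time_h[1]) > 1e-9)
    stop_data(sprintf("%s: first fraction must start at t = 0", path))
  dose_schedule(df$dose_Gy, interval)
}

#' @rdname read_schedule_csv
#' @param schedule A [dose_schedule()].
#' @export
write_schedule_csv <- function(schedule, path) {
  stopifnot(inherits(schedule, "dose_schedule"))
  df <- data.frame(fraction_index = seq_len(schedule$n_fractions),
                   dose_Gy = schedule$fraction_doses,
                   start_time_h = schedule$start_times)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
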