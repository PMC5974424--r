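#' Clonogenic survival curve container
#'
#' Dose / surviving-fraction pairs with optional standard deviations and a
#' provenance tag distinguishing measured from modelled curves.
#'
#' @param dose Doses (Gy), non-negative, strictly increasing.
#' @param survival Surviving fractions in (0, 1].
#' @param sd Optional standard deviations, > 0 where present.
#' @param provenance `"measured"` or `"modelled"`.
#' @return An object of class `survival_curve`.
#' @export
survival_curve <- function(dose, survival, sd = NULL,
                           provenance = c("measured", "modelled")) {
  provenance <- match.arg(provenance)
  if (length(dose) != length(survival) || length(dose) < 1L)
    stop_data("'dose' and 'survival' must be non-empty and equal length")
  if (any(dose < 0) || is.unsorted(dose, strictly = TRUE))
    stop_data("'dose' must be non-negative and strictly increasing")
  if (any(survival <= 0) || any(survival > 1))
    stop_data("'survival' must lie in (0, 1]")
  if (!is.null(sd)) {
    if (length(sd) != length(dose)) stop_data("'sd' length mismatch")
    if (any(!is.na(sd) & sd <= 0)) stop_data("'sd' must be positive")
  }
  structure(list(dose = as.numeric(dose), survival = as.numeric(survival),
                 sd = sd, provenance = provenance),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("Survival curve (%s): %d doses, %g-%g Gy, S in [%.3g, %.3g]\n",
              x$provenance, length(x$dose), min(x$dose), max(x$dose),
              min(x$survival), max(x$survival)))
  invisible(x)
}

#' Mean inactivation dose of a survival curve
#'
#' The mean dose needed to inactivate a cell, treating the survival curve
#' as the complement of the cumulative dose-to-inactivation distribution:
#' `D_bar = integral of S(D) dD from 0 to infinity`.  Integration is
#' adaptive quadrature on [0, U] with the upper bound `U` doubled until
#' `S(U) < 1e-12`, at relative tolerance 1e-8.
#'
#' @param survival_fn Function mapping dose (Gy) to surviving fraction;
#'   must satisfy `survival_fn(0) = 1` (up to 1e-6) and decay to 0.
#' @return Mean inactivation dose (Gy).
#' @examples
#' mean_inactivation_dose(function(d) exp(-0.5 * d))  # = 2
#' @export
mean_inactivation_dose <- function(survival_fn) {
  if (!is.function(survival_fn)) stop_domain("'survival_fn' must be a function")
  if (abs(survival_fn(0) - 1) > 1e-6)
    stop_domain("'survival_fn(0)' must equal 1")
  upper <- 10
  while (survival_fn(upper) >= 1e-12) {
    upper <- upper * 2
    if (upper > 1e9)
      stop_estimation("survival does not decay; mean inactivation dose diverges")
  }
  res <- stats::integrate(function(d) vapply(d, survival_fn, numeric(1)),
                          lower = 0, upper = upper,
                          rel.tol = 1e-8, subdivisions = 500L)
  res$value
}

#' Reduced chi-square between measured and modelled survival
#'
#' `chi^2 = (1/n) * sum_i (S_exp_i - S_model_i)^2 / sigma_exp_i^2` over a
#' matched dose grid.
#'
#' @param measured A [survival_curve()] with an `sd` for every point.
#' @param modelled A [survival_curve()] on the identical dose grid.
#' @return Reduced chi-square (dimensionless, >= 0).
#' @examples
#' m <- survival_curve(c(1, 2), c(0.5, 0.2), sd = c(0.05, 0.02))
#' e <- survival_curve(c(1, 2), c(0.45, 0.22), provenance = "modelled")
#' reduced_chi_square(m, e)
#' @export
reduced_chi_square <- function(measured, modelled) {
  stopifnot(inherits(measured, "survival_curve"),
            inherits(modelled, "survival_curve"))
  if (length(measured$dose) != length(modelled$dose) ||
      any(abs(measured$dose - modelled$dose) > 1e-9))
    stop_data("measured and modelled curves must share one dose grid")
  if (is.null(measured$sd) || anyNA(measured$sd))
    stop_data("measured curve must carry an SD for every point")
  if (any(measured$sd <= 0)) stop_data("SDs must be positive")
  mean((measured$survival - modelled$survival)^2 / measured$sd^2)
}

#' Coefficient of determination
#'
#' Standard R^2 = 1 - SS_res / SS_tot between observed and estimated
#' values.
#'
#' @param observed,estimated Numeric vectors of equal length >= 2.
#' @return R^2 (1 for a perfect fit; 0 when the fit is no better than the
#'   observed mean).
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 4))  # 0.5
#' @export
r_squared <- function(observed, estimated) {
  if (length(observed) != length(estimated) || length(observed) < 2L)
    stop_data("'observed' and 'estimated' must be equal length >= 2")
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop_data("'observed' is constant; R^2 is undefined")
  1 - sum((observed - estimated)^2) / ss_tot
}

#' Read / write a survival curve as CSV
#'
#' Columns `dose_Gy,survival,sd` (sd optional).
#'
#' @param path File path.
#' @param provenance Tag for the curve read in.
#' @return `read_survival_csv()` returns a [survival_curve()]; the writer
#'   returns `path` invisibly.
#' @export
read_survival_csv <- function(path, provenance = "measured") {
  df <- read_imk_csv(path, c("dose_Gy", "survival"))
  sd <- if ("sd" %in% names(df) && !all(is.na(df$sd))) df$sd else NULL
  survival_curve(df$dose_Gy, df$survival, sd = sd, provenance = provenance)
}

#' @rdname read_survival_csv
#' @param curve A [survival_curve()].
#' @export
write_survival_csv <- function(curve, path) {
  stopifnot(inherits(curve, "survival_curve"))
  df <- data.frame(dose_Gy = curve$dose, survival = curve$survival,
                   sd = if (is.null(curve$sd)) NA else curve$sd)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
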