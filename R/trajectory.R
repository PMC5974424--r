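#' Per-fraction cell-state trajectory
#'
#' Records, for each fraction of a schedule, the cell state entering the
#' lesion-yield calculation: `g_rel` is the mean DNA content per nucleus
#' relative to the first fraction, `g2_rel` the relative second moment of
#' DNA content, and `c` the sub-lethal damage repair (SLDR) rate (h^-1) in
#' force for lesions created by that fraction.  A constant trajectory
#' (all `g_rel = g2_rel = 1`, all `c = c0`) reduces the IMK model to the
#' classic microdosimetric-kinetic model.
#'
#' @param g_rel Relative mean DNA per nucleus, one value per fraction, > 0.
#' @param g2_rel Relative second moment of DNA per nucleus, > 0.
#' @param c_rates SLDR rate per fraction (h^-1), > 0.
#' @return An object of class `cell_state_trajectory`.
#' @examples
#' constant_trajectory(5, c0 = 0.704)
#' @export
cell_state_trajectory <- function(g_rel, g2_rel, c_rates) {
  n <- length(g_rel)
  if (length(g2_rel) != n || length(c_rates) != n)
    stop_config("'g_rel', 'g2_rel' and 'c_rates' must have equal length")
  if (n < 1L) stop_config("trajectory must cover at least one fraction")
  for (v in list(g_rel = g_rel, g2_rel = g2_rel, c_rates = c_rates)) {
    if (!is.numeric(v) || anyNA(v) || any(v <= 0))
      stop_domain("trajectory entries must be positive finite numbers")
  }
  structure(
    list(g_rel = as.numeric(g_rel), g2_rel = as.numeric(g2_rel),
         c_rates = as.numeric(c_rates), n_fractions = n),
    class = "cell_state_trajectory"
  )
}

#' @rdname cell_state_trajectory
#' @param n_fractions Number of fractions.
#' @param c0 Constant SLDR rate (h^-1).
#' @export
constant_trajectory <- function(n_fractions, c0) {
  cell_state_trajectory(rep(1, n_fractions), rep(1, n_fractions),
                        rep(c0, n_fractions))
}

#' @export
print.cell_state_trajectory <- function(x, ...) {
  cat(sprintf("Cell-state trajectory over %d fraction(s)\n", x$n_fractions))
  cat(sprintf("  g_rel  in [%.4g, %.4g]\n", min(x$g_rel), max(x$g_rel)))
  cat(sprintf("  g2_rel in [%.4g, %.4g]\n", min(x$g2_rel), max(x$g2_rel)))
  cat(sprintf("  SLDR c in [%.4g, %.4g] h^-1\n",
              min(x$c_rates), max(x$c_rates)))
  invisible(x)
}

#' Read / write a cell-state trajectory as CSV
#'
#' Columns: `fraction_index`, `g_rel`, `g2_rel`, `c_per_h`.
#'
#' @param path File path.
#' @return `read_trajectory_csv()` returns a [cell_state_trajectory()];
#'   the writer returns `path` invisibly.
#' @export
read_trajectory_csv <- function(path) {
  df <- read_imk_csv(path, c("fraction_index", "g_rel", "g2_rel", "c_per_h"))
  df <- df[order(df$fraction_index), , drop = FALSE]
  cell_state_trajectory(df$g_rel, df$g2_rel, df$c_per_h)
}

#' @rdname read_trajectory_csv
#' @param trajectory A [cell_state_trajectory()].
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "cell_state_trajectory"))
  df <- data.frame(fraction_index = seq_len(trajectory$n_fractions),
                   g_rel = trajectory$g_rel,
                   g2_rel = trajectory$g2_rel,
                   c_per_h = trajectory$c_rates)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

check_schedule_trajectory <- function(schedule, trajectory) {
  if (!inherits(schedule, "dose_schedule"))
    stop_config("'schedule' must be a dose_schedule")
  if (!inherits(trajectory, "cell_state_trajectory"))
    stop_config("'trajectory' must be a cell_state_trajectory")
  if (schedule$n_fractions != trajectory$n_fractions)
    stop_config(sprintf(
      "schedule has %d fractions but trajectory covers %d",
      schedule$n_fractions, trajectory$n_fractions))
  invisible(TRUE)
}
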