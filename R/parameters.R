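#' Radiobiological parameter set for the IMK model
#'
#' Bundles the baseline coefficients of the integrated
#' microdosimetric-kinetic (IMK) cell-survival model.  `alpha0` and `beta0`
#' are the linear and quadratic coefficients of the acute dose-response at
#' the baseline cell state (the state at the first fraction); `repair_rate0`
#' is the composite first-order rate `a + c` at which potentially lethal
#' lesions disappear from a domain (lethal conversion `a` plus sub-lethal
#' damage repair `c`, per hour); `gamma` is the single-event dose-mean
#' specific energy of the radiation quality (Gy), the microdosimetric
#' correction that adds `gamma * beta0` to the effective linear coefficient.
#'
#' The microscopic constants of the underlying lesion kinetics (PLL induction
#' coefficient, pairwise interaction rate, domain multiplicity, specific
#' energy and DNA-content densities) are not identifiable from survival data
#' and are absorbed into `alpha0`, `beta0` and `gamma`; all model output is
#' expressed through these composites.
#'
#' @param alpha0 Linear coefficient at baseline state (Gy^-1), >= 0.
#' @param beta0 Quadratic coefficient at baseline state (Gy^-2), >= 0.
#' @param repair_rate0 Composite rate `a + c` at baseline (h^-1), > 0.
#' @param a_rate First-order lethal-conversion rate `a` (h^-1).  Defaults to
#'   0: `a` is a few percent of `c` and is not separately measurable, so the
#'   composite carries it.  Must satisfy `0 <= a_rate < repair_rate0`.
#' @param gamma Single-event dose-mean specific energy (Gy), >= 0.  See
#'   [microdosimetry_gamma()] to derive it from lineal-energy quantities.
#' @param label Optional name for printing.
#' @return An object of class `imk_parameters`.
#' @examples
#' imk_parameters(alpha0 = 0.155, beta0 = 0.048, repair_rate0 = 0.704,
#'                gamma = 0.924)
#' @seealso [load_parameters()] for the packaged CHO-K1 presets.
#' @export
imk_parameters <- function(alpha0, beta0, repair_rate0, a_rate = 0,
                           gamma = 0, label = NULL) {
  check_scalar(alpha0, "alpha0", lower = 0)
  check_scalar(beta0, "beta0", lower = 0)
  check_scalar(repair_rate0, "repair_rate0", lower = 0, strict_lower = TRUE)
  check_scalar(a_rate, "a_rate", lower = 0)
  if (a_rate >= repair_rate0)
    stop_domain("'a_rate' must be smaller than 'repair_rate0'")
  check_scalar(gamma, "gamma", lower = 0)
  structure(
    list(alpha0 = alpha0, beta0 = beta0, repair_rate0 = repair_rate0,
         a_rate = a_rate, gamma = gamma, label = label),
    class = "imk_parameters"
  )
}

#' @export
print.imk_parameters <- function(x, ...) {
  cat("IMK model parameters", if (!is.null(x$label)) paste0("(", x$label, ")"),
      "\n")
  cat(sprintf("  alpha0       %.4g Gy^-1\n", x$alpha0))
  cat(sprintf("  beta0        %.4g Gy^-2\n", x$beta0))
  cat(sprintf("  repair rate  %.4g h^-1 (a = %.4g h^-1)\n",
              x$repair_rate0, x$a_rate))
  cat(sprintf("  gamma        %.4g Gy\n", x$gamma))
  invisible(x)
}

#' Dose-mean specific energy per event from microdosimetric quantities
#'
#' Converts a dose-mean lineal-energy-derived quantity `y_D` into the
#' single-event dose-mean specific energy `gamma = y_D / (rho * pi * r_d^2)`
#' for spherical domains of radius `r_d`.  With `y_D` expressed in
#' Gy * um^2 * (g cm^-3) (the working unit in which published tables quote
#' the numerator of this ratio), `rho` in g cm^-3 and `r_d` in um, the result
#' is in Gy.
#'
#' @param y_d Dose-mean lineal-energy-derived numerator (see above).
#' @param rho Density of the medium (g cm^-3), > 0.
#' @param r_d Domain radius (um), > 0.
#' @return `gamma` in Gy.
#' @examples
#' # 250 kVp X-rays on 0.5 um water domains: gamma = 0.924 Gy
#' microdosimetry_gamma(y_d = 0.924 * pi * 0.25, rho = 1, r_d = 0.5)
#' @export
microdosimetry_gamma <- function(y_d, rho = 1.0, r_d = 0.5) {
  check_scalar(y_d, "y_d", lower = 0)
  check_scalar(rho, "rho", lower = 0, strict_lower = TRUE)
  check_scalar(r_d, "r_d", lower = 0, strict_lower = TRUE)
  y_d / (rho * pi * r_d^2)
}

#' Load an IMK parameter set from a preset or configuration file
#'
#' Two presets for the CHO-K1 cell line under 250 kVp X-rays ship with the
#' package: `"cho-k1-plateau"` (density-arrested plateau-phase culture,
#' alpha0 = 0.155 Gy^-1, beta0 = 0.048 Gy^-2, a + c = 0.704 h^-1,
#' gamma = 0.924 Gy) and `"cho-k1-log"` (logarithmic growth phase,
#' alpha0 = 0.075 Gy^-1, beta0 = 0.028 Gy^-2, a + c = 1.782 h^-1).
#' Alternatively a plain-text config file with a `[params]` section of
#' `key = value` lines (keys `alpha0`, `beta0`, `repair_rate0`, `a_rate`,
#' `gamma`) may be given.
#'
#' @param preset Name of a packaged preset, or `NULL`.
#' @param file Path to a config file, or `NULL`.  Exactly one of `preset`
#'   and `file` must be supplied.
#' @return An [imk_parameters()] object.
#' @examples
#' load_parameters("cho-k1-plateau")
#' @export
load_parameters <- function(preset = NULL, file = NULL) {
  if (is.null(preset) == is.null(file))
    stop_config("supply exactly one of 'preset' or 'file'")
  if (!is.null(preset)) {
    fname <- paste0(gsub("-", "_", preset), ".cfg")
    file <- system.file("extdata", fname, package = "imkmodel")
    if (file == "")
      stop_config(sprintf(
        "unknown preset '%s' (available: cho-k1-plateau, cho-k1-log)", preset))
  }
  vals <- read_params_config(file)
  required <- c("alpha0", "beta0", "repair_rate0", "gamma")
  missing <- setdiff(required, names(vals))
  if (length(missing))
    stop_config(sprintf("config %s: missing key(s): %s",
                        file, paste(missing, collapse = ", ")))
  imk_parameters(alpha0 = vals$alpha0, beta0 = vals$beta0,
                 repair_rate0 = vals$repair_rate0,
                 a_rate = if (is.null(vals$a_rate)) 0 else vals$a_rate,
                 gamma = vals$gamma,
                 label = if (is.null(vals$label)) preset else vals$label)
}

# Minimal plain-text config reader: '[section]' headers, 'key = value' lines,
# '#' comments.  Only the [params] section is interpreted.
read_params_config <- function(file) {
  if (!file.exists(file)) stop_config(sprintf("config file not found: %s", file))
  lines <- trimws(readLines(file))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  section <- ""
  vals <- list()
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      next
    }
    if (section != "params") next
    m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.+?)\\s*(#.*)?$", ln))[[1]]
    if (length(m) < 3L)
      stop_config(sprintf("config %s: cannot parse line '%s'", file, ln))
    key <- m[2]
    raw <- gsub('^"|"$', "", m[3])
    num <- suppressWarnings(as.numeric(raw))
    if (key != "label" && is.na(num))
      stop_config(sprintf("config %s: key '%s' has non-numeric value '%s'",
                          file, key, raw))
    vals[[key]] <- if (key == "label") raw else num
  }
  vals
}
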