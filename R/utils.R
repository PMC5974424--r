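#' @keywords internal
"_PACKAGE"

# Classed conditions so callers (and the CLI) can distinguish bad values in a
# quantity's domain, malformed configuration, and malformed data files.
imk_stop <- function(class, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "imk_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

stop_domain <- function(msg) imk_stop("imk_domain_error", msg, sys.call(-1))
stop_config <- function(msg) imk_stop("imk_config_error", msg, sys.call(-1))
stop_data   <- function(msg) imk_stop("imk_data_error", msg, sys.call(-1))
stop_estimation <- function(msg) imk_stop("imk_estimation_error", msg, sys.call(-1))

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_domain(sprintf("'%s' must be a single finite number", name))
  ok_low <- if (strict_lower) x > lower else x >= lower
  if (!ok_low || x > upper)
    stop_domain(sprintf("'%s' = %g is outside its valid range", name, x))
  invisible(x)
}

# All tabular I/O uses one dialect: comma-separated, dot decimal, header
# required.  Lines starting with '#' carry key=value metadata.
read_imk_csv <- function(path, required_cols) {
  if (!file.exists(path)) stop_data(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, comment.char = "#", strip.white = TRUE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing))
    stop_data(sprintf("%s: missing required column(s): %s",
                      path, paste(missing, collapse = ", ")))
  df
}

read_csv_metadata <- function(path) {
  lines <- readLines(path, n = 50L)
  meta <- grep("^#", lines, value = TRUE)
  kv <- regmatches(meta, regexec("^#\\s*([A-Za-z0-9_.]+)\\s*=\\s*(\\S+)", meta))
  kv <- Filter(function(m) length(m) == 3L, kv)
  stats::setNames(
    lapply(kv, function(m) {
      v <- suppressWarnings(as.numeric(m[3]))
      if (is.na(v)) m[3] else v
    }),
    vapply(kv, function(m) m[2], "")
  )
}

# Exponent guard: the model never needs exp() of anything below -700
# (double underflow); clamp so survival degrades to 0 rather than NaN.
safe_exp <- function(x) exp(pmax(x, -700))
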