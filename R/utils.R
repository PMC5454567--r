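# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# All package errors carry a condition class so the CLI can map them to exit
# codes and tests can assert on the failure mode rather than message text.
ld_stop <- function(msg, class = "legdose_validation_error") {
  stop(errorCondition(msg, class = c(class, "legdose_error")))
}

is_scalar_num <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

assert_num <- function(x, name, lower = -Inf, upper = Inf,
                       class = "legdose_validation_error") {
  if (!is_scalar_num(x) || x < lower || x > upper) {
    ld_stop(sprintf("`%s` must be a finite number in [%s, %s] (got: %s)",
                    name, format(lower), format(upper),
                    paste(format(x), collapse = ", ")),
            class = class)
  }
  invisible(x)
}

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    ld_stop(sprintf("`%s` must be TRUE or FALSE", name))
  }
  invisible(x)
}

# Timestamp dialect: ISO-8601 local time, minute resolution, no timezone
# suffix. All POSIXct values are carried in UTC internally so arithmetic is
# DST-free.
TS_FMT <- "%Y-%m-%dT%H:%M:%S"

parse_ts <- function(x) {
  as.POSIXct(as.character(x), format = TS_FMT, tz = "UTC")
}

format_ts <- function(t) {
  format(t, TS_FMT, tz = "UTC")
}

as_ts <- function(x, name = "timestamp") {
  if (inherits(x, "POSIXct")) return(as.POSIXct(x, tz = "UTC"))
  if (inherits(x, "Date")) {
    return(as.POSIXct(format(x), tz = "UTC"))
  }
  out <- parse_ts(x)
  if (anyNA(out)) ld_stop(sprintf("`%s` is not a valid '%s' timestamp", name, TS_FMT))
  out
}

minute_grid <- function(start, n) {
  start + 60 * (seq_len(n) - 1L)
}

# Numeric formatting for CSV output: shortest representation when it
# round-trips exactly, full 17 significant digits otherwise. Guarantees
# read(write(x)) == x bit-for-bit and byte-identical re-writes.
fmt_num <- function(x) {
  out <- rep("", length(x))
  ok <- !is.na(x)
  if (!any(ok)) return(out)
  long <- sprintf("%.17g", x[ok])
  short <- as.character(x[ok])
  exact <- suppressWarnings(as.numeric(short)) == x[ok]
  exact[is.na(exact)] <- FALSE
  long[exact] <- short[exact]
  out[ok] <- long
  out
}

# Derive a per-stream child seed that stays inside 32-bit integer range.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i) %% 2147483647)
}

# Centered finite-difference slope; one-sided at the edges. `m` gives sample
# positions in minutes (gaps allowed, no interpolation).
slope_centered <- function(d, m) {
  n <- length(d)
  if (n < 2L) return(rep(0, n))
  s <- numeric(n)
  s[1] <- (d[2] - d[1]) / (m[2] - m[1])
  s[n] <- (d[n] - d[n - 1]) / (m[n] - m[n - 1])
  if (n > 2L) {
    i <- 2:(n - 1)
    s[i] <- (d[i + 1] - d[i - 1]) / (m[i + 1] - m[i - 1])
  }
  s
}

# Backward finite-difference slope (slope over the minute ending at i).
slope_backward <- function(d, m) {
  n <- length(d)
  if (n < 2L) return(rep(0, n))
  s <- c((d[2] - d[1]) / (m[2] - m[1]), diff(d) / diff(m))
  s
}

# 3-point centered moving average, edges kept as-is.
smooth3 <- function(x) {
  n <- length(x)
  if (n < 3L) return(x)
  sm <- as.numeric(stats::filter(x, rep(1 / 3, 3), sides = 2))
  sm[1] <- x[1]
  sm[n] <- x[n]
  sm
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
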