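# Internal helpers shared across modules.

# Linear-interpolation (type-7) quantile, the single convention used for IQR
# scaling, presumed-normal panel quantiles, threshold percentiles and go-cutoff
# calibration.
quantile7 <- function(x, probs) {
  stats::quantile(x, probs = probs, type = 7, names = FALSE, na.rm = FALSE)
}

# Average days per month (Gregorian year / 12); used to express month-denominated
# defaults (e.g. the 36-month durable-OS horizon) in days.
DAYS_PER_MONTH <- 30.4375

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1))
    stop_config(field, "must be a probability in [0, 1]")
  invisible(x)
}

check_flag <- function(x, field) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_config(field, "must be TRUE or FALSE")
  invisible(x)
}
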