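# Internal helpers shared across modules.

# Report-time rounding: counts stay real internally, integers only at output.
round_half_up <- function(x) floor(x + 0.5)

# Validate that `data` has the named columns; abort with the offender.
check_columns <- function(data, cols, what = "input") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing column(s): %s", what,
                  paste(missing, collapse = ", ")),
          class = "aeb_validation_error")
  }
  invisible(data)
}

check_fraction <- function(x, name, lower = 0, upper = 1,
                           open_lower = FALSE, open_upper = FALSE) {
  bad <- !is.finite(x) |
    (if (open_lower) x <= lower else x < lower) |
    (if (open_upper) x >= upper else x > upper)
  if (any(bad)) {
    abort(sprintf("`%s` must lie in %s%s, %s%s; got %s",
                  name,
                  if (open_lower) "(" else "[", format(lower),
                  format(upper), if (open_upper) ")" else "]",
                  paste(format(x[bad]), collapse = ", ")),
          class = "aeb_validation_error")
  }
  invisible(x)
}

# Canonical casualty kinds, in report order.
aeb_kinds <- function() c("fatality", "severe_injury")

match_kind <- function(kind) {
  match.arg(kind, aeb_kinds())
}

#' Validate an annual casualty series
#'
#' A casualty series is a data frame with a `year` column (strictly
#' increasing, consecutive calendar years) and a `count` column of strictly
#' positive annual casualty counts. The grey model operates on the raw
#' positive series, so zeros or gaps are rejected outright.
#'
#' @param data A data frame with columns `year` and `count`.
#' @param min_length Minimum number of observations (the GM(1,1) normal
#'   equations need at least 4).
#' @return The validated data, invisibly coerced to a tibble sorted by year.
#' @export
validate_casualty_series <- function(data, min_length = 4) {
  check_columns(data, c("year", "count"), "casualty series")
  data <- as_tibble(data)
  if (nrow(data) < min_length) {
    abort(sprintf("casualty series has %d observation(s); at least %d are required",
                  nrow(data), min_length),
          class = "aeb_length_error")
  }
  if (anyNA(data$year) || anyNA(data$count)) {
    abort("casualty series contains missing values", class = "aeb_validation_error")
  }
  if (any(diff(data$year) != 1)) {
    abort("casualty series years must be strictly increasing and consecutive",
          class = "aeb_validation_error")
  }
  if (any(data$count <= 0)) {
    abort("casualty counts must be strictly positive for grey modelling",
          class = "aeb_validation_error")
  }
  data
}
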