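# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Commercial (half-up) rounding, used for all reported figures: base
#' `round()` is round-half-even, which would turn an expert-panel mean of
#' 100.5 patients into 100 rather than 101.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 0).
#' @return `x` rounded half away from zero.
#' @examples
#' round_half_up(100.5)      # 101
#' round_half_up(0.125, 2)   # 0.13
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_positive_scalar <- function(x, name) {
  if (!is_scalar_number(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number.", name),
          class = "oncobudget_validation_error")
  }
  invisible(x)
}

check_non_negative_scalar <- function(x, name) {
  if (!is_scalar_number(x) || x < 0) {
    abort(sprintf("`%s` must be a single non-negative finite number.", name),
          class = "oncobudget_validation_error")
  }
  invisible(x)
}

# Months-to-days conversion used when mapping treatment exposure onto cycle
# cadence (mean Gregorian month).
DAYS_PER_MONTH <- 30.44

MONTHS_PER_YEAR <- 12
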