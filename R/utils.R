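# days per month used for all day -> month conversions (documented convention)
DAYS_PER_MONTH <- 30.4375

#' Round half away from zero
#'
#' Decimal rounding with ties going up (`0.05 -> 0.1` at one digit), the
#' convention used for all reported percentages; base `round()` rounds ties
#' to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1L) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

days_to_months <- function(days) days / DAYS_PER_MONTH
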