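# Shared small helpers: rounding, percentage reporting, input checks.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; summary percentages in reports use
#' conventional half-up rounding so that e.g. 36.5 -> 37 (well, 36.5 -> 37 for
#' positive values).
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return numeric vector rounded half away from zero
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage of a count over a denominator
#'
#' Returns `100 * num / den` rounded half-up to `digits` decimals; `NA` when
#' the denominator is zero.
#'
#' @param num numerator (integerish)
#' @param den denominator (integerish)
#' @param digits decimals to keep (default 1)
#' @return numeric percentage
#' @export
pct <- function(num, den, digits = 1) {
  ifelse(den == 0, NA_real_, round_half_up(100 * num / den, digits))
}

# stopifnot-style check with a readable message
check_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

is_count <- function(x) is.numeric(x) && all(!is.na(x)) && all(x >= 0) && all(x == floor(x))

# deterministic child seed: keep below 2^31
child_seed <- function(seed, k) {
  (as.integer(seed) * 1103L + as.integer(k) * 12345L) %% 2147483629L
}
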