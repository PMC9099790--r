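#' Round half away from zero
#'
#' Printed tables in the corrosion-inhibition literature round half-values
#' away from zero; base [round()] rounds half to even, so comparisons against
#' printed columns use this helper instead.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` places, halves away from zero.
#' @examples
#' round_half_away(c(0.125, -0.125), 2)
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

stopf <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "corrqsar_error")))
}

# All stochastic code routes randomness through here so the caller's
# .Random.seed is never disturbed.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}
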