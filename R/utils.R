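#' @keywords internal
#' Round half away from zero.
#'
#' `base::round()` rounds half to even; pixel geometry here uses the
#' conventional half-away-from-zero rule so that symmetric layouts stay
#' symmetric.
#' @noRd
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' @noRd
clamp <- function(x, lo, hi) {
  pmin(pmax(x, lo), hi)
}

#' Derive a child seed from a root seed.
#'
#' Keeps derived seeds inside the 32-bit integer range.
#' @noRd
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647L)
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == as.integer(x)
}
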