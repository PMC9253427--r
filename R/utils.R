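`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round a monetary amount to the smallest currency unit
#'
#' Rounds half away from zero, the convention for displayed currency, so that
#' a computed immediate outcome of 0.525 becomes 0.53 and -0.525 becomes
#' -0.53.
#'
#' @param x Numeric vector of amounts (GBP).
#' @param penny Smallest currency unit (default 0.01 GBP).
#' @return Numeric vector rounded to multiples of `penny`.
#' @export
penny_round <- function(x, penny = 0.01) {
  sign(x) * floor(abs(x) / penny + 0.5) * penny
}

# integer number of pennies; robust equality tests for currency amounts
.pennies <- function(x, penny = 0.01) as.integer(round(x / penny))

# deterministic child seed derivation, kept inside 32-bit integer range
derive_seed <- function(seed, index = 0L, salt = 0L) {
  s <- (as.numeric(seed) * 48271 + as.numeric(index) * 69621 +
          as.numeric(salt) * 16807) %% 2147483563
  as.integer(s) + 1L
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# lower median: for even n take the lower of the two central order statistics
lower_median <- function(x) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n == 0L) return(NA_real_)
  x[[floor((n + 1) / 2)]]
}
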