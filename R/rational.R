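# Exact rational representation for productivities and thresholds.
# Threshold crossing C >= theta must be decided exactly, never by floating
# tolerance; all quantities here are small integers, so exact integer
# arithmetic in doubles (< 2^53) suffices.

#' Convert numerics to exact rationals
#'
#' Represents each value as an integer numerator over a common denominator,
#' using continued-fraction rationalization (via [MASS::fractions()]).
#'
#' @param x Numeric vector (e.g. productivity factors).
#' @return A list with integer vector `num` and scalar `den` such that
#'   `x == num / den` exactly for all representable inputs.
#' @keywords internal
as_rational <- function(x) {
  fr <- attr(MASS::fractions(x), "fracs")
  parts <- strsplit(fr, "/", fixed = TRUE)
  num <- vapply(parts, function(p) as.numeric(p[[1]]), numeric(1))
  den <- vapply(parts, function(p) if (length(p) > 1) as.numeric(p[[2]]) else 1, numeric(1))
  d <- Reduce(lcm2, den)
  list(num = num * (d / den), den = d)
}

gcd2 <- function(a, b) {
  while (b != 0) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}

lcm2 <- function(a, b) a / gcd2(a, b) * b
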