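#' Round away from zero
#'
#' Deterministic rounding used by the integer neuron dynamics:
#' `sign(x) * ceiling(|x|)`.  It is an odd function and the identity on
#' integers.  Loihi applies it to the decay products of the synaptic-input
#' and voltage updates.
#'
#' @param x Numeric vector, finite.
#' @return Numeric vector of integers (stored as doubles; the simulator keeps
#'   all state in doubles, which represent integers exactly up to 2^53).
#' @examples
#' round_away_from_zero(c(2.3, -2.3, 0, 968.75))
#' @export
round_away_from_zero <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("x: must be finite numeric", call. = FALSE)
  }
  sign(x) * ceiling(abs(x))
}

#' Truncate an integer to a power-of-two precision
#'
#' Zeroes the `ns` low bits of the magnitude, i.e. rounds toward zero to the
#' nearest multiple of `2^ns`, and reapplies the sign.  This is the
#' bit-shift pair `(x >> ns) << ns` of the weight codec; for negative values
#' we follow the toward-zero convention (an arithmetic shift on two's
#' complement would instead round toward -Inf — see the methods vignette).
#'
#' @param x Integer-valued numeric vector, `|x| <= 2^15`.
#' @param ns Non-negative precision exponent (number of low bits zeroed),
#'   `0 <= ns <= 8`.
#' @return Multiples of `2^ns` with `|result| <= |x|`.  Idempotent.
#' @examples
#' truncate_to_precision(255, 2)  # 252
#' truncate_to_precision(-5, 1)   # -4
#' @export
truncate_to_precision <- function(x, ns) {
  if (!is.numeric(ns) || length(ns) != 1L || !is.finite(ns) || ns < 0 ||
      ns != floor(ns)) {
    stop("ns: must be a single non-negative integer", call. = FALSE)
  }
  if (!is.numeric(x) || any(!is.finite(x)) || any(x != floor(x))) {
    stop("x: must be integer-valued", call. = FALSE)
  }
  step <- 2^ns
  sign(x) * (abs(x) %/% step) * step
}

#' Stochastic rounding to a power-of-two grid
#'
#' Rounds `|x|` to one of the two bracketing multiples of `2^ns` and
#' reapplies the sign: down with probability proportional to the distance to
#' the upper multiple, up with probability proportional to the distance to
#' the lower one.  Values already on the grid are returned unchanged with
#' probability 1.  Unbiased in expectation.  One uniform variate is consumed
#' per element of `x`, in element order, so draw counts are predictable.
#'
#' Loihi applies this (at `ns = 0`) to synaptic-trace decay products and (at
#' the weight-precision `ns`) to plastic mantissa updates.
#'
#' @param x Finite numeric vector.
#' @param ns Precision exponent, grid step `2^ns`.
#' @param rng An [rng_stream].
#' @return Numeric vector of multiples of `2^ns`, `|result - x| < 2^ns`.
#' @examples
#' r <- rng_stream(1)
#' stochastic_round(c(4, 1.5, 87.5), 0, r)
#' @export
stochastic_round <- function(x, ns, rng) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("x: must be finite numeric", call. = FALSE)
  }
  if (!is.numeric(ns) || length(ns) != 1L || ns < 0 || ns != floor(ns)) {
    stop("ns: must be a single non-negative integer", call. = FALSE)
  }
  step <- 2^ns
  m <- abs(x)
  base <- floor(m / step) * step
  frac <- (m - base) / step
  u <- rng_uniform(rng, length(x))
  sign(x) * (base + (u < frac) * step)
}
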