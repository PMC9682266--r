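#' Reproducible uniform-variate stream
#'
#' A self-contained random stream backed by R's Mersenne-Twister generator.
#' The stream keeps its own copy of the generator state, so drawing from it
#' neither reads nor disturbs the global `.Random.seed`.  All stochastic
#' operations in the simulator (Poisson generators, trace rounding, plastic
#' weight rounding, fixture construction) draw from a single stream in a
#' documented, fixed order, which makes whole simulations bit-reproducible
#' from `(config, steps, seed)` alone.
#'
#' Draw order within one scheduler step: spike generators in configuration
#' order (one variate per generator unit, Poisson mode only), then synaptic
#' traces per plastic connection group in configuration order (x1, x2 over
#' source units, then y1, y2, y3 over target units), then — on learning
#' epochs only — plastic mantissa rounding in synapse-pair order.
#'
#' @param seed Integer seed.
#' @return An object of class `rng_stream`.
#' @examples
#' r <- rng_stream(42)
#' rng_uniform(r, 3)
#' @export
rng_stream <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed: must be a single finite integer", call. = FALSE)
  }
  e <- new.env(parent = emptyenv())
  old <- .get_global_seed()
  set.seed(as.integer(seed))
  e$state <- get(".Random.seed", envir = globalenv())
  .set_global_seed(old)
  e$seed <- as.integer(seed)
  e$n_drawn <- 0L
  class(e) <- "rng_stream"
  e
}

#' Draw uniform variates from a stream
#'
#' @param rng An `rng_stream`.
#' @param n Number of variates.
#' @return Numeric vector of `n` draws from U(0, 1).
#' @export
rng_uniform <- function(rng, n) {
  stopifnot(inherits(rng, "rng_stream"))
  n <- as.integer(n)
  if (n == 0L) return(numeric(0))
  old <- .get_global_seed()
  assign(".Random.seed", rng$state, envir = globalenv())
  u <- stats::runif(n)
  rng$state <- get(".Random.seed", envir = globalenv())
  .set_global_seed(old)
  rng$n_drawn <- rng$n_drawn + n
  u
}

#' @export
print.rng_stream <- function(x, ...) {
  cat(sprintf("<rng_stream> seed %d, %d variates drawn\n", x$seed, x$n_drawn))
  invisible(x)
}

.get_global_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.set_global_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
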