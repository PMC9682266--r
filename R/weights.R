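SIGN_MODES <- c("excitatory", "inhibitory", "mixed")

#' Mantissa range of a sign mode
#'
#' Excitatory synapses store mantissas in [0, 255], inhibitory in [-255, 0],
#' and mixed mode — which spends one mantissa bit on the sign — in
#' [-256, 254].
#'
#' @param sign_mode One of `"excitatory"`, `"inhibitory"`, `"mixed"`.
#' @return Length-2 numeric `c(lo, hi)`.
#' @export
mantissa_range <- function(sign_mode) {
  sign_mode <- match.arg(sign_mode, SIGN_MODES)
  switch(sign_mode,
    excitatory = c(0, 255),
    inhibitory = c(-255, 0),
    mixed      = c(-256, 254)
  )
}

#' Weight precision exponent
#'
#' The number of low mantissa bits that are zeroed,
#' `ns = 8 - (n_wb - sigma_mixed)`, where `sigma_mixed` is 1 in mixed sign
#' mode (one bit stores the sign) and 0 otherwise.  Representable mantissas
#' are multiples of `2^ns`: with 8 weight bits in excitatory mode the step is
#' 1, with 6 bits it is 4, and with 8 bits in mixed mode it is 2.
#'
#' @param n_wb Number of weight bits, integer in [1, 8].
#' @param sign_mode Sign mode string.
#' @return Integer precision exponent in [0, 8].
#' @examples
#' precision_exponent(8, "excitatory")  # 0
#' precision_exponent(6, "excitatory")  # 2
#' precision_exponent(8, "mixed")       # 1
#' @export
precision_exponent <- function(n_wb, sign_mode) {
  if (!is.numeric(n_wb) || length(n_wb) != 1L || !is.finite(n_wb) ||
      n_wb != floor(n_wb) || n_wb < 1 || n_wb > 8) {
    stop("n_wb: must be an integer in [1, 8]", call. = FALSE)
  }
  sign_mode <- match.arg(sign_mode, SIGN_MODES)
  sigma_mixed <- as.integer(sign_mode == "mixed")
  as.integer(8 - (n_wb - sigma_mixed))
}

#' Synapse specification
#'
#' Bundles a raw weight mantissa, weight exponent, weight-bit count, sign
#' mode and plasticity flag, validating each field.  Vectorized over
#' `mantissa` and `exponent` (recycled to common length) so one spec can
#' describe a whole connection group.
#'
#' @param mantissa Integer mantissa(s) within the sign-mode range.
#' @param exponent Weight exponent(s) Theta, integer in [-8, 7].
#' @param n_wb Weight bits, integer in [1, 8] (scalar, shared).
#' @param sign_mode Sign mode string (scalar, shared).
#' @param plastic Logical, whether the synapse weight may change at run time.
#' @return A list of class `synapse_spec`.
#' @export
synapse_spec <- function(mantissa, exponent = 0, n_wb = 8,
                         sign_mode = "excitatory", plastic = FALSE) {
  sign_mode <- match.arg(sign_mode, SIGN_MODES)
  rng <- mantissa_range(sign_mode)
  if (!is.numeric(mantissa) || any(!is.finite(mantissa)) ||
      any(mantissa != floor(mantissa)) ||
      any(mantissa < rng[1]) || any(mantissa > rng[2])) {
    stop(sprintf("mantissa: must be integer in [%d, %d] for %s sign mode",
                 rng[1], rng[2], sign_mode), call. = FALSE)
  }
  if (!is.numeric(exponent) || any(!is.finite(exponent)) ||
      any(exponent != floor(exponent)) ||
      any(exponent < -8) || any(exponent > 7)) {
    stop("exponent: must be integer in [-8, 7]", call. = FALSE)
  }
  n <- max(length(mantissa), length(exponent))
  structure(list(
    mantissa  = rep_len(as.numeric(mantissa), n),
    exponent  = rep_len(as.numeric(exponent), n),
    n_wb      = as.integer(n_wb),
    sign_mode = sign_mode,
    plastic   = isTRUE(plastic)
  ), class = "synapse_spec")
}

#' @export
print.synapse_spec <- function(x, ...) {
  cat(sprintf("<synapse_spec> %d synapse(s), %s, n_wb=%d%s\n",
              length(x$mantissa), x$sign_mode, x$n_wb,
              if (x$plastic) ", plastic" else ""))
  invisible(x)
}

#' Encode a synapse spec into its effective weight
#'
#' The weight codec: the mantissa is truncated toward zero to the precision
#' grid (`2^ns` with `ns` from [precision_exponent]), scaled by `2^(6+Theta)`
#' (a toward-zero integer division when `6 + Theta < 0`), clipped to the
#' 21-bit limit, and finally has its 6 low bits zeroed.  The result `J` is
#' the integer added to the post-synaptic input for every delivered spike;
#' it is always a multiple of 64 and `|J| <= 2^21 - 2^6`.  Clipping fires in
#' exactly one representable case: mantissa -256 with exponent 7 in mixed
#' mode.
#'
#' @param spec A [synapse_spec].
#' @return Numeric vector of effective weights, one per synapse in `spec`.
#' @examples
#' encode_weight(synapse_spec(255, 0))                        # 16320
#' encode_weight(synapse_spec(128, -6, sign_mode = "mixed"))  # 128
#' @export
encode_weight <- function(spec) {
  stopifnot(inherits(spec, "synapse_spec"))
  ns <- precision_exponent(spec$n_wb, spec$sign_mode)
  w_shifted <- truncate_to_precision(spec$mantissa, ns)
  shift <- 6 + spec$exponent
  j_scaled <- ifelse(shift >= 0,
                     w_shifted * 2^shift,
                     sign(w_shifted) * (abs(w_shifted) %/% 2^(-shift)))
  lim <- 2^21 - 1
  j_scaled <- pmax(pmin(j_scaled, lim), -lim)
  sign(j_scaled) * (abs(j_scaled) %/% 64) * 64
}

#' Normalize a spec to its on-chip representation
#'
#' Weight initialization: replaces the mantissa by its precision-truncated
#' value, so the spec is exactly what the hardware stores.  Idempotent, and
#' a fixed point of the codec: re-encoding a normalized spec gives the same
#' effective weight.
#'
#' @param spec A [synapse_spec].
#' @return A `synapse_spec` whose mantissas lie on the precision grid.
#' @export
normalize_spec <- function(spec) {
  stopifnot(inherits(spec, "synapse_spec"))
  ns <- precision_exponent(spec$n_wb, spec$sign_mode)
  spec$mantissa <- truncate_to_precision(spec$mantissa, ns)
  spec
}

#' Enumerate the full weight table
#'
#' One row per representable (mantissa, exponent) pair: exponents span
#' [-8, 7] and mantissas the multiples of `2^ns` within the sign-mode range.
#' With 8 weight bits in excitatory mode this is the full 4096-row table
#' (256 mantissas x 16 exponents).
#'
#' @param n_wb Weight bits.
#' @param sign_mode Sign mode string.
#' @return A data.frame with columns `mantissa`, `exponent`, `weight`,
#'   sorted by (exponent, mantissa).
#' @export
enumerate_weight_table <- function(n_wb = 8, sign_mode = "excitatory") {
  sign_mode <- match.arg(sign_mode, SIGN_MODES)
  ns <- precision_exponent(n_wb, sign_mode)
  r <- mantissa_range(sign_mode)
  mantissas <- seq(ceiling(r[1] / 2^ns) * 2^ns, r[2], by = 2^ns)
  grid <- expand.grid(mantissa = mantissas, exponent = -8:7,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$exponent, grid$mantissa), , drop = FALSE]
  rownames(grid) <- NULL
  spec <- synapse_spec(grid$mantissa, grid$exponent, n_wb, sign_mode)
  grid$weight <- encode_weight(spec)
  grid
}

#' Write a weight table as CSV
#'
#' @param table A data.frame from [enumerate_weight_table].
#' @param path Output CSV path (columns mantissa, exponent, weight).
#' @return `path`, invisibly.
#' @export
write_weight_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
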