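TRACE_NAMES <- c("x1", "x2", "y1", "y2", "y3")

#' Synaptic trace parameters
#'
#' Loihi provides two pre-synaptic traces (x1, x2) and three post-synaptic
#' traces (y1, y2, y3).  Each is a bounded integer low-pass filter of a
#' spike train: on a spike the trace jumps by its impulse, otherwise it
#' decays with factor `alpha = 1 - 1/tau` followed by stochastic rounding.
#' Values live in [0, 127].
#'
#' @param x1_impulse,x2_impulse,y1_impulse,y2_impulse,y3_impulse Impulse
#'   amplitudes, integers in [0, 127].  A zero impulse leaves that trace
#'   permanently at zero.
#' @param x1_tau,x2_tau,y1_tau,y2_tau,y3_tau Decay time constants, positive
#'   integers.
#' @return A list of class `trace_params` with elements `impulse` and `tau`,
#'   each a named numeric vector over x1, x2, y1, y2, y3.
#' @export
trace_params <- function(x1_impulse = 0, x1_tau = 1,
                         x2_impulse = 0, x2_tau = 1,
                         y1_impulse = 0, y1_tau = 1,
                         y2_impulse = 0, y2_tau = 1,
                         y3_impulse = 0, y3_tau = 1) {
  impulse <- c(x1 = x1_impulse, x2 = x2_impulse, y1 = y1_impulse,
               y2 = y2_impulse, y3 = y3_impulse)
  tau <- c(x1 = x1_tau, x2 = x2_tau, y1 = y1_tau, y2 = y2_tau, y3 = y3_tau)
  if (any(!is.finite(impulse)) || any(impulse != floor(impulse)) ||
      any(impulse < 0) || any(impulse > 127)) {
    stop("trace impulses must be integers in [0, 127]", call. = FALSE)
  }
  if (any(!is.finite(tau)) || any(tau != floor(tau)) || any(tau < 1)) {
    stop("trace decay constants must be integers >= 1", call. = FALSE)
  }
  structure(list(impulse = impulse, tau = tau), class = "trace_params")
}

#' Single-step trace update
#'
#' Applies the first-order decay `(1 - 1/tau) * prev`, stochastically rounds
#' the (possibly fractional) product to an integer, adds the impulse for
#' units that spiked, and clamps the result to [0, 127].  One uniform
#' variate is drawn per element regardless of whether the decay product is
#' fractional, keeping the stream's draw count predictable.
#'
#' @param prev Previous trace values, integers in [0, 127] (vectorized).
#' @param tau Decay time constant, integer >= 1.
#' @param spike Logical vector: which units spiked this step.
#' @param impulse Impulse amplitude added on a spike.
#' @param rng An [rng_stream].
#' @return Updated integer trace values in [0, 127].
#' @examples
#' r <- rng_stream(1)
#' update_trace(0, 8, TRUE, 120, r)    # 120
#' update_trace(120, 8, TRUE, 120, r)  # 0.875*120 = 105, +120, clamp -> 127
#' @export
update_trace <- function(prev, tau, spike, impulse, rng) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) ||
      tau < 1 || tau != floor(tau)) {
    stop("tau: must be an integer >= 1", call. = FALSE)
  }
  if (any(prev < 0) || any(prev > 127)) {
    stop("prev: trace values must lie in [0, 127]", call. = FALSE)
  }
  decayed <- prev * (tau - 1) / tau
  x <- stochastic_round(decayed, 0, rng)
  x <- x + impulse * as.numeric(spike)
  pmin(pmax(x, 0), 127)
}

#' Parse a learning-rule expression
#'
#' Learning rules are sums of products of the dependency factors `x0`, `y0`
#' (1 iff the pre-/post-synaptic neuron spiked since the last learning
#' evaluation), the traces `x1`, `x2`, `y1`, `y2`, `y3`, integer constants,
#' and power-of-two scale literals written `2^m` (e.g. `2^-2`).  Only
#' addition, subtraction and multiplication are allowed; anything else
#' (division, parentheses, unknown variables) is rejected with an error
#' naming the offending token.
#'
#' The canonical asymmetric STDP rule is
#' `"2^-2*x1*y0 - 2^-2*x0*y1"`: potentiation when the pre-trace is high at a
#' post spike, depression when the post-trace is high at a pre spike.
#'
#' @param text Rule expression string.
#' @param epoch_exponent Non-negative integer k: the rule is evaluated every
#'   `2^k` steps.
#' @return A list of class `learning_rule` with a `terms` list; each term
#'   has `sign` (+1/-1), `scale_exponent` (summed exponent of its
#'   power-of-two literals), `factors` (character vector of trace /
#'   dependency names) and `constants` (plain integer factors).
#' @examples
#' parse_learning_rule("2^-2*x1*y0 - 2^-2*x0*y1")
#' @export
parse_learning_rule <- function(text, epoch_exponent = 0) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text))) {
    stop("text: must be a non-empty rule expression", call. = FALSE)
  }
  if (!is.numeric(epoch_exponent) || length(epoch_exponent) != 1L ||
      epoch_exponent < 0 || epoch_exponent != floor(epoch_exponent)) {
    stop("epoch_exponent: must be a non-negative integer", call. = FALSE)
  }
  tokens <- .tokenize_rule(text)
  terms <- list()
  i <- 1L
  sign <- 1
  # leading sign
  if (tokens$type[i] %in% c("plus", "minus")) {
    if (tokens$type[i] == "minus") sign <- -1
    i <- i + 1L
  }
  repeat {
    parsed <- .parse_term(tokens, i)
    term <- parsed$term
    term$sign <- sign
    terms[[length(terms) + 1L]] <- term
    i <- parsed$i
    if (i > length(tokens$type)) break
    if (tokens$type[i] == "plus") {
      sign <- 1
    } else if (tokens$type[i] == "minus") {
      sign <- -1
    } else {
      stop(sprintf("learning rule: unexpected token '%s'", tokens$text[i]),
           call. = FALSE)
    }
    i <- i + 1L
    if (i > length(tokens$type)) {
      stop("learning rule: expression ends after operator", call. = FALSE)
    }
  }
  structure(list(terms = terms, epoch_exponent = as.integer(epoch_exponent),
                 text = text),
            class = "learning_rule")
}

.tokenize_rule <- function(text) {
  pat <- c(
    pow2  = "^2\\^-?[0-9]+",
    var   = "^[xy][0-9]",
    int   = "^[0-9]+",
    plus  = "^\\+",
    minus = "^-",
    times = "^\\*"
  )
  s <- text
  types <- character(0)
  texts <- character(0)
  repeat {
    s <- sub("^\\s+", "", s)
    if (!nzchar(s)) break
    hit <- NA_character_
    for (ty in names(pat)) {
      m <- regmatches(s, regexpr(pat[[ty]], s))
      if (length(m) == 1L) {
        hit <- ty
        types <- c(types, ty)
        texts <- c(texts, m)
        s <- substring(s, nchar(m) + 1L)
        break
      }
    }
    if (is.na(hit)) {
      bad <- regmatches(s, regexpr("^\\S+", s))
      stop(sprintf(
        "learning rule: unsupported token '%s' (only +, -, * over x0,x1,x2,y0,y1,y2,y3, integers and 2^m are allowed)",
        bad), call. = FALSE)
    }
  }
  known <- c("x0", "x1", "x2", "y0", "y1", "y2", "y3")
  isvar <- types == "var"
  if (any(isvar & !(texts %in% known))) {
    stop(sprintf("learning rule: unknown variable '%s'",
                 texts[isvar & !(texts %in% known)][1L]), call. = FALSE)
  }
  list(type = types, text = texts)
}

.parse_term <- function(tokens, i) {
  factors <- character(0)
  constants <- numeric(0)
  scale_exponent <- 0
  expect_factor <- TRUE
  n <- length(tokens$type)
  while (i <= n) {
    ty <- tokens$type[i]
    if (expect_factor) {
      if (ty == "var") {
        factors <- c(factors, tokens$text[i])
      } else if (ty == "pow2") {
        scale_exponent <- scale_exponent +
          as.numeric(sub("^2\\^", "", tokens$text[i]))
      } else if (ty == "int") {
        constants <- c(constants, as.numeric(tokens$text[i]))
      } else {
        stop(sprintf("learning rule: expected a factor, got '%s'",
                     tokens$text[i]), call. = FALSE)
      }
      expect_factor <- FALSE
      i <- i + 1L
    } else {
      if (ty == "times") {
        expect_factor <- TRUE
        i <- i + 1L
      } else {
        break  # term ends at +/- or end of input
      }
    }
  }
  if (expect_factor) {
    stop("learning rule: term has no factor", call. = FALSE)
  }
  list(term = list(sign = 1, scale_exponent = scale_exponent,
                   factors = factors, constants = constants),
       i = i)
}

#' @export
print.learning_rule <- function(x, ...) {
  cat(sprintf("<learning_rule> %s  (%d term(s), evaluated every 2^%d steps)\n",
              x$text, length(x$terms), x$epoch_exponent))
  invisible(x)
}

#' Evaluate a learning rule on trace values
#'
#' Computes the raw (possibly fractional) weight change `dw` from current
#' trace values and dependency factors.  All trace arguments are vectorized
#' over synapse pairs.
#'
#' @param rule A [learning_rule].
#' @param x0,y0 Dependency factors (0/1) per pair.
#' @param x1,x2,y1,y2,y3 Trace values per pair.
#' @return Numeric `dw` per pair.
#' @examples
#' rule <- parse_learning_rule("2^-2*x1*y0 - 2^-2*x0*y1")
#' evaluate_learning_rule(rule, x0 = 0, y0 = 1, x1 = 120, y1 = 0)  # 30
#' @export
evaluate_learning_rule <- function(rule, x0 = 0, x1 = 0, x2 = 0,
                                   y0 = 0, y1 = 0, y2 = 0, y3 = 0) {
  stopifnot(inherits(rule, "learning_rule"))
  env <- list(x0 = x0, x1 = x1, x2 = x2, y0 = y0, y1 = y1, y2 = y2, y3 = y3)
  n <- max(vapply(env, length, 1L))
  dw <- numeric(n)
  for (term in rule$terms) {
    val <- rep(term$sign * 2^term$scale_exponent * prod(term$constants), n)
    for (f in term$factors) val <- val * rep_len(env[[f]], n)
    dw <- dw + val
  }
  dw
}

#' Apply a learning rule to a plastic synapse spec
#'
#' The plastic weight update: evaluate `dw` from the traces, add it to the
#' mantissa, stochastically round the candidate to the weight-precision grid
#' (`2^ns`), clip to the sign-mode mantissa range, store, and re-encode the
#' effective weight through the codec.  Vectorized over the synapses in
#' `spec`; one uniform variate is drawn per synapse in pair order.
#'
#' @param spec A plastic [synapse_spec].
#' @param traces A list with per-pair entries `x0`, `x1`, `x2`, `y0`, `y1`,
#'   `y2`, `y3` (missing entries default to 0).
#' @param rule A [learning_rule].
#' @param rng An [rng_stream].
#' @return A list with the updated `spec` and the re-encoded effective
#'   weight `J`.
#' @export
apply_learning <- function(spec, traces, rule, rng) {
  stopifnot(inherits(spec, "synapse_spec"), inherits(rule, "learning_rule"))
  if (!spec$plastic) {
    stop("apply_learning: synapse spec is static (plastic = FALSE)",
         call. = FALSE)
  }
  g <- function(nm) if (is.null(traces[[nm]])) 0 else traces[[nm]]
  dw <- evaluate_learning_rule(rule,
                               x0 = g("x0"), x1 = g("x1"), x2 = g("x2"),
                               y0 = g("y0"), y1 = g("y1"), y2 = g("y2"),
                               y3 = g("y3"))
  ns <- precision_exponent(spec$n_wb, spec$sign_mode)
  candidate <- spec$mantissa + rep_len(dw, length(spec$mantissa))
  rounded <- stochastic_round(candidate, ns, rng)
  r <- mantissa_range(spec$sign_mode)
  clipped <- pmin(pmax(rounded, r[1]), r[2])
  # a clipped boundary value may sit off the precision grid; truncate back
  spec$mantissa <- truncate_to_precision(clipped, ns)
  list(spec = spec, J = encode_weight(spec))
}
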