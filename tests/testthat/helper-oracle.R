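# Independent scalar reference implementation of the static-network
# dynamics, written with plain per-unit / per-synapse loops and its own
# arithmetic.  Used to cross-check the vectorized engine: on a static
# network with explicit generator spikes the two must agree bit for bit.

# scalar round away from zero
.o_raz <- function(x) {
  if (x >= 0) ceiling(x) else -ceiling(-x)
}

# scalar weight codec (independent of encode_weight)
.o_encode <- function(mantissa, exponent, n_wb, sign_mode) {
  ns <- 8 - (n_wb - as.integer(sign_mode == "mixed"))
  m <- abs(mantissa)
  w_shifted <- sign(mantissa) * floor(m / 2^ns) * 2^ns
  shift <- 6 + exponent
  if (shift >= 0) {
    js <- w_shifted * 2^shift
  } else {
    js <- sign(w_shifted) * floor(abs(w_shifted) / 2^(-shift))
  }
  lim <- 2^21 - 1
  if (js > lim) js <- lim
  if (js < -lim) js <- -lim
  sign(js) * floor(abs(js) / 64) * 64
}

# desc: list(
#   pops  = list of list(name, size, decay_I, decay_v, threshold, bias,
#                        refractory),
#   gens  = list of list(name, size, spikes = data.frame(step, unit))
#           (explicit spikes, 0-based),
#   conns = list of list(source, source_kind, target, pre, post (1-based),
#                        mantissa, exponent, n_wb, sign_mode)
# )
# Returns list(spikes = data.frame(step, population, unit), state).
oracle_run <- function(desc, steps) {
  pops <- list()
  for (p in desc$pops) {
    pops[[p$name]] <- list(par = p,
                           I = rep(0, p$size), v = rep(0, p$size),
                           refr = rep(0, p$size),
                           spiked = rep(FALSE, p$size))
  }
  gens <- list()
  for (g in desc$gens) gens[[g$name]] <- g

  conns <- desc$conns
  for (k in seq_along(conns)) {
    cn <- conns[[k]]
    J <- numeric(length(cn$pre))
    for (s in seq_along(cn$pre)) {
      J[s] <- .o_encode(cn$mantissa[s], cn$exponent[s], cn$n_wb,
                        cn$sign_mode)
    }
    conns[[k]]$J <- J
  }

  out_step <- integer(0)
  out_pop <- character(0)
  out_unit <- integer(0)

  for (t in seq_len(steps) - 1L) {
    gen_spiked <- list()
    for (g in desc$gens) {
      fl <- rep(FALSE, g$size)
      hit <- g$spikes$unit[g$spikes$step == t]
      fl[hit + 1L] <- TRUE
      gen_spiked[[g$name]] <- fl
    }
    prev <- lapply(pops, function(p) p$spiked)

    weighted <- lapply(pops, function(p) rep(0, p$par$size))
    for (cn in conns) {
      src <- if (cn$source_kind == "generator") gen_spiked[[cn$source]]
             else prev[[cn$source]]
      for (s in seq_along(cn$pre)) {
        if (src[cn$pre[s]]) {
          weighted[[cn$target]][cn$post[s]] <-
            weighted[[cn$target]][cn$post[s]] + cn$J[s]
        }
      }
    }

    for (pn in names(pops)) {
      p <- pops[[pn]]
      par <- p$par
      for (i in seq_len(par$size)) {
        p$I[i] <- .o_raz(p$I[i] * (4096 - par$decay_I) / 4096) +
          weighted[[pn]][i]
        was_refr <- p$refr[i] > 0
        if (was_refr) {
          p$v[i] <- 0
          p$spiked[i] <- FALSE
          p$refr[i] <- p$refr[i] - 1
        } else {
          p$v[i] <- .o_raz(p$v[i] * (4096 - par$decay_v) / 4096) +
            p$I[i] + par$bias
          if (p$v[i] > par$threshold) {
            p$spiked[i] <- TRUE
            p$v[i] <- 0
            p$refr[i] <- par$refractory
          } else {
            p$spiked[i] <- FALSE
          }
        }
      }
      pops[[pn]] <- p
      hit <- which(p$spiked)
      if (length(hit)) {
        out_step <- c(out_step, rep.int(t, length(hit)))
        out_pop <- c(out_pop, rep.int(pn, length(hit)))
        out_unit <- c(out_unit, hit - 1L)
      }
    }
  }

  list(spikes = data.frame(step = out_step, population = out_pop,
                           unit = out_unit),
       state = lapply(pops, function(p) list(I = p$I, v = p$v)))
}

# Build a randomized static test network: one mixed-sign recurrent
# population plus an explicit-spike generator.  Returns both the engine
# configuration and the matching oracle description.
random_static_network <- function(seed, n_units = 50, n_gen = 5,
                                  steps = 1000) {
  set.seed(seed)
  n_pairs <- round(0.1 * n_units^2)
  pairs <- unique(data.frame(
    pre = sample.int(n_units, n_pairs, replace = TRUE) - 1L,
    post = sample.int(n_units, n_pairs, replace = TRUE) - 1L
  ))
  mantissa <- sample(seq(-256L, 254L, by = 2L), nrow(pairs), replace = TRUE)
  exponent <- sample(-2:2, nrow(pairs), replace = TRUE)

  n_gspk <- 8 * n_gen
  gspk <- data.frame(
    step = sample.int(steps, n_gspk, replace = TRUE) - 1L,
    unit = sample.int(n_gen, n_gspk, replace = TRUE) - 1L
  )
  gspk <- unique(gspk)
  g_pairs <- data.frame(pre = rep(seq_len(n_gen) - 1L, each = 4),
                        post = sample.int(n_units, 4 * n_gen,
                                          replace = TRUE) - 1L)
  g_pairs <- unique(g_pairs)

  config <- list(
    populations = list(
      list(name = "pop", size = n_units,
           neuron = list(decay_I = 512L, decay_v = 256L, threshold = 9000L,
                         bias = 100L, refractory = 2L))
    ),
    generators = list(
      list(name = "gen", size = n_gen, mode = "explicit",
           spikes = list(step = gspk$step, unit = gspk$unit))
    ),
    connections = list(
      list(name = "rec", source = "pop", target = "pop",
           connect = list(pairs = list(pre = pairs$pre, post = pairs$post)),
           weights = list(mantissa = mantissa, exponent = exponent,
                          n_wb = 8L, sign_mode = "mixed")),
      list(name = "drive", source = "gen", target = "pop",
           connect = list(pairs = list(pre = g_pairs$pre,
                                       post = g_pairs$post)),
           weights = list(mantissa = 200L, exponent = 1L, n_wb = 8L,
                          sign_mode = "excitatory"))
    ),
    monitors = list(list(type = "spikes", target = "pop"))
  )

  desc <- list(
    pops = list(list(name = "pop", size = n_units, decay_I = 512,
                     decay_v = 256, threshold = 9000, bias = 100,
                     refractory = 2)),
    gens = list(list(name = "gen", size = n_gen, spikes = gspk)),
    conns = list(
      list(source = "pop", source_kind = "population", target = "pop",
           pre = pairs$pre + 1L, post = pairs$post + 1L,
           mantissa = mantissa, exponent = exponent, n_wb = 8,
           sign_mode = "mixed"),
      list(source = "gen", source_kind = "generator", target = "pop",
           pre = g_pairs$pre + 1L, post = g_pairs$post + 1L,
           mantissa = rep(200, nrow(g_pairs)),
           exponent = rep(1, nrow(g_pairs)), n_wb = 8,
           sign_mode = "excitatory")
    )
  )

  list(config = config, desc = desc)
}

# order spike frames identically before comparison
sort_spikes <- function(sp) {
  sp <- sp[order(sp$step, sp$population, sp$unit), , drop = FALSE]
  rownames(sp) <- NULL
  sp
}
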