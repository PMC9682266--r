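#' Build a network from a validated configuration
#'
#' Constructs populations, spike generators and connection groups from a
#' configuration list (see [load_config] for the schema).  Construction is
#' deterministic given the configuration and the stream: probabilistic
#' connectivity and distribution-drawn mantissas consume variates from `rng`
#' in connection order (connectivity first, then mantissas, per group).
#'
#' @param config A configuration list (validated with [validate_config]
#'   if not already).
#' @param rng An [rng_stream] used for probabilistic connectivity and
#'   weight draws.
#' @return A list of class `loihi_network`.
#' @export
build_network <- function(config, rng = rng_stream(0)) {
  config <- validate_config(config)

  pops <- list()
  for (p in config$populations) {
    np <- neuron_params(p$neuron$decay_I, p$neuron$decay_v,
                        p$neuron$threshold, p$neuron$bias,
                        p$neuron$refractory)
    pops[[p$name]] <- list(name = p$name, size = as.integer(p$size),
                           params = np, state = neuron_state(p$size))
  }

  gens <- list()
  for (g in config$generators) {
    entry <- list(name = g$name, size = as.integer(g$size), mode = g$mode,
                  rate = if (g$mode == "poisson") g$rate else NULL,
                  spiked = logical(g$size))
    if (g$mode == "explicit") {
      # 0-based steps/units in config; keep a per-step lookup of 1-based units
      units <- as.integer(unlist(g$spikes$unit)) + 1L
      entry$spikes_by_step <- split(units, as.integer(unlist(g$spikes$step)))
    }
    gens[[g$name]] <- entry
  }

  conns <- list()
  for (cn in config$connections) {
    src_kind <- if (cn$source %in% names(gens)) "generator" else "population"
    src_size <- if (src_kind == "generator") gens[[cn$source]]$size
                else pops[[cn$source]]$size
    tgt_size <- pops[[cn$target]]$size

    if (!is.null(cn$connect$pairs)) {
      pre <- as.integer(unlist(cn$connect$pairs$pre)) + 1L
      post <- as.integer(unlist(cn$connect$pairs$post)) + 1L
    } else if (isTRUE(cn$connect$all_to_all)) {
      grid <- expand.grid(pre = seq_len(src_size), post = seq_len(tgt_size))
      pre <- grid$pre
      post <- grid$post
    } else {
      u <- rng_uniform(rng, src_size * tgt_size)
      keep <- which(u < cn$connect$probability)
      # column-major over (pre, post)
      pre <- ((keep - 1L) %% src_size) + 1L
      post <- ((keep - 1L) %/% src_size) + 1L
    }
    if (anyDuplicated(cbind(pre, post))) {
      stop(sprintf("connections['%s']: duplicate (pre, post) pairs", cn$name),
           call. = FALSE)
    }
    n_pairs <- length(pre)

    w <- cn$weights
    if (!is.null(w$lognormal)) {
      u <- rng_uniform(rng, n_pairs)
      mag <- floor(stats::qlnorm(u, w$lognormal$meanlog, w$lognormal$sdlog))
      r <- mantissa_range(w$sign_mode)
      if (w$sign_mode == "inhibitory") {
        mantissa <- pmax(-mag, r[1])
      } else {
        mantissa <- pmin(mag, r[2])
      }
    } else {
      mantissa <- rep_len(unlist(w$mantissa), n_pairs)
    }
    spec <- synapse_spec(mantissa, rep_len(unlist(w$exponent), n_pairs), w$n_wb,
                         w$sign_mode, plastic = isTRUE(cn$plastic))
    spec <- normalize_spec(spec)
    J <- encode_weight(spec)

    entry <- list(name = cn$name, source = cn$source,
                  source_kind = src_kind, target = cn$target,
                  pre = pre, post = post, spec = spec, J = J,
                  W = .conn_matrix(post, pre, J, tgt_size, src_size),
                  rule = NULL, tp = NULL, tstate = NULL)
    if (!is.null(cn$rule)) {
      entry$rule <- parse_learning_rule(cn$rule, cn$epoch_exponent)
      entry$tp <- do.call(trace_params, cn$traces)
      entry$tstate <- list(x1 = numeric(src_size), x2 = numeric(src_size),
                           y1 = numeric(tgt_size), y2 = numeric(tgt_size),
                           y3 = numeric(tgt_size),
                           x0 = numeric(src_size), y0 = numeric(tgt_size))
    }
    conns[[cn$name]] <- entry
  }

  structure(list(populations = pops, generators = gens, connections = conns,
                 config = config),
            class = "loihi_network")
}

.conn_matrix <- function(post, pre, J, n_tgt, n_src) {
  Matrix::sparseMatrix(i = post, j = pre, x = J, dims = c(n_tgt, n_src))
}

#' @export
print.loihi_network <- function(x, ...) {
  cat(sprintf("<loihi_network> %d population(s), %d generator(s), %d connection group(s)\n",
              length(x$populations), length(x$generators),
              length(x$connections)))
  for (p in x$populations) {
    cat(sprintf("  population %-12s %5d units (v_th=%g, decay_I=%g, decay_v=%g)\n",
                p$name, p$size, p$params$threshold, p$params$decay_I,
                p$params$decay_v))
  }
  for (g in x$generators) {
    cat(sprintf("  generator  %-12s %5d units (%s)\n", g$name, g$size, g$mode))
  }
  for (cn in x$connections) {
    cat(sprintf("  connection %-12s %s -> %s, %d synapse(s)%s\n", cn$name,
                cn$source, cn$target, length(cn$pre),
                if (!is.null(cn$rule)) ", plastic" else ""))
  }
  invisible(x)
}

#' Advance a network by one scheduler step
#'
#' Executes the per-step update schedule, in order:
#' \enumerate{
#'   \item spike generators emit spikes for step `t` (Poisson draws in
#'     generator order);
#'   \item per population, the synaptic input is updated with the weighted
#'     spikes delivered this step — generator spikes are delivered
#'     same-step, neuron spikes emitted at step `t-1` arrive now
#'     (one-step causal delay on recurrence);
#'   \item the voltage is updated (refractory units clamped to zero);
#'   \item thresholding, reset and refractory bookkeeping;
#'   \item synaptic traces are updated with this step's spikes;
#'   \item on learning epochs (`t mod 2^k == 0`) plastic groups apply their
#'     rule and dependency flags are reset.
#' }
#'
#' @param net A `loihi_network`.
#' @param t Step index (>= 0).
#' @param rng The simulation [rng_stream].
#' @return The updated network; `net$populations[[p]]$state$spiked` and
#'   `net$generators[[g]]$spiked` flag this step's spikes.
#' @export
step_network <- function(net, t, rng) {
  stopifnot(inherits(net, "loihi_network"), t >= 0)

  # (1) generators
  for (gn in names(net$generators)) {
    g <- net$generators[[gn]]
    if (g$mode == "poisson") {
      u <- rng_uniform(rng, g$size)
      g$spiked <- u < g$rate
    } else {
      g$spiked <- logical(g$size)
      hit <- g$spikes_by_step[[as.character(t)]]
      if (!is.null(hit)) g$spiked[hit] <- TRUE
    }
    net$generators[[gn]] <- g
  }

  # neuron spikes from the previous step, captured before any update
  prev_spiked <- lapply(net$populations, function(p) p$state$spiked)

  # (2)-(4) per-population dynamics
  weighted <- lapply(net$populations, function(p) numeric(p$size))
  for (cn in net$connections) {
    s <- if (cn$source_kind == "generator") {
      net$generators[[cn$source]]$spiked
    } else {
      prev_spiked[[cn$source]]
    }
    if (any(s)) {
      weighted[[cn$target]] <- weighted[[cn$target]] +
        as.numeric(cn$W %*% as.numeric(s))
    }
  }
  for (pn in names(net$populations)) {
    p <- net$populations[[pn]]
    st <- p$state
    st$I <- update_synaptic_input(st$I, p$params$decay_I, weighted[[pn]])
    st$v <- update_voltage(st$v, p$params$decay_v, st$I, p$params$bias,
                           st$refractory_remaining > 0)
    st <- threshold_and_reset(st, p$params)
    net$populations[[pn]]$state <- st
  }

  # (5) traces, with this step's spikes
  for (cni in seq_along(net$connections)) {
    cn <- net$connections[[cni]]
    if (is.null(cn$rule)) next
    s_pre <- if (cn$source_kind == "generator") {
      net$generators[[cn$source]]$spiked
    } else {
      net$populations[[cn$source]]$state$spiked
    }
    s_post <- net$populations[[cn$target]]$state$spiked
    ts <- cn$tstate
    tp <- cn$tp
    ts$x1 <- update_trace(ts$x1, tp$tau[["x1"]], s_pre, tp$impulse[["x1"]], rng)
    ts$x2 <- update_trace(ts$x2, tp$tau[["x2"]], s_pre, tp$impulse[["x2"]], rng)
    ts$y1 <- update_trace(ts$y1, tp$tau[["y1"]], s_post, tp$impulse[["y1"]], rng)
    ts$y2 <- update_trace(ts$y2, tp$tau[["y2"]], s_post, tp$impulse[["y2"]], rng)
    ts$y3 <- update_trace(ts$y3, tp$tau[["y3"]], s_post, tp$impulse[["y3"]], rng)
    ts$x0 <- pmax(ts$x0, as.numeric(s_pre))
    ts$y0 <- pmax(ts$y0, as.numeric(s_post))
    cn$tstate <- ts

    # (6) epoch-gated learning
    if (t %% 2^cn$rule$epoch_exponent == 0) {
      traces <- list(x0 = ts$x0[cn$pre], x1 = ts$x1[cn$pre],
                     x2 = ts$x2[cn$pre],
                     y0 = ts$y0[cn$post], y1 = ts$y1[cn$post],
                     y2 = ts$y2[cn$post], y3 = ts$y3[cn$post])
      upd <- apply_learning(cn$spec, traces, cn$rule, rng)
      cn$spec <- upd$spec
      cn$J <- upd$J
      cn$W <- .conn_matrix(cn$post, cn$pre, cn$J,
                           net$populations[[cn$target]]$size,
                           if (cn$source_kind == "generator")
                             net$generators[[cn$source]]$size
                           else net$populations[[cn$source]]$size)
      cn$tstate$x0 <- numeric(length(ts$x0))
      cn$tstate$y0 <- numeric(length(ts$y0))
    }
    net$connections[[cni]] <- cn
  }

  net
}
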