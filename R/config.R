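POP_VARS <- c("I", "v")
CONN_VARS <- c("x1", "x2", "y1", "y2", "y3", "mantissa", "J")

.cfg_stop <- function(path, msg) {
  stop(sprintf("%s: %s", path, msg), call. = FALSE)
}

.check_keys <- function(x, path, required, optional = character(0)) {
  if (!is.list(x)) .cfg_stop(path, "must be a mapping")
  keys <- names(x)
  unknown <- setdiff(keys, c(required, optional))
  if (length(unknown)) {
    .cfg_stop(paste0(path, ".", unknown[1]), "unknown key")
  }
  missing <- setdiff(required, keys)
  if (length(missing)) {
    .cfg_stop(paste0(path, ".", missing[1]), "required key is missing")
  }
  invisible(TRUE)
}

.check_int <- function(x, path, lo = -Inf, hi = Inf, len = 1L) {
  if (!is.numeric(x) || (!is.null(len) && length(x) != len) ||
      any(!is.finite(x)) || any(x != floor(x)) || any(x < lo) || any(x > hi)) {
    .cfg_stop(path, sprintf("must be integer in [%s, %s]",
                            format(lo), format(hi)))
  }
  invisible(TRUE)
}

#' Validate and normalize a network configuration
#'
#' Checks a configuration list against the schema (unknown keys are
#' rejected, every numeric hardware parameter must be an integer in its
#' legal range, and all cross-references between populations, generators,
#' connections and monitors must resolve) and fills in defaults.  The
#' normalized configuration, together with a seed, fully determines a
#' simulation.
#'
#' Schema (YAML): top-level keys `name` (optional), `populations`,
#' `generators`, `connections`, `monitors`.  Each population has `name`,
#' `size` and a `neuron` block (`decay_I`, `decay_v`, `threshold`,
#' optional `bias`, `refractory`).  Each generator has `name`, `size`,
#' `mode` (`"poisson"` with `rate`, the per-step spike probability, or
#' `"explicit"` with parallel `spikes: {step: [...], unit: [...]}` lists,
#' 0-based).  Each connection has `name`, `source` (population or
#' generator), `target` (population), a `connect` block (`pairs` with
#' 0-based `pre`/`post` lists, or `probability`, or `all_to_all`), a
#' `weights` block (`mantissa` scalar/vector or a `lognormal`
#' `{meanlog, sdlog}` draw; optional `exponent`, `n_wb`, `sign_mode`), and
#' optionally `plastic`, `rule`, `epoch_exponent` and a `traces` block
#' (`x1_impulse`, `x1_tau`, ... `y3_tau`).  Monitors are
#' `{type: spikes, target: POP}` or
#' `{type: state, target: POP-or-CONNECTION, variables: [...],
#' units/pairs: [...]}`.  If no monitors are given, spikes of every
#' population are recorded.
#'
#' @param config A configuration list.
#' @return The normalized configuration (defaults filled in).
#' @export
validate_config <- function(config) {
  .check_keys(config, "config", "populations",
              c("name", "generators", "connections", "monitors"))
  if (is.null(config$generators)) config$generators <- list()
  if (is.null(config$connections)) config$connections <- list()

  if (!is.list(config$populations) || !length(config$populations)) {
    .cfg_stop("config.populations", "must be a non-empty list")
  }

  pop_names <- character(0)
  pop_sizes <- integer(0)
  for (i in seq_along(config$populations)) {
    path <- sprintf("populations[%d]", i)
    p <- config$populations[[i]]
    .check_keys(p, path, c("name", "size", "neuron"))
    .check_int(p$size, paste0(path, ".size"), 1)
    n <- p$neuron
    npath <- paste0(path, ".neuron")
    .check_keys(n, npath, c("decay_I", "decay_v", "threshold"),
                c("bias", "refractory"))
    .check_int(n$decay_I, paste0(npath, ".decay_I"), 0, 4096)
    .check_int(n$decay_v, paste0(npath, ".decay_v"), 0, 4096)
    .check_int(n$threshold, paste0(npath, ".threshold"), 1)
    if (is.null(n$bias)) n$bias <- 0
    .check_int(n$bias, paste0(npath, ".bias"))
    if (is.null(n$refractory)) n$refractory <- 1
    .check_int(n$refractory, paste0(npath, ".refractory"), 1)
    p$neuron <- n
    config$populations[[i]] <- p
    pop_names <- c(pop_names, p$name)
    pop_sizes <- c(pop_sizes, as.integer(p$size))
  }
  names(pop_sizes) <- pop_names

  gen_names <- character(0)
  gen_sizes <- integer(0)
  for (i in seq_along(config$generators)) {
    path <- sprintf("generators[%d]", i)
    g <- config$generators[[i]]
    .check_keys(g, path, c("name", "size", "mode"), c("rate", "spikes"))
    .check_int(g$size, paste0(path, ".size"), 1)
    if (!is.character(g$mode) || !(g$mode %in% c("poisson", "explicit"))) {
      .cfg_stop(paste0(path, ".mode"), "must be 'poisson' or 'explicit'")
    }
    if (g$mode == "poisson") {
      if (!is.null(g$spikes)) {
        .cfg_stop(paste0(path, ".spikes"), "not allowed in poisson mode")
      }
      if (!is.numeric(g$rate) || length(g$rate) != 1L || g$rate < 0 ||
          g$rate > 1) {
        .cfg_stop(paste0(path, ".rate"), "must be a probability in [0, 1]")
      }
    } else {
      if (!is.null(g$rate)) {
        .cfg_stop(paste0(path, ".rate"), "not allowed in explicit mode")
      }
      .check_keys(g$spikes, paste0(path, ".spikes"), c("step", "unit"))
      if (length(g$spikes$step)) {
        .check_int(g$spikes$step, paste0(path, ".spikes.step"), 0, len = NULL)
        .check_int(g$spikes$unit, paste0(path, ".spikes.unit"), 0,
                   g$size - 1, len = NULL)
      }
      if (length(g$spikes$step) != length(g$spikes$unit)) {
        .cfg_stop(paste0(path, ".spikes"),
                  "step and unit must have equal length")
      }
    }
    config$generators[[i]] <- g
    gen_names <- c(gen_names, g$name)
    gen_sizes <- c(gen_sizes, as.integer(g$size))
  }
  names(gen_sizes) <- gen_names

  conn_names <- character(0)
  all_names <- c(pop_names, gen_names)
  if (anyDuplicated(all_names)) {
    .cfg_stop("config", sprintf("duplicate object name '%s'",
                                all_names[duplicated(all_names)][1]))
  }

  for (i in seq_along(config$connections)) {
    path <- sprintf("connections[%d]", i)
    cn <- config$connections[[i]]
    .check_keys(cn, path, c("name", "source", "target", "connect", "weights"),
                c("plastic", "rule", "epoch_exponent", "traces"))
    if (!(cn$source %in% c(pop_names, gen_names))) {
      .cfg_stop(paste0(path, ".source"),
                sprintf("unknown population/generator '%s'", cn$source))
    }
    if (!(cn$target %in% pop_names)) {
      .cfg_stop(paste0(path, ".target"),
                sprintf("unknown population '%s'", cn$target))
    }
    src_size <- if (cn$source %in% gen_names) gen_sizes[[cn$source]]
                else pop_sizes[[cn$source]]
    tgt_size <- pop_sizes[[cn$target]]

    cpath <- paste0(path, ".connect")
    .check_keys(cn$connect, cpath, character(0),
                c("pairs", "probability", "all_to_all"))
    ways <- sum(!is.null(cn$connect$pairs), !is.null(cn$connect$probability),
                !is.null(cn$connect$all_to_all))
    if (ways != 1L) {
      .cfg_stop(cpath,
                "exactly one of pairs, probability, all_to_all is required")
    }
    if (!is.null(cn$connect$pairs)) {
      .check_keys(cn$connect$pairs, paste0(cpath, ".pairs"), c("pre", "post"))
      .check_int(cn$connect$pairs$pre, paste0(cpath, ".pairs.pre"), 0,
                 src_size - 1, len = NULL)
      .check_int(cn$connect$pairs$post, paste0(cpath, ".pairs.post"), 0,
                 tgt_size - 1, len = NULL)
      if (length(cn$connect$pairs$pre) != length(cn$connect$pairs$post)) {
        .cfg_stop(paste0(cpath, ".pairs"),
                  "pre and post must have equal length")
      }
    } else if (!is.null(cn$connect$probability)) {
      pr <- cn$connect$probability
      if (!is.numeric(pr) || length(pr) != 1L || pr < 0 || pr > 1) {
        .cfg_stop(paste0(cpath, ".probability"), "must be in [0, 1]")
      }
    }

    wpath <- paste0(path, ".weights")
    w <- cn$weights
    .check_keys(w, wpath, character(0),
                c("mantissa", "lognormal", "exponent", "n_wb", "sign_mode"))
    if (is.null(w$sign_mode)) w$sign_mode <- "excitatory"
    if (!(w$sign_mode %in% SIGN_MODES)) {
      .cfg_stop(paste0(wpath, ".sign_mode"),
                "must be excitatory, inhibitory or mixed")
    }
    if (is.null(w$n_wb)) w$n_wb <- 8
    .check_int(w$n_wb, paste0(wpath, ".n_wb"), 1, 8)
    if (is.null(w$exponent)) w$exponent <- 0
    .check_int(w$exponent, paste0(wpath, ".exponent"), -8, 7, len = NULL)
    if (sum(!is.null(w$mantissa), !is.null(w$lognormal)) != 1L) {
      .cfg_stop(wpath, "exactly one of mantissa, lognormal is required")
    }
    if (!is.null(w$mantissa)) {
      r <- mantissa_range(w$sign_mode)
      .check_int(w$mantissa, paste0(wpath, ".mantissa"), r[1], r[2],
                 len = NULL)
    } else {
      .check_keys(w$lognormal, paste0(wpath, ".lognormal"),
                  c("meanlog", "sdlog"))
      if (!is.numeric(w$lognormal$meanlog) ||
          !is.numeric(w$lognormal$sdlog) || w$lognormal$sdlog < 0) {
        .cfg_stop(paste0(wpath, ".lognormal"),
                  "meanlog must be numeric, sdlog non-negative")
      }
    }
    cn$weights <- w

    if (is.null(cn$plastic)) cn$plastic <- FALSE
    if (!is.logical(cn$plastic)) {
      .cfg_stop(paste0(path, ".plastic"), "must be logical")
    }
    if (cn$plastic && is.null(cn$rule)) {
      .cfg_stop(paste0(path, ".rule"),
                "a plastic connection requires a learning rule")
    }
    if (!cn$plastic && !is.null(cn$rule)) {
      .cfg_stop(paste0(path, ".rule"),
                "a learning rule requires plastic: true")
    }
    if (is.null(cn$epoch_exponent)) cn$epoch_exponent <- 0
    .check_int(cn$epoch_exponent, paste0(path, ".epoch_exponent"), 0)
    if (!is.null(cn$rule)) {
      parse_learning_rule(cn$rule, cn$epoch_exponent)  # syntax check
      if (is.null(cn$traces)) cn$traces <- list()
      .check_keys(cn$traces, paste0(path, ".traces"), character(0),
                  as.vector(outer(TRACE_NAMES, c("_impulse", "_tau"),
                                  paste0)))
      do.call(trace_params, cn$traces)  # range check
    } else if (!is.null(cn$traces)) {
      .cfg_stop(paste0(path, ".traces"),
                "trace parameters require a learning rule")
    }
    config$connections[[i]] <- cn
    conn_names <- c(conn_names, cn$name)
  }
  if (anyDuplicated(c(all_names, conn_names))) {
    .cfg_stop("config.connections", "duplicate object name")
  }

  if (is.null(config$monitors)) {
    config$monitors <- lapply(pop_names, function(pn) {
      list(type = "spikes", target = pn)
    })
  }
  for (i in seq_along(config$monitors)) {
    path <- sprintf("monitors[%d]", i)
    m <- config$monitors[[i]]
    .check_keys(m, path, c("type", "target"),
                c("variables", "units", "pairs"))
    if (!(m$type %in% c("spikes", "state"))) {
      .cfg_stop(paste0(path, ".type"), "must be 'spikes' or 'state'")
    }
    if (m$type == "spikes") {
      if (!(m$target %in% pop_names)) {
        .cfg_stop(paste0(path, ".target"),
                  sprintf("unknown population '%s'", m$target))
      }
      if (!is.null(m$variables) || !is.null(m$units) || !is.null(m$pairs)) {
        .cfg_stop(path, "spikes monitors take no variables/units/pairs")
      }
    } else {
      if (!is.null(m$variables)) {
        m$variables <- as.character(unlist(m$variables))
      }
      if (m$target %in% pop_names) {
        if (is.null(m$variables)) m$variables <- POP_VARS
        if (!all(m$variables %in% POP_VARS)) {
          .cfg_stop(paste0(path, ".variables"),
                    "population variables are I, v")
        }
        if (is.null(m$units)) m$units <- seq_len(pop_sizes[[m$target]]) - 1L
        .check_int(m$units, paste0(path, ".units"), 0,
                   pop_sizes[[m$target]] - 1, len = NULL)
        if (!is.null(m$pairs)) {
          .cfg_stop(paste0(path, ".pairs"),
                    "population monitors use units, not pairs")
        }
      } else if (m$target %in% conn_names) {
        ci <- which(conn_names == m$target)
        if (is.null(config$connections[[ci]]$rule)) {
          allowed <- c("mantissa", "J")
        } else {
          allowed <- CONN_VARS
        }
        if (is.null(m$variables)) m$variables <- c("mantissa", "J")
        if (!all(m$variables %in% allowed)) {
          .cfg_stop(paste0(path, ".variables"),
                    paste("connection variables are",
                          paste(allowed, collapse = ", ")))
        }
        if (is.null(m$pairs)) m$pairs <- 0L
        .check_int(m$pairs, paste0(path, ".pairs"), 0, len = NULL)
        if (!is.null(m$units)) {
          .cfg_stop(paste0(path, ".units"),
                    "connection monitors use pairs, not units")
        }
      } else {
        .cfg_stop(paste0(path, ".target"),
                  sprintf("unknown population/connection '%s'", m$target))
      }
    }
    config$monitors[[i]] <- m
  }

  config
}

#' Load a YAML network configuration
#'
#' Reads, validates and normalizes a configuration file.  Unknown keys are
#' rejected so that misspelled hardware parameters cannot be silently
#' ignored.
#'
#' @param path Path to a YAML file.
#' @return A validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  validate_config(yaml::read_yaml(path))
}

#' Write a network configuration as YAML
#'
#' The configuration is validated and normalized first, so
#' `load_config(write_config(cfg, path))` reproduces the normalized
#' configuration exactly.
#'
#' @param config A configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  config <- validate_config(config)
  yaml::write_yaml(config, path)
  invisible(path)
}
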