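#' Run a simulation
#'
#' Builds the network from `config` and advances it for `steps` scheduler
#' steps, recording spikes and state samples as requested by the
#' configuration's monitors.  The run is fully deterministic given
#' `(config, steps, seed)`: a single [rng_stream] seeded with `seed` drives
#' network construction and every stochastic element of the simulation in a
#' fixed draw order.
#'
#' @param config A configuration list (see [load_config]) or a path to a
#'   YAML configuration file.
#' @param steps Number of steps to simulate (>= 1); steps are indexed
#'   `0 .. steps-1`.
#' @param seed Integer seed.
#' @return A `loihi_recording`: a list with `spikes` (data.frame `step`,
#'   `population`, `unit`; unit indices 0-based), `samples` (data.frame
#'   `step`, `target`, `index`, `variable`, `value`), the final `network`,
#'   and metadata (`steps`, `seed`, `n_draws`).
#' @examples
#' cfg <- make_fixture("stdp")
#' rec <- run_network(cfg, steps = 200, seed = 7)
#' rec
#' @export
run_network <- function(config, steps, seed = 1) {
  if (is.character(config)) config <- load_config(config)
  config <- validate_config(config)
  if (!is.numeric(steps) || length(steps) != 1L || steps < 1 ||
      steps != floor(steps)) {
    stop("steps: must be a positive integer", call. = FALSE)
  }
  steps <- as.integer(steps)
  rng <- rng_stream(seed)
  net <- build_network(config, rng)

  spike_targets <- character(0)
  state_mons <- list()
  for (m in config$monitors) {
    if (m$type == "spikes") {
      spike_targets <- c(spike_targets, m$target)
    } else {
      sel <- as.integer(unlist(if (!is.null(m$units)) m$units else m$pairs))
      kind <- if (m$target %in% names(net$connections)) "connection"
              else "population"
      vars <- as.character(unlist(m$variables))
      store <- lapply(vars, function(v)
        matrix(NA_real_, nrow = steps, ncol = length(sel)))
      names(store) <- vars
      state_mons[[length(state_mons) + 1L]] <-
        list(target = m$target, kind = kind, sel = sel, store = store)
    }
  }

  spike_steps <- stats::setNames(vector("list", length(spike_targets)),
                                 spike_targets)
  spike_units <- spike_steps

  for (t in seq_len(steps) - 1L) {
    net <- step_network(net, t, rng)

    for (pn in spike_targets) {
      hit <- which(net$populations[[pn]]$state$spiked)
      if (length(hit)) {
        spike_steps[[pn]][[length(spike_steps[[pn]]) + 1L]] <-
          rep.int(t, length(hit))
        spike_units[[pn]][[length(spike_units[[pn]]) + 1L]] <- hit - 1L
      }
    }
    for (mi in seq_along(state_mons)) {
      m <- state_mons[[mi]]
      row <- t + 1L
      if (m$kind == "population") {
        st <- net$populations[[m$target]]$state
        for (v in names(m$store)) {
          state_mons[[mi]]$store[[v]][row, ] <- st[[v]][m$sel + 1L]
        }
      } else {
        cn <- net$connections[[m$target]]
        for (v in names(m$store)) {
          vals <- switch(v,
            mantissa = cn$spec$mantissa[m$sel + 1L],
            J        = cn$J[m$sel + 1L],
            x1 = cn$tstate$x1[cn$pre[m$sel + 1L]],
            x2 = cn$tstate$x2[cn$pre[m$sel + 1L]],
            y1 = cn$tstate$y1[cn$post[m$sel + 1L]],
            y2 = cn$tstate$y2[cn$post[m$sel + 1L]],
            y3 = cn$tstate$y3[cn$post[m$sel + 1L]])
          state_mons[[mi]]$store[[v]][row, ] <- vals
        }
      }
    }
  }

  spikes <- do.call(rbind, lapply(spike_targets, function(pn) {
    data.frame(step = unlist(spike_steps[[pn]], use.names = FALSE),
               population = rep.int(pn, length(unlist(spike_units[[pn]]))),
               unit = unlist(spike_units[[pn]], use.names = FALSE))
  }))
  if (is.null(spikes)) {
    spikes <- data.frame(step = integer(0), population = character(0),
                         unit = integer(0))
  }

  samples <- do.call(rbind, lapply(state_mons, function(m) {
    do.call(rbind, lapply(names(m$store), function(v) {
      data.frame(step = rep(seq_len(steps) - 1L, times = length(m$sel)),
                 target = m$target,
                 index = rep(m$sel, each = steps),
                 variable = v,
                 value = as.vector(m$store[[v]]))
    }))
  }))
  if (is.null(samples)) {
    samples <- data.frame(step = integer(0), target = character(0),
                          index = integer(0), variable = character(0),
                          value = numeric(0))
  }

  structure(list(spikes = spikes, samples = samples, network = net,
                 steps = steps, seed = as.integer(seed),
                 n_draws = rng$n_drawn),
            class = "loihi_recording")
}

#' @export
print.loihi_recording <- function(x, ...) {
  cat(sprintf("<loihi_recording> %d steps, seed %d, %d spikes, %d samples, %d RNG draws\n",
              x$steps, x$seed, nrow(x$spikes), nrow(x$samples), x$n_draws))
  if (nrow(x$spikes)) {
    counts <- table(x$spikes$population)
    for (pn in names(counts)) {
      cat(sprintf("  %s: %d spikes\n", pn, counts[[pn]]))
    }
  }
  invisible(x)
}

#' Write a recording to CSV files
#'
#' Writes `spikes.csv` (columns step, population, unit) and `samples.csv`
#' (columns step, target, index, variable, value) into `dir`.
#'
#' @param rec A `loihi_recording`.
#' @param dir Output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "loihi_recording"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(rec$spikes, file.path(dir, "spikes.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(rec$samples, file.path(dir, "samples.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
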