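#' Built-in fixture networks
#'
#' Returns a complete, validated configuration for one of three reference
#' experiments:
#'
#' \describe{
#'   \item{`"single-neuron"`}{One unit receiving randomly timed excitatory
#'     and inhibitory generator spikes (20 excitatory and 10 inhibitory
#'     spikes over the first 100 steps, timed from `seed`), with synaptic
#'     input and voltage monitored.}
#'   \item{`"chaotic-net"`}{A recurrent network of 400 excitatory and 100
#'     inhibitory units, driven by 40 Poisson spike generators connected
#'     with probability 0.05, with log-normally distributed excitatory
#'     mantissas; the classic chaotic balanced-network regime.}
#'   \item{`"stdp"`}{A single post-synaptic unit with one plastic synapse
#'     from an `input` generator (mantissa 128, exponent -6, so its
#'     effective weight 128 barely moves the unit) and one strong static
#'     synapse from a `noise` generator (mantissa 254, exponent 0) that
#'     reliably drives post-synaptic spikes.  The plastic synapse learns
#'     under the asymmetric STDP rule `2^-2*x1*y0 - 2^-2*x0*y1` with trace
#'     impulses 120 and decay constants 8 for x1 and y1.}
#' }
#'
#' @param name Fixture name: `"single-neuron"`, `"chaotic-net"` or
#'   `"stdp"`.
#' @param seed Integer seed used only for the single-neuron fixture's
#'   explicit input spike times (the other fixtures are fully declarative;
#'   their randomness is resolved at build time from the simulation seed).
#' @return A validated configuration list, usable with [run_network] or
#'   [write_config].
#' @examples
#' cfg <- make_fixture("stdp")
#' cfg$connections[[1]]$weights$mantissa  # 128
#' @export
make_fixture <- function(name = c("single-neuron", "chaotic-net", "stdp"),
                         seed = 1) {
  if (!is.character(name) || length(name) != 1L ||
      !(name %in% c("single-neuron", "chaotic-net", "stdp"))) {
    stop("unknown fixture; valid names: single-neuron, chaotic-net, stdp",
         call. = FALSE)
  }
  cfg <- switch(name,
    "single-neuron" = .fixture_single_neuron(seed),
    "chaotic-net"   = .fixture_chaotic_net(),
    "stdp"          = .fixture_stdp()
  )
  validate_config(cfg)
}

.fixture_single_neuron <- function(seed) {
  rng <- rng_stream(seed)
  exc_steps <- sort(order(rng_uniform(rng, 100))[1:20]) - 1L
  inh_steps <- sort(order(rng_uniform(rng, 100))[1:10]) - 1L
  list(
    name = "single-neuron",
    populations = list(
      list(name = "cell", size = 1L,
           neuron = list(decay_I = 512L, decay_v = 256L, threshold = 12000L,
                         bias = 0L, refractory = 2L))
    ),
    generators = list(
      list(name = "exc_in", size = 1L, mode = "explicit",
           spikes = list(step = exc_steps,
                         unit = rep(0L, length(exc_steps)))),
      list(name = "inh_in", size = 1L, mode = "explicit",
           spikes = list(step = inh_steps,
                         unit = rep(0L, length(inh_steps))))
    ),
    connections = list(
      list(name = "exc_syn", source = "exc_in", target = "cell",
           connect = list(pairs = list(pre = 0L, post = 0L)),
           weights = list(mantissa = 64L, exponent = 0L, n_wb = 8L,
                          sign_mode = "excitatory")),
      list(name = "inh_syn", source = "inh_in", target = "cell",
           connect = list(pairs = list(pre = 0L, post = 0L)),
           weights = list(mantissa = -64L, exponent = 0L, n_wb = 8L,
                          sign_mode = "inhibitory"))
    ),
    monitors = list(
      list(type = "spikes", target = "cell"),
      list(type = "state", target = "cell", variables = c("I", "v"),
           units = 0L)
    )
  )
}

.fixture_chaotic_net <- function() {
  neuron <- list(decay_I = 512L, decay_v = 256L, threshold = 30000L,
                 bias = 0L, refractory = 2L)
  exc_w <- list(lognormal = list(meanlog = 3.0, sdlog = 0.5),
                exponent = 0L, n_wb = 8L, sign_mode = "excitatory")
  inh_w <- list(lognormal = list(meanlog = 4.8, sdlog = 0.5),
                exponent = 0L, n_wb = 8L, sign_mode = "inhibitory")
  conn <- function(name, source, target, p, w) {
    list(name = name, source = source, target = target,
         connect = list(probability = p), weights = w)
  }
  gen_w <- list(mantissa = 64L, exponent = 0L, n_wb = 8L,
                sign_mode = "excitatory")
  list(
    name = "chaotic-net",
    populations = list(
      list(name = "inh", size = 100L, neuron = neuron),
      list(name = "exc", size = 400L, neuron = neuron)
    ),
    generators = list(
      list(name = "noise", size = 40L, mode = "poisson", rate = 0.1)
    ),
    connections = list(
      conn("noise_exc", "noise", "exc", 0.05, gen_w),
      conn("noise_inh", "noise", "inh", 0.05, gen_w),
      conn("e2e", "exc", "exc", 0.1, exc_w),
      conn("e2i", "exc", "inh", 0.1, exc_w),
      conn("i2e", "inh", "exc", 0.1, inh_w),
      conn("i2i", "inh", "inh", 0.1, inh_w)
    ),
    monitors = list(
      list(type = "spikes", target = "exc"),
      list(type = "spikes", target = "inh")
    )
  )
}

.fixture_stdp <- function() {
  list(
    name = "stdp",
    populations = list(
      list(name = "post", size = 1L,
           neuron = list(decay_I = 512L, decay_v = 256L, threshold = 10000L,
                         bias = 0L, refractory = 1L))
    ),
    generators = list(
      list(name = "input", size = 1L, mode = "poisson", rate = 0.05),
      list(name = "noise", size = 1L, mode = "poisson", rate = 0.05)
    ),
    connections = list(
      list(name = "plastic_syn", source = "input", target = "post",
           connect = list(pairs = list(pre = 0L, post = 0L)),
           weights = list(mantissa = 128L, exponent = -6L, n_wb = 8L,
                          sign_mode = "excitatory"),
           plastic = TRUE,
           rule = "2^-2*x1*y0 - 2^-2*x0*y1",
           epoch_exponent = 0L,
           traces = list(x1_impulse = 120L, x1_tau = 8L,
                         y1_impulse = 120L, y1_tau = 8L)),
      list(name = "noise_syn", source = "noise", target = "post",
           connect = list(pairs = list(pre = 0L, post = 0L)),
           weights = list(mantissa = 254L, exponent = 0L, n_wb = 8L,
                          sign_mode = "excitatory"))
    ),
    monitors = list(
      list(type = "spikes", target = "post"),
      list(type = "state", target = "plastic_syn",
           variables = c("mantissa", "J", "x1", "y1"), pairs = 0L)
    )
  )
}
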