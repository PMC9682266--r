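minimal_config <- function(...) {
  upd <- list(...)
  cfg <- list(
    populations = list(
      list(name = "pop", size = 2L,
           neuron = list(decay_I = 512L, decay_v = 256L, threshold = 100L))
    ),
    generators = list(
      list(name = "gen", size = 1L, mode = "explicit",
           spikes = list(step = 0L, unit = 0L))
    ),
    connections = list(
      list(name = "drive", source = "gen", target = "pop",
           connect = list(pairs = list(pre = 0L, post = 0L)),
           weights = list(mantissa = 64L, exponent = 0L))
    )
  )
  cfg[names(upd)] <- upd  # replace whole sections (modifyList would merge)
  cfg
}

test_that("network construction validates parameter ranges", {
  bad <- minimal_config()
  bad$populations[[1]]$neuron$decay_I <- 5000L
  expect_error(build_network(bad), "decay_I.*\\[0, 4096\\]")

  bad <- minimal_config()
  bad$connections[[1]]$weights$mantissa <- 300L
  expect_error(build_network(bad), "mantissa")

  bad <- minimal_config()
  bad$connections[[1]]$source <- "nope"
  expect_error(build_network(bad), "unknown population/generator 'nope'")

  # empty connection list: a valid network of isolated units
  cfg <- minimal_config(connections = list(), generators = list())
  net <- build_network(cfg)
  expect_s3_class(net, "loihi_network")
  expect_length(net$connections, 0)
})

test_that("a generator spike is delivered in the same step (I[0] = J)", {
  cfg <- minimal_config()
  rec <- run_network(minimal_config(monitors = list(
    list(type = "state", target = "pop", variables = "I", units = c(0L, 1L))
  )), steps = 3, seed = 1)
  J <- encode_weight(synapse_spec(64, 0))  # 4096
  I0 <- subset(rec$samples, step == 0 & index == 0)$value
  expect_equal(I0, J)
  # the unconnected unit stays silent
  expect_true(all(subset(rec$samples, index == 1)$value == 0))
})

test_that("neuron-to-neuron spikes arrive with a one-step delay", {
  # gen -> unit 0 -> unit 1 chain; strong weights force immediate spikes
  cfg <- list(
    populations = list(
      list(name = "pop", size = 2L,
           neuron = list(decay_I = 4096L, decay_v = 4096L,
                         threshold = 100L))
    ),
    generators = list(
      list(name = "gen", size = 1L, mode = "explicit",
           spikes = list(step = 2L, unit = 0L))
    ),
    connections = list(
      list(name = "drive", source = "gen", target = "pop",
           connect = list(pairs = list(pre = 0L, post = 0L)),
           weights = list(mantissa = 255L, exponent = 0L)),
      list(name = "chain", source = "pop", target = "pop",
           connect = list(pairs = list(pre = 0L, post = 1L)),
           weights = list(mantissa = 255L, exponent = 0L))
    ),
    monitors = list(list(type = "spikes", target = "pop"))
  )
  rec <- run_network(cfg, steps = 6, seed = 1)
  sp <- rec$spikes
  # hand-stepped: generator spike at t=2 -> unit 0 fires at t=2 (full-decay
  # params make I = J = 16320 > threshold immediately), unit 1 at t=3
  expect_equal(sp$step[sp$unit == 0], 2)
  expect_equal(sp$step[sp$unit == 1], 3)
})

test_that("a zero-input network records nothing but zeros", {
  cfg <- minimal_config(generators = list(), connections = list(),
                        monitors = list(
                          list(type = "spikes", target = "pop"),
                          list(type = "state", target = "pop")
                        ))
  rec <- run_network(cfg, steps = 10, seed = 1)
  expect_equal(nrow(rec$spikes), 0)
  expect_true(all(rec$samples$value == 0))
  # sample streams: steps x units x variables
  expect_equal(nrow(rec$samples), 10 * 2 * 2)
})

test_that("identical (config, steps, seed) gives bit-identical recordings", {
  cfg <- make_fixture("stdp")
  a <- run_network(cfg, steps = 300, seed = 9)
  b <- run_network(cfg, steps = 300, seed = 9)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$samples, b$samples)
  expect_identical(a$n_draws, b$n_draws)
  c <- run_network(cfg, steps = 300, seed = 10)
  expect_false(identical(a$samples, c$samples))
})

test_that("monitor record counts match threshold crossings and steps", {
  cfg <- make_fixture("single-neuron")
  steps <- 150
  rec <- run_network(cfg, steps, seed = 2)
  expect_true(all(diff(order(rec$spikes$step)) > 0) ||
                !is.unsorted(rec$spikes$step))
  for (v in c("I", "v")) {
    expect_equal(sum(rec$samples$variable == v), steps)
  }
  # voltage is clamped to zero through the refractory window after a spike
  v_tr <- subset(rec$samples, variable == "v")
  v_tr <- v_tr[order(v_tr$step), ]
  for (s in rec$spikes$step) {
    blocked <- v_tr$value[v_tr$step %in% (s + 1:2)]
    expect_true(all(blocked == 0))
  }
})

test_that("poisson generators hit their configured rate", {
  cfg <- list(
    populations = list(
      list(name = "pop", size = 1L,
           neuron = list(decay_I = 512L, decay_v = 256L,
                         threshold = 1000000L))
    ),
    generators = list(
      list(name = "g", size = 20L, mode = "poisson", rate = 0.08)
    ),
    connections = list(
      list(name = "c", source = "g", target = "pop",
           connect = list(all_to_all = TRUE),
           weights = list(mantissa = 1L, exponent = 0L))
    ),
    monitors = list(
      list(type = "state", target = "pop", variables = "I", units = 0L)
    )
  )
  # infer generator spike counts from the rng draw budget is indirect;
  # instead count delivered spikes via the synaptic input jumps
  steps <- 2000
  rec <- run_network(cfg, steps, seed = 31)
  J <- encode_weight(synapse_spec(1, 0))  # 64
  I <- subset(rec$samples, variable == "I")$value
  decayed <- c(0, round_away_from_zero(I[-steps] * (4096 - 512) / 4096))
  n_spikes <- sum(I - decayed) / J
  n_trials <- 20 * steps
  p <- 0.08
  expect_lt(abs(n_spikes / n_trials - p), 4 * sqrt(p * (1 - p) / n_trials))
})

test_that("vectorized engine matches the scalar oracle exactly", {
  for (seed in c(101, 202)) {
    nw <- random_static_network(seed, n_units = 30, steps = 400)
    rec <- run_network(nw$config, steps = 400, seed = seed)
    ora <- oracle_run(nw$desc, steps = 400)
    expect_gt(nrow(ora$spikes), 0)
    expect_identical(sort_spikes(rec$spikes)[c("step", "unit")],
                     sort_spikes(ora$spikes)[c("step", "unit")])
    st <- rec$network$populations$pop$state
    expect_identical(st$I, ora$state$pop$I)
    expect_identical(st$v, ora$state$pop$v)
  }
})

test_that("fixture configs build at the documented scale", {
  cfg <- make_fixture("chaotic-net")
  net <- build_network(cfg, rng_stream(1))
  expect_equal(net$populations$exc$size, 400L)
  expect_equal(net$populations$inh$size, 100L)
  expect_equal(net$generators$noise$size, 40L)
  # generator fan-out matches p = 0.05 within binomial bounds
  n_gen_syn <- length(net$connections$noise_exc$pre) +
    length(net$connections$noise_inh$pre)
  n_trials <- 40 * 500
  expect_lt(abs(n_gen_syn / n_trials - 0.05),
            4 * sqrt(0.05 * 0.95 / n_trials))
  # inhibitory groups encode non-positive weights, excitatory non-negative
  expect_true(all(net$connections$i2e$J <= 0))
  expect_true(all(net$connections$e2e$J >= 0))
  expect_error(make_fixture("nope"), "single-neuron, chaotic-net, stdp")
})

test_that("recordings write to CSV", {
  rec <- run_network(make_fixture("single-neuron"), 50, seed = 1)
  dir <- withr::local_tempdir()
  write_recording(rec, dir)
  sp <- read.csv(file.path(dir, "spikes.csv"))
  sa <- read.csv(file.path(dir, "samples.csv"))
  expect_equal(nrow(sp), nrow(rec$spikes))
  expect_equal(nrow(sa), nrow(rec$samples))
})
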