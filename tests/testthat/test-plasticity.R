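test_that("trace updates decay, jump on spikes and clamp at 127", {
  r <- rng_stream(1)
  expect_equal(update_trace(0, 8, TRUE, 120, r), 120)
  # 0.875 * 120 = 105 exactly, + 120 clamps at the ceiling
  expect_equal(update_trace(120, 8, TRUE, 120, r), 127)
  expect_error(update_trace(10, 0, FALSE, 0, r), "tau")
  expect_error(update_trace(130, 8, FALSE, 0, r), "\\[0, 127\\]")

  # 100 * 7/8 = 87.5: both bracketing integers occur, at equal frequency
  draws <- vapply(1:2000, function(i) update_trace(100, 8, FALSE, 0, r),
                  numeric(1))
  expect_true(all(draws %in% c(87, 88)))
  p_up <- mean(draws == 88)
  expect_lt(abs(p_up - 0.5), 4 * sqrt(0.25 / 2000))
})

test_that("traces stay in [0, 127] and absorb at 0 without spikes", {
  r <- rng_stream(42)
  for (tau in c(2, 8, 20)) {
    x <- 127
    zeros <- 0
    for (t in 1:600) {
      x_next <- update_trace(x, tau, FALSE, 0, r)
      expect_true(x_next >= 0 && x_next <= 127)
      expect_lte(x_next, x)  # no spikes: non-increasing
      x <- x_next
      if (x == 0) {
        zeros <- zeros + 1
        break
      }
    }
    expect_equal(x, 0)  # unbiased rounding lets the trace reach 0
  }
})

test_that("mean trace decay matches (1 - 1/tau)^t", {
  # Monte-Carlo mean over 400 trials within 3 sigma of the exponential
  tau <- 8
  n_trials <- 400
  n_steps <- 30
  x0 <- 120
  traj <- matrix(0, n_trials, n_steps)
  r <- rng_stream(7)
  for (k in seq_len(n_trials)) {
    x <- x0
    for (t in seq_len(n_steps)) {
      x <- update_trace(x, tau, FALSE, 0, r)
      traj[k, t] <- x
    }
  }
  expected <- x0 * (1 - 1 / tau)^seq_len(n_steps)
  emp_mean <- colMeans(traj)
  emp_se <- apply(traj, 2, stats::sd) / sqrt(n_trials)
  # rounding noise makes sd = 0 impossible except at exact-integer products
  expect_true(all(abs(emp_mean - expected) <= 3 * pmax(emp_se, 0.05)))
})

test_that("the rule parser handles the canonical STDP expression", {
  rule <- parse_learning_rule("2^-2*x1*y0 - 2^-2*x0*y1")
  expect_length(rule$terms, 2)
  expect_equal(rule$terms[[1]]$sign, 1)
  expect_equal(rule$terms[[1]]$scale_exponent, -2)
  expect_equal(rule$terms[[1]]$factors, c("x1", "y0"))
  expect_equal(rule$terms[[2]]$sign, -1)
  expect_equal(rule$terms[[2]]$scale_exponent, -2)
  expect_equal(rule$terms[[2]]$factors, c("x0", "y1"))

  plain <- parse_learning_rule("x1*y0 - y1*x0")
  expect_length(plain$terms, 2)
  expect_equal(plain$terms[[1]]$scale_exponent, 0)
  expect_equal(plain$terms[[2]]$factors, c("y1", "x0"))

  multi <- parse_learning_rule("3*x2*y3 + 2^1*y2 - 7")
  expect_equal(multi$terms[[1]]$constants, 3)
  expect_equal(multi$terms[[2]]$scale_exponent, 1)
  expect_equal(multi$terms[[3]]$sign, -1)
  expect_equal(multi$terms[[3]]$constants, 7)
})

test_that("the rule grammar rejects unsupported constructs", {
  expect_error(parse_learning_rule("x1/y0"), "unsupported token")
  expect_error(parse_learning_rule("x1*z0"), "unsupported token|unknown")
  expect_error(parse_learning_rule("x9*y0"), "unknown variable")
  expect_error(parse_learning_rule("x1*(y0-1)"), "unsupported token")
  expect_error(parse_learning_rule("x1 +"), "ends after operator")
  expect_error(parse_learning_rule(""), "non-empty")
})

test_that("rule evaluation reproduces hand-computed dw", {
  rule <- parse_learning_rule("2^-2*x1*y0 - 2^-2*x0*y1")
  expect_equal(evaluate_learning_rule(rule, x1 = 120, y0 = 1, x0 = 0), 30)
  expect_equal(evaluate_learning_rule(rule, x0 = 0, y0 = 0,
                                      x1 = 90, y1 = 90), 0)
  expect_equal(evaluate_learning_rule(rule, x0 = 1, y1 = 80), -20)
  # vectorized over pairs
  expect_equal(evaluate_learning_rule(rule, x1 = c(120, 40), y0 = c(1, 1)),
               c(30, 10))
})

test_that("apply_learning rounds, clips and re-encodes the mantissa", {
  rule <- parse_learning_rule("2^-2*x1*y0 - 2^-2*x0*y1")
  r <- rng_stream(3)

  spec <- synapse_spec(128, -6, 8, "excitatory", plastic = TRUE)
  # dw = 30 exactly: integer candidate, no rounding randomness
  upd <- apply_learning(spec, list(x1 = 120, y0 = 1), rule, r)
  expect_equal(upd$spec$mantissa, 158)
  expect_equal(upd$J, encode_weight(upd$spec))

  # no spikes in the epoch: dw = 0, mantissa unchanged
  upd0 <- apply_learning(spec, list(x1 = 120, y1 = 80), rule, r)
  expect_equal(upd0$spec$mantissa, 128)

  # candidate 240 + 30 = 270 exceeds the excitatory range: clipped to 255
  spec_hi <- synapse_spec(240, 0, 8, "excitatory", plastic = TRUE)
  updc <- apply_learning(spec_hi, list(x1 = 120, y0 = 1), rule, r)
  expect_equal(updc$spec$mantissa, 255)

  # static synapse refuses the update
  expect_error(apply_learning(synapse_spec(10, 0), list(), rule, r),
               "static")
})

test_that("plastic mantissas stay on the precision grid and in range", {
  rule <- parse_learning_rule("x1*y0 - y1*x0")
  r <- rng_stream(5)
  for (n_wb in c(4, 6, 8)) {
    spec <- synapse_spec(100, 0, n_wb, "mixed", plastic = TRUE)
    spec <- normalize_spec(spec)
    ns <- precision_exponent(n_wb, "mixed")
    for (k in 1:100) {
      traces <- list(x1 = sample(0:127, 1), y0 = sample(0:1, 1),
                     y1 = sample(0:127, 1), x0 = sample(0:1, 1))
      spec <- apply_learning(spec, traces, rule, r)$spec
      expect_equal(spec$mantissa %% 2^ns, 0)
      expect_gte(spec$mantissa, -256)
      expect_lte(spec$mantissa, 254)
    }
  }
})

test_that("the STDP window is asymmetric and decays with lag", {
  # pre-then-post potentiates, post-then-pre depresses, |E[dw]| shrinks
  # with the lag: the discrete-trace analogue of the classic STDP window
  rule <- parse_learning_rule("2^-2*x1*y0 - 2^-2*x0*y1")
  tau <- 8
  impulse <- 120
  n_trials <- 400
  lags <- 1:10
  r <- rng_stream(12)

  mean_dw <- function(lag) {
    # lag > 0: pre fires at step 0, post at step `lag` (potentiation);
    # lag < 0: post first (depression). dw is evaluated every step; the
    # relevant contribution lands on the second spike's step.
    total <- numeric(n_trials)
    for (k in seq_len(n_trials)) {
      x1 <- 0
      y1 <- 0
      acc <- 0
      for (t in 0:abs(lag)) {
        pre <- (t == if (lag > 0) 0 else abs(lag))
        post <- (t == if (lag > 0) lag else 0)
        x1 <- update_trace(x1, tau, pre, impulse, r)
        y1 <- update_trace(y1, tau, post, impulse, r)
        acc <- acc + evaluate_learning_rule(rule,
                                            x0 = as.numeric(pre), x1 = x1,
                                            y0 = as.numeric(post), y1 = y1)
      }
      total[k] <- acc
    }
    mean(total)
  }

  pot <- vapply(lags, mean_dw, numeric(1))
  dep <- vapply(-lags, mean_dw, numeric(1))
  expect_true(all(pot > 0))
  expect_true(all(dep < 0))
  expect_true(all(diff(pot) < 0))          # potentiation fades with lag
  expect_true(all(diff(abs(dep)) < 0))     # so does depression
})
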