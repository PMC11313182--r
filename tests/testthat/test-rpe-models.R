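test_that("expected value follows the symmetric win/loss closed form", {
  expect_equal(expected_value(0.5 + 1e-12, 7), 7 * 2e-12, tolerance = 1e-6)
  expect_equal(expected_value(0.75, 9), 4.5)
  expect_equal(expected_value(0.25, 3), -1.5)
  expect_error(expected_value(0, 3), "probability")
  expect_error(expected_value(1, 3), "probability")
  expect_error(expected_value(0.5, -1), "stake")
})

test_that("unbiased RPEs are outcome minus expected value; session mean is zero", {
  s <- hand_schedule(c(0.75, 0.25), c(9, 3), c("win", "loss"))
  tr <- unbiased_rpes(s)
  expect_equal(tr$delta, c(9 - 4.5, -3 - (-1.5)))
  full <- unbiased_rpes(generate_schedule(schedule_config(seed = 3)))
  # exact-frequency outcome balance makes the session sum exactly zero
  expect_equal(mean(full$delta), 0, tolerance = 1e-12)
})

test_that("bias degenerates with zero bias weight or zero update rate", {
  s <- generate_schedule(small_cfg(seed = 2))
  tr0 <- biased_rpes(s, model_params(eta = 0.7, bias_weight = 0))
  expect_identical(tr0$delta_biased, tr0$delta)
  expect_true(all(tr0$pmod_momentum_bias == 0))
  tr1 <- biased_rpes(s, model_params(eta = 0, bias_weight = 2))
  expect_true(all(tr1$h == 0))
  expect_true(all(tr1$pmod_momentum_bias == 0))
})

test_that("eta = 1 additive recursion matches the hand-built oracle", {
  s <- hand_schedule(c(0.75, 0.25, 0.75, 0.25, 0.75), c(9, 3, 3, 9, 9),
                     c("win", "loss", "win", "win", "loss"))
  p <- model_params(eta = 1, bias_weight = 0.4)
  tr <- biased_rpes(s, p)
  orc <- oracle_recursion(tr$outcome_signed, tr$ev, 1, 0.4)
  expect_equal(tr$delta_biased, orc$delta_biased, tolerance = 1e-12)
  # with eta = 1, h_t = biased delta, so Delta_t = omega * prior biased delta
  expect_equal(tr$pmod_momentum_bias,
               0.4 * c(0, tr$delta_biased[-5]), tolerance = 1e-12)
})

test_that("recursion matches the independent oracle on random 50-trial schedules (both forms)", {
  for (i in 1:100) {
    set.seed(i)
    n <- 50
    s <- hand_schedule(sample(c(0.25, 0.75), n, TRUE),
                       sample(c(3, 9), n, TRUE),
                       sample(c("win", "loss"), n, TRUE))
    form <- if (i %% 2) "additive" else "multiplicative"
    p <- model_params(eta = runif(1), bias_weight = runif(1, 0, 2),
                      bias_form = form)
    tr <- biased_rpes(s, p)
    orc <- oracle_recursion(tr$outcome_signed, tr$ev, p$eta, p$bias_weight,
                            form, max_stake = max(s$stake))
    expect_equal(tr$delta_biased, orc$delta_biased, tolerance = 1e-12)
    expect_equal(tr$h, orc$h_in, tolerance = 1e-12)
    expect_equal(tr$h_post, orc$h_post, tolerance = 1e-12)
    expect_equal(tr$pmod_momentum_bias, tr$delta_biased - tr$delta,
                 tolerance = 1e-12)
  }
})

test_that("the additive difference modulator depends only on outcomes before t", {
  s <- generate_schedule(small_cfg(seed = 6))
  p <- model_params(eta = 0.3, bias_weight = 0.5)
  tr <- biased_rpes(s, p)
  t_pert <- 20
  s2 <- s
  s2$outcome[t_pert] <- if (s$outcome[t_pert] == "win") "loss" else "win"
  tr2 <- biased_rpes(s2, p)
  expect_equal(tr2$pmod_momentum_bias[seq_len(t_pert)],
               tr$pmod_momentum_bias[seq_len(t_pert)], tolerance = 1e-12)
  expect_equal(tr$pmod_momentum_bias, p$bias_weight * tr$h, tolerance = 1e-12)
})

test_that("momentum is bounded by the largest biased RPE magnitude (convex combination)", {
  for (seed in 1:5) {
    s <- generate_schedule(small_cfg(seed = seed))
    p <- model_params(eta = runif(1), bias_weight = runif(1))
    tr <- biased_rpes(s, p)
    expect_true(all(abs(tr$h_post) <= cummax(abs(tr$delta_biased)) + 1e-12))
  }
})

test_that("momentum series behaves as specified in limiting regimes", {
  wins <- hand_schedule(0.75, 9, rep("win", 20))
  h <- momentum_series(wins, model_params(eta = 0.4, bias_weight = 0.3))
  expect_true(all(diff(h) >= -1e-12))

  alt <- hand_schedule(0.75, 9, rep(c("win", "loss"), 10))
  p1 <- model_params(eta = 1, bias_weight = 0.2)
  tr <- biased_rpes(alt, p1)
  expect_equal(momentum_series(alt, p1), tr$delta_biased)
  expect_true(all(sign(tr$delta_biased) == rep(c(1, -1), 10)))

  s <- generate_schedule(small_cfg(seed = 3))
  p0 <- model_params(eta = 0.35, bias_weight = 0)
  expect_equal(momentum_series(s, p0),
               momentum_only_regressor(s, 0.35), tolerance = 1e-12)
})

test_that("carryover regressors are lagged products with zeroed first trial", {
  s4 <- hand_schedule(c(0.75, 0.25, 0.75, 0.25), c(9, 9, 3, 3),
                      c("win", "loss", "loss", "win"))
  d <- unbiased_rpes(s4)$delta
  cr <- carryover_regressors(s4)
  expect_equal(cr$delta_prev, c(0, d[-4]))
  expect_equal(cr$interaction, c(0, d[-4]) * d)
  # constant delta: all wins at one condition
  cs <- hand_schedule(0.75, 9, rep("win", 6))
  crc <- carryover_regressors(cs)
  expect_equal(crc$interaction[-1], rep(4.5^2, 5))
  expect_equal(crc$interaction[1], 0)
  expect_error(carryover_regressors(hand_schedule(0.75, 9, "win")),
               "at least 2")
})

test_that("momentum-only regressor is the EMA of unbiased RPEs", {
  s <- generate_schedule(small_cfg(seed = 9))
  d <- unbiased_rpes(s)$delta
  expect_equal(momentum_only_regressor(s, 1), d)
  expect_equal(momentum_only_regressor(s, 0), rep(0, length(d)))
  eta <- 0.5
  h_oracle <- Reduce(function(h, x) (1 - eta) * h + eta * x, d, accumulate = TRUE,
                     init = 0)[-1]
  expect_equal(momentum_only_regressor(s, eta), h_oracle, tolerance = 1e-12)
  # hand case: inputs (2, 0, 0) at eta = 0.5 halve each step
  expect_equal(Reduce(function(h, x) 0.5 * h + 0.5 * x, c(2, 0, 0),
                      accumulate = TRUE, init = 0)[-1],
               c(1, 0.5, 0.25))
})

test_that("difference modulator is weakly correlated with the unbiased RPE across seeds", {
  for (seed in c(1, 12, 123, 1234, 31)) {
    tr <- biased_rpes(generate_schedule(schedule_config(seed = seed)),
                      model_params())
    expect_lt(abs(cor(tr$pmod_momentum_bias, tr$delta)), 0.3)
  }
})

test_that("trace TSV round-trips", {
  tr <- biased_rpes(generate_schedule(small_cfg(seed = 2)), model_params())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trace(tr, path)
  expect_equal(as.data.frame(read_trace(path)), as.data.frame(tr))
})
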