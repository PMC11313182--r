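make_run_design <- function(seed = 1, variant = "rpe", n_blocks = 1,
                            orthogonalize = FALSE) {
  s <- generate_schedule(small_cfg(n_blocks = n_blocks, seed = seed))
  sim <- simulate_participant(s, noiseless_truth(seed = seed))
  list(sim = sim,
       designs = build_design_set(sim, variant, orthogonalize = orthogonalize))
}

test_that("the RPE variant has exactly 11 named task/motion regressors", {
  d <- make_run_design()$designs[[1]]
  expect_length(d$task_names, 11)
  expect_identical(d$task_names,
                   c("choice", "anticipation", "outcome",
                     "outcome_x_delta", "outcome_x_momentum_bias",
                     paste0("motion", 1:6)))
  expect_true(all(c("intercept", "drift_lin", "drift_quad") %in% colnames(d$X)))
  expect_true(is.finite(d$condition_number))
})

test_that("modulator columns are mean-centered at event level; constant pmods vanish", {
  s <- generate_schedule(small_cfg(seed = 2))
  n <- nrow(s)
  motion <- matrix(rnorm(200 * 6, 0, 0.01), 200, 6)
  pm <- data.frame(delta = rnorm(n), momentum_bias = rep(2, n))
  expect_warning(
    d <- build_design(s, pm, motion, tr = 2, n_scans = 200),
    "all-zero")
  expect_true(all(d$X[, "outcome_x_momentum_bias"] == 0))
  # shifting a pmod by a constant leaves its column unchanged (centering)
  pm2 <- data.frame(delta = pm$delta + 5, momentum_bias = rnorm(n))
  d2 <- build_design(s, pm2, motion, tr = 2, n_scans = 200)
  expect_equal(d2$X[, "outcome_x_delta"], d$X[, "outcome_x_delta"],
               tolerance = 1e-12)
})

test_that("pmod misalignment and bad motion raise errors", {
  s <- generate_schedule(small_cfg(seed = 2))
  motion <- matrix(0, 200, 6)
  expect_error(build_design(s, data.frame(delta = 1:5, momentum_bias = 1:5),
                            motion, 2, 200), "does not match outcome-event count")
  expect_error(build_design(s, data.frame(delta = rnorm(32)), motion, 2, 200),
               "missing columns")
  expect_error(build_design(s, data.frame(delta = rnorm(32),
                                          momentum_bias = rnorm(32)),
                            motion[, 1:5], 2, 200), "6")
})

test_that("fit_glm recovers known coefficients and matches lm on random instances", {
  d <- make_run_design(seed = 3)$designs[[1]]
  X <- d$X
  for (i in 1:100) {
    set.seed(i)
    b <- rnorm(ncol(X))
    y <- as.numeric(X %*% b)
    if (i %% 2 == 0) y <- y + rnorm(nrow(X), 0, 0.5)
    fit <- fit_glm(list(y), list(d))
    ref <- unname(coef(lm(y ~ X - 1)))
    expect_equal(unname(fit$betas), ref, tolerance = 1e-6)
    if (i %% 2 == 1) expect_equal(unname(fit$betas), b, tolerance = 1e-6)
  }
})

test_that("null data give unbiased modulator betas over 1000 simulations", {
  d <- make_run_design(seed = 4)$designs[[1]]
  n <- nrow(d$X)
  set.seed(99)
  betas <- vapply(1:1000, function(i) {
    fit_glm(list(rnorm(n)), list(d))$betas[["outcome_x_momentum_bias"]]
  }, numeric(1))
  expect_lt(abs(mean(betas)), 2 * sd(betas) / sqrt(1000))
})

test_that("rank deficiency raises an error naming collinear columns", {
  d <- make_run_design(seed = 5)$designs[[1]]
  d$X <- cbind(d$X, dup_outcome = d$X[, "outcome"])
  y <- rnorm(nrow(d$X))
  expect_error(fit_glm(list(y), list(d)), "dup_outcome|outcome")
})

test_that("difference coding keeps the two modulators' VIF below 5 on default schedules", {
  for (seed in c(1, 17)) {
    s <- generate_schedule(schedule_config(seed = seed))
    sim <- simulate_participant(s, noiseless_truth(seed = seed))
    d <- build_design_set(sim, "rpe")[[1]]
    r2 <- summary(lm(d$X[, "outcome_x_momentum_bias"] ~
                       d$X[, "outcome_x_delta"]))$r.squared
    expect_lt(1 / (1 - r2), 5)
  }
})

test_that("betas are invariant to a constant offset in the series", {
  md <- make_run_design(seed = 6)
  y <- md$sim$rois$ventral_striatum$values[[1]]
  f1 <- fit_glm(list(y), md$designs)
  f2 <- fit_glm(list(y + 100), md$designs)
  keep <- setdiff(names(f1$betas), "intercept")
  expect_equal(f1$betas[keep], f2$betas[keep], tolerance = 1e-8)
})

test_that("equal-weight run averaging equals a concatenated GLM with per-run terms (noiseless)", {
  md <- make_run_design(seed = 7, n_blocks = 2)
  task <- md$designs[[1]]$task_names
  X1 <- md$designs[[1]]$X[, task]; X2 <- md$designs[[2]]$X[, task]
  set.seed(7)
  b <- rnorm(length(task))
  y1 <- as.numeric(X1 %*% b); y2 <- as.numeric(X2 %*% b)
  avg <- fit_glm(list(y1, y2), md$designs)$betas
  bigX <- rbind(cbind(X1, run1 = 1, run2 = 0),
                cbind(X2, run1 = 0, run2 = 1))
  conc <- coef(lm(c(y1, y2) ~ bigX - 1))
  expect_equal(unname(avg[task]), unname(conc[seq_along(task)]),
               tolerance = 1e-6)
})

test_that("extract_contrast returns run-averaged betas and errors on unknown names", {
  md <- make_run_design(seed = 8)
  fit <- fit_glm(md$sim$rois$ventral_striatum, md$designs)
  expect_equal(extract_contrast(fit, "outcome_x_delta"),
               md$sim$truth$beta_delta, tolerance = 1e-6)
  expect_error(extract_contrast(fit, "outcome_x_deltaa"), "unknown regressor")
  zsim <- simulate_participant(md$sim$schedule,
                               noiseless_truth(beta_delta = 0, beta_choice = 0,
                                               beta_anticipation = 0,
                                               beta_outcome = 0, gamma0 = 0))
  zfit <- fit_glm(zsim$rois$ventral_striatum, build_design_set(zsim, "rpe"))
  expect_lt(abs(extract_contrast(zfit, "outcome_x_momentum_bias")), 1e-10)
})

test_that("serial orthogonalization changes the delta beta but not the unique momentum-bias beta", {
  md1 <- make_run_design(seed = 9, orthogonalize = FALSE)
  md2 <- make_run_design(seed = 9, orthogonalize = TRUE)
  y <- md1$sim$rois$ventral_striatum$values[[1]]
  f1 <- fit_glm(list(y), md1$designs)
  f2 <- fit_glm(list(y), md2$designs)
  # orthogonalizing the second modulator against the first leaves the
  # second's coefficient unchanged and pushes shared variance into the first
  expect_equal(f1$betas[["outcome_x_momentum_bias"]],
               f2$betas[["outcome_x_momentum_bias"]], tolerance = 1e-6)
})
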