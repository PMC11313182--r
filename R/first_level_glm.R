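#' Build the first-level design matrix for one run
#'
#' Three condition columns (unit impulses at choice, anticipation, and
#' outcome onsets), parametric-modulator columns built from mean-centered
#' per-trial values placed at outcome onsets, all convolved with the
#' canonical HRF on a fine grid and sampled at the scan grid, followed by
#' the 6 motion realignment parameters — 11 named task/motion regressors
#' for the RPE variant — plus per-run intercept and linear/quadratic drift
#' nuisance columns.
#'
#' @param schedule_run a `trial_schedule` restricted to one run, onsets
#'   relative to run start.
#' @param pmods data frame of per-trial modulator values aligned to this
#'   run's outcome events: columns `delta` and `momentum_bias` for the
#'   `"rpe"` variant, `momentum` for the `"momentum"` variant.
#' @param motion `n_scans x 6` matrix of realignment parameters.
#' @param tr repetition time in seconds.
#' @param n_scans number of scans in the run.
#' @param variant `"rpe"` (default) or `"momentum"`.
#' @param dt fine-grid resolution for convolution.
#' @param orthogonalize if `TRUE`, serially orthogonalize each modulator
#'   column against the columns before it (SPM-style); default `FALSE` —
#'   the difference coding of the momentum-bias modulator exists precisely
#'   to avoid collinearity.
#' @param drift add per-run linear + quadratic drift columns (default).
#' @return A `design_matrix`: list with `X` (matrix), `task_names` (the
#'   named task/motion regressors), `nuisance_names`, `condition_number`.
#' @export
build_design <- function(schedule_run, pmods, motion, tr, n_scans,
                         variant = c("rpe", "momentum"), dt = 0.1,
                         orthogonalize = FALSE, drift = TRUE) {
  variant <- match.arg(variant)
  validate_schedule(schedule_run)
  n_trials <- nrow(schedule_run)
  need <- switch(variant, rpe = c("delta", "momentum_bias"), momentum = "momentum")
  miss <- setdiff(need, names(pmods))
  if (length(miss))
    stop("pmods missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(pmods) != n_trials)
    stop("pmod length (", nrow(pmods), ") does not match outcome-event count (",
         n_trials, ")", call. = FALSE)
  motion <- as.matrix(motion)
  if (nrow(motion) != n_scans || ncol(motion) != 6)
    stop("motion must be an n_scans x 6 matrix", call. = FALSE)

  run_dur <- (n_scans - 1L) * tr
  n_fine <- as.integer(ceiling(max(run_dur, max(schedule_run$onset_outcome)) / dt)) + 1L
  kernel <- hrf(dt)
  scan_idx <- round(seq(0, run_dur, by = tr) / dt) + 1L
  conv_col <- function(onsets, amps) {
    convolve_hrf(stick_train(onsets, amps, n_fine, dt), kernel)[scan_idx]
  }

  ones <- rep(1, n_trials)
  cols <- list(
    choice = conv_col(schedule_run$onset_choice, ones),
    anticipation = conv_col(schedule_run$onset_anticipation, ones),
    outcome = conv_col(schedule_run$onset_outcome, ones))
  for (nm in need) {
    centered <- pmods[[nm]] - mean(pmods[[nm]])
    cols[[paste0("outcome_x_", nm)]] <- conv_col(schedule_run$onset_outcome, centered)
  }
  if (orthogonalize) {
    mod_names <- paste0("outcome_x_", need)
    for (i in seq_along(mod_names)[-1]) {
      prior <- do.call(cbind, cols[mod_names[seq_len(i - 1)]])
      y <- cols[[mod_names[i]]]
      cols[[mod_names[i]]] <- y - prior %*% qr.solve(crossprod(prior), crossprod(prior, y))
    }
  }
  for (j in 1:6) cols[[paste0("motion", j)]] <- motion[, j]
  task_names <- names(cols)

  nuisance_names <- "intercept"
  cols$intercept <- rep(1, n_scans)
  if (drift) {
    t01 <- seq(0, 1, length.out = n_scans)
    cols$drift_lin <- t01 - mean(t01)
    cols$drift_quad <- (t01 - mean(t01))^2 - mean((t01 - mean(t01))^2)
    nuisance_names <- c(nuisance_names, "drift_lin", "drift_quad")
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  zero <- task_names[apply(X[, task_names, drop = FALSE], 2,
                           function(v) all(abs(v) < 1e-12))]
  if (length(zero))
    warning("all-zero design column(s): ", paste(zero, collapse = ", "),
            call. = FALSE)
  structure(list(X = X, task_names = task_names,
                 nuisance_names = nuisance_names,
                 condition_number = kappa(X, exact = TRUE)),
            class = "design_matrix")
}

#' Build per-run designs for a simulated participant
#'
#' Splits the schedule by block, aligns the modulator trace, and calls
#' [build_design()] once per run.
#'
#' @param sim a `participant_sim` from [simulate_participant()].
#' @param variant `"rpe"` or `"momentum"`.
#' @param ... passed to [build_design()].
#' @return List of `design_matrix`, one per run.
#' @export
build_design_set <- function(sim, variant = c("rpe", "momentum"), ...) {
  variant <- match.arg(variant)
  blocks <- sort(unique(sim$schedule$block))
  lapply(seq_along(blocks), function(bi) {
    b <- blocks[bi]
    sr <- sim$schedule[sim$schedule$block == b, ]
    trb <- sim$trace[sim$trace$block == b, ]
    pm <- switch(variant,
      rpe = data.frame(delta = trb$delta,
                       momentum_bias = trb$pmod_momentum_bias),
      momentum = data.frame(momentum = trb$h_post))
    build_design(sr, pm, sim$motion[[bi]], tr = sim$acq$tr,
                 n_scans = nrow(sim$motion[[bi]]), variant = variant,
                 dt = sim$acq$dt, ...)
  })
}

#' Fit the first-level GLM
#'
#' Ordinary least squares per run; betas are averaged across runs with
#' equal weights and the mean residual variance is reported. Rank-deficient
#' designs raise an error naming the collinear columns.
#'
#' @param ts an `roi_timeseries` (list of per-run value vectors), or a
#'   single numeric vector for a one-run fit.
#' @param designs a `design_matrix` or list of them, one per run.
#' @param participant optional participant id carried into the result.
#' @return A `first_level_result`: list with `betas` (named, run-averaged),
#'   `per_run` (runs x coefficients matrix), `sigma2`, `task_names`.
#' @export
fit_glm <- function(ts, designs, participant = NA_character_) {
  runs <- if (inherits(ts, "roi_timeseries")) ts$values else
    if (is.list(ts)) ts else list(ts)
  if (inherits(designs, "design_matrix")) designs <- list(designs)
  if (length(runs) != length(designs))
    stop("number of runs (", length(runs), ") does not match number of designs (",
         length(designs), ")", call. = FALSE)
  per_run <- NULL
  sigma2 <- numeric(length(runs))
  for (r in seq_along(runs)) {
    X <- designs[[r]]$X
    y <- runs[[r]]
    if (length(y) != nrow(X))
      stop("run ", r, ": series length ", length(y),
           " does not match design rows ", nrow(X), call. = FALSE)
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      dropped <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
      stop("rank-deficient design in run ", r, "; collinear column(s): ",
           paste(dropped, collapse = ", "), call. = FALSE)
    }
    beta <- qr.coef(qx, y)
    res <- y - X %*% beta
    sigma2[r] <- sum(res^2) / (nrow(X) - ncol(X))
    per_run <- rbind(per_run, beta)
  }
  betas <- colMeans(per_run)
  structure(list(participant = participant, betas = betas,
                 per_run = per_run, sigma2 = mean(sigma2),
                 task_names = designs[[1]]$task_names),
            class = "first_level_result")
}

#' Extract a contrast value
#'
#' Under the identity contrast vector the contrast for a named regressor is
#' its run-averaged beta.
#'
#' @param result a `first_level_result`.
#' @param name regressor name, e.g. `"outcome_x_momentum_bias"`.
#' @return Scalar beta.
#' @export
extract_contrast <- function(result, name) {
  stopifnot(inherits(result, "first_level_result"))
  if (!name %in% names(result$betas))
    stop("unknown regressor: '", name, "'; available: ",
         paste(names(result$betas), collapse = ", "), call. = FALSE)
  unname(result$betas[[name]])
}
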