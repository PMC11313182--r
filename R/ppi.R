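#' Generalized psychophysiological interaction fit
#'
#' Quantifies how seed-target coupling is modulated by a trialwise
#' psychological quantity. Per run: the psychological regressor psi is the
#' HRF-convolved train of outcome events weighted by the modulator values;
#' both the seed series and psi are mean-centered within the run and their
#' elementwise product forms the PPI term; the target series is regressed
#' on intercept, seed, psi, the PPI term, the 6 motion parameters, and
#' linear/quadratic drift. Coefficients are averaged across runs with equal
#' weights. The interaction is formed at the BOLD level (seed BOLD times
#' convolved psychological regressor); the deconvolution-based neural-level
#' scheme is not implemented.
#'
#' @param seed_ts `roi_timeseries` of the seed region (ventral striatum).
#' @param target_ts `roi_timeseries` of the target region (left insula).
#' @param schedule the participant's `trial_schedule`.
#' @param pmod per-trial psychological values aligned to outcome events
#'   (full session; split by block internally).
#' @param motion list of per-run `n_scans x 6` motion matrices.
#' @param psych_name label recorded in the result (`"momentum_bias"` or
#'   `"delta"`).
#' @param dt fine-grid resolution for convolution.
#' @param neural_level reserved; must be `FALSE`.
#' @param participant optional id.
#' @return A `ppi_result`: list with `beta_seed`, `beta_psych`, `beta_ppi`,
#'   `psych_name`, `per_run`, `participant`.
#' @export
ppi_fit <- function(seed_ts, target_ts, schedule, pmod, motion,
                    psych_name = "momentum_bias", dt = 0.1,
                    neural_level = FALSE, participant = NA_character_) {
  if (isTRUE(neural_level))
    stop("neural-level (deconvolution) PPI is not implemented", call. = FALSE)
  validate_schedule(schedule)
  stopifnot(inherits(seed_ts, "roi_timeseries"),
            inherits(target_ts, "roi_timeseries"))
  blocks <- sort(unique(schedule$block))
  if (length(seed_ts$values) != length(blocks) ||
      length(target_ts$values) != length(blocks) ||
      length(motion) != length(blocks))
    stop("seed, target, motion, and schedule disagree on run structure",
         call. = FALSE)
  if (length(pmod) != nrow(schedule))
    stop("pmod length (", length(pmod), ") does not match trial count (",
         nrow(schedule), ")", call. = FALSE)
  if (all(abs(pmod) < 1e-12)) {
    warning("degenerate psychological regressor (all zeros); beta_ppi = 0 by convention",
            call. = FALSE)
    return(structure(list(beta_seed = NA_real_, beta_psych = 0,
                          beta_ppi = 0, psych_name = psych_name,
                          per_run = NULL, participant = participant),
                     class = "ppi_result"))
  }
  tr <- seed_ts$tr
  kernel <- hrf(dt)
  per_run <- NULL
  for (bi in seq_along(blocks)) {
    b <- blocks[bi]
    sr <- schedule[schedule$block == b, ]
    pm <- pmod[schedule$block == b]
    seed <- seed_ts$values[[bi]]
    target <- target_ts$values[[bi]]
    n_scans <- length(seed)
    if (length(target) != n_scans)
      stop("run ", b, ": seed and target lengths differ", call. = FALSE)
    run_dur <- (n_scans - 1L) * tr
    n_fine <- as.integer(ceiling(max(run_dur, max(sr$onset_outcome)) / dt)) + 1L
    scan_idx <- round(seq(0, run_dur, by = tr) / dt) + 1L
    psi <- convolve_hrf(stick_train(sr$onset_outcome, pm, n_fine, dt),
                        kernel)[scan_idx]
    seed_c <- seed - mean(seed)
    psi_c <- psi - mean(psi)
    t01 <- seq(0, 1, length.out = n_scans)
    X <- cbind(intercept = 1, seed = seed_c, psych = psi_c,
               ppi = seed_c * psi_c, motion[[bi]],
               drift_lin = t01 - mean(t01),
               drift_quad = (t01 - mean(t01))^2 - mean((t01 - mean(t01))^2))
    colnames(X)[5:10] <- paste0("motion", 1:6)
    qx <- qr(X)
    if (qx$rank < ncol(X))
      stop("rank-deficient PPI design in run ", b, call. = FALSE)
    per_run <- rbind(per_run, qr.coef(qx, target))
  }
  betas <- colMeans(per_run)
  structure(list(beta_seed = unname(betas["seed"]),
                 beta_psych = unname(betas["psych"]),
                 beta_ppi = unname(betas["ppi"]),
                 psych_name = psych_name, per_run = per_run,
                 participant = participant),
            class = "ppi_result")
}

#' PPI specificity analysis with the unbiased RPE
#'
#' Identical machinery to [ppi_fit()] with the psychological regressor
#' built from the unbiased RPEs, used to confirm that coupling is
#' specifically modulated by the momentum-biased difference term.
#'
#' @inheritParams ppi_fit
#' @param delta_pmod per-trial unbiased RPE values.
#' @return A `ppi_result` with `psych_name = "delta"`.
#' @export
ppi_specificity <- function(seed_ts, target_ts, schedule, delta_pmod, motion,
                            dt = 0.1, participant = NA_character_) {
  ppi_fit(seed_ts, target_ts, schedule, delta_pmod, motion,
          psych_name = "delta", dt = dt, participant = participant)
}
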