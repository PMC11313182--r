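#' Canonical double-gamma hemodynamic response function
#'
#' The canonical HRF as the difference of two gamma densities (response
#' peaking near 5 s, undershoot near 15 s, undershoot ratio 1/6),
#' peak-normalized to 1.
#'
#' @param tr sampling interval in seconds (`> 0`).
#' @param duration kernel length in seconds; default 32.
#' @return Numeric vector sampled at `0, tr, 2 tr, ...` up to `duration`.
#' @export
#' @examples
#' k <- hrf(0.1)
#' seq(0, 32, by = 0.1)[which.max(k)]   # ~5 s
hrf <- function(tr, duration = 32) {
  stopifnot(tr > 0, duration > 0)
  t <- seq(0, duration, by = tr)
  k <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  k / max(k)
}

#' Acquisition parameters for the synthetic scanner
#'
#' @param tr repetition time in seconds; default 2 (conventional; the
#'   emulated study's TR is not printed in its main text).
#' @param dt resolution of the internal neural/convolution grid in seconds.
#' @param pad seconds of rest appended after the last trial so late
#'   hemodynamic responses are sampled.
#' @return An object of class `acquisition`.
#' @export
acquisition <- function(tr = 2, dt = 0.1, pad = 16) {
  stopifnot(tr > 0, dt > 0, dt <= tr, pad >= 0)
  structure(list(tr = tr, dt = dt, pad = pad), class = "acquisition")
}

#' Per-participant generative ground truth
#'
#' Amplitudes and noise parameters from which a participant's ROI time
#' series are synthesized. The ventral striatum (VS) responds to outcomes
#' with amplitude `beta_outcome + beta_delta * delta_t +
#' beta_momentum_bias * Delta_t`; the left insula carries
#' `beta_momentum * h_t` at outcomes plus a coupling term
#' `(gamma0 + gamma1 * Delta_t)` times the VS neural signal; the right
#' insula has outcome responses and baseline (`gamma0`) coupling but no
#' momentum term and no momentum-modulated coupling.
#'
#' @param group `"bipolar"` or `"control"` (label only).
#' @param beta_choice,beta_anticipation,beta_outcome condition amplitudes.
#' @param beta_delta unbiased-RPE tracking weight (VS).
#' @param beta_momentum_bias momentum-biased-RPE (difference modulator)
#'   tracking weight (VS).
#' @param beta_momentum momentum tracking weight (left insula).
#' @param gamma0 baseline insula-VS coupling gain.
#' @param gamma1 momentum-bias modulation of coupling (the gPPI target).
#' @param noise_sigma marginal SD of the AR(1) noise.
#' @param ar1_rho lag-1 autocorrelation of the noise.
#' @param drift_amplitude amplitude of the slow cosine drift.
#' @param motion_amplitude scale of motion-correlated nuisance leaking into
#'   the BOLD signal.
#' @param seed participant-level seed; the simulation is deterministic
#'   given it.
#' @return An object of class `participant_truth`.
#' @export
participant_truth <- function(group = c("control", "bipolar"),
                              beta_choice = 1, beta_anticipation = 1,
                              beta_outcome = 1,
                              beta_delta = 0.25, beta_momentum_bias = 0,
                              beta_momentum = 0,
                              gamma0 = 0.3, gamma1 = 0,
                              noise_sigma = 1, ar1_rho = 0.3,
                              drift_amplitude = 0.5,
                              motion_amplitude = 0.1,
                              seed = 1L) {
  group <- match.arg(group)
  stopifnot(noise_sigma >= 0, ar1_rho > -1, ar1_rho < 1,
            drift_amplitude >= 0, motion_amplitude >= 0)
  structure(list(group = group, beta_choice = beta_choice,
                 beta_anticipation = beta_anticipation,
                 beta_outcome = beta_outcome, beta_delta = beta_delta,
                 beta_momentum_bias = beta_momentum_bias,
                 beta_momentum = beta_momentum,
                 gamma0 = gamma0, gamma1 = gamma1,
                 noise_sigma = noise_sigma, ar1_rho = ar1_rho,
                 drift_amplitude = drift_amplitude,
                 motion_amplitude = motion_amplitude,
                 seed = as.integer(seed)),
            class = "participant_truth")
}

# Impulse train on the fine grid: amplitudes added at the nearest grid point.
stick_train <- function(onsets, amplitudes, n_fine, dt) {
  x <- numeric(n_fine)
  idx <- pmin(n_fine, round(onsets / dt) + 1L)
  for (i in seq_along(idx)) x[idx[i]] <- x[idx[i]] + amplitudes[i]
  x
}

# Causal convolution with an HRF kernel, truncated to the input length.
# FFT with padding to an FFT-friendly composite length (much faster than
# stats::convolve at awkward sizes).
convolve_hrf <- function(x, kernel) {
  n <- length(x)
  L <- stats::nextn(n + length(kernel) - 1L)
  xp <- c(x, numeric(L - n))
  kp <- c(kernel, numeric(L - length(kernel)))
  y <- Re(stats::fft(stats::fft(xp) * stats::fft(kp), inverse = TRUE)) / L
  y[seq_len(n)]
}

run_scan_count <- function(sched_run, cfg, acq) {
  dur <- max(sched_run$onset_outcome) + cfg$outcome_duration + acq$pad
  as.integer(floor(dur / acq$tr)) + 1L
}

#' Simulate one participant's ROI time series
#'
#' Generates neural impulse trains for the three task phases, injects
#' RPE/momentum tracking and momentum-modulated insular-striatal coupling
#' at the neural level, convolves with the canonical HRF on a fine grid,
#' samples at the scan grid, then adds AR(1) noise, slow cosine drift, and
#' motion-correlated nuisance. Also returns the realized motion parameters
#' (6 series per run) and, per ROI, the noiseless sampled signal for
#' recovery testing.
#'
#' @param schedule a `trial_schedule` (each block is one run).
#' @param truth a [participant_truth()].
#' @param params a [model_params()] governing the momentum recursion used
#'   to build the ground-truth modulator series.
#' @param acq an [acquisition()].
#' @return A list of class `participant_sim`: `rois` (named list
#'   `ventral_striatum`, `left_insula`, `right_insula`, each of class
#'   `roi_timeseries` with `tr`, `values` — list of per-run numeric
#'   vectors — and `clean`), `motion` (list of per-run `n_scans x 6`
#'   matrices), `schedule`, `trace`, `truth`.
#' @export
simulate_participant <- function(schedule, truth = participant_truth(),
                                 params = model_params(),
                                 acq = acquisition()) {
  validate_schedule(schedule)
  cfg <- attr(schedule, "config")
  if (is.null(cfg)) cfg <- schedule_config()
  trace <- biased_rpes(schedule, params)
  blocks <- sort(unique(schedule$block))
  kernel <- hrf(acq$dt)

  with_seed(truth$seed, {
    motion_w <- stats::rnorm(6, 0, 1)  # participant-stable leak weights
    rois <- list(ventral_striatum = list(), left_insula = list(),
                 right_insula = list())
    clean <- rois
    motion <- vector("list", length(blocks))
    for (bi in seq_along(blocks)) {
      b <- blocks[bi]
      sr <- schedule[schedule$block == b, ]
      trb <- trace[trace$block == b, ]
      n_scans <- run_scan_count(sr, cfg, acq)
      run_dur <- (n_scans - 1L) * acq$tr
      n_fine <- as.integer(ceiling(run_dur / acq$dt)) + 1L
      scan_idx <- round(seq(0, run_dur, by = acq$tr) / acq$dt) + 1L

      amp_vs_outcome <- truth$beta_outcome + truth$beta_delta * trb$delta +
        truth$beta_momentum_bias * trb$pmod_momentum_bias
      neural_vs <-
        stick_train(sr$onset_choice, rep(truth$beta_choice, nrow(sr)), n_fine, acq$dt) +
        stick_train(sr$onset_anticipation, rep(truth$beta_anticipation, nrow(sr)), n_fine, acq$dt) +
        stick_train(sr$onset_outcome, amp_vs_outcome, n_fine, acq$dt)

      # coupling gain applies trialwise to every VS neural event
      gain <- truth$gamma0 + truth$gamma1 * trb$pmod_momentum_bias
      neural_li <-
        stick_train(sr$onset_outcome, truth$beta_momentum * trb$h_post, n_fine, acq$dt) +
        stick_train(sr$onset_choice, gain * truth$beta_choice, n_fine, acq$dt) +
        stick_train(sr$onset_anticipation, gain * truth$beta_anticipation, n_fine, acq$dt) +
        stick_train(sr$onset_outcome, gain * amp_vs_outcome, n_fine, acq$dt)
      # right insula: no momentum term, and baseline coupling to the
      # condition (unmodulated) part of the striatal signal only — the
      # momentum GLM has no RPE column, so any coupled delta tracking would
      # masquerade as momentum tracking (delta and momentum share the
      # same-trial update term); this keeps the right insula genuinely
      # momentum-free (left-lateralized selectivity by design)
      neural_conditions <-
        stick_train(sr$onset_choice, rep(truth$beta_choice, nrow(sr)), n_fine, acq$dt) +
        stick_train(sr$onset_anticipation, rep(truth$beta_anticipation, nrow(sr)), n_fine, acq$dt) +
        stick_train(sr$onset_outcome, rep(truth$beta_outcome, nrow(sr)), n_fine, acq$dt)
      neural_ri <-
        stick_train(sr$onset_outcome, rep(truth$beta_outcome, nrow(sr)), n_fine, acq$dt) +
        truth$gamma0 * neural_conditions

      sampled <- lapply(list(vs = neural_vs, li = neural_li, ri = neural_ri),
                        function(x) convolve_hrf(x, kernel)[scan_idx])
      if (any(!vapply(sampled, function(v) all(is.finite(v)), logical(1))))
        stop("non-finite simulated signal in run ", b, call. = FALSE)

      mot <- matrix(cumsum(stats::rnorm(n_scans * 6, 0, 0.02)),
                    nrow = n_scans, ncol = 6)
      scan_t <- seq(0, run_dur, by = acq$tr)
      for (k in seq_along(sampled)) {
        noise <- if (truth$noise_sigma > 0) {
          as.numeric(stats::filter(
            stats::rnorm(n_scans, 0, truth$noise_sigma * sqrt(1 - truth$ar1_rho^2)),
            truth$ar1_rho, method = "recursive"))
        } else numeric(n_scans)
        drift <- if (truth$drift_amplitude > 0) {
          truth$drift_amplitude * cos(2 * pi * scan_t / 128 + stats::runif(1, 0, 2 * pi))
        } else numeric(n_scans)
        nuis <- truth$motion_amplitude * as.numeric(mot %*% motion_w)
        roi <- names(rois)[k]
        clean[[roi]][[bi]] <- sampled[[k]]
        rois[[roi]][[bi]] <- sampled[[k]] + noise + drift + nuis
      }
      motion[[bi]] <- mot
    }
    rois <- lapply(seq_along(rois), function(k) {
      structure(list(roi = names(clean)[k], tr = acq$tr,
                     values = rois[[k]], clean = clean[[k]]),
                class = "roi_timeseries")
    })
    names(rois) <- names(clean)
    structure(list(rois = rois, motion = motion, schedule = schedule,
                   trace = trace, truth = truth, acq = acq, params = params),
              class = "participant_sim")
  })
}

#' Group-level effect specification for cohort simulation
#'
#' Means and SDs of the generative per-participant amplitudes, calibrated
#' so that the distribution of recovered contrast values reproduces the
#' group effect sizes of the emulated study: unbiased-RPE tracking
#' d = 1.27 (bipolar) / 1.42 (control), momentum-bias tracking d = 0.54
#' (bipolar, mean 0.75, SD 1.37) / 0.18 (control, mean 0.19, SD 1.08),
#' coupling modulation mean 0.22 SD 0.31 (control) / mean -0.11 SD 0.30
#' (bipolar). Momentum tracking is common to both groups (d = 0.33;
#' the study prints no group means, so mean 0.33, SD 1 is used).
#'
#' `symptom_coupling` sets the latent correlation between residual manic
#' symptoms and the coupling modulation in the bipolar-like group;
#' `n_missing_symptoms` marks that many bipolar-like participants as
#' missing symptom scores (the study analysed 20 complete cases).
#'
#' @param overrides named list; any entry replaces the default of the same
#'   name.
#' @return A list of class `effect_spec` with per-group `mean`/`sd` pairs.
#' @export
effect_spec <- function(overrides = list()) {
  spec <- list(
    beta_delta = list(bipolar = c(mean = 0.28, sd = 0.22),
                      control = c(mean = 0.20, sd = 0.14)),
    beta_momentum_bias = list(bipolar = c(mean = 0.75, sd = 1.37),
                              control = c(mean = 0.19, sd = 1.08)),
    beta_momentum = list(bipolar = c(mean = 0.33, sd = 1),
                         control = c(mean = 0.33, sd = 1)),
    gamma1 = list(bipolar = c(mean = -0.11, sd = 0.30),
                  control = c(mean = 0.22, sd = 0.31)),
    gamma0 = list(bipolar = c(mean = 0.3, sd = 0.1),
                  control = c(mean = 0.3, sd = 0.1)),
    beta_outcome = 1, beta_choice = 1, beta_anticipation = 1,
    noise_sigma = 1, ar1_rho = 0.3, drift_amplitude = 0.5,
    motion_amplitude = 0.1,
    symptoms = list(bipolar = list(MAS = c(mean = 3.55, sd = 3.09),
                                   HAMD = c(mean = 3.83, sd = 2.96),
                                   BIS = c(mean = 76.95, sd = 9.94)),
                    control = list(MAS = c(mean = 0.38, sd = 1.11),
                                   HAMD = c(mean = 0.60, sd = 1.04),
                                   BIS = c(mean = 62.62, sd = 6.00))),
    symptom_coupling = -0.45,
    n_missing_symptoms = 1L)
  for (nm in names(overrides)) {
    if (!nm %in% names(spec))
      stop("unknown effect_spec field: ", nm, call. = FALSE)
    spec[[nm]] <- overrides[[nm]]
  }
  for (nm in c("beta_delta", "beta_momentum_bias", "beta_momentum",
               "gamma1", "gamma0")) {
    for (g in c("bipolar", "control")) {
      if (spec[[nm]][[g]]["sd"] < 0)
        stop("negative SD requested for ", nm, " (", g, ")", call. = FALSE)
    }
  }
  class(spec) <- "effect_spec"
  spec
}

draw_group <- function(spec_entry, group, n) {
  stats::rnorm(n, spec_entry[[group]]["mean"], spec_entry[[group]]["sd"])
}

#' Simulate a two-group cohort
#'
#' Draws per-participant generative amplitudes from the group distributions
#' in an [effect_spec()], simulates each participant's schedule and ROI
#' time series, and records every drawn value in a ground-truth ledger for
#' recovery testing. Symptom scores (MAS, HAMD-17, BIS-11) are drawn per
#' group, truncated at 0, with the bipolar-like group's coupling modulation
#' latently correlated with MAS at `symptom_coupling`.
#'
#' @param n_per_group participants per group (`>= 2`).
#' @param spec an [effect_spec()].
#' @param seed cohort seed; everything downstream derives from it.
#' @param sched_cfg schedule configuration shared by all participants
#'   (per-participant seeds vary the pseudorandom order only).
#' @param params a [model_params()].
#' @param acq an [acquisition()].
#' @return A list of class `cohort`: `participants` (list of
#'   `participant_sim`), `ledger` (data frame of drawn truths and symptom
#'   scores), `spec`, `seed`.
#' @export
simulate_cohort <- function(n_per_group = 21, spec = effect_spec(),
                            seed = 1L,
                            sched_cfg = schedule_config(),
                            params = model_params(),
                            acq = acquisition()) {
  stopifnot(n_per_group >= 2)
  n_total <- 2L * as.integer(n_per_group)
  groups <- rep(c("bipolar", "control"), each = n_per_group)
  draws <- with_seed(derive_seed(seed, 1), {
    out <- data.frame(id = sprintf("sub-%03d", seq_len(n_total)),
                      group = groups, stringsAsFactors = FALSE)
    for (nm in c("beta_delta", "beta_momentum_bias", "beta_momentum", "gamma0"))
      out[[nm]] <- c(draw_group(spec[[nm]], "bipolar", n_per_group),
                     draw_group(spec[[nm]], "control", n_per_group))
    # gamma1 correlated with MAS (bipolar group) through a shared latent
    r <- spec$symptom_coupling
    z_mas <- stats::rnorm(n_per_group)
    z_g1 <- r * z_mas + sqrt(max(0, 1 - r^2)) * stats::rnorm(n_per_group)
    g1_b <- spec$gamma1$bipolar["mean"] + spec$gamma1$bipolar["sd"] * z_g1
    out$gamma1 <- c(g1_b, draw_group(spec$gamma1, "control", n_per_group))
    sym <- function(entry, z) pmax(0, entry["mean"] + entry["sd"] * z)
    out$MAS <- c(sym(spec$symptoms$bipolar$MAS, z_mas),
                 sym(spec$symptoms$control$MAS, stats::rnorm(n_per_group)))
    out$HAMD <- c(sym(spec$symptoms$bipolar$HAMD, stats::rnorm(n_per_group)),
                  sym(spec$symptoms$control$HAMD, stats::rnorm(n_per_group)))
    out$BIS <- c(sym(spec$symptoms$bipolar$BIS, stats::rnorm(n_per_group)),
                 sym(spec$symptoms$control$BIS, stats::rnorm(n_per_group)))
    out$symptoms_missing <- FALSE
    if (spec$n_missing_symptoms > 0) {
      miss <- sample(which(out$group == "bipolar"),
                     min(spec$n_missing_symptoms, n_per_group))
      out$symptoms_missing[miss] <- TRUE
    }
    out
  })

  participants <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    p_seed <- derive_seed(seed, 100 + i)
    cfg_i <- sched_cfg; cfg_i$seed <- p_seed
    sched <- generate_schedule(cfg_i)
    truth <- participant_truth(
      group = draws$group[i],
      beta_choice = spec$beta_choice,
      beta_anticipation = spec$beta_anticipation,
      beta_outcome = spec$beta_outcome,
      beta_delta = draws$beta_delta[i],
      beta_momentum_bias = draws$beta_momentum_bias[i],
      beta_momentum = draws$beta_momentum[i],
      gamma0 = draws$gamma0[i], gamma1 = draws$gamma1[i],
      noise_sigma = spec$noise_sigma, ar1_rho = spec$ar1_rho,
      drift_amplitude = spec$drift_amplitude,
      motion_amplitude = spec$motion_amplitude,
      seed = derive_seed(seed, 10000 + i))
    participants[[i]] <- simulate_participant(sched, truth, params, acq)
    participants[[i]]$id <- draws$id[i]
  }
  structure(list(participants = participants, ledger = draws,
                 spec = spec, seed = seed, params = params, acq = acq),
            class = "cohort")
}

#' Write a cohort's artifacts to disk
#'
#' Per participant: BIDS-style events TSV, one time-series TSV per ROI
#' (columns are runs), and 6-column whitespace-delimited motion parameter
#' files per run; plus a cohort manifest TSV mapping participants to files,
#' group, and symptom scores.
#'
#' @param cohort a `cohort`.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort$participants, function(p) {
    pd <- file.path(dir, p$id)
    dir.create(pd, showWarnings = FALSE)
    write_events(p$schedule, file.path(pd, "events.tsv"))
    for (roi in names(p$rois)) {
      m <- do.call(cbind, p$rois[[roi]]$values)
      colnames(m) <- sprintf("run%02d", seq_len(ncol(m)))
      write_tsv17(as.data.frame(m), file.path(pd, paste0(roi, ".tsv")))
    }
    for (r in seq_along(p$motion)) {
      utils::write.table(format(p$motion[[r]], digits = 10),
                         file.path(pd, sprintf("motion_run%02d.txt", r)),
                         sep = " ", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    }
    data.frame(id = p$id, group = p$truth$group, dir = pd,
               stringsAsFactors = FALSE)
  })
  manifest <- merge(do.call(rbind, rows),
                    cohort$ledger[, c("id", "MAS", "HAMD", "BIS",
                                      "symptoms_missing")], by = "id")
  path <- file.path(dir, "manifest.tsv")
  write_tsv17(manifest, path)
  invisible(path)
}
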