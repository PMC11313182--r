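# Shared fixtures and independent oracles.

# Reduced schedule used where the full 8 x 34 session would be wasteful:
# 32 trials per block keeps the 2 x 2 cells and the exact 25%/75% outcome
# frequencies realizable at any block count.
small_cfg <- function(n_blocks = 1L, seed = 1L)
  schedule_config(n_blocks = n_blocks, trials_per_block = 32L, seed = seed)

# Hand-built schedule with explicit conditions; onsets on a fixed grid.
hand_schedule <- function(probability, stake, outcome, spacing = 12) {
  n <- length(outcome)
  onset <- (seq_len(n) - 1) * spacing
  sched <- data.frame(block = 1L, trial = seq_len(n),
                      probability = rep_len(probability, n),
                      stake = rep_len(stake, n),
                      outcome = outcome,
                      onset_choice = onset,
                      onset_anticipation = onset + 4,
                      onset_outcome = onset + 7.5,
                      duration_anticipation = 3.5,
                      stringsAsFactors = FALSE)
  class(sched) <- c("trial_schedule", "data.frame")
  sched
}

# Independent brute-force momentum recursion, coded straight from the
# update equations on raw vectors (no schedule machinery).
oracle_recursion <- function(o, ev, eta, omega,
                             form = "additive", max_stake = max(abs(o)),
                             h0 = 0) {
  n <- length(o)
  h <- numeric(n + 1); h[1] <- h0
  o_perc <- numeric(n); d_b <- numeric(n)
  for (t in seq_len(n)) {
    o_perc[t] <- if (form == "additive") o[t] + omega * h[t]
                 else o[t] * (1 + omega * h[t] / max_stake)
    d_b[t] <- o_perc[t] - ev[t]
    h[t + 1] <- (1 - eta) * h[t] + eta * d_b[t]
  }
  list(o_perceived = o_perc, delta_biased = d_b,
       h_in = h[seq_len(n)], h_post = h[-1])
}

# Truth with every stochastic/nuisance component switched off, for
# construct-then-recover identities.
noiseless_truth <- function(...) {
  participant_truth(noise_sigma = 0, drift_amplitude = 0,
                    motion_amplitude = 0, ...)
}
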