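#' Momentum-model parameters
#'
#' Parameters of the recursive momentum-biased RPE model. `eta` is the
#' momentum update rate (how quickly the integrated outcome history decays),
#' `bias_weight` (omega) scales how strongly current momentum distorts the
#' perception of the next outcome, and `bias_form` selects the functional
#' form of that distortion. With `bias_weight = 0` or `eta = 0` the model
#' degenerates to the standard unbiased RPE model.
#'
#' The study this pipeline emulates used a fixed group-average bias
#' parameter rather than per-participant fits; the defaults here are
#' documented configuration placeholders, not estimates.
#'
#' @param eta momentum update rate in `[0, 1]`; default 0.3.
#' @param bias_weight momentum-bias strength, `>= 0`; default 0.5.
#' @param bias_form `"additive"` (default): perceived outcome
#'   `o~ = o + bias_weight * h`; or `"multiplicative"`:
#'   `o~ = o * (1 + bias_weight * h / max_stake)`.
#' @param h0 initial momentum entering the first trial; default 0.
#' @return An object of class `model_params`.
#' @export
model_params <- function(eta = 0.3, bias_weight = 0.5,
                         bias_form = c("additive", "multiplicative"),
                         h0 = 0) {
  bias_form <- match.arg(bias_form)
  if (!is.numeric(eta) || length(eta) != 1 || eta < 0 || eta > 1)
    stop("eta must be a single value in [0, 1]", call. = FALSE)
  if (!is.numeric(bias_weight) || length(bias_weight) != 1 || bias_weight < 0)
    stop("bias_weight must be a single nonnegative value", call. = FALSE)
  structure(list(eta = eta, bias_weight = bias_weight,
                 bias_form = bias_form, h0 = h0),
            class = "model_params")
}

#' Expected value of a Roulette trial
#'
#' Win yields `+stake`, loss yields `-stake`, so the expectation is
#' `(2 * probability - 1) * stake`.
#'
#' @param probability win probability, strictly inside (0, 1).
#' @param stake stake in currency units, `> 0`.
#' @return Expected value in currency units (vectorized).
#' @export
#' @examples
#' expected_value(0.75, 9)   # 4.5
#' expected_value(0.25, 3)   # -1.5
expected_value <- function(probability, stake) {
  if (any(!is.finite(probability)) || any(probability <= 0) || any(probability >= 1))
    stop("probability must lie strictly inside (0, 1)", call. = FALSE)
  if (any(!is.finite(stake)) || any(stake <= 0))
    stop("stake must be positive", call. = FALSE)
  (2 * probability - 1) * stake
}

signed_outcome <- function(schedule) {
  ifelse(schedule$outcome == "win", schedule$stake, -schedule$stake)
}

#' Unbiased reward prediction errors
#'
#' The standard (veridical) RPE: signed outcome minus expected value,
#' `delta_t = o_t - EV_t`.
#'
#' @param schedule a `trial_schedule`.
#' @return A data frame (class `rpe_trace`) with columns `block`, `trial`,
#'   `ev`, `outcome_signed`, `delta`.
#' @export
unbiased_rpes <- function(schedule) {
  validate_schedule(schedule)
  o <- signed_outcome(schedule)
  ev <- expected_value(schedule$probability, schedule$stake)
  tr <- data.frame(block = schedule$block, trial = schedule$trial,
                   ev = ev, outcome_signed = o, delta = o - ev)
  class(tr) <- c("rpe_trace", "data.frame")
  tr
}

#' Momentum-biased reward prediction errors
#'
#' Forward recursion over trials. Momentum `h` integrates recent biased
#' RPEs; the momentum entering a trial distorts the perceived outcome,
#' whose prediction error feeds back into momentum — the recursive cycle:
#' \deqn{\tilde o_t = o_t + \omega h_{t-1} \quad \textrm{(additive)}}
#' \deqn{\tilde\delta_t = \tilde o_t - EV_t, \qquad
#'       h_t = (1-\eta) h_{t-1} + \eta \tilde\delta_t}
#' The multiplicative variant uses
#' `o~_t = o_t * (1 + omega * h_{t-1} / max(stake))`. The quantity entered
#' downstream as the momentum-bias parametric modulator is the difference
#' `Delta_t = delta~_t - delta_t` (biased minus unbiased), which under the
#' additive form equals `omega * h_{t-1}` and is therefore decorrelated
#' from the same-trial outcome.
#'
#' @param schedule a `trial_schedule`.
#' @param params a [model_params()].
#' @return An `rpe_trace` data frame with columns `block`, `trial`, `ev`,
#'   `outcome_signed`, `delta`, `h` (momentum entering the trial),
#'   `o_perceived`, `delta_biased`, `pmod_momentum_bias`, and `h_post`
#'   (momentum after the trial's update).
#' @export
biased_rpes <- function(schedule, params = model_params()) {
  validate_schedule(schedule)
  stopifnot(inherits(params, "model_params"))
  tr <- unbiased_rpes(schedule)
  n <- nrow(tr)
  h_in <- numeric(n); h_post <- numeric(n)
  o_perc <- numeric(n); d_b <- numeric(n)
  max_stake <- if (n) max(schedule$stake) else 1
  h <- params$h0
  for (t in seq_len(n)) {
    h_in[t] <- h
    o_perc[t] <- switch(params$bias_form,
      additive = tr$outcome_signed[t] + params$bias_weight * h,
      multiplicative = tr$outcome_signed[t] *
        (1 + params$bias_weight * h / max_stake))
    d_b[t] <- o_perc[t] - tr$ev[t]
    h <- (1 - params$eta) * h + params$eta * d_b[t]
    if (!is.finite(h) || !is.finite(d_b[t]))
      stop("non-finite momentum recursion at trial ", t, call. = FALSE)
    h_post[t] <- h
  }
  tr$h <- h_in
  tr$o_perceived <- o_perc
  tr$delta_biased <- d_b
  tr$pmod_momentum_bias <- d_b - tr$delta
  tr$h_post <- h_post
  tr
}

#' Momentum series aligned to outcome events
#'
#' The per-trial momentum values `h_t` (after each trial's update) from the
#' recursive biased model, used as the parametric modulator in the separate
#' momentum GLM.
#'
#' @inheritParams biased_rpes
#' @return Numeric vector, one value per trial.
#' @export
momentum_series <- function(schedule, params = model_params()) {
  biased_rpes(schedule, params)$h_post
}

#' Carryover regressors without modeling assumptions
#'
#' The model-free confirmatory check: previous-trial RPE, current RPE, and
#' their product, with the first trial's lagged terms set to 0.
#'
#' @param schedule a `trial_schedule` with at least 2 trials.
#' @return Data frame with columns `delta_prev`, `delta`, `interaction`.
#' @export
carryover_regressors <- function(schedule) {
  tr <- unbiased_rpes(schedule)
  if (nrow(tr) < 2)
    stop("carryover regressors need at least 2 trials", call. = FALSE)
  prev <- c(0, tr$delta[-nrow(tr)])
  data.frame(delta_prev = prev, delta = tr$delta,
             interaction = prev * tr$delta)
}

#' Accumulated RPE history with no perception bias
#'
#' The simpler confirmatory model: an exponential moving average of the
#' unbiased RPEs, `h_t = (1 - eta) h_{t-1} + eta delta_t` with `h_0 = 0`.
#' There is no feedback into outcome perception.
#'
#' @param schedule a `trial_schedule`.
#' @param eta update rate in `[0, 1]`.
#' @return Numeric vector of accumulated history, one value per trial.
#' @export
momentum_only_regressor <- function(schedule, eta = 0.3) {
  if (!is.numeric(eta) || length(eta) != 1 || eta < 0 || eta > 1)
    stop("eta must be a single value in [0, 1]", call. = FALSE)
  d <- unbiased_rpes(schedule)$delta
  h <- numeric(length(d))
  prev <- 0
  for (t in seq_along(d)) {
    prev <- (1 - eta) * prev + eta * d[t]
    h[t] <- prev
  }
  h
}

#' Write / read an RPE trace
#'
#' TSV with one row per trial; doubles round-trip bit-exactly.
#'
#' @param trace an `rpe_trace` data frame.
#' @param path file path.
#' @return `path` (writer) or the trace (reader).
#' @export
write_trace <- function(trace, path) write_tsv17(as.data.frame(trace), path)

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  tr <- read_tsv(path)
  class(tr) <- c("rpe_trace", "data.frame")
  tr
}
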