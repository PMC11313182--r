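#' Roulette-task schedule configuration
#'
#' Describes one session of the probabilistic Roulette task: trials are a
#' fully crossed 2 x 2 design of win probability (25% / 75%) and stake
#' (3 / 9 currency units), pseudorandomized within blocks so that the
#' conditions are balanced, with win/loss outcomes realized at exactly the
#' nominal frequencies at session level.
#'
#' @param n_blocks number of blocks (runs); default 8.
#' @param trials_per_block trials per block; default 34.
#' @param probabilities the two win probabilities; default `c(0.25, 0.75)`.
#' @param stakes the two stakes in currency units; default `c(3, 9)`.
#' @param choice_duration seconds allotted to the choice phase.
#' @param anticipation_range two seconds values; the wheel spins for a
#'   uniformly jittered duration in this interval (default 3-4 s).
#' @param outcome_duration seconds the outcome is displayed.
#' @param iti_range inter-trial interval range in seconds, uniform jitter.
#' @param seed integer seed controlling trial order and jitter. Marginal
#'   condition counts are identical for every seed; only order varies.
#' @return An object of class `schedule_config`.
#' @export
schedule_config <- function(n_blocks = 8L, trials_per_block = 34L,
                            probabilities = c(0.25, 0.75),
                            stakes = c(3, 9),
                            choice_duration = 4,
                            anticipation_range = c(3, 4),
                            outcome_duration = 2,
                            iti_range = c(1, 2),
                            seed = 1L) {
  n_blocks <- as.integer(n_blocks)
  trials_per_block <- as.integer(trials_per_block)
  stopifnot(n_blocks >= 1, trials_per_block >= 1,
            length(probabilities) == 2, length(stakes) == 2,
            all(probabilities > 0 & probabilities < 1),
            all(stakes > 0),
            length(anticipation_range) == 2,
            anticipation_range[1] <= anticipation_range[2],
            length(iti_range) == 2, iti_range[1] <= iti_range[2],
            choice_duration > 0, outcome_duration > 0)
  cfg <- list(n_blocks = n_blocks, trials_per_block = trials_per_block,
              probabilities = sort(probabilities), stakes = sort(stakes),
              choice_duration = choice_duration,
              anticipation_range = anticipation_range,
              outcome_duration = outcome_duration,
              iti_range = iti_range, seed = as.integer(seed))
  class(cfg) <- "schedule_config"
  cfg
}

# Per-block 2x2 cell counts satisfying: each probability level and each stake
# level gets exactly trials_per_block / 2 trials per block, and each of the
# four cells gets exactly total / 4 trials over the session. With 34 trials a
# block the cells alternate 9/8 between blocks.
block_cell_counts <- function(cfg) {
  tpb <- cfg$trials_per_block
  total <- cfg$n_blocks * tpb
  if (total %% 4L != 0L)
    stop("cannot balance probability x stake cells: ", total,
         " total trials is not divisible by 4", call. = FALSE)
  if (tpb %% 2L != 0L)
    stop("cannot balance probability and stake within blocks: ",
         tpb, " trials per block is odd", call. = FALSE)
  half <- tpb %/% 2L
  if (tpb %% 4L == 0L) {
    a <- rep(tpb %/% 4L, cfg$n_blocks)
  } else {
    if (cfg$n_blocks %% 2L != 0L)
      stop("cannot balance probability x stake cells: trials_per_block = ",
           tpb, " needs an even number of blocks", call. = FALSE)
    a <- rep(c(tpb %/% 4L + 1L, tpb %/% 4L), length.out = cfg$n_blocks)
  }
  # rows = blocks; columns = cells (p_lo:s_lo, p_lo:s_hi, p_hi:s_lo, p_hi:s_hi)
  cbind(a, half - a, half - a, a, deparse.level = 0)
}

#' Generate a balanced pseudorandomized trial schedule
#'
#' Builds one session: equal counts of every probability x stake cell at
#' session level, equal probability and stake marginals within every block,
#' and win/loss outcomes realized at exactly the nominal frequency within
#' each cell (exact-frequency assignment, not Bernoulli draws), then
#' shuffled within blocks. Event onsets accumulate choice, jittered
#' anticipation, outcome, and jittered inter-trial durations; onsets are
#' seconds from the start of each block's run.
#'
#' @param config a [schedule_config()].
#' @return A `trial_schedule`: a data frame with one row per trial and
#'   columns `block`, `trial` (index within block), `probability`, `stake`,
#'   `outcome` (`"win"`/`"loss"`), `onset_choice`, `onset_anticipation`,
#'   `onset_outcome`, `duration_anticipation`; the config is attached as
#'   attribute `config`.
#' @export
#' @examples
#' sched <- generate_schedule(schedule_config(seed = 7))
#' nrow(sched)                       # 272
#' table(sched$probability, sched$stake)
generate_schedule <- function(config = schedule_config()) {
  stopifnot(inherits(config, "schedule_config"))
  counts <- block_cell_counts(config)
  total <- config$n_blocks * config$trials_per_block
  per_cell <- total %/% 4L
  cells <- expand.grid(stake = config$stakes,
                       probability = config$probabilities)[, c(2, 1)]

  # exact-frequency outcome multisets per cell
  wins_per_cell <- config$probabilities[c(1, 1, 2, 2)] * per_cell
  bad <- which(abs(wins_per_cell - round(wins_per_cell)) > 1e-9)
  if (length(bad)) {
    stop(sprintf(
      "cannot realize exact outcome frequencies in cell (p = %g, stake = %g): %g wins of %d trials is not integral",
      cells$probability[bad[1]], cells$stake[bad[1]],
      wins_per_cell[bad[1]], per_cell), call. = FALSE)
  }
  wins_per_cell <- as.integer(round(wins_per_cell))

  with_seed(config$seed, {
    cell_outcomes <- lapply(seq_len(4), function(k) {
      sample(rep(c("win", "loss"), c(wins_per_cell[k], per_cell - wins_per_cell[k])))
    })
    taken <- integer(4)
    rows <- vector("list", config$n_blocks)
    for (b in seq_len(config$n_blocks)) {
      cell_idx <- rep(seq_len(4), counts[b, ])
      outcome <- character(length(cell_idx))
      for (k in seq_len(4)) {
        sel <- which(cell_idx == k)
        outcome[sel] <- cell_outcomes[[k]][taken[k] + seq_along(sel)]
        taken[k] <- taken[k] + length(sel)
      }
      ord <- sample.int(length(cell_idx))
      cell_idx <- cell_idx[ord]; outcome <- outcome[ord]

      n <- length(cell_idx)
      antic <- stats::runif(n, config$anticipation_range[1], config$anticipation_range[2])
      iti <- stats::runif(n, config$iti_range[1], config$iti_range[2])
      trial_len <- config$choice_duration + antic + config$outcome_duration + iti
      onset_choice <- cumsum(c(0, trial_len[-n]))
      rows[[b]] <- data.frame(
        block = b,
        trial = seq_len(n),
        probability = cells$probability[cell_idx],
        stake = cells$stake[cell_idx],
        outcome = outcome,
        onset_choice = onset_choice,
        onset_anticipation = onset_choice + config$choice_duration,
        onset_outcome = onset_choice + config$choice_duration + antic,
        duration_anticipation = antic,
        stringsAsFactors = FALSE)
    }
    sched <- do.call(rbind, rows)
    rownames(sched) <- NULL
    attr(sched, "config") <- config
    class(sched) <- c("trial_schedule", "data.frame")
    sched
  })
}

validate_schedule <- function(schedule) {
  req <- c("block", "trial", "probability", "stake", "outcome",
           "onset_choice", "onset_anticipation", "onset_outcome",
           "duration_anticipation")
  miss <- setdiff(req, names(schedule))
  if (length(miss))
    stop("schedule is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(schedule) == 0) return(invisible(schedule))
  if (!all(schedule$outcome %in% c("win", "loss")))
    stop("schedule outcomes must be 'win' or 'loss'", call. = FALSE)
  bad <- schedule$onset_choice < 0 |
    schedule$onset_anticipation <= schedule$onset_choice |
    schedule$onset_outcome <= schedule$onset_anticipation
  if (any(bad))
    stop("non-increasing or negative onsets at schedule row ", which(bad)[1],
         call. = FALSE)
  invisible(schedule)
}

#' Write a trial schedule as a BIDS-style events table
#'
#' One row per event (choice, anticipation, outcome per trial), tab
#' separated, with columns `onset`, `duration`, `trial_type`, `probability`,
#' `stake`, `outcome`, `block`, `trial`. Onsets are seconds from run start
#' with a period decimal separator; doubles are written with enough digits
#' to round-trip bit-exactly.
#'
#' @param schedule a `trial_schedule`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(schedule, path) {
  validate_schedule(schedule)
  cfg <- attr(schedule, "config")
  choice_dur <- if (!is.null(cfg)) cfg$choice_duration else 4
  outcome_dur <- if (!is.null(cfg)) cfg$outcome_duration else 2
  if (nrow(schedule) == 0) {
    ev <- data.frame(onset = double(), duration = double(),
                     trial_type = character(), probability = double(),
                     stake = double(), outcome = character(),
                     block = integer(), trial = integer())
  } else {
    base <- schedule[rep(seq_len(nrow(schedule)), each = 3), ]
    type <- rep(c("choice", "anticipation", "outcome"), nrow(schedule))
    onset <- as.vector(rbind(schedule$onset_choice,
                             schedule$onset_anticipation,
                             schedule$onset_outcome))
    duration <- as.vector(rbind(rep(choice_dur, nrow(schedule)),
                                schedule$duration_anticipation,
                                rep(outcome_dur, nrow(schedule))))
    ev <- data.frame(onset = onset, duration = duration, trial_type = type,
                     probability = base$probability, stake = base$stake,
                     outcome = base$outcome, block = base$block,
                     trial = base$trial, stringsAsFactors = FALSE)
  }
  write_tsv17(ev, path)
}

#' Read an events table back into a trial schedule
#'
#' Inverse of [write_events()]: `read_events(write_events(s, p))` recovers
#' every trial field of `s` bit-exactly.
#'
#' @param path events TSV path.
#' @return A `trial_schedule` data frame (without the generating config).
#' @export
read_events <- function(path) {
  ev <- read_tsv(path)
  req <- c("onset", "duration", "trial_type", "probability", "stake",
           "outcome", "block", "trial")
  miss <- setdiff(req, names(ev))
  if (length(miss))
    stop("events file ", path, ": missing columns ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(ev) == 0) {
    sched <- data.frame(block = integer(), trial = integer(),
                        probability = double(), stake = double(),
                        outcome = character(),
                        onset_choice = double(), onset_anticipation = double(),
                        onset_outcome = double(),
                        duration_anticipation = double())
    class(sched) <- c("trial_schedule", "data.frame")
    return(sched)
  }
  bad <- which(!is.finite(ev$onset) | ev$onset < 0)
  if (length(bad))
    stop("events file ", path, ": negative or non-numeric onset at line ",
         bad[1] + 1L, call. = FALSE)
  if (!all(ev$trial_type %in% c("choice", "anticipation", "outcome")))
    stop("events file ", path, ": unknown trial_type at line ",
         which(!ev$trial_type %in% c("choice", "anticipation", "outcome"))[1] + 1L,
         call. = FALSE)

  key <- paste(ev$block, ev$trial)
  ukey <- unique(key)
  pick <- function(type) ev[ev$trial_type == type, ][match(ukey, key[ev$trial_type == type]), ]
  ch <- pick("choice"); an <- pick("anticipation"); ou <- pick("outcome")
  if (any(is.na(ch$onset)) || any(is.na(an$onset)) || any(is.na(ou$onset)))
    stop("events file ", path, ": trial missing one of its three events",
         call. = FALSE)
  sched <- data.frame(block = as.integer(ch$block), trial = as.integer(ch$trial),
                      probability = as.numeric(ch$probability),
                      stake = as.numeric(ch$stake),
                      outcome = ch$outcome,
                      onset_choice = ch$onset,
                      onset_anticipation = an$onset,
                      onset_outcome = ou$onset,
                      duration_anticipation = an$duration,
                      stringsAsFactors = FALSE)
  sched <- sched[order(sched$block, sched$trial), ]
  rownames(sched) <- NULL
  class(sched) <- c("trial_schedule", "data.frame")
  validate_schedule(sched)
  sched
}
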