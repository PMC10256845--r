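#' Build the probabilistic shooting-task schedule
#'
#' Constructs the trial-by-trial design of the hostile-expectation learning
#' task: two opponents whose gun probabilities flip between `p_high` and
#' `1 - p_high` at each block boundary, crossed with regular, contiguous
#' high/low-threat blocks that are orthogonal to the gun-probability schedule.
#'
#' The default arguments reproduce the published design: probability blocks of
#' 40, 15, 25, 25, 15 and 40 trials (160 trials in total, five switch points),
#' gun probability 0.8/0.2, and alternating 20-trial threat blocks starting
#' with high threat.
#'
#' @param block_lengths Integer vector of probability-block lengths.
#' @param p_high Gun probability of opponent A in odd blocks; opponent B always
#'   carries `1 - p_gun_A`. Must lie in (0.5, 1).
#' @param threat_period Length of each contiguous threat block; must divide the
#'   total number of trials.
#' @param threat_phase Integer phase offset of the threat alternation, in
#'   trials. With `0` the task starts with a full high-threat block; the
#'   default `10` (half a period) starts with 10 low-threat trials and makes
#'   the threat labels exactly orthogonal to the default gun-probability
#'   blocks (phi coefficient 0).
#' @param flip_phase If `TRUE`, opponent A starts at `1 - p_high` instead
#'   (swaps the two opponents' probabilities trial-wise).
#' @param opponents How opponents interleave across trials: `"alternate"`
#'   (deterministic ABAB...) or `"random"` (seed-controlled permutation with
#'   equal counts per probability block; see `seed`).
#' @param seed Integer seed used when `opponents = "random"`.
#'
#' @return An object of class `hex_schedule`: a data frame with one row per
#'   trial and columns `trial`, `block`, `opponent` (`"A"`/`"B"`), `p_gun`
#'   (gun probability of the opponent shown on that trial), `p_gun_A`, and
#'   `threat` (`"high"`/`"low"`), with the design parameters kept as
#'   attributes.
#' @examples
#' sched <- build_schedule()
#' nrow(sched)            # 160
#' table(sched$threat)    # 80 high / 80 low
#' @export
build_schedule <- function(block_lengths = c(40L, 15L, 25L, 25L, 15L, 40L),
                           p_high = 0.8,
                           threat_period = 20L,
                           threat_phase = 10L,
                           flip_phase = FALSE,
                           opponents = c("alternate", "random"),
                           seed = 1L) {
  opponents <- match.arg(opponents)
  stopifnot(is.numeric(threat_phase), threat_phase >= 0)
  if (length(block_lengths) < 1L || any(block_lengths != round(block_lengths)) ||
      any(block_lengths <= 0)) {
    stop_hex("invalid_design", "block lengths must be positive integers")
  }
  if (!(p_high > 0.5 && p_high < 1)) {
    stop_hex("invalid_design", "p_high must lie in (0.5, 1)")
  }
  n_trials <- sum(block_lengths)
  if (threat_period <= 0 || n_trials %% threat_period != 0) {
    stop_hex("invalid_design",
             "threat_period (%d) must divide the total trial count (%d)",
             as.integer(threat_period), n_trials)
  }

  block <- rep(seq_along(block_lengths), times = block_lengths)
  # opponent A's gun probability flips at every block boundary; p_low is
  # computed once so every trial carries one of exactly two values
  p_low <- round(1 - p_high, 10)  # 1 - 0.8 prints and compares as 0.2
  odd <- (block %% 2L) == 1L
  p_gun_A <- ifelse(xor(odd, flip_phase), p_high, p_low)

  # block index floors toward -Inf, so a positive phase prepends a partial
  # block of the opposite (low) condition before the first full high block
  threat_idx <- ((seq_len(n_trials) - 1L - as.integer(threat_phase)) %/%
                   as.integer(threat_period)) %% 2L
  threat <- ifelse(threat_idx == 0L, "high", "low")

  if (opponents == "alternate") {
    opp <- rep_len(c("A", "B"), n_trials)
  } else {
    opp <- character(n_trials)
    rs <- .save_rng_state()
    on.exit(.restore_rng_state(rs), add = TRUE)
    set.seed(seed)
    for (b in seq_along(block_lengths)) {
      len <- block_lengths[b]
      half <- len %/% 2L
      pool <- c(rep("A", len - half), rep("B", half))
      opp[block == b] <- sample(pool)
    }
  }
  p_gun <- ifelse(opp == "A", p_gun_A, ifelse(p_gun_A == p_high, p_low, p_high))

  out <- data.frame(
    trial = seq_len(n_trials),
    block = block,
    opponent = opp,
    p_gun = p_gun,
    p_gun_A = p_gun_A,
    threat = threat,
    stringsAsFactors = FALSE
  )
  structure(out,
            class = c("hex_schedule", "data.frame"),
            block_lengths = as.integer(block_lengths),
            p_high = p_high,
            threat_period = as.integer(threat_period),
            threat_phase = as.integer(threat_phase),
            flip_phase = flip_phase,
            opponents = opponents)
}

#' @export
print.hex_schedule <- function(x, ...) {
  bl <- attr(x, "block_lengths")
  cat(sprintf("Task schedule: %d trials, %d probability blocks (%s)\n",
              nrow(x), length(bl), paste(bl, collapse = ", ")))
  cat(sprintf("  p(gun) in {%.2g, %.2g}; threat period %d, phase offset %d\n",
              attr(x, "p_high"), 1 - attr(x, "p_high"),
              attr(x, "threat_period"), attr(x, "threat_phase")))
  invisible(x)
}

.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' Draw gun/phone outcome sequences from a schedule
#'
#' Realizes the schedule's per-trial gun probabilities as binary outcomes
#' (`1` = gun, `0` = phone). `"bernoulli"` draws each trial independently;
#' `"exact_proportion"` fixes, within every probability block and opponent,
#' the gun count to the nearest integer `round(p * n)` and permutes positions.
#'
#' @param schedule A `hex_schedule` from [build_schedule()].
#' @param seed Integer seed; the same seed always yields the same sequence.
#' @param mode `"bernoulli"` or `"exact_proportion"`.
#' @return Integer vector of outcomes (`u`), one per trial, with the seed and
#'   mode kept as attributes.
#' @examples
#' sched <- build_schedule()
#' u <- sample_outcomes(sched, seed = 1)
#' mean(u[sched$p_gun == 0.8])
#' @export
sample_outcomes <- function(schedule, seed = 1L,
                            mode = c("bernoulli", "exact_proportion")) {
  mode <- match.arg(mode)
  stopifnot(inherits(schedule, "hex_schedule"))
  rs <- .save_rng_state()
  on.exit(.restore_rng_state(rs), add = TRUE)
  set.seed(seed)
  n <- nrow(schedule)
  u <- integer(n)
  if (mode == "bernoulli") {
    u <- rbinom(n, 1L, schedule$p_gun)
  } else {
    for (b in unique(schedule$block)) {
      for (o in unique(schedule$opponent)) {
        idx <- which(schedule$block == b & schedule$opponent == o)
        if (!length(idx)) next
        k <- round(schedule$p_gun[idx[1]] * length(idx))
        cell <- c(rep(1L, k), rep(0L, length(idx) - k))
        u[idx] <- sample(cell)
      }
    }
  }
  structure(as.integer(u), seed = as.integer(seed), mode = mode)
}

#' Build a hostile-interpretation (face-judgement) task design
#'
#' Trial list for the binary hostile/not-hostile face-judgement task: four
#' emotions (anger, disgust, fear, joy) at five morph intensities (20--100%),
#' each repeated `repetitions` times, plus neutral trials and separately
#' flagged practice trials. The published design uses 8 repetitions, 8 neutral
#' trials and 16 practice trials: 168 main trials.
#'
#' @param repetitions Repetitions per emotion-by-intensity cell.
#' @param n_neutral Number of neutral (intensity `NA`) main trials.
#' @param n_practice Number of practice trials (flagged, drawn from random
#'   cells).
#' @param seed Integer seed for shuffling.
#' @return A data frame of class `hex_hibt_design` with columns `trial`,
#'   `emotion`, `intensity` (percent, `NA` for neutral) and `is_practice`.
#' @examples
#' d <- build_hibt_design()
#' sum(!d$is_practice)   # 168
#' @export
build_hibt_design <- function(repetitions = 8L, n_neutral = 8L,
                              n_practice = 16L, seed = 1L) {
  if (repetitions < 0 || n_neutral < 0 || n_practice < 0) {
    stop_hex("invalid_design", "counts must be non-negative")
  }
  rs <- .save_rng_state()
  on.exit(.restore_rng_state(rs), add = TRUE)
  set.seed(seed)
  emotions <- c("anger", "disgust", "fear", "joy")
  intensities <- c(20L, 40L, 60L, 80L, 100L)
  cells <- expand.grid(emotion = emotions, intensity = intensities,
                       stringsAsFactors = FALSE)
  main <- cells[rep(seq_len(nrow(cells)), each = repetitions), , drop = FALSE]
  if (n_neutral > 0) {
    main <- rbind(main, data.frame(emotion = rep("neutral", n_neutral),
                                   intensity = rep(NA_integer_, n_neutral)))
  }
  if (nrow(main) > 1) main <- main[sample(nrow(main)), , drop = FALSE]
  practice <- if (n_practice > 0) {
    pick <- sample(nrow(cells), n_practice, replace = TRUE)
    cells[pick, , drop = FALSE]
  } else cells[0, , drop = FALSE]
  out <- rbind(
    data.frame(practice, is_practice = rep(TRUE, nrow(practice))),
    data.frame(main, is_practice = rep(FALSE, nrow(main)))
  )
  out$trial <- seq_len(nrow(out))
  rownames(out) <- NULL
  out <- out[, c("trial", "emotion", "intensity", "is_practice")]
  structure(out, class = c("hex_hibt_design", "data.frame"),
            repetitions = as.integer(repetitions),
            n_neutral = as.integer(n_neutral),
            n_practice = as.integer(n_practice), seed = as.integer(seed))
}
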