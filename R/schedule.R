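#' Build a cued-response trial schedule
#'
#' Generates the block/trial/stimulus layout of a two-choice cued-response
#' experiment: `blocks` blocks of `trials_per_block` audio-track trials, each
#' trial presenting `stimuli_per_trial` response cues separated by
#' inter-stimulus intervals drawn evenly from `isi_set`. Condition ordering is
#' constrained: no two consecutive trials share a condition (across block
#' boundaries), and no condition appears more than `max_per_block` times
#' within one block. Within a trial no ISI value repeats twice in a row, and
#' cued hands are balanced (half left, half right per trial).
#'
#' The default parameters give 4 blocks x 10 trials x 40 cues = 1600 cued
#' responses, 800 per hand and 400 (200 per hand) for each of the four
#' listening conditions.
#'
#' @param blocks number of blocks.
#' @param trials_per_block trials (audio tracks) per block.
#' @param stimuli_per_trial response cues per trial.
#' @param trial_duration trial length in seconds (includes the lead-in).
#' @param lead_in seconds of warm-up audio before the first cue.
#' @param iti inter-trial interval in seconds, applied between consecutive
#'   trials within a block.
#' @param isi_set candidate inter-stimulus intervals in milliseconds.
#' @param stimulus_duration_ms duration of each response cue in milliseconds.
#' @param conditions character vector of condition labels; its length must
#'   divide the total trial count.
#' @param max_per_block maximum trials of one condition per block.
#' @param seed integer seed; schedules are deterministic given the seed.
#'
#' @return An object of class `trial_schedule`: the call parameters plus an
#'   `events` data frame with one row per cue
#'   (`block`, `trial`, `condition`, `stimulus_index`, `onset_time` in
#'   seconds relative to trial start, `hand`).
#' @export
build_schedule <- function(blocks = 4L, trials_per_block = 10L,
                           stimuli_per_trial = 40L, trial_duration = 65,
                           lead_in = 5, iti = 5,
                           isi_set = c(1100, 1200, 1300, 1400),
                           stimulus_duration_ms = 200,
                           conditions = c("high_groove", "low_groove",
                                          "noise", "silence"),
                           max_per_block = 3L, seed = 1L) {
  n_trials <- blocks * trials_per_block
  if (length(isi_set) == 0L) stopf("isi_set must be non-empty")
  if (n_trials %% length(conditions) != 0L)
    stopf("number of conditions (%d) must divide total trials (%d)",
          length(conditions), n_trials)
  with_seed(seed, {
    cond_seq <- sample_condition_sequence(conditions, blocks,
                                          trials_per_block, max_per_block)
    ev <- vector("list", n_trials)
    for (tr in seq_len(n_trials)) {
      hands <- trial_hands(stimuli_per_trial)
      isis <- trial_isis(stimuli_per_trial - 1L, isi_set)
      onsets <- lead_in +
        c(0, cumsum(rep(stimulus_duration_ms / 1000, stimuli_per_trial - 1L) +
                      isis / 1000))
      if (max(onsets) > trial_duration)
        stopf("cues do not fit: last onset %.2f s exceeds trial duration %g s",
              max(onsets), trial_duration)
      ev[[tr]] <- data.frame(
        block = (tr - 1L) %/% trials_per_block + 1L,
        trial = tr,
        condition = cond_seq[tr],
        stimulus_index = seq_len(stimuli_per_trial),
        onset_time = onsets,
        hand = hands,
        stringsAsFactors = FALSE)
    }
    structure(list(blocks = blocks, trials_per_block = trials_per_block,
                   stimuli_per_trial = stimuli_per_trial,
                   trial_duration = trial_duration, lead_in = lead_in,
                   iti = iti, isi_set = isi_set,
                   stimulus_duration_ms = stimulus_duration_ms,
                   conditions = conditions, seed = seed,
                   events = do.call(rbind, ev)),
              class = "trial_schedule")
  })
}

# Condition sequence with the adjacency and per-block constraints.
sample_condition_sequence <- function(conditions, blocks, trials_per_block,
                                      max_per_block, max_tries = 500L) {
  n_trials <- blocks * trials_per_block
  per_cond <- n_trials %/% length(conditions)
  if (length(conditions) > 1L && per_cond > ceiling(n_trials / 2))
    stopf("no-adjacent-repeat ordering is infeasible")
  for (try in seq_len(max_tries)) {
    remaining <- stats::setNames(rep(per_cond, length(conditions)), conditions)
    out <- character(n_trials)
    ok <- TRUE
    for (i in seq_len(n_trials)) {
      blk <- (i - 1L) %/% trials_per_block + 1L
      in_block <- out[seq_len(i - 1L)][
        ((seq_len(i - 1L)) - 1L) %/% trials_per_block + 1L == blk]
      cand <- conditions[remaining[conditions] > 0L]
      if (i > 1L) cand <- setdiff(cand, out[i - 1L])
      cand <- cand[vapply(cand, function(x) sum(in_block == x), integer(1)) <
                     max_per_block]
      if (length(cand) == 0L) { ok <- FALSE; break }
      w <- remaining[cand]
      pick <- if (length(cand) == 1L) cand else sample(cand, 1L, prob = w)
      out[i] <- pick
      remaining[pick] <- remaining[pick] - 1L
    }
    if (ok) return(out)
  }
  stopf("could not satisfy condition-ordering constraints after %d tries",
        max_tries)
}

trial_hands <- function(n) {
  n_left <- n %/% 2L
  extra <- if (n %% 2L == 1L) sample(c("left", "right"), 1L) else character(0)
  sample(c(rep("left", n_left), rep("right", n - n_left - length(extra)),
           extra))
}

trial_isis <- function(n, isi_set) {
  if (n <= 0L) return(numeric(0))
  pool <- rep(isi_set, length.out = ceiling(n / length(isi_set)) *
                length(isi_set))[seq_len(n)]
  if (length(isi_set) == 1L) return(pool)
  as.numeric(shuffle_no_repeat(as.character(pool)))
}

#' Block and total duration of a schedule
#'
#' Block duration counts the trials plus the inter-trial intervals between
#' them (none after the last trial of a block); between-block breaks are
#' participant-determined and excluded.
#'
#' @param schedule a [build_schedule()] result.
#' @return list with `block_minutes` and `total_minutes`.
#' @export
schedule_duration <- function(schedule) {
  stopifnot(inherits(schedule, "trial_schedule"))
  block_min <- (schedule$trials_per_block * schedule$trial_duration +
                  (schedule$trials_per_block - 1L) * schedule$iti) / 60
  list(block_minutes = block_min,
       total_minutes = schedule$blocks * block_min)
}

#' Cued-response counts by hand and condition
#'
#' @param schedule a [build_schedule()] result.
#' @return list with `total`, `per_hand` and `per_condition_hand` tables.
#' @export
response_counts <- function(schedule) {
  stopifnot(inherits(schedule, "trial_schedule"))
  ev <- schedule$events
  list(total = nrow(ev),
       per_hand = table(ev$hand),
       per_condition = table(ev$condition),
       per_condition_hand = table(ev$condition, ev$hand))
}

#' @export
print.trial_schedule <- function(x, ...) {
  cat(sprintf("Trial schedule: %d blocks x %d trials x %d cues (seed %d)\n",
              x$blocks, x$trials_per_block, x$stimuli_per_trial, x$seed))
  d <- schedule_duration(x)
  cat(sprintf("  conditions: %s\n", paste(x$conditions, collapse = ", ")))
  cat(sprintf("  block %.2f min, total %.2f min\n",
              d$block_minutes, d$total_minutes))
  invisible(x)
}

# Absolute onset time (s) of every cue when trials are laid out back to back
# with the ITI between trials of a block (blocks concatenate directly; the
# participant-determined break has no fixed length).
absolute_onsets <- function(schedule) {
  ev <- schedule$events
  within_block_trial <- (ev$trial - 1L) %% schedule$trials_per_block
  trial_start <- (ev$block - 1L) * schedule$trials_per_block *
    schedule$trial_duration +
    (ev$block - 1L) * (schedule$trials_per_block - 1L) * schedule$iti +
    within_block_trial * (schedule$trial_duration + schedule$iti)
  trial_start + ev$onset_time
}
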