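#' Default reduced electrode montage
#'
#' Approximate 10/20 positions (unit-circle head coordinates) for the
#' channels the LRP analysis consumes: the motor pair C3/C4, vertex Cz,
#' frontals Fp1/Fp2, mastoid references M1/M2 and two ocular channels.
#' Positions are only used for distance-weighted channel interpolation.
#'
#' @return data frame with `label`, `x`, `y` and logical `scalp`.
#' @export
default_montage <- function() {
  data.frame(
    label = c("C3", "C4", "Cz", "Fp1", "Fp2", "M1", "M2", "VEOG", "HEOG"),
    x = c(-0.40, 0.40, 0.00, -0.31, 0.31, -1.05, 1.05, -0.35, -1.10),
    y = c(0.00, 0.00, 0.00, 0.95, 0.95, -0.35, -0.35, 1.15, 0.60),
    scalp = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

# Blink scalp-propagation gains relative to VEOG.
blink_propagation <- c(VEOG = 1, Fp1 = 0.55, Fp2 = 0.55, HEOG = 0.10,
                       Cz = 0.15, C3 = 0.08, C4 = 0.08, M1 = 0.02, M2 = 0.02)

#' Construct a continuous EEG recording object
#'
#' @param data numeric matrix, channels x samples, microvolts.
#' @param srate sampling rate in Hz.
#' @param channels character vector of channel labels (rows of `data`).
#' @param events data frame with at least `sample` and `code`; event samples
#'   must lie within the data.
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, srate, channels,
                          events = data.frame(sample = integer(0),
                                              code = character(0))) {
  data <- as.matrix(data)
  if (srate <= 0) stopf("srate must be positive")
  if (nrow(data) != length(channels))
    stopf("data has %d rows but %d channel labels given",
          nrow(data), length(channels))
  if (nrow(events) && (any(events$sample < 1) ||
                       any(events$sample > ncol(data))))
    stopf("event samples outside the recording")
  rownames(data) <- channels
  structure(list(data = data, srate = srate, channels = channels,
                 events = events), class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$data), ncol(x$data), x$srate, ncol(x$data) / x$srate,
              nrow(x$events)))
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}

#' Raised-cosine motor-potential template
#'
#' Smooth ramp from zero to `peak_amp` over `rise_ms`, then a raised-cosine
#' decay back to zero over `fall_ms`. The half-peak point of the rising limb
#' sits exactly at `rise_ms / 2`, which is the analytic ground truth for
#' 50%-of-peak onset scoring.
#'
#' @param srate sampling rate Hz.
#' @param rise_ms,fall_ms ramp durations in ms.
#' @param peak_amp peak amplitude, microvolts.
#' @return numeric vector of template samples.
#' @export
lrp_template <- function(srate, rise_ms = 120, fall_ms = 200,
                         peak_amp = -2.5) {
  n_up <- max(2L, round(rise_ms / 1000 * srate))
  n_dn <- max(2L, round(fall_ms / 1000 * srate))
  up <- 0.5 * (1 - cos(pi * seq(0, 1, length.out = n_up)))
  dn <- 0.5 * (1 + cos(pi * seq(0, 1, length.out = n_dn + 1L)[-1L]))
  peak_amp * c(up, dn)
}

# Biphasic blink waveform: dominant positive lobe then a smaller undershoot.
blink_waveform <- function(srate, duration_ms, amp) {
  n <- max(4L, round(duration_ms / 1000 * srate))
  n1 <- round(0.7 * n)
  lobe1 <- sin(pi * seq(0, 1, length.out = n1))
  lobe2 <- -0.25 * sin(pi * seq(0, 1, length.out = n - n1))
  amp * c(lobe1, lobe2)
}

#' Simulate a continuous EEG recording with known embedded LRPs
#'
#' For every correct response a lateralized raised-cosine negativity is added
#' to the electrode contralateral to the pressed hand (right hand to C3, left
#' hand to C4), starting `lrp_onset` ms (plus any per-condition onset offset)
#' after the cue. Blinks are added as biphasic frontal/ocular deflections at
#' `blink_rate` per minute with fixed scalp-propagation gains, and broadband
#' Gaussian noise at `noise_sd` microvolts on all channels. Stimulus and
#' response events are written to the event table.
#'
#' @param schedule a [build_schedule()] result.
#' @param responses a [sample_behavior()] table aligned with the schedule.
#' @param subject a [subject_params()] object.
#' @param seed integer seed (noise and blink placement).
#' @param srate simulation sampling rate, Hz.
#' @param montage montage data frame, see [default_montage()].
#' @return an [eeg_recording()] whose events carry `code`
#'   ("stimulus"/"response"), `condition`, `hand`, `rt` and `correct`.
#' @export
simulate_recording <- function(schedule, responses, subject, seed = 1L,
                               srate = 256, montage = default_montage()) {
  stopifnot(inherits(schedule, "trial_schedule"),
            inherits(subject, "subject_params"))
  if (nrow(responses) != nrow(schedule$events))
    stopf("responses do not align with schedule events")
  channels <- montage$label
  onsets <- absolute_onsets(schedule)
  total_s <- max(onsets) + 3  # tail room for the last epoch
  n <- ceiling(total_s * srate)
  with_seed(seed, {
    data <- if (subject$noise_sd > 0)
      matrix(stats::rnorm(length(channels) * n, 0, subject$noise_sd),
             nrow = length(channels)) else
      matrix(0, nrow = length(channels), ncol = n)
    rownames(data) <- channels

    stim_sample <- round(onsets * srate) + 1L
    resp_sample <- round((onsets + responses$rt / 1000) * srate) + 1L

    # lateralized templates on correct responses only
    tpl_starts <- numeric(0)
    for (i in seq_len(nrow(responses))) {
      if (!responses$correct[i]) next
      cond <- responses$condition[i]
      amp <- subject$lrp_peak_amp + condition_effect(subject, cond, "amp")
      onset_ms <- subject$lrp_onset + condition_effect(subject, cond, "onset")
      tpl <- lrp_template(srate, subject$lrp_rise, subject$lrp_fall, amp)
      start <- stim_sample[i] + round(onset_ms / 1000 * srate)
      idx <- start:(start + length(tpl) - 1L)
      keep <- idx >= 1L & idx <= n
      target <- if (responses$pressed_hand[i] == "right") "C3" else "C4"
      data[target, idx[keep]] <- data[target, idx[keep]] + tpl[keep]
      tpl_starts <- c(tpl_starts, start)
    }
    if (length(tpl_starts) > 1L) {
      tpl_len <- length(lrp_template(srate, subject$lrp_rise,
                                     subject$lrp_fall, subject$lrp_peak_amp))
      if (min(diff(sort(tpl_starts))) < tpl_len)
        warning("inter-event spacing shorter than the LRP template; ",
                "templates overlap", call. = FALSE)
    }

    # blinks
    n_blinks <- stats::rpois(1, subject$blink_rate * total_s / 60)
    if (n_blinks > 0) {
      b_on <- sort(stats::runif(n_blinks, 0, total_s))
      for (b in b_on) {
        wf <- blink_waveform(srate, stats::runif(1, 100, 400),
                             stats::runif(1, 100, 200))
        start <- round(b * srate) + 1L
        idx <- start:(start + length(wf) - 1L)
        keep <- idx >= 1L & idx <= n
        for (ch in names(blink_propagation)) {
          if (!ch %in% channels) next
          data[ch, idx[keep]] <- data[ch, idx[keep]] +
            blink_propagation[[ch]] * wf[keep]
        }
      }
    }

    ev <- rbind(
      data.frame(sample = stim_sample, code = "stimulus",
                 condition = responses$condition, hand = responses$pressed_hand,
                 cued_hand = responses$hand, rt = responses$rt,
                 correct = responses$correct, stringsAsFactors = FALSE),
      data.frame(sample = resp_sample, code = "response",
                 condition = responses$condition, hand = responses$pressed_hand,
                 cued_hand = responses$hand, rt = responses$rt,
                 correct = responses$correct, stringsAsFactors = FALSE))
    ev <- ev[ev$sample >= 1 & ev$sample <= n, ]
    ev <- ev[order(ev$sample), ]
    eeg_recording(data, srate, channels, ev)
  })
}
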