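#' Extract event-locked epochs with baseline correction
#'
#' Cuts fixed windows around stimulus or response events and subtracts the
#' per-epoch, per-channel mean over the baseline window. Default windows
#' follow the usual LRP conventions: stimulus-locked epochs run -200 to
#' +800 ms with a -200 to 0 ms baseline; response-locked epochs run -800 to
#' +200 ms with a -800 to -600 ms baseline (1000 ms epochs either way, each
#' starting at its baseline start).
#'
#' Events whose window falls outside the recording are dropped and counted
#' with reason `"other"`.
#'
#' @param rec an [eeg_recording()] whose events carry `code`, `condition`,
#'   `hand`, `rt`, `correct`.
#' @param lock `"stimulus"` or `"response"`.
#' @param window,baseline 2-vectors in ms relative to the locking event;
#'   `baseline` must lie within `window`.
#' @return object of class `epoch_set`: `data` (epochs x channels x samples),
#'   `times` (ms), `meta` (one row per epoch: condition, hand, rt, correct,
#'   rejected, reason), plus `lock`, `window`, `baseline`, `srate`,
#'   `channels`, `n_dropped_edge`.
#' @export
extract_epochs <- function(rec, lock = c("stimulus", "response"),
                           window = NULL, baseline = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  lock <- match.arg(lock)
  if (is.null(window))
    window <- if (lock == "stimulus") c(-200, 800) else c(-800, 200)
  if (is.null(baseline))
    baseline <- if (lock == "stimulus") c(-200, 0) else c(-800, -600)
  if (baseline[1] < window[1] || baseline[2] > window[2])
    stopf("baseline must lie within the epoch window")
  ev <- rec$events[rec$events$code == lock, , drop = FALSE]
  if (nrow(ev) == 0L) stopf("no '%s' events in recording", lock)
  s0 <- round(window[1] / 1000 * rec$srate)
  s1 <- round(window[2] / 1000 * rec$srate)
  times <- (s0:s1) / rec$srate * 1000
  b_idx <- which(times >= baseline[1] & times <= baseline[2])
  n_samp <- length(times)
  ok <- ev$sample + s0 >= 1 & ev$sample + s1 <= ncol(rec$data)
  dropped <- sum(!ok)
  ev <- ev[ok, , drop = FALSE]
  n_ep <- nrow(ev)
  dat <- array(NA_real_, dim = c(n_ep, nrow(rec$data), n_samp),
               dimnames = list(NULL, rec$channels, NULL))
  for (i in seq_len(n_ep)) {
    seg <- rec$data[, (ev$sample[i] + s0):(ev$sample[i] + s1), drop = FALSE]
    seg <- seg - rowMeans(seg[, b_idx, drop = FALSE])
    dat[i, , ] <- seg
  }
  meta <- data.frame(condition = ev$condition, hand = ev$hand,
                     rt = ev$rt, correct = ev$correct,
                     rejected = FALSE, reason = NA_character_,
                     stringsAsFactors = FALSE)
  structure(list(data = dat, times = times, lock = lock, window = window,
                 baseline = baseline, meta = meta, srate = rec$srate,
                 channels = rec$channels, n_dropped_edge = dropped),
            class = "epoch_set")
}

#' Serialize an epoch set or rejection report
#'
#' The epoch array travels as R's native serialized container with the
#' per-epoch metadata alongside as CSV; the rejection report as JSON.
#'
#' @param epochs an [extract_epochs()] result.
#' @param path output path (`.rds`); the metadata CSV is written next to it
#'   with suffix `_meta.csv`.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  saveRDS(epochs, path)
  utils::write.csv(epochs$meta,
                   sub("\\.rds$", "_meta.csv", path, ignore.case = TRUE),
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  ep <- readRDS(path)
  stopifnot(inherits(ep, "epoch_set"))
  ep
}

#' @rdname write_epochs
#' @param report a `rejection_report`.
#' @export
write_rejection_json <- function(report, path) {
  stopifnot(inherits(report, "rejection_report"))
  jsonlite::write_json(list(counts = as.list(report$counts),
                            n_total = report$n_total,
                            n_rejected = report$n_rejected,
                            rate = report$rate,
                            excluded = report$excluded),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rule-based trial rejection
#'
#' Flags epochs, in strict precedence, as: `incorrect` (wrong hand pressed),
#' `during_stimulus` (response before stimulus offset, i.e. RT below the
#' stimulus duration), `rt_gt_1200` (RT strictly greater than `rt_max_ms`),
#' and `blink` (any ocular/frontal sample exceeding `blink_threshold`
#' microvolts in absolute value within the epoch). A subject whose rejection
#' rate exceeds 0.30 is flagged for exclusion.
#'
#' @param epochs an [extract_epochs()] result (meta must carry rt/correct).
#' @param blink_threshold microvolts, on channels matching `blink_channels`.
#' @param blink_channels labels scanned for blinks.
#' @param stimulus_duration_ms duration of the response cue.
#' @param rt_max_ms slow-response cutoff (strictly greater than).
#' @return list with the flagged `epochs` and a `rejection_report`
#'   (counts by reason, totals, rate, `excluded` flag).
#' @export
reject_trials <- function(epochs, blink_threshold = 75,
                          blink_channels = c("VEOG", "HEOG", "Fp1", "Fp2"),
                          stimulus_duration_ms = 200, rt_max_ms = 1200) {
  stopifnot(inherits(epochs, "epoch_set"))
  meta <- epochs$meta
  blink_channels <- intersect(blink_channels, epochs$channels)
  n <- nrow(meta)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (!isTRUE(meta$correct[i])) reason[i] <- "incorrect"
    else if (meta$rt[i] < stimulus_duration_ms) reason[i] <- "during_stimulus"
    else if (meta$rt[i] > rt_max_ms) reason[i] <- "rt_gt_1200"
    else if (length(blink_channels) &&
             max(abs(epochs$data[i, blink_channels, ])) > blink_threshold)
      reason[i] <- "blink"
  }
  meta$rejected <- !is.na(reason)
  meta$reason <- reason
  epochs$meta <- meta
  counts <- c(incorrect = sum(reason == "incorrect", na.rm = TRUE),
              during_stimulus = sum(reason == "during_stimulus", na.rm = TRUE),
              rt_gt_1200 = sum(reason == "rt_gt_1200", na.rm = TRUE),
              blink = sum(reason == "blink", na.rm = TRUE),
              other = epochs$n_dropped_edge)
  n_total <- n + epochs$n_dropped_edge
  rate <- (sum(meta$rejected) + epochs$n_dropped_edge) / n_total
  report <- structure(list(counts = counts, n_total = n_total,
                           n_rejected = sum(meta$rejected) +
                             epochs$n_dropped_edge,
                           rate = rate, excluded = rate > 0.30),
                      class = "rejection_report")
  list(epochs = epochs, report = report)
}

#' @export
print.rejection_report <- function(x, ...) {
  cat(sprintf("Rejection report: %d/%d epochs rejected (rate %.3f%s)\n",
              x$n_rejected, x$n_total, x$rate,
              if (x$excluded) ", subject excluded >30%" else ""))
  print(x$counts)
  invisible(x)
}

#' Per-cell average waveforms at the LRP electrodes
#'
#' Arithmetic mean over surviving (non-rejected) epochs for every
#' (condition, hand, channel) cell.
#'
#' @param epochs a flagged [epoch_set][extract_epochs()].
#' @param channels channels to average (the LRP pair by default).
#' @return object of class `cell_averages`: `avg[[condition]][[hand]]` is a
#'   channels x time matrix; plus `counts`, `times`, `lock`, `srate`.
#' @export
average_by_cell <- function(epochs, channels = c("C3", "C4")) {
  stopifnot(inherits(epochs, "epoch_set"))
  keep <- !epochs$meta$rejected
  meta <- epochs$meta[keep, , drop = FALSE]
  dat <- epochs$data[keep, channels, , drop = FALSE]
  conds <- unique(meta$condition)
  hands <- c("left", "right")
  avg <- list(); counts <- list()
  for (cond in conds) {
    avg[[cond]] <- list()
    for (h in hands) {
      sel <- meta$condition == cond & meta$hand == h
      if (!any(sel))
        stopf("no surviving epochs in cell (%s, %s)", cond, h)
      m <- apply(dat[sel, , , drop = FALSE], c(2, 3), mean)
      rownames(m) <- channels
      avg[[cond]][[h]] <- m
      counts[[paste(cond, h, sep = ".")]] <- sum(sel)
    }
  }
  structure(list(avg = avg, counts = unlist(counts), times = epochs$times,
                 lock = epochs$lock, srate = epochs$srate),
            class = "cell_averages")
}
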