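#' Coles-method LRP difference wave
#'
#' Double subtraction averaging out non-lateralized activity:
#' `LRP(t) = 0.5 * [ (C4 - C3)(t) on left-hand trials
#'                 + (C3 - C4)(t) on right-hand trials ]`.
#' Motor preparation contralateral to the responding hand appears as a
#' negative deflection under this convention. Amplitudes are stored signed in
#' microvolts; no negative-up plotting assumption is made.
#'
#' @param cell_averages an [average_by_cell()] result.
#' @param condition which condition's cells to combine.
#' @return object of class `lrp_wave`: `values` (microvolts), `times` (ms),
#'   `lock`, `condition`, `n_trials`, `srate`, `filtered_15hz` flag.
#' @export
coles_lrp <- function(cell_averages, condition) {
  stopifnot(inherits(cell_averages, "cell_averages"))
  cells <- cell_averages$avg[[condition]]
  if (is.null(cells)) stopf("condition '%s' not present", condition)
  L <- cells$left; R <- cells$right
  if (is.null(L) || is.null(R) || ncol(L) != ncol(R))
    stopf("left/right cell averages missing or on mismatched time grids")
  values <- 0.5 * ((L["C4", ] - L["C3", ]) + (R["C3", ] - R["C4", ]))
  structure(list(values = as.numeric(values), times = cell_averages$times,
                 lock = cell_averages$lock, condition = condition,
                 n_trials = sum(cell_averages$counts[startsWith(
                   names(cell_averages$counts), paste0(condition, "."))]),
                 srate = cell_averages$srate, filtered_15hz = FALSE),
            class = "lrp_wave")
}

#' Construct an LRP wave directly
#'
#' Convenience constructor used by simulations and tests.
#' @param values microvolt series.
#' @param times ms grid (strictly increasing).
#' @param srate sampling rate Hz.
#' @param lock,condition metadata labels.
#' @export
lrp_wave <- function(values, times, srate, lock = "stimulus",
                     condition = "none") {
  if (any(diff(times) <= 0)) stopf("times must be strictly increasing")
  structure(list(values = as.numeric(values), times = as.numeric(times),
                 lock = lock, condition = condition, n_trials = NA_integer_,
                 srate = srate, filtered_15hz = FALSE), class = "lrp_wave")
}

#' Low-pass an LRP wave for onset scoring
#'
#' Onset latency is scored on a 15 Hz low-passed copy because the 50%-of-peak
#' criterion is noise sensitive; mean amplitude must be measured on the
#' original wide-band wave, which is why the filtered flag is enforced by
#' both [mean_amplitude()] and this function (double filtering refused).
#'
#' @param wave an [lrp_wave()].
#' @param cutoff_hz half-amplitude cutoff (default 15 Hz).
#' @export
lowpass_for_onset <- function(wave, cutoff_hz = 15) {
  stopifnot(inherits(wave, "lrp_wave"))
  if (isTRUE(wave$filtered_15hz)) stopf("wave is already low-pass filtered")
  wave$values <- butter_filtfilt(wave$values, wave$srate, cutoff_hz, "low", 2)
  wave$filtered_15hz <- TRUE
  wave
}

# 50%-of-peak onset of a single wave. Finds the extremum in `polarity`
# within the search window, then the earliest criterion crossing before it,
# linearly interpolated between samples.
onset_of_wave <- function(values, times, criterion = 0.5,
                          polarity = c("negative", "positive", "auto"),
                          search_window = NULL) {
  polarity <- match.arg(polarity)
  idx <- if (is.null(search_window)) seq_along(times) else
    which(times >= search_window[1] & times <= search_window[2])
  if (length(idx) < 2L) stopf("search window too narrow")
  v <- values[idx]; tt <- times[idx]
  sgn <- switch(polarity,
                negative = -1,
                positive = 1,
                auto = if (abs(min(v)) >= abs(max(v))) -1 else 1)
  w <- sgn * v  # peak is now a maximum
  ip <- which.max(w)
  peak <- w[ip]
  if (peak <= 0) stopf("wave has no deflection in the requested polarity")
  thr <- criterion * peak
  cross <- which(w[seq_len(ip)] >= thr)
  if (length(cross) == 0L) stopf("wave never reaches the onset criterion")
  j <- cross[1L]
  if (j == 1L) {
    onset <- tt[1L]
  } else {
    # linear interpolation between samples j-1 and j
    frac <- (thr - w[j - 1L]) / (w[j] - w[j - 1L])
    onset <- tt[j - 1L] + frac * (tt[j] - tt[j - 1L])
  }
  list(onset = onset, peak_amp = sgn * peak, peak_ms = tt[ip])
}

#' Jackknife onset-latency estimate
#'
#' Scores onset as the earliest time the grand-average wave reaches
#' `criterion` (default 50%) of its peak amplitude, with linear interpolation
#' between samples. The same scoring is applied to each leave-one-subject-out
#' grand average; their dispersion gives the jackknife standard error
#' `sqrt(((n-1)/n) * sum((o_i - mean(o))^2))`. The leave-one-out scores are
#' the per-subject values used for jackknife-based group statistics (see
#' [jackknife_adjust()]).
#'
#' @param subject_lrps list of [lrp_wave()]s (one per subject, same grid),
#'   low-pass filtered for onset scoring.
#' @param criterion fraction of peak in (0, 1).
#' @param polarity peak polarity; LRPs are negative by convention.
#' @param search_window optional ms pair restricting the peak search.
#' @return object of class `lrp_onset`: `onset_ms`, `criterion`, `peak_amp`,
#'   `peak_ms`, `jackknife_values`, `se_jackknife`, `n`.
#' @export
onset_latency_jackknife <- function(subject_lrps, criterion = 0.5,
                                    polarity = "negative",
                                    search_window = NULL) {
  n <- length(subject_lrps)
  if (n < 3L) stopf("need at least 3 subjects for jackknife scoring")
  if (criterion <= 0 || criterion >= 1) stopf("criterion must be in (0, 1)")
  if (!all(vapply(subject_lrps, function(w) isTRUE(w$filtered_15hz),
                  logical(1))))
    warning("onset scoring on unfiltered waves; apply lowpass_for_onset() ",
            "first", call. = FALSE)
  times <- subject_lrps[[1L]]$times
  M <- vapply(subject_lrps, function(w) {
    if (length(w$values) != length(times)) stopf("mismatched time grids")
    w$values
  }, numeric(length(times)))
  grand <- rowMeans(M)
  full <- onset_of_wave(grand, times, criterion, polarity, search_window)
  loo <- vapply(seq_len(n), function(i) {
    onset_of_wave(rowMeans(M[, -i, drop = FALSE]), times, criterion,
                  polarity, search_window)$onset
  }, numeric(1))
  se <- sqrt((n - 1) / n * sum((loo - mean(loo))^2))
  structure(list(onset_ms = full$onset, criterion = criterion,
                 peak_amp = full$peak_amp, peak_ms = full$peak_ms,
                 jackknife_values = loo, se_jackknife = se, n = n),
            class = "lrp_onset")
}

#' @export
print.lrp_onset <- function(x, ...) {
  cat(sprintf(
    "LRP onset: %.1f ms (%.0f%% of %.2f uV peak at %.1f ms), jackknife SE %.1f ms, n = %d\n",
    x$onset_ms, 100 * x$criterion, x$peak_amp, x$peak_ms, x$se_jackknife,
    x$n))
  invisible(x)
}

#' @description Plot an LRP difference wave (microvolts over ms; a dashed
#'   line marks the locking event).
#' @param x an `lrp_wave`.
#' @param ... passed to [graphics::plot()].
#' @export
#' @rdname coles_lrp
plot.lrp_wave <- function(x, ...) {
  graphics::plot(x$times, x$values, type = "l",
                 xlab = sprintf("time (ms, %s-locked)", x$lock),
                 ylab = "amplitude (uV)",
                 main = sprintf("LRP: %s%s", x$condition,
                                if (isTRUE(x$filtered_15hz))
                                  " (15 Hz low-passed)" else ""), ...)
  graphics::abline(v = 0, lty = 2)
  graphics::abline(h = 0, col = "grey")
  invisible(x)
}

#' Adjust a test statistic computed on jackknife scores
#'
#' Statistics computed on leave-one-out scores are inflated because the
#' scores are nearly identical by construction; dividing F by (n-1)^2 (or t
#' by n-1) restores the correct type-I error rate.
#'
#' @param statistic F or t value computed on jackknife scores.
#' @param n number of subjects.
#' @param type `"F"` or `"t"`.
#' @export
jackknife_adjust <- function(statistic, n, type = c("F", "t")) {
  type <- match.arg(type)
  if (n < 2L) stopf("need n >= 2")
  if (type == "F") statistic / (n - 1)^2 else statistic / (n - 1)
}

#' Mean amplitude of an LRP wave over a window
#'
#' Arithmetic mean of the (already baseline-corrected) wave within the
#' window. Must be measured on the wide-band wave, not the 15 Hz low-passed
#' copy used for onset scoring.
#'
#' @param wave an [lrp_wave()].
#' @param window ms pair, inclusive.
#' @export
mean_amplitude <- function(wave, window) {
  stopifnot(inherits(wave, "lrp_wave"))
  if (isTRUE(wave$filtered_15hz))
    stopf("mean amplitude must be measured on the unfiltered wave")
  idx <- which(wave$times >= window[1] & wave$times <= window[2])
  if (length(idx) == 0L) stopf("empty measurement window")
  mean(wave$values[idx])
}
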