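#' Band-pass filter specification
#'
#' Half-amplitude (-6 dB) cutoff convention: the filter is realized as an
#' order `rolloff_db_oct / 6` Butterworth high-pass/low-pass cascade applied
#' forward and backward (zero phase). Each single pass contributes -3 dB at
#' its design cutoff, so the two-pass magnitude is exactly -6 dB (half
#' amplitude) at the requested cutoffs.
#'
#' @param low_hz,high_hz half-amplitude cutoffs in Hz; `low_hz = 0` disables
#'   the high-pass stage, `high_hz = Inf` the low-pass stage.
#' @param rolloff_db_oct single-pass roll-off, one of 12, 24, 48 dB/octave.
#' @export
filter_spec <- function(low_hz = 0.05, high_hz = 100, rolloff_db_oct = 12) {
  if (!rolloff_db_oct %in% c(12, 24, 48))
    stopf("rolloff_db_oct must be 12, 24 or 48")
  if (low_hz < 0 || high_hz <= low_hz)
    stopf("need 0 <= low_hz < high_hz")
  structure(list(low_hz = low_hz, high_hz = high_hz,
                 rolloff_db_oct = rolloff_db_oct, family = "butterworth"),
            class = "filter_spec")
}

# Direct-form IIR with zero initial conditions; the MA taps are applied by
# vector shifts and the AR part by stats::filter's C recursion, which is
# much faster than an R-level loop on long recordings.
iir_pass <- function(b, a, x) {
  n <- length(x)
  xm <- b[1L] * x
  for (j in seq_along(b)[-1L])
    xm[j:n] <- xm[j:n] + b[j] * x[1L:(n - j + 1L)]
  if (length(a) > 1L)
    xm <- as.numeric(stats::filter(xm, -a[-1L] / a[1L],
                                   method = "recursive"))
  xm / a[1L]
}

# Zero-phase Butterworth on a numeric vector: the signal mean is removed,
# the remainder is filtered forward and backward from rest (with a short
# zero-pad to flush the reversed transient), and the mean is restored scaled
# by the squared DC gain. Constants therefore pass a low-pass exactly and
# vanish exactly under a high-pass, without exciting step transients.
butter_filtfilt <- function(x, srate, cutoff, type, order) {
  bf <- signal::butter(order, cutoff / (srate / 2), type = type)
  g_dc <- sum(bf$b) / sum(bf$a)
  n <- length(x)
  m <- mean(x)
  pad <- 2L * max(length(bf$a), length(bf$b))
  y <- iir_pass(bf$b, bf$a, c(x - m, numeric(pad)))
  y <- rev(iir_pass(bf$b, bf$a, rev(y)))
  y[seq_len(n)] + m * g_dc^2
}

#' Re-reference a recording
#'
#' Subtracts the instantaneous mean of the reference channels from every
#' channel. The event table is untouched.
#'
#' @param rec an [eeg_recording()].
#' @param ref_channels labels of the reference channels (default: the two
#'   mastoids).
#' @export
rereference <- function(rec, ref_channels = c("M1", "M2")) {
  stopifnot(inherits(rec, "eeg_recording"))
  missing_ref <- setdiff(ref_channels, rec$channels)
  if (length(missing_ref))
    stopf("reference channel(s) not in recording: %s",
          paste(missing_ref, collapse = ", "))
  ref <- colMeans(rec$data[ref_channels, , drop = FALSE])
  rec$data <- sweep(rec$data, 2L, ref, "-")
  rec
}

#' Zero-phase Butterworth band-pass filter
#'
#' High-pass and low-pass stages are applied as a cascade (numerically more
#' stable than a single band-pass design when the high-pass corner sits at
#' 0.05 Hz) with `signal::filtfilt`, giving zero phase shift and -6 dB
#' attenuation at the stated cutoffs.
#'
#' @param rec an [eeg_recording()].
#' @param spec a [filter_spec()].
#' @export
bandpass <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(spec, "filter_spec"))
  nyq <- rec$srate / 2
  if (is.finite(spec$high_hz) && spec$high_hz >= nyq)
    stopf("high_hz (%g) must be below the Nyquist frequency (%g)",
          spec$high_hz, nyq)
  ord <- spec$rolloff_db_oct / 6
  for (ch in seq_len(nrow(rec$data))) {
    x <- rec$data[ch, ]
    if (spec$low_hz > 0)
      x <- butter_filtfilt(x, rec$srate, spec$low_hz, "high", ord)
    if (is.finite(spec$high_hz))
      x <- butter_filtfilt(x, rec$srate, spec$high_hz, "low", ord)
    rec$data[ch, ] <- x
  }
  rec
}

#' Interpolate bad channels from their neighbors
#'
#' Replaces each bad channel by an inverse-squared-distance weighted average
#' of the good scalp channels. The LRP channels C3 and C4 must never be
#' interpolated (the analysis would be measuring reconstructed data).
#'
#' @param rec an [eeg_recording()].
#' @param bad labels of channels to rebuild.
#' @param montage montage with positions, see [default_montage()].
#' @export
interpolate_channels <- function(rec, bad, montage = default_montage()) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (length(bad) == 0L) return(rec)
  if (any(bad %in% c("C3", "C4")))
    stopf("refusing to interpolate C3/C4: these carry the LRP signal")
  missing_ch <- setdiff(bad, rec$channels)
  if (length(missing_ch))
    stopf("unknown channel(s): %s", paste(missing_ch, collapse = ", "))
  pos <- montage[match(rec$channels, montage$label), ]
  donors <- rec$channels[!(rec$channels %in% bad) &
                           pos$scalp %in% TRUE]
  if (length(donors) == 0L) stopf("no good scalp channels left to donate")
  for (b in bad) {
    pb <- montage[montage$label == b, ]
    d2 <- (montage$x[match(donors, montage$label)] - pb$x)^2 +
      (montage$y[match(donors, montage$label)] - pb$y)^2
    w <- 1 / pmax(d2, 1e-12)
    w <- w / sum(w)
    rec$data[b, ] <- as.numeric(w %*% rec$data[donors, , drop = FALSE])
  }
  rec
}

#' Attenuate ocular artifacts by EOG regression
#'
#' Estimates per-channel EOG propagation coefficients by least squares on
#' blink-rich segments (samples where any EOG channel exceeds
#' `blink_sd_threshold` robust SDs, dilated by 200 ms) and subtracts the
#' fitted EOG contribution from every non-EOG channel. With no detectable
#' blink activity the coefficients are estimated on the full recording and
#' are near zero for uncorrelated EOG.
#'
#' @param rec an [eeg_recording()].
#' @param eog_channels EOG channel labels.
#' @param blink_sd_threshold robust-SD multiplier defining blink-rich samples.
#' @export
regress_ocular <- function(rec, eog_channels = c("VEOG", "HEOG"),
                           blink_sd_threshold = 3) {
  stopifnot(inherits(rec, "eeg_recording"))
  eog_channels <- intersect(eog_channels, rec$channels)
  if (length(eog_channels) == 0L) stopf("no EOG channel present")
  flat <- vapply(eog_channels,
                 function(ch) stats::sd(rec$data[ch, ]) == 0, logical(1))
  eog_channels <- eog_channels[!flat]
  if (length(eog_channels) == 0L) return(rec)  # no ocular activity at all
  E <- t(rec$data[eog_channels, , drop = FALSE])
  if (qr(E)$rank < ncol(E)) stopf("EOG channels are rank deficient")
  n <- nrow(E)
  # blink-rich mask
  dev <- abs(scale(E, center = TRUE, scale = apply(E, 2, stats::mad)))
  mask <- rowSums(dev > blink_sd_threshold, na.rm = TRUE) > 0
  if (any(mask)) {
    halo <- round(0.2 * rec$srate)
    idx <- which(mask)
    mask <- rep(FALSE, n)
    for (k in -halo:halo) {
      shifted <- idx + k
      mask[shifted[shifted >= 1 & shifted <= n]] <- TRUE
    }
  } else mask <- rep(TRUE, n)
  Ef <- scale(E[mask, , drop = FALSE], center = TRUE, scale = FALSE)
  targets <- setdiff(rec$channels, eog_channels)
  XtX <- crossprod(Ef)
  for (ch in targets) {
    y <- rec$data[ch, mask] - mean(rec$data[ch, mask])
    beta <- solve(XtX, crossprod(Ef, y))
    rec$data[ch, ] <- rec$data[ch, ] -
      as.numeric(t(beta) %*% rec$data[eog_channels, , drop = FALSE])
  }
  rec
}
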