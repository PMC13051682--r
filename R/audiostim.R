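#' Gated noise-burst probes for silence-condition trials
#'
#' In the active-listening variant the silence condition carries no music to
#' modulate, so the response cues are brief white-noise bursts presented
#' either loudly (`+depth_db` re baseline) or softly (`-depth_db`), on the
#' same event grid as [embed_intensity_changes()]: `duration_ms` bursts with
#' `ramp_ms` amplitude ramps, gaps drawn evenly from `isi_set` with no
#' immediate repeat.
#'
#' @param duration track length in seconds.
#' @param srate sampling rate Hz.
#' @param n_loud,n_soft counts of loud/soft bursts.
#' @param baseline_amp linear amplitude of a 0 dB burst.
#' @param depth_db level change of loud (+) and soft (-) bursts re baseline.
#' @param duration_ms,ramp_ms burst duration and ramp length.
#' @param isi_set inter-event gaps in ms.
#' @param lead_in_s seconds before the first burst.
#' @param seed integer seed.
#' @return list with the `track` (silence plus bursts) and `events`
#'   (direction `"up"` for loud, `"down"` for soft).
#' @export
gated_noise_probes <- function(duration, srate, n_loud = 20L, n_soft = 20L,
                               baseline_amp = 0.1, depth_db = 15,
                               duration_ms = 300, ramp_ms = 30,
                               isi_set = c(1000, 1100, 1200, 1300),
                               lead_in_s = 5, seed = 1L) {
  n <- round(duration * srate)
  n_ev <- n_loud + n_soft
  with_seed(seed, {
    dirs <- sample(c(rep("up", n_loud), rep("down", n_soft)))
    isis <- trial_isis(n_ev - 1L, isi_set)
    onsets <- lead_in_s + c(0, cumsum(duration_ms / 1000 + isis / 1000))
    if (max(onsets) + duration_ms / 1000 > duration)
      stopf("bursts do not fit the track (limited by isi_set)")
    x <- numeric(n)
    n_ramp <- round(ramp_ms / 1000 * srate)
    n_burst <- round(duration_ms / 1000 * srate)
    envelope <- c(seq(0, 1, length.out = n_ramp + 1L)[-1L],
                  rep(1, n_burst - 2L * n_ramp),
                  seq(1, 0, length.out = n_ramp + 1L)[-1L])
    for (i in seq_len(n_ev)) {
      amp <- baseline_amp *
        10^((if (dirs[i] == "up") depth_db else -depth_db) / 20)
      start <- round(onsets[i] * srate) + 1L
      idx <- start:(start + length(envelope) - 1L)
      keep <- idx <= n
      x[idx[keep]] <- amp * envelope[keep] *
        stats::rnorm(sum(keep))
    }
    list(track = audio_track(x, srate),
         events = data.frame(onset_s = onsets, direction = dirs,
                             depth_db = depth_db, duration_ms = duration_ms,
                             ramp_ms = ramp_ms, stringsAsFactors = FALSE))
  })
}

#' Point-wise average of audio tracks
#'
#' Tracks must share the sampling rate; lengths are trimmed to the shortest
#' before averaging (the standard rule when pooling same-duration song
#' excerpts that differ by a few samples).
#'
#' @param tracks list of [audio_track()]s.
#' @return an [audio_track()] holding the per-sample mean.
#' @export
average_tracks <- function(tracks) {
  if (length(tracks) == 0L) stopf("empty track list")
  srates <- vapply(tracks, function(t) t$srate, numeric(1))
  if (length(unique(srates)) != 1L) stopf("tracks differ in sampling rate")
  nch <- vapply(tracks, function(t) nrow(t$samples), integer(1))
  if (length(unique(nch)) != 1L) stopf("tracks differ in channel count")
  len <- min(vapply(tracks, function(t) ncol(t$samples), integer(1)))
  acc <- 0
  for (t in tracks) acc <- acc + t$samples[, seq_len(len), drop = FALSE]
  audio_track(acc / length(tracks), srates[1L])
}

#' Smoothed spectral envelope of a track
#'
#' Magnitude spectrum of the (first channel of the) track on the one-sided
#' FFT grid, turned into an upper envelope by a moving maximum followed by a
#' moving-average low-pass, both with windows of `smooth_hz` width.
#'
#' @param track an [audio_track()].
#' @param smooth_hz smoothing window width in Hz.
#' @return object of class `spectral_envelope` with `freqs` (0..Nyquist) and
#'   non-negative `magnitude`.
#' @export
spectral_envelope <- function(track, smooth_hz = 50) {
  stopifnot(inherits(track, "audio_track"))
  x <- track$samples[1L, ]
  n <- length(x)
  if (n == 0L) stopf("empty track")
  mag <- Mod(stats::fft(x))[seq_len(n %/% 2L + 1L)]
  freqs <- (seq_along(mag) - 1L) * track$srate / n
  w <- max(1L, round(smooth_hz / (track$srate / n)))
  env <- moving_max(mag, w)
  env <- stats::filter(c(rep(env[1L], w), env, rep(env[length(env)], w)),
                       rep(1 / (2 * w + 1), 2 * w + 1), sides = 2)
  env <- as.numeric(env)[(w + 1L):(w + length(mag))]
  env[is.na(env)] <- mag[is.na(env)]
  structure(list(freqs = freqs, magnitude = pmax(env, 0)),
            class = "spectral_envelope")
}

moving_max <- function(x, w) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n))
    out[i] <- max(x[max(1L, i - w):min(n, i + w)])
  out
}

#' Synthesize noise spectrally matched to an envelope
#'
#' White Gaussian noise is transformed to the frequency domain, its
#' magnitudes are multiplied by the target envelope (interpolated onto the
#' output FFT grid), and the result is inverse-transformed. The phases stay
#' those of the white noise, i.e. uniform random; only magnitudes are
#' shaped. Each channel is scaled to its own maximum amplitude.
#'
#' @param envelope a [spectral_envelope()].
#' @param duration seconds of output.
#' @param srate output sampling rate Hz.
#' @param seed integer seed.
#' @param channels number of independent noise channels.
#' @return an [audio_track()].
#' @export
synthesize_matched_noise <- function(envelope, duration, srate, seed = 1L,
                                     channels = 1L) {
  stopifnot(inherits(envelope, "spectral_envelope"))
  n <- round(duration * srate)
  if (all(envelope$magnitude == 0))
    warning("zero envelope: output will be silent", call. = FALSE)
  half <- seq_len(n %/% 2L + 1L)
  f_grid <- (half - 1L) * srate / n
  h_half <- stats::approx(envelope$freqs, envelope$magnitude, xout = f_grid,
                          rule = 2)$y
  # full symmetric gain vector matching fft() bin order
  h <- c(h_half, rev(h_half[2L:(n - length(h_half) + 1L)]))
  out <- matrix(0, nrow = channels, ncol = n)
  with_seed(seed, {
    for (ch in seq_len(channels)) {
      wn <- stats::rnorm(n)
      shaped <- Re(stats::fft(stats::fft(wn) * h, inverse = TRUE)) / n
      peak <- max(abs(shaped))
      out[ch, ] <- if (peak > 0) shaped / peak else shaped
    }
  })
  audio_track(out, srate)
}

#' Embed intensity-change response cues into a track
#'
#' Scales the signal by `+/- depth_db` over `duration_ms`, with
#' linear-in-dB onset and offset ramps of `ramp_ms`, at `n_up` increasing
#' and `n_down` decreasing events in shuffled order. Gaps between events are
#' drawn evenly from `isi_set` with no value repeating twice in a row.
#'
#' @param track an [audio_track()].
#' @param n_up,n_down counts of up/down events.
#' @param depth_db intensity change in dB (default 15).
#' @param duration_ms event duration including ramps.
#' @param ramp_ms onset/offset ramp duration.
#' @param isi_set inter-event gaps in ms.
#' @param lead_in_s seconds before the first event.
#' @param seed integer seed.
#' @return list with the modified `track` and `events` (data frame:
#'   `onset_s`, `direction`, `depth_db`, `duration_ms`, `ramp_ms`).
#' @export
embed_intensity_changes <- function(track, n_up = 20L, n_down = 20L,
                                    depth_db = 15, duration_ms = 300,
                                    ramp_ms = 30,
                                    isi_set = c(1000, 1100, 1200, 1300),
                                    lead_in_s = 5, seed = 1L) {
  stopifnot(inherits(track, "audio_track"))
  n_ev <- n_up + n_down
  need_s <- lead_in_s + n_ev * duration_ms / 1000 +
    (n_ev - 1L) * min(isi_set) / 1000
  if (need_s > track$duration)
    stopf("track too short: %d events need >= %.1f s (limited by duration_ms/isi_set)",
          n_ev, need_s)
  with_seed(seed, {
    dirs <- sample(c(rep("up", n_up), rep("down", n_down)))
    isis <- trial_isis(n_ev - 1L, isi_set)
    onsets <- lead_in_s +
      c(0, cumsum(duration_ms / 1000 + isis / 1000))
    if (max(onsets) + duration_ms / 1000 > track$duration)
      stopf("events do not fit the track (limited by isi_set)")
    n <- ncol(track$samples)
    gain_db <- numeric(n)
    n_ramp <- round(ramp_ms / 1000 * track$srate)
    n_hold <- round(duration_ms / 1000 * track$srate) - 2L * n_ramp
    for (i in seq_len(n_ev)) {
      d <- if (dirs[i] == "up") depth_db else -depth_db
      prof <- c(seq(0, d, length.out = n_ramp + 1L)[-1L],
                rep(d, n_hold),
                seq(d, 0, length.out = n_ramp + 1L)[-1L])
      start <- round(onsets[i] * track$srate) + 1L
      idx <- start:(start + length(prof) - 1L)
      keep <- idx <= n
      gain_db[idx[keep]] <- prof[keep]
    }
    track$samples <- sweep(track$samples, 2L, 10^(gain_db / 20), "*")
    list(track = track,
         events = data.frame(onset_s = onsets, direction = dirs,
                             depth_db = depth_db, duration_ms = duration_ms,
                             ramp_ms = ramp_ms, stringsAsFactors = FALSE))
  })
}
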