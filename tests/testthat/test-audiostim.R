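srate_a <- 8000

test_that("average_tracks is the pointwise mean", {
  set.seed(1)
  x <- audio_track(rnorm(srate_a), srate_a)
  expect_equal(average_tracks(rep(list(x), 10))$samples, x$samples)
  neg <- audio_track(-x$samples, srate_a)
  expect_true(all(average_tracks(list(x, neg))$samples == 0))
  tracks <- replicate(3, audio_track(rnorm(srate_a), srate_a),
                      simplify = FALSE)
  manual <- (tracks[[1]]$samples + tracks[[2]]$samples +
               tracks[[3]]$samples) / 3
  expect_equal(average_tracks(tracks)$samples, manual)
  expect_error(average_tracks(list()), "empty")
  expect_error(average_tracks(list(x, audio_track(rnorm(10), 44100))),
               "sampling rate")
})

test_that("spectral envelope localizes tones and flattens white noise", {
  t <- seq(0, 1 - 1 / srate_a, by = 1 / srate_a)
  sine <- audio_track(sin(2 * pi * 440 * t), srate_a)
  env <- spectral_envelope(sine, smooth_hz = 20)
  expect_lt(abs(env$freqs[which.max(env$magnitude)] - 440), 25)
  expect_true(all(env$magnitude >= 0))
  expect_true(all(diff(env$freqs) > 0))

  dc <- audio_track(rep(0.5, srate_a), srate_a)
  env_dc <- spectral_envelope(dc, smooth_hz = 20)
  expect_equal(env_dc$freqs[which.max(env_dc$magnitude)], 0)

  set.seed(7)
  wn <- audio_track(rnorm(4 * srate_a), srate_a)
  env_wn <- spectral_envelope(wn, smooth_hz = 400)
  cv <- sd(env_wn$magnitude) / mean(env_wn$magnitude)
  expect_lt(cv, 0.2)
})

test_that("matched noise inherits the target spectrum", {
  t <- seq(0, 1 - 1 / srate_a, by = 1 / srate_a)
  song <- audio_track(0.9 * sin(2 * pi * 440 * t) +
                        0.05 * sin(2 * pi * 2000 * t), srate_a)
  env <- spectral_envelope(song, smooth_hz = 50)
  noise <- synthesize_matched_noise(env, 1, srate_a, seed = 1)
  expect_lte(max(abs(noise$samples)), 1)
  spec <- Mod(fft(noise$samples[1, ]))[1:(srate_a / 2)]
  f <- (seq_along(spec) - 1)
  band <- function(f0) mean(spec[f > f0 - 50 & f < f0 + 50]^2)
  expect_gt(band(440), 20 * band(1200))   # energy concentrates at the tone
  expect_identical(synthesize_matched_noise(env, 1, srate_a, seed = 2)$samples,
                   synthesize_matched_noise(env, 1, srate_a, seed = 2)$samples)

  flat <- structure(list(freqs = c(0, srate_a / 2), magnitude = c(1, 1)),
                    class = "spectral_envelope")
  wn <- synthesize_matched_noise(flat, 2, srate_a, seed = 3)
  sp <- Mod(fft(wn$samples[1, ]))[2:(srate_a / 2)]
  lf <- log10(seq_along(sp))
  slope <- coef(lm(log10(sp^2) ~ lf))[2]
  expect_lt(abs(slope), 0.1)             # white: spectral slope ~ 0

  silent <- structure(list(freqs = c(0, srate_a / 2), magnitude = c(0, 0)),
                      class = "spectral_envelope")
  expect_warning(synthesize_matched_noise(silent, 0.5, srate_a, seed = 1),
                 "silent")
})

test_that("intensity events obey count, identity and gain contracts", {
  tr <- audio_track(rep(0.1, 70 * srate_a), srate_a)
  emb <- embed_intensity_changes(tr, 20, 20, seed = 3)
  expect_equal(nrow(emb$events), 40L)
  expect_equal(sum(emb$events$direction == "up"), 20L)
  gaps <- round(diff(emb$events$onset_s) * 1000 - 300)
  expect_true(all(gaps %in% c(1000, 1100, 1200, 1300)))
  expect_true(all(diff(gaps) != 0))

  unchanged <- embed_intensity_changes(tr, 5, 5, depth_db = 0, seed = 1)
  expect_equal(unchanged$track$samples, tr$samples)

  one <- embed_intensity_changes(tr, 1, 0, depth_db = 15, seed = 2)
  ev <- one$events[1, ]
  x <- one$track$samples[1, ]
  inside <- round((ev$onset_s + c(0.05, 0.25)) * srate_a)
  outside <- round((ev$onset_s - c(0.6, 0.2)) * srate_a)
  ratio <- sqrt(mean(x[inside[1]:inside[2]]^2) /
                  mean(x[outside[1]:outside[2]]^2))
  expect_equal(ratio, 10^(15 / 20), tolerance = 0.01)

  # ramp continuity: per-sample dB step bounded by depth * Ts / ramp
  gain_db <- 20 * log10(pmax(abs(x / 0.1), 1e-12))
  bound <- 15 * (1000 / srate_a) / 30
  expect_lte(max(abs(diff(gain_db))), bound * 1.01)

  short <- audio_track(rep(0.1, srate_a), srate_a)
  expect_error(embed_intensity_changes(short, 20, 20, seed = 1), "short")
})

test_that("gated noise probes carry the loud/soft level contrast", {
  pr <- gated_noise_probes(70, srate_a, n_loud = 5L, n_soft = 5L, seed = 4)
  expect_equal(nrow(pr$events), 10L)
  x <- pr$track$samples[1, ]
  rms_at <- function(ev) {
    mid <- round((ev$onset_s + c(0.05, 0.25)) * srate_a)
    sqrt(mean(x[mid[1]:mid[2]]^2))
  }
  loud <- sapply(which(pr$events$direction == "up"),
                 function(i) rms_at(pr$events[i, ]))
  soft <- sapply(which(pr$events$direction == "down"),
                 function(i) rms_at(pr$events[i, ]))
  # loud bursts sit ~30 dB above soft ones (+15 vs -15 re baseline)
  expect_equal(20 * log10(mean(loud) / mean(soft)), 30, tolerance = 0.1)
  # silence between events
  gap <- round((pr$events$onset_s[1] - 1) * srate_a)
  expect_equal(max(abs(x[(gap - 100):gap])), 0)
})

test_that("epoch sets and rejection reports roundtrip to disk", {
  rec <- small_recording(seed = 12)
  ep <- extract_epochs(rec, "stimulus")
  f <- tempfile(fileext = ".rds")
  write_epochs(ep, f)
  back <- read_epochs(f)
  expect_equal(back$data, ep$data)
  meta <- read.csv(sub("\\.rds$", "_meta.csv", f))
  expect_equal(nrow(meta), nrow(ep$meta))
  rj <- reject_trials(ep, stimulus_duration_ms = 200)
  fj <- tempfile(fileext = ".json")
  write_rejection_json(rj$report, fj)
  j <- jsonlite::read_json(fj)
  expect_equal(j$rate, rj$report$rate)
  expect_equal(j$counts$blink, unname(rj$report$counts["blink"]))
  unlink(c(f, sub("\\.rds$", "_meta.csv", f), fj))
})

test_that("event placement is seed-deterministic", {
  tr <- audio_track(rep(0.1, 70 * srate_a), srate_a)
  expect_identical(embed_intensity_changes(tr, 10, 10, seed = 9)$events,
                   embed_intensity_changes(tr, 10, 10, seed = 9)$events)
})
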