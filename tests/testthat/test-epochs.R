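test_that("baseline correction zeroes constant data and preserves steps", {
  srate <- 256
  const <- eeg_recording(matrix(5, 2, 4 * srate), srate, c("C3", "C4"),
                         data.frame(sample = 2L * srate, code = "stimulus",
                                    condition = "noise", hand = "left",
                                    rt = 500, correct = TRUE))
  ep <- extract_epochs(const, "stimulus")
  expect_true(all(abs(ep$data) < 1e-12))
  expect_equal(ep$window, c(-200, 800))
  expect_equal(diff(ep$window), 1000)        # 1000 ms epochs
  expect_equal(dim(ep$data)[3], length(ep$times))
  # time grid hits the window bounds to within half a sample
  expect_lt(max(abs(range(ep$times) - ep$window)), 1000 / srate)

  # step of 3 uV starting 100 ms post-event, zero baseline
  dat <- matrix(0, 2, 4 * srate)
  step_start <- 2L * srate + round(0.1 * srate)
  dat[1, step_start:ncol(dat)] <- 3
  rec <- eeg_recording(dat, srate, c("C3", "C4"), const$events)
  ep2 <- extract_epochs(rec, "stimulus")
  expected <- ifelse(ep2$times >= 100, 3, 0)
  expect_equal(as.numeric(ep2$data[1, 1, ]), expected)

  # response-locked defaults
  rrec <- eeg_recording(matrix(0, 2, 4 * srate), srate, c("C3", "C4"),
                        data.frame(sample = 2L * srate, code = "response",
                                   condition = "noise", hand = "left",
                                   rt = 500, correct = TRUE))
  epr <- extract_epochs(rrec, "response")
  expect_equal(epr$window, c(-800, 200))
  expect_equal(epr$baseline, c(-800, -600))
})

test_that("edge events are dropped with reason 'other'", {
  srate <- 256
  rec <- eeg_recording(matrix(0, 1, srate), srate, "C3",
                       data.frame(sample = c(5L, 128L), code = "stimulus",
                                  condition = "noise", hand = "left",
                                  rt = 500, correct = TRUE))
  ep <- extract_epochs(rec, "stimulus", window = c(-100, 100),
                       baseline = c(-100, 0))
  expect_equal(dim(ep$data)[1], 1L)
  expect_equal(ep$n_dropped_edge, 1L)
  rep_ <- reject_trials(ep, blink_channels = character(0))$report
  expect_equal(unname(rep_$counts["other"]), 1L)
  expect_error(extract_epochs(rec, "stimulus", window = c(-100, 100),
                              baseline = c(-200, 0)), "baseline")
})

test_that("rejection applies the rules with the stated precedence", {
  n <- 10
  arr <- array(0, dim = c(n, 2, 50),
               dimnames = list(NULL, c("C3", "VEOG"), NULL))
  meta <- data.frame(condition = "noise", hand = "left",
                     rt = c(1300, 1300, 150, rep(600, n - 3)),
                     correct = c(FALSE, FALSE, FALSE, FALSE, rep(TRUE, n - 4)),
                     rejected = FALSE, reason = NA_character_,
                     stringsAsFactors = FALSE)
  meta$correct[1:3] <- c(TRUE, TRUE, TRUE)
  meta$correct[4:6] <- FALSE                  # 3 incorrect
  meta$rt[4] <- 150                           # incorrect wins over during_stimulus
  ep <- manual_epochs(arr, meta = meta)
  res <- reject_trials(ep, stimulus_duration_ms = 200)
  expect_equal(unname(res$report$counts[c("incorrect", "during_stimulus",
                                          "rt_gt_1200")]),
               c(3L, 1L, 2L))
  expect_equal(res$epochs$meta$reason[4], "incorrect")

  # blink rule and count conservation
  arr[7, "VEOG", 25] <- 120
  ep2 <- manual_epochs(arr, meta = meta)
  res2 <- reject_trials(ep2, blink_threshold = 75,
                        stimulus_duration_ms = 200)
  expect_equal(unname(res2$report$counts["blink"]), 1L)
  # conservation: accepted + rejected = extracted
  expect_equal(res2$report$n_total - res2$report$n_rejected,
               sum(!res2$epochs$meta$rejected))
  expect_equal(sum(res2$report$counts), res2$report$n_rejected)
})

test_that("a rejection rate above 30% flags the subject", {
  arr <- array(0, dim = c(40, 1, 10), dimnames = list(NULL, "C3", NULL))
  meta <- data.frame(condition = "noise", hand = "left", rt = 600,
                     correct = c(rep(FALSE, 13), rep(TRUE, 27)),
                     rejected = FALSE, reason = NA_character_,
                     stringsAsFactors = FALSE)
  res <- reject_trials(manual_epochs(arr, meta = meta),
                       blink_channels = character(0))
  expect_equal(res$report$rate, 0.325)
  expect_true(res$report$excluded)

  meta$correct <- c(rep(FALSE, 12), rep(TRUE, 28))  # exactly 0.30: retained
  res2 <- reject_trials(manual_epochs(arr, meta = meta),
                        blink_channels = character(0))
  expect_false(res2$report$excluded)
})

test_that("rejection is invariant to epoch order", {
  set.seed(4)
  arr <- array(rnorm(20 * 2 * 30), dim = c(20, 2, 30),
               dimnames = list(NULL, c("C3", "VEOG"), NULL))
  arr[, "VEOG", ] <- arr[, "VEOG", ] * 60
  meta <- data.frame(condition = "noise", hand = "left",
                     rt = runif(20, 100, 1400),
                     correct = runif(20) > 0.2, rejected = FALSE,
                     reason = NA_character_, stringsAsFactors = FALSE)
  r1 <- reject_trials(manual_epochs(arr, meta = meta))$report
  perm <- sample(20)
  r2 <- reject_trials(manual_epochs(arr[perm, , , drop = FALSE],
                                    meta = meta[perm, ]))$report
  expect_identical(r1$counts, r2$counts)
})

test_that("baseline correction is idempotent through re-extraction", {
  rec <- small_recording(seed = 6)
  ep1 <- extract_epochs(rec, "stimulus")
  b_idx <- which(ep1$times >= -200 & ep1$times <= 0)
  means <- apply(ep1$data[, , b_idx, drop = FALSE], c(1, 2), mean)
  expect_true(all(abs(means) < 1e-10))
})

test_that("cell averages are means over surviving epochs", {
  one <- array(rnorm(2 * 40), dim = c(1, 2, 40),
               dimnames = list(NULL, c("C3", "C4"), NULL))
  arr <- array(0, dim = c(6, 2, 40), dimnames = dimnames(one))
  for (i in 1:6) arr[i, , ] <- one[1, , ]
  meta <- data.frame(condition = "noise",
                     hand = rep(c("left", "right"), 3), rt = 600,
                     correct = TRUE, rejected = FALSE,
                     reason = NA_character_, stringsAsFactors = FALSE)
  ca <- average_by_cell(manual_epochs(arr, meta = meta))
  expect_equal(ca$avg$noise$left, one[1, , ], tolerance = 1e-12)
  expect_equal(unname(ca$counts["noise.left"]), 3L)

  arr2 <- arr[1:4, , , drop = FALSE]
  arr2[2, , ] <- -arr2[1, , ]       # left-hand pair cancels
  arr2[4, , ] <- -arr2[3, , ]       # right-hand pair cancels
  meta2 <- meta[1:4, ]
  meta2$hand <- c("left", "left", "right", "right")
  ca2 <- average_by_cell(manual_epochs(arr2, meta = meta2))
  expect_true(all(abs(ca2$avg$noise$left) < 1e-12))
  expect_true(all(abs(ca2$avg$noise$right) < 1e-12))
  expect_error(average_by_cell(manual_epochs(arr[1, , , drop = FALSE],
                                             meta = meta[1, ])),
               "right")
})

test_that("averaging concentrates noise at the CLT rate", {
  set.seed(11)
  n <- 400; len <- 64
  signal <- sin(seq(0, 2 * pi, length.out = len))
  arr <- array(NA_real_, dim = c(n, 2, len),
               dimnames = list(NULL, c("C3", "C4"), NULL))
  for (i in seq_len(n))
    arr[i, , ] <- rbind(signal + rnorm(len), signal + rnorm(len))
  meta <- data.frame(condition = "noise",
                     hand = rep(c("left", "right"), n / 2), rt = 600,
                     correct = TRUE, rejected = FALSE,
                     reason = NA_character_, stringsAsFactors = FALSE)
  ca <- average_by_cell(manual_epochs(arr, meta = meta))
  err <- ca$avg$noise$left["C3", ] - signal
  expect_true(all(abs(err) < 3 / sqrt(n / 2) * 3))
})
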