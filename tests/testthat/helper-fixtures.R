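# Small programmatic fixtures shared across test files.

# A compact schedule: 1 block x 4 trials x 12 cues, 3 trials of each
# condition impossible with 4 conditions in 4 trials, so defaults stay valid.
small_schedule <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(blocks = 1L, trials_per_block = 4L, stimuli_per_trial = 12L,
         trial_duration = 25, lead_in = 2, iti = 2, seed = seed),
    list(...))
  do.call(build_schedule, args)
}

# Simulate one subject end to end up to preprocessed recording.
small_recording <- function(seed = 1L, subject = subject_params(),
                            preprocess = TRUE, ...) {
  sch <- small_schedule(seed = seed, ...)
  beh <- sample_behavior(sch, subject, seed = seed + 100L)
  rec <- simulate_recording(sch, beh, subject, seed = seed + 200L)
  if (preprocess) rec <- bandpass(rereference(rec), filter_spec())
  rec
}

# Build an epoch_set directly from an epochs x channels x samples array,
# bypassing the simulator, for arithmetic-level tests.
manual_epochs <- function(arr, srate = 256, lock = "stimulus",
                          meta = NULL, window = c(-200, 800),
                          baseline = c(-200, 0)) {
  n_ep <- dim(arr)[1]
  if (is.null(meta))
    meta <- data.frame(condition = rep("high_groove", n_ep),
                       hand = rep(c("left", "right"), length.out = n_ep),
                       rt = rep(500, n_ep), correct = TRUE,
                       rejected = FALSE, reason = NA_character_,
                       stringsAsFactors = FALSE)
  t0 <- round(window[1] / 1000 * srate)
  times <- (t0:(t0 + dim(arr)[3] - 1L)) / srate * 1000
  structure(list(data = arr, times = times, lock = lock, window = window,
                 baseline = baseline, meta = meta, srate = srate,
                 channels = dimnames(arr)[[2]], n_dropped_edge = 0L),
            class = "epoch_set")
}

# Subject-level LRP wave: raised-cosine template at known onset + filtered
# noise, on the standard stimulus-locked grid.
template_wave <- function(onset_ms = 180, rise = 120, fall = 200,
                          amp = -2.5, noise_sd = 0, srate = 256,
                          window = c(-200, 800)) {
  times <- seq(window[1], window[2], by = 1000 / srate)
  v <- numeric(length(times))
  tpl <- lrp_template(srate, rise, fall, amp)
  i0 <- which.min(abs(times - onset_ms))
  idx <- i0:min(length(v), i0 + length(tpl) - 1L)
  v[idx] <- tpl[seq_along(idx)]
  if (noise_sd > 0) v <- v + rnorm(length(v), 0, noise_sd)
  lrp_wave(v, times, srate)
}

# Independent trapezoid quadrature used as the oracle for the Bayes-factor
# integrators. The t-test oracle integrates the noncentral-t predictive over
# the Cauchy effect-size prior; the correlation oracle integrates the exact
# sampling density of r with the hypergeometric factor evaluated through its
# Euler integral representation (a different route than the series the
# package uses).
oracle_bf_ttest <- function(t, n, scale = sqrt(2) / 2) {
  delta <- seq(-8, 8, length.out = 6001)
  # dt() warns that its noncentral tail precision is limited; the lattice
  # only uses moderate t where the comparison tolerance absorbs it
  f <- suppressWarnings(dt(t, n - 1, ncp = delta * sqrt(n))) *
    dcauchy(delta, 0, scale)
  num <- sum((f[-1] + f[-length(f)]) / 2) * diff(delta[1:2])
  num / dt(t, n - 1)
}

hyp2f1_euler <- function(a, b, cc, z) {
  # 2F1 via Euler's integral (c > b > 0), independent of the series route
  integrand <- function(u) u^(b - 1) * (1 - u)^(cc - b - 1) * (1 - z * u)^(-a)
  exp(lgamma(cc) - lgamma(b) - lgamma(cc - b)) *
    integrate(integrand, 0, 1, rel.tol = 1e-10)$value
}

oracle_bf_correlation <- function(r, n, kappa = 1) {
  a <- 1 / kappa
  lik <- function(rho) (1 - rho^2)^((n - 1) / 2) *
    (1 - rho * r)^(-(n - 1.5)) *
    hyp2f1_euler(0.5, 0.5, n - 0.5, (rho * r + 1) / 2)
  rho <- seq(-0.9999, 0.9999, length.out = 4001)
  f <- vapply(rho, lik, numeric(1)) * dbeta((rho + 1) / 2, a, a) / 2
  num <- sum((f[-1] + f[-length(f)]) / 2) * diff(rho[1:2])
  num / lik(0)
}

# Null replicate for jackknife calibration: n subjects x k conditions of
# identical-truth template waves plus noise, scored by the leave-one-out
# method; returns the adjusted and unadjusted ANOVA p values and the
# pseudovalue score matrix. The calibration question concerns the
# F/(n-1)^2 adjustment itself, so plain within-subject dfs are used:
# sphericity holds by construction, and layering the estimated
# Greenhouse-Geisser correction on top adds its own conservatism.
null_onset_replicate <- function(n = 8, k = 4, noise_sd = 0.6) {
  loo <- matrix(NA_real_, n, k)
  for (j in seq_len(k)) {
    waves <- replicate(n, {
      w <- template_wave(noise_sd = noise_sd)
      lowpass_for_onset(w)
    }, simplify = FALSE)
    est <- onset_latency_jackknife(waves, search_window = c(0, 800))
    loo[, j] <- est$jackknife_values
  }
  fr <- rm_anova_gg(loo)
  f_adj <- jackknife_adjust(fr$statistic, n, "F")
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  pseudo <- n * matrix(colMeans(loo), n, k, byrow = TRUE) - (n - 1) * loo
  list(p_adj = pf(f_adj, df1, df2, lower.tail = FALSE),
       p_unadj = pf(fr$statistic, df1, df2, lower.tail = FALSE),
       pseudo = pseudo)
}
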