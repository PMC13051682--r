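#' Ex-Gaussian random deviates
#'
#' Sum of a Gaussian and an exponential component, the standard descriptive
#' model for reaction-time distributions. Mean is `mu + tau`, variance
#' `sigma^2 + tau^2`.
#'
#' @param n number of draws.
#' @param mu,sigma Gaussian location/scale in ms.
#' @param tau exponential mean in ms; `tau = 0` drops the exponential part.
#' @export
rexgauss <- function(n, mu, sigma, tau) {
  g <- stats::rnorm(n, mu, sigma)
  if (tau > 0) g <- g + stats::rexp(n, rate = 1 / tau)
  g
}

#' Ground-truth parameters for one simulated participant
#'
#' Container for the quantities the simulator embeds, so downstream recovery
#' can be checked against known truth. The negativity convention is that the
#' motor potential is a negative deflection at the electrode contralateral to
#' the responding hand, so `lrp_peak_amp <= 0`.
#'
#' @param lrp_onset template onset in ms after the response cue.
#' @param lrp_peak_amp peak amplitude in microvolts (<= 0).
#' @param lrp_rise ms from template onset to peak (raised-cosine ramp).
#' @param lrp_fall ms from peak back to zero.
#' @param rt_mu,rt_sigma,rt_tau ex-Gaussian reaction-time parameters, ms.
#' @param error_rate probability of pressing the wrong hand.
#' @param blink_rate blink events per minute.
#' @param noise_sd broadband background noise SD, microvolts.
#' @param condition_effects named list of per-condition additive offsets, each
#'   a numeric vector like `c(onset = 0, amp = 0)` (ms and microvolts).
#' @return object of class `subject_params`.
#' @export
subject_params <- function(lrp_onset = 180, lrp_peak_amp = -2.5,
                           lrp_rise = 120, lrp_fall = 200,
                           rt_mu = 350, rt_sigma = 50, rt_tau = 100,
                           error_rate = 0.05, blink_rate = 15,
                           noise_sd = 1, condition_effects = list()) {
  if (error_rate < 0 || error_rate > 1) stopf("error_rate must be in [0, 1]")
  if (any(c(rt_mu, rt_sigma, rt_tau) < 0)) stopf("rt parameters must be >= 0")
  if (lrp_peak_amp > 0)
    stopf("lrp_peak_amp must be <= 0 (negativity convention)")
  structure(list(lrp_onset = lrp_onset, lrp_peak_amp = lrp_peak_amp,
                 lrp_rise = lrp_rise, lrp_fall = lrp_fall,
                 rt_mu = rt_mu, rt_sigma = rt_sigma, rt_tau = rt_tau,
                 error_rate = error_rate, blink_rate = blink_rate,
                 noise_sd = noise_sd, condition_effects = condition_effects),
            class = "subject_params")
}

condition_effect <- function(subject, condition, what = c("onset", "amp")) {
  what <- match.arg(what)
  ce <- subject$condition_effects[[condition]]
  if (is.null(ce) || is.na(ce[what])) 0 else unname(ce[what])
}

#' Simulate behavioral responses for a schedule
#'
#' One row per cued stimulus: an ex-Gaussian reaction time and the pressed
#' hand (the cued hand, flipped with probability `error_rate`).
#'
#' @param schedule a [build_schedule()] result.
#' @param subject a [subject_params()] object.
#' @param seed integer seed.
#' @return data frame with the schedule event columns plus `rt` (ms),
#'   `pressed_hand` and `correct`.
#' @export
sample_behavior <- function(schedule, subject, seed = 1L) {
  stopifnot(inherits(schedule, "trial_schedule"),
            inherits(subject, "subject_params"))
  ev <- schedule$events
  n <- nrow(ev)
  with_seed(seed, {
    rt <- rexgauss(n, subject$rt_mu, subject$rt_sigma, subject$rt_tau)
    rt <- pmax(rt, 1)  # physical lower bound
    wrong <- stats::runif(n) < subject$error_rate
    ev$rt <- rt
    ev$pressed_hand <- ifelse(wrong,
                              ifelse(ev$hand == "left", "right", "left"),
                              ev$hand)
    ev$correct <- !wrong
    ev
  })
}
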