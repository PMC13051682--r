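#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Within-subject F test over `k` conditions for `n` subjects. Sums of
#' squares come from `stats::aov` with an `Error(subject)` stratum; the
#' Greenhouse-Geisser epsilon is estimated from the double-centered sample
#' covariance of the condition scores and multiplies both degrees of
#' freedom. Partial eta squared is `SS_effect / (SS_effect + SS_error)`.
#'
#' @param x numeric matrix, subjects x conditions (no missing cells).
#' @return object of class `freq_result`: `statistic` (F), `df_num`,
#'   `df_den` (GG-adjusted), `p`, `effect_size` (partial eta squared),
#'   `epsilon_gg`, `method`.
#' @export
rm_anova_gg <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  if (k < 2L || n < 3L) stopf("need >= 2 conditions and >= 3 subjects")
  if (anyNA(x)) stopf("missing cells; apply listwise deletion upstream")
  d <- data.frame(y = as.vector(x),
                  subject = factor(rep(seq_len(n), times = k)),
                  condition = factor(rep(seq_len(k), each = n)))
  fit <- stats::aov(y ~ condition + Error(subject), data = d)
  tab <- summary(fit)[["Error: Within"]][[1L]]
  ss_eff <- tab["condition", "Sum Sq"]
  ss_err <- tab["Residuals", "Sum Sq"]
  if (ss_err < .Machine$double.eps * max(1, ss_eff))
    stopf("zero within-subject error variance; F undefined")
  f_stat <- (ss_eff / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
  eps <- gg_epsilon(x)
  df1 <- eps * (k - 1)
  df2 <- eps * (k - 1) * (n - 1)
  structure(list(statistic = f_stat, df_num = df1, df_den = df2,
                 p = stats::pf(f_stat, df1, df2, lower.tail = FALSE),
                 effect_size = ss_eff / (ss_eff + ss_err),
                 epsilon_gg = eps, method = "rm_anova_gg"),
            class = "freq_result")
}

# Greenhouse-Geisser epsilon from the double-centered covariance matrix.
gg_epsilon <- function(x) {
  k <- ncol(x)
  S <- stats::cov(x)
  rm_ <- rowMeans(S); gm <- mean(S)
  Sdc <- S - outer(rm_, rep(1, k)) - outer(rep(1, k), rm_) + gm
  sum(diag(Sdc))^2 / ((k - 1) * sum(Sdc^2))
}

#' @export
print.freq_result <- function(x, ...) {
  if (x$method == "paired_t")
    cat(sprintf("t(%g) = %.3f, p = %.4g, d = %.3f\n",
                x$df_num, x$statistic, x$p, x$effect_size))
  else
    cat(sprintf("F(%.2f, %.2f) = %.3f, p = %.4g, partial eta^2 = %.3f, GG epsilon = %.3f\n",
                x$df_num, x$df_den, x$statistic, x$p, x$effect_size,
                x$epsilon_gg))
  invisible(x)
}

#' Pearson correlation with two-sided p value
#'
#' Thin wrapper over [stats::cor.test()] returning the fields the reporting
#' layer uses.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stopf("x and y must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stopf("zero variance input")
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Cohen's d from a paired t statistic
#'
#' For a paired design, `d = t / sqrt(n)`.
#'
#' @param t paired t statistic.
#' @param n number of subjects (pairs).
#' @export
cohens_d_from_t <- function(t, n) {
  if (n < 1L) stopf("need n >= 1")
  t / sqrt(n)
}
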