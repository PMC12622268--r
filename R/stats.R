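# Agreement and diagnostic statistics: ICC(A,1), Bland-Altman, diagnostic
# performance, Wald-type asymptotic noninferiority with continuity
# correction, and thin wrappers for the standard paired tests.

#' Intraclass correlation for absolute agreement, ICC(A,1)
#'
#' Two-way random-effects model, absolute agreement, single measurement,
#' computed from the ANOVA mean squares (McGraw & Wong), with the
#' F-distribution confidence interval and the F test of ICC = 0.
#'
#' @param x,y paired ratings of the same subjects by two raters/methods.
#' @param conf_level confidence level (default 0.95).
#' @return list: `icc`, `ci95` (`c(lo, hi)`), `p_value`, `ms` (mean squares).
#'   With zero variance in both raters the ICC is undefined and returned as
#'   NA.
#' @export
icc_absolute <- function(x, y, conf_level = 0.95) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  k <- 2
  dat <- cbind(x, y)
  grand <- mean(dat)
  row_m <- rowMeans(dat)
  col_m <- colMeans(dat)
  ssr <- k * sum((row_m - grand)^2)          # subjects (rows)
  ssc <- n * sum((col_m - grand)^2)          # raters (columns)
  sst <- sum((dat - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k / n * (msc - mse)
  if (denom <= 0 || (msr == 0 && mse == 0 && msc == 0)) {
    return(list(icc = NA_real_, ci95 = c(NA_real_, NA_real_),
                p_value = NA_real_,
                ms = list(msr = msr, msc = msc, mse = mse)))
  }
  icc <- (msr - mse) / denom
  alpha <- 1 - conf_level
  # Satterthwaite df for the agreement CI (McGraw & Wong 1996)
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  fl <- stats::qf(1 - alpha / 2, n - 1, v)
  fu <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  fv <- msr / mse
  p <- stats::pf(fv, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  list(icc = icc, ci95 = c(lo, hi), p_value = p,
       ms = list(msr = msr, msc = msc, mse = mse))
}

#' Bland-Altman agreement analysis
#'
#' Differences d = x - y; limits of agreement mean(d) +/- 1.96 sd(d)
#' (sample sd). "Within" counts differences strictly inside the limits.
#'
#' @param x,y paired measurements.
#' @return list: `mean_diff`, `sd_diff`, `loa` (`c(lo, hi)`), `n_pairs`,
#'   `n_within`, `pct_within` (print-style one-decimal percentage).
#' @export
bland_altman <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  d <- x[ok] - y[ok]
  n <- length(d)
  if (n < 2) stop("need at least 2 complete pairs")
  m <- mean(d)
  s <- stats::sd(d)
  loa <- c(m - 1.96 * s, m + 1.96 * s)
  within <- sum(d > loa[1] & d < loa[2])
  if (s == 0) within <- n   # degenerate: all differences identical
  list(mean_diff = m, sd_diff = s, loa = loa, n_pairs = n,
       n_within = within, pct_within = prop_pct(within, n))
}

#' Plot a Bland-Altman comparison
#' @param ba result of [bland_altman()].
#' @param x,y the paired measurements used.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `ba`.
#' @export
plot_bland_altman <- function(ba, x, y, ...) {
  graphics::plot((x + y) / 2, x - y, xlab = "mean of pair",
                 ylab = "difference", ...)
  graphics::abline(h = c(ba$mean_diff, ba$loa), lty = c(1, 2, 2))
  invisible(ba)
}

#' Diagnostic performance of a binary classifier
#'
#' @param pred,truth aligned logical vectors.
#' @return list: `sensitivity`, `specificity`, `ppv`, `npv`, `accuracy`;
#'   entries with a zero denominator are NA (undefined), never 0.
#' @export
diagnostic_performance <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop("pred and truth have different lengths")
  }
  pred <- as.logical(pred); truth <- as.logical(truth)
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  fn <- sum(!pred & truth); tn <- sum(!pred & !truth)
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  list(sensitivity = rate(tp, tp + fn),
       specificity = rate(tn, tn + fp),
       ppv = rate(tp, tp + fp),
       npv = rate(tn, tn + fn),
       accuracy = rate(tp + tn, tp + fp + fn + tn),
       table = c(tp = tp, fp = fp, fn = fn, tn = tn))
}

#' Wald-type asymptotic noninferiority test for two proportions
#'
#' Tests H0: p1 <= p0 - margin against H1: p1 > p0 - margin with
#' z = (p1hat - p0hat + margin - cc) / SE, Wald standard error
#' sqrt(p1(1-p1)/n1 + p0(1-p0)/n0), and sample-size continuity correction
#' cc = (1/n1 + 1/n0) / 2. One-sided p from the normal upper tail; the
#' noninferiority margin defaults to 0.1 and the decision level to 0.025.
#'
#' @param successes1,n1 test arm (e.g. automated reader).
#' @param successes0,n0 reference arm (e.g. expert reader).
#' @param margin noninferiority margin on the proportion scale.
#' @param alpha one-sided decision level.
#' @return list: `p1`, `p0`, `n1`, `n0`, `margin`, `z`, `p_one_sided`,
#'   `alpha`, `noninferior`.
#' @export
noninferiority_wald <- function(successes1, n1, successes0, n0,
                                margin = 0.1, alpha = 0.025) {
  stopifnot(n1 > 0, n0 > 0, margin > 0,
            successes1 >= 0, successes1 <= n1,
            successes0 >= 0, successes0 <= n0)
  p1 <- successes1 / n1
  p0 <- successes0 / n0
  se <- sqrt(p1 * (1 - p1) / n1 + p0 * (1 - p0) / n0)
  cc <- (1 / n1 + 1 / n0) / 2
  num <- p1 - p0 + margin - cc
  z <- if (se == 0) {
    if (num > 0) Inf else if (num < 0) -Inf else 0
  } else {
    num / se
  }
  p <- stats::pnorm(z, lower.tail = FALSE)
  list(p1 = p1, p0 = p0, n1 = n1, n0 = n0, margin = margin, z = z,
       p_one_sided = p, alpha = alpha, noninferior = p < alpha)
}

#' Paired t and Wilcoxon signed-rank tests
#'
#' Two-sided p values; the Wilcoxon follows the signed-rank zero-exclusion
#' convention (zeros dropped). Degenerate inputs (zero-variance differences)
#' yield NA, reported as undefined rather than thrown.
#'
#' @param x,y paired samples.
#' @return list: `t_p`, `wilcoxon_p`.
#' @export
paired_tests <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  t_p <- tryCatch(stats::t.test(x, y, paired = TRUE)$p.value,
                  error = function(e) NA_real_)   # zero-variance differences
  w_p <- if (all(d == 0)) {
    NA_real_
  } else {
    suppressWarnings(stats::wilcox.test(x, y, paired = TRUE)$p.value)
  }
  list(t_p = t_p, wilcoxon_p = w_p)
}

#' Chi-square test of a contingency table (no continuity correction)
#' @param tab matrix of counts.
#' @return list: `statistic`, `p_value`.
#' @export
chi_square <- function(tab) {
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

#' Full agreement report for two raters
#'
#' Bundles ICC(A,1), Bland-Altman and paired tests, the battery reported per
#' measured parameter when validating one reader (or an automated pipeline)
#' against another.
#'
#' @param x,y paired measurements.
#' @return list of class `agreement_report`.
#' @export
agreement_report <- function(x, y) {
  icc <- icc_absolute(x, y)
  ba <- bland_altman(x, y)
  pt <- paired_tests(x, y)
  structure(list(icc = icc$icc, icc_ci95 = icc$ci95,
                 icc_p_value = icc$p_value,
                 ba_mean_diff = ba$mean_diff, ba_sd_diff = ba$sd_diff,
                 loa = ba$loa, n_pairs = ba$n_pairs,
                 n_within_loa = ba$n_within, pct_within_loa = ba$pct_within,
                 paired_t_p = pt$t_p, wilcoxon_p = pt$wilcoxon_p),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("ICC(A,1) %.3f [95%% CI %.3f-%.3f], p = %.3g\n",
              x$icc, x$icc_ci95[1], x$icc_ci95[2], x$icc_p_value))
  cat(sprintf("Bland-Altman: mean diff %.3g +/- %.3g, LoA [%.3g, %.3g]\n",
              x$ba_mean_diff, x$ba_sd_diff, x$loa[1], x$loa[2]))
  cat(sprintf("  %d/%d (%.1f%%) within limits of agreement\n",
              x$n_within_loa, x$n_pairs, x$pct_within_loa))
  invisible(x)
}
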