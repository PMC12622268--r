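test_that("ICC(A,1) matches the independent ANOVA mean-squares oracle", {
  fixtures <- list(
    list(x = c(9.1, 7.8, 8.4, 10.2, 6.5, 8.8, 9.9, 7.2),
         y = c(8.8, 8.1, 8.0, 10.6, 6.9, 8.5, 10.4, 7.0)),
    list(x = c(120, 95, 180, 210, 160, 140, 100, 130),
         y = c(110, 90, 195, 190, 170, 150, 120, 118)),
    list(x = c(48, 60, 75, 52, 66, 81, 58, 70),
         y = c(58, 63, 70, 61, 60, 90, 66, 64))
  )
  for (fx in fixtures) {
    r <- icc_absolute(fx$x, fx$y)
    df <- data.frame(v = c(fx$x, fx$y),
                     subj = factor(rep(seq_along(fx$x), 2)),
                     rater = factor(rep(1:2, each = length(fx$x))))
    a <- summary(stats::aov(v ~ subj + rater, data = df))[[1]]
    msr <- a["subj", "Mean Sq"]
    msc <- a["rater", "Mean Sq"]
    mse <- a["Residuals", "Mean Sq"]
    n <- length(fx$x)
    oracle <- (msr - mse) / (msr + mse + (2 / n) * (msc - mse))
    expect_lt(abs(r$icc - oracle), 1e-9)
    expect_true(r$ci95[1] <= r$icc && r$icc <= r$ci95[2])
  }
  # confidence interval frozen from an independent implementation
  # (pingouin ICC(A,1) on the first fixture)
  r1 <- icc_absolute(fixtures[[1]]$x, fixtures[[1]]$y)
  expect_equal(r1$ci95, c(0.8314583617, 0.9924869816), tolerance = 1e-8)
})

test_that("ICC is symmetric, perfect on equality, and penalizes bias", {
  x <- c(3, 7, 5, 9, 4, 8, 6, 10)
  expect_equal(icc_absolute(x, x)$icc, 1)
  y <- x + c(0.3, -0.2, 0.1, 0, -0.1, 0.2, -0.3, 0.1)
  expect_identical(icc_absolute(x, y)$icc, icc_absolute(y, x)$icc)
  # constant offset: absolute agreement < Pearson correlation (= 1)
  off <- icc_absolute(x, x + 10)$icc
  expect_lt(off, 1)
  expect_lt(off, stats::cor(x, x + 10))
  # zero variance in both raters is undefined
  expect_true(is.na(icc_absolute(rep(5, 8), rep(5, 8))$icc))
  expect_error(icc_absolute(1:2, 2:3), "3 complete pairs")
})

test_that("Bland-Altman limits, strict-inside counting and percentages", {
  x <- c(10, 12, 9, 14, 11, 13)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$mean_diff, 0)
  expect_equal(ba0$loa, c(0, 0))
  expect_equal(ba0$pct_within, 100)
  set.seed(4)
  y <- x + rnorm(6)
  ba <- bland_altman(x, y)
  d <- x - y
  expect_equal(ba$loa, mean(d) + c(-1.96, 1.96) * sd(d))
  expect_equal(ba$n_within, sum(d > ba$loa[1] & d < ba$loa[2]))
  expect_error(bland_altman(1, 2), "2 complete pairs")
  # the printed within-limits percentages recompute from their counts
  expect_equal(prop_pct(1140, 1218), 93.6)
  expect_equal(prop_pct(1297, 1384), 93.7)
})

test_that("within-LoA fraction is ~95% for large Gaussian samples", {
  set.seed(12)
  d <- rnorm(1e5)
  ba <- bland_altman(d, rep(0, 1e5))
  expect_equal(ba$n_within / ba$n_pairs, 0.95, tolerance = 0.006 / 0.95)
})

test_that("diagnostic performance matches hand tabulation", {
  dp0 <- diagnostic_performance(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE))
  expect_true(all(unlist(dp0[c("sensitivity", "specificity", "ppv", "npv",
                               "accuracy")]) == 1))
  # TP=10 FP=20 FN=5 TN=65
  pred <- c(rep(TRUE, 30), rep(FALSE, 70))
  truth <- c(rep(TRUE, 10), rep(FALSE, 20), rep(TRUE, 5), rep(FALSE, 65))
  dp <- diagnostic_performance(pred, truth)
  expect_equal(dp$sensitivity, 10 / 15, tolerance = 1e-12)
  expect_equal(dp$specificity, 65 / 85, tolerance = 1e-12)
  expect_equal(dp$ppv, 10 / 30, tolerance = 1e-12)
  expect_equal(dp$npv, 65 / 70, tolerance = 1e-12)
  expect_equal(dp$accuracy, 0.75)
  # all-negative truth: sensitivity undefined, never 0
  dp2 <- diagnostic_performance(rep(FALSE, 10), rep(FALSE, 10))
  expect_true(is.na(dp2$sensitivity))
  expect_error(diagnostic_performance(TRUE, c(TRUE, FALSE)), "length")
})

test_that("noninferiority z matches a closed-form recomputation", {
  oracle_z <- function(s1, n1, s0, n0, margin = 0.1) {
    p1 <- s1 / n1; p0 <- s0 / n0
    (p1 - p0 + margin - (1 / n1 + 1 / n0) / 2) /
      sqrt(p1 * (1 - p1) / n1 + p0 * (1 - p0) / n0)
  }
  set.seed(30)
  for (i in 1:20) {
    n1 <- sample(50:500, 1); n0 <- sample(50:500, 1)
    s1 <- rbinom(1, n1, runif(1, 0.3, 0.95))
    s0 <- rbinom(1, n0, runif(1, 0.3, 0.95))
    if (s1 %in% c(0, n1) && s0 %in% c(0, n0)) next
    r <- noninferiority_wald(s1, n1, s0, n0)
    expect_lt(abs(r$z - oracle_z(s1, n1, s0, n0)), 1e-9)
    expect_identical(r$noninferior, r$p_one_sided < 0.025)
  }
  # equal large proportions: clearly noninferior
  r <- noninferiority_wald(400, 500, 400, 500)
  expect_gt(r$z, 1.96)
  expect_true(r$noninferior)
  # boundary with vanishing continuity correction: p -> 0.5
  rb <- noninferiority_wald(7e7, 1e8, 8e7, 1e8)
  expect_equal(rb$p_one_sided, 0.5, tolerance = 1e-3)
  expect_false(rb$noninferior)
  # degenerate proportions on both arms: SE = 0 path
  rd <- noninferiority_wald(100, 100, 100, 100)
  expect_equal(rd$z, Inf)           # numerator margin - cc > 0
  expect_equal(rd$p_one_sided, 0)
  rz <- noninferiority_wald(10, 10, 10, 10)
  expect_equal(rz$z, 0)             # numerator exactly 0 at n = 10
  expect_equal(rz$p_one_sided, 0.5)
})

test_that("noninferiority z is monotone in successes1", {
  zs <- vapply(40:90, function(s) {
    noninferiority_wald(s, 100, 80, 100)$z
  }, 0)
  expect_true(all(diff(zs) > 0))
})

test_that("boundary-null rejection rate stays at or below nominal", {
  # H0 boundary: p1 = p0 - 0.1; continuity correction keeps the test
  # conservative
  set.seed(2024)
  n <- 200; p0 <- 0.85; p1 <- p0 - 0.1
  s1 <- rbinom(1e4, n, p1); s0 <- rbinom(1e4, n, p0)
  rej <- mapply(function(a, b) noninferiority_wald(a, n, b, n)$noninferior,
                s1, s0)
  se <- sqrt(0.025 * 0.975 / 1e4)
  expect_lte(mean(rej), 0.025 + 3 * se)
})

test_that("paired tests follow the standard conventions", {
  x <- c(1, 2, 3, 4, 5)
  pt0 <- paired_tests(x, x)
  expect_true(is.na(pt0$t_p))       # zero-variance differences: undefined
  expect_true(is.na(pt0$wilcoxon_p))
  set.seed(6)
  a <- rnorm(30, sd = 0.1); b <- a + 1 + rnorm(30, sd = 0.1)
  pt <- paired_tests(b, a)
  expect_lt(pt$t_p, 1e-6)
  expect_lt(pt$wilcoxon_p, 1e-6)
  # agreement with base R on a generic pair
  y <- x + c(0.5, -0.2, 0.4, -0.1, 0.3)
  expect_equal(paired_tests(x, y)$t_p, t.test(x, y, paired = TRUE)$p.value)
})

test_that("chi-square without continuity correction matches hand computation", {
  cs <- chi_square(matrix(c(20, 10, 10, 20), 2))
  expect_equal(cs$statistic, 20 / 3, tolerance = 1e-9)
  expect_equal(cs$p_value, pchisq(20 / 3, 1, lower.tail = FALSE))
})

test_that("agreement_report bundles the battery coherently", {
  set.seed(8)
  x <- rnorm(40, 100, 15); y <- x + rnorm(40, 2, 5)
  rep <- agreement_report(x, y)
  expect_true(rep$loa[1] <= rep$ba_mean_diff)
  expect_true(rep$ba_mean_diff <= rep$loa[2])
  expect_equal(rep$pct_within_loa,
               prop_pct(rep$n_within_loa, rep$n_pairs))
  expect_true(rep$icc >= -1 && rep$icc <= 1)
  expect_output(print(rep), "ICC")
})
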