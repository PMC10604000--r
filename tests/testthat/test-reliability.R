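# Agreement statistics: ICC(2,1), its classification, Bland-Altman, and
# absolute-error summaries.

test_that("icc_2_1 matches the two-way ANOVA oracle on random tables", {
  set.seed(101)
  for (i in 1:30) {
    n <- sample(5:50, 1); k <- sample(2:3, 1)
    case_eff <- rnorm(n, 0, runif(1, 0.5, 4))
    rater_eff <- rnorm(k, 0, runif(1, 0, 2))
    x <- outer(case_eff, rater_eff, `+`) + matrix(rnorm(n * k), n, k) + 50
    expect_equal(icc_2_1(x)$icc, icc21_aov_oracle(x), tolerance = 1e-9)
  }
})

test_that("identical rater columns give ICC exactly 1; constant tables are undefined", {
  set.seed(102)
  v <- rnorm(15, 40, 8)
  expect_equal(icc_2_1(cbind(v, v))$icc, 1.0)
  expect_error(icc_2_1(matrix(5, 10, 3)), class = "spinalign_undefined_icc")
})

test_that("absolute agreement penalizes systematic bias below the Pearson correlation", {
  set.seed(103)
  a <- rnorm(25, 50, 10)
  b <- a + 8  # pure constant shift
  expect_lt(icc_2_1(cbind(a, b))$icc, cor(a, b))
  # and adding a common constant to all cells changes nothing
  x <- cbind(a, a + rnorm(25, 0, 2))
  expect_equal(icc_2_1(x)$icc, icc_2_1(x + 100)$icc, tolerance = 1e-12)
})

test_that("independent noise on one rater strictly lowers the ICC", {
  set.seed(104)
  a <- rnorm(40, 50, 10)
  base <- cbind(a, a + rnorm(40, 0, 1))
  noisy <- base
  noisy[, 2] <- noisy[, 2] + rnorm(40, 0, 6)
  expect_lt(icc_2_1(noisy)$icc, icc_2_1(base)$icc)
})

test_that("the confidence interval brackets the ICC and narrows with n", {
  set.seed(105)
  a <- rnorm(60, 50, 10)
  x <- cbind(a, a + rnorm(60, 0, 3))
  r_small <- icc_2_1(x[1:12, ])
  r_large <- icc_2_1(x)
  for (r in list(r_small, r_large)) {
    expect_lt(r$ci95[1], r$icc)
    expect_gt(r$ci95[2], r$icc)
  }
  expect_lt(diff(r_large$ci95), diff(r_small$ci95))
})

test_that("classification respects the printed cut-points with upper labels at boundaries", {
  expect_identical(classify_icc(0.27), "poor")
  expect_identical(classify_icc(0.399), "poor")
  expect_identical(classify_icc(0.40), "fair")
  expect_identical(classify_icc(0.599), "fair")
  expect_identical(classify_icc(0.60), "good")
  expect_identical(classify_icc(0.62), "good")
  expect_identical(classify_icc(0.74), "good")
  expect_identical(classify_icc(0.75), "excellent")
  expect_identical(classify_icc(1.0), "excellent")
})

test_that("bland_altman reproduces bias and limits of agreement", {
  a <- c(1, 2, 3, 4, 5)
  ba0 <- bland_altman(a, a)
  expect_equal(ba0$mean_diff, 0)
  expect_equal(ba0$loa_low, 0)
  expect_equal(ba0$loa_high, 0)
  ba5 <- bland_altman(a + 5, a)
  expect_equal(ba5$mean_diff, 5)
  expect_equal(ba5$sd_diff, 0)
  set.seed(106)
  d <- rnorm(500, 2, 3)
  ba <- bland_altman(d, rep(0, 500))
  expect_equal(ba$mean_diff, mean(d))
  expect_equal(ba$loa_high - ba$loa_low, 2 * 1.96 * sd(d), tolerance = 1e-12)
  expect_error(bland_altman(1:4, 1:5), class = "spinalign_paired_data")
})

test_that("error_stats matches direct-summation formulas", {
  a <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(error_stats(a, a)$mae, 0)
  expect_equal(error_stats(a, a)$pearson_r, 1)
  es_neg <- error_stats(a, -a)
  expect_equal(es_neg$pearson_r, -1)
  expect_equal(es_neg$r_squared, 1)
  set.seed(107)
  x <- rnorm(50, 30, 5); y <- x + rnorm(50, 1, 2)
  es <- error_stats(x, y)
  d <- abs(x - y)
  expect_equal(es$mae, sum(d) / 50, tolerance = 1e-12)
  expect_equal(es$std_ae, sqrt(sum((d - mean(d))^2) / 49), tolerance = 1e-12)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(es$pearson_r, r_direct, tolerance = 1e-12)
  expect_equal(es$r_squared, r_direct^2, tolerance = 1e-12)
  expect_error(error_stats(x, rep(1, 50)), class = "spinalign_undefined_correlation")
})

test_that("agreement_report is internally consistent and tracks constructed noise", {
  set.seed(108)
  truth <- rnorm(30, 45, 12)
  tab <- rater_table(cbind(specialist = truth,
                           resident = truth + rnorm(30, 1, 4),
                           ai = truth + rnorm(30, 0.2, 1.5)))
  rep <- agreement_report(tab, "specialist")
  expect_equal(nrow(rep), 2)
  expect_equal(rep$r_squared, rep$pearson_r^2, tolerance = 1e-12)
  expect_identical(rep$classification, classify_icc(rep$icc))
  # the lower-noise rater agrees better
  expect_gt(rep$icc[rep$rater == "ai"], rep$icc[rep$rater == "resident"])
  expect_lt(rep$mae[rep$rater == "ai"], rep$mae[rep$rater == "resident"])
  # three identical raters: perfect agreement everywhere
  tri <- rater_table(cbind(a = truth, b = truth, c = truth))
  rep3 <- agreement_report(tri, "a")
  expect_equal(rep3$icc, c(1, 1))
  expect_equal(rep3$mae, c(0, 0))
  expect_equal(attr(rep3, "pooled_icc")$icc, 1)
})

test_that("rows with missing cells are dropped listwise with an accounted count", {
  x <- cbind(a = c(1, 2, NA, 4, 5), b = c(1.1, 2.2, 3, 4.1, NA))
  tab <- rater_table(x)
  expect_equal(nrow(tab$values), 3)
  expect_error(rater_table(cbind(a = c(1, NA), b = c(NA, 2))))
})
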