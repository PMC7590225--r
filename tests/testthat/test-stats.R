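# Two-sample machinery, correlation, OLS: brute-force oracles and
# cross-checks against independent implementations.

test_that("BMI categories use lower-inclusive boundaries", {
  expect_equal(as.character(classify_bmi(c(24, 30, 18.5, 17, 25, 29.9))),
               c("normal", "obese", "normal", "underweight", "overweight", "overweight"))
  expect_error(classify_bmi(c(22, -1)), "positive")
  expect_error(classify_bmi(0), "positive")
})

test_that("urbanicity thresholds classify county populations", {
  expect_identical(classify_urbanicity(c(99999, 100000, 250000)), c(FALSE, TRUE, TRUE))
  expect_identical(classify_urbanicity(70000, threshold = 60000), TRUE)
})

test_that("Levene statistic matches a hand-computed ANOVA on absolute deviations", {
  a <- c(3.1, 4.7, 2.2, 5.9, 4.4, 3.8)
  b <- c(10.2, 1.1, 7.4, 12.9, 0.4)
  got <- levene_test(a, b)
  za <- abs(a - mean(a)); zb <- abs(b - mean(b))
  z <- c(za, zb); grp <- c(rep(1, 6), rep(2, 5))
  ssb <- sum(tapply(z, grp, function(x) length(x) * (mean(x) - mean(z))^2))
  ssw <- sum((z - ave(z, grp))^2)
  w <- (length(z) - 2) * ssb / ssw
  expect_equal(got$statistic, w, tolerance = 1e-12)
  expect_equal(got$p, pf(w, 1, 9, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("Levene agrees with car::leveneTest(center = mean)", {
  skip_if_not_installed("car")
  set.seed(41)
  a <- rnorm(25, sd = 1); b <- rnorm(30, sd = 3)
  got <- levene_test(a, b)
  ref <- car::leveneTest(c(a, b), factor(rep(1:2, c(25, 30))), center = mean)
  expect_equal(got$statistic, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(got$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("Levene is 0 for identical samples and detects a 5-fold SD ratio", {
  a <- c(1.5, 2.5, 9, 4)
  expect_equal(levene_test(a, a)$statistic, 0)
  expect_equal(levene_test(rep(2, 5), rep(7, 8))$p, 1)
  set.seed(101)
  hits <- mean(replicate(100, {
    levene_test(rnorm(200, sd = 1), rnorm(200, sd = 5))$p < 0.01
  }))
  expect_gte(hits, 0.95)
})

test_that("two-sample t matches textbook formulas and stats::t.test", {
  a <- c(12.1, 14.3, 11.8, 15.2, 13.3, 12.9, 14.8, 13.1, 12.4, 14.0)
  b <- c(10.2, 11.9, 10.8, 12.6, 11.1, 10.4, 12.2, 11.5, 10.9, 11.7)
  pooled <- two_sample_t(a, b, method = "pooled")
  sp2 <- (9 * var(a) + 9 * var(b)) / 18
  se <- sqrt(sp2 * (1 / 10 + 1 / 10))
  expect_equal(pooled$t, (mean(a) - mean(b)) / se, tolerance = 1e-12)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(pooled$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(pooled$p, ref$p.value, tolerance = 1e-12)

  welch <- two_sample_t(a, b, method = "welch")
  refw <- t.test(a, b)
  expect_equal(welch$t, unname(refw$statistic), tolerance = 1e-12)
  expect_equal(welch$df, unname(refw$parameter), tolerance = 1e-12)
  expect_equal(welch$p, refw$p.value, tolerance = 1e-12)
})

test_that("pooled and Welch coincide for equal sizes and equal variances", {
  a <- c(5, 7, 9, 11, 13)
  b <- a + 2.5  # identical variance
  p <- two_sample_t(a, b, method = "pooled")
  w <- two_sample_t(a, b, method = "welch")
  expect_equal(p$t, w$t, tolerance = 1e-12)
  expect_equal(p$df, w$df, tolerance = 1e-12)
})

test_that("degenerate two-sample inputs give t = 0, p = 1", {
  r <- two_sample_t(rep(4, 5), rep(4, 6))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  r2 <- two_sample_t(c(1, 1, 2), c(1, 1, 2))
  expect_equal(r2$t, 0)
})

test_that("the auto method applies the Levene gate at alpha 0.05", {
  set.seed(53)
  a <- rnorm(100, sd = 1); b <- rnorm(100, sd = 6)
  r <- two_sample_t(a, b, method = "auto")
  expect_identical(r$method, "welch")
  expect_lt(r$levene_p, 0.05)
  b2 <- rnorm(100, sd = 1)
  r2 <- two_sample_t(a, b2, method = "auto")
  expect_identical(r2$method, if (r2$levene_p < 0.05) "welch" else "pooled")
})

test_that("summary-statistic t equals the raw-sample pooled test", {
  set.seed(61)
  a <- rnorm(14, 20, 3); b <- rnorm(23, 18, 4)
  raw <- two_sample_t(a, b, method = "pooled")
  summ <- t_from_summary(mean(a), sd(a), 14, mean(b), sd(b), 23, method = "pooled")
  expect_equal(summ$t, raw$t, tolerance = 1e-12)
  expect_equal(summ$se_diff, raw$se_diff, tolerance = 1e-12)
  expect_equal(summ$p, raw$p, tolerance = 1e-12)
  raww <- two_sample_t(a, b, method = "welch")
  summw <- t_from_summary(mean(a), sd(a), 14, mean(b), sd(b), 23, method = "welch")
  expect_equal(summw$df, raww$df, tolerance = 1e-12)
  expect_equal(t_from_summary(5, 1, 10, 5, 2, 12, "welch")$t, 0)
  expect_error(t_from_summary(5, 0, 10, 5, 2, 12), "positive")
})

test_that("Welch df stays within its theoretical bounds", {
  set.seed(71)
  for (i in 1:50) {
    n1 <- sample(3:30, 1); n2 <- sample(3:30, 1)
    r <- two_sample_t(rnorm(n1, sd = runif(1, 0.5, 5)),
                      rnorm(n2, sd = runif(1, 0.5, 5)), method = "welch")
    expect_gte(r$df, min(n1, n2) - 1 - 1e-9)
    expect_lte(r$df, n1 + n2 - 2 + 1e-9)
  }
})

test_that("correlation matrix matches the covariance-formula brute force", {
  set.seed(83)
  m <- matrix(rnorm(20 * 12), 20, 12, dimnames = list(NULL, paste0("v", 1:12)))
  got <- pearson_matrix(m)
  for (i in c(1, 4, 9)) for (j in c(2, 7, 12)) {
    x <- m[, i]; y <- m[, j]
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(got[i, j], r, tolerance = 1e-12)
  }
  expect_equal(diag(got), rep(1, 12), ignore_attr = TRUE)
  expect_true(isSymmetric(got))
  expect_equal(unname(pearson_matrix(cbind(a = m[, 1], b = 2 * m[, 1] + 1))[1, 2]), 1)
  z <- cbind(m[, 1:2], flat = rep(3, 20))
  expect_true(all(is.na(pearson_matrix(z)[3, 1:2])))
})

test_that("OLS matches a normal-equations brute force and lm diagnostics", {
  set.seed(97)
  n <- 50
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n), x4 = rnorm(n))
  d$y <- 2 + 1.5 * d$x1 - 0.7 * d$x2 + 0.3 * d$x3 + rnorm(n)
  fit <- ols_model(d, "y", c("x1", "x2", "x3", "x4"))
  X <- cbind(1, as.matrix(d[, c("x1", "x2", "x3", "x4")]))
  beta_hat <- solve(t(X) %*% X, t(X) %*% d$y)
  expect_equal(fit$coefficients$B, beta_hat[-1], tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(fit$intercept, beta_hat[1], tolerance = 1e-10, ignore_attr = TRUE)
  res <- d$y - X %*% beta_hat
  sigma2 <- sum(res^2) / (n - 5)
  se <- sqrt(diag(sigma2 * solve(t(X) %*% X)))[-1]
  expect_equal(fit$coefficients$SE, se, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(fit$coefficients$beta,
               fit$coefficients$B * apply(d[, c("x1", "x2", "x3", "x4")], 2, sd) / sd(d$y),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("an exact linear response gives R2 = 1 and zero residual", {
  d <- data.frame(x = 1:20)
  d$y <- 3 * d$x - 5
  fit <- suppressWarnings(ols_model(d, "y", "x"))  # lm warns on a perfect fit
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(fit$coefficients$B, 3, tolerance = 1e-10)
})

test_that("standardized beta is invariant to affine rescaling of a predictor", {
  set.seed(103)
  d <- data.frame(x1 = rnorm(40), x2 = rnorm(40))
  d$y <- 1 + 0.8 * d$x1 + 0.2 * d$x2 + rnorm(40, sd = 0.5)
  f1 <- ols_model(d, "y", c("x1", "x2"))
  d2 <- d; d2$x1 <- 1000 * d$x1 + 77
  f2 <- ols_model(d2, "y", c("x1", "x2"))
  expect_equal(f1$coefficients$beta, f2$coefficients$beta, tolerance = 1e-10)
  expect_equal(f2$coefficients$B[1], f1$coefficients$B[1] / 1000, tolerance = 1e-10)
})

test_that("an irrelevant predictor cannot reduce R2 but can reduce adjusted R2", {
  set.seed(107)
  d <- data.frame(x = rnorm(30), junk = rnorm(30))
  d$y <- 2 * d$x + rnorm(30)
  f1 <- ols_model(d, "y", "x")
  f2 <- ols_model(d, "y", c("x", "junk"))
  expect_gte(f2$r2, f1$r2 - 1e-12)
  expect_lte(f2$adj_r2, f2$r2)
})

test_that("rank-deficient designs fail loudly, naming the offending column", {
  d <- data.frame(x = rnorm(20))
  d$dup <- 2 * d$x
  d$y <- d$x + rnorm(20)
  expect_error(ols_model(d, "y", c("x", "dup")), "dup")
})

test_that("significance stars follow the printed-table convention", {
  expect_identical(signif_stars(c(0.0005, 0.005, 0.04, 0.2, NA)),
                   c("***", "**", "*", "", ""))
})
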