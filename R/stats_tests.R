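# Two-sample machinery, variable helpers, and correlation.

#' Classify body mass index
#'
#' Categories use lower-inclusive boundaries: \[0, 18.5) underweight,
#' \[18.5, 25) normal, \[25, 30) overweight, \[30, Inf) obese.
#'
#' @param bmi Numeric vector of BMI values (kg/m^2), all positive.
#' @return Factor with levels underweight, normal, overweight, obese.
#' @export
classify_bmi <- function(bmi) {
  if (any(!is.finite(bmi) | bmi <= 0)) stop("BMI values must be positive")
  cut(bmi, breaks = c(0, 18.5, 25, 30, Inf), right = FALSE,
      labels = c("underweight", "normal", "overweight", "obese"))
}

#' Classify counties as urban by population
#'
#' @param population Numeric vector of county populations.
#' @param threshold Population at or above which a county counts as urban
#'   (default 100000; the MSA-based 60000 variant can be selected by passing
#'   that threshold).
#' @return Logical vector.
#' @export
classify_urbanicity <- function(population, threshold = 100000) {
  stopifnot(threshold > 0)
  population >= threshold
}

#' Levene's test for equality of two variances
#'
#' Classic mean-centered form: a one-way ANOVA F statistic on the absolute
#' deviations from the group means, referred to F(1, n1 + n2 - 2).
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @return List with `statistic` and `p`; a fully degenerate input (both
#'   samples constant) returns statistic 0, p 1.
#' @export
levene_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  stopifnot(length(a) >= 2, length(b) >= 2)
  za <- abs(a - mean(a)); zb <- abs(b - mean(b))
  n1 <- length(za); n2 <- length(zb); n <- n1 + n2
  zbar <- mean(c(za, zb))
  ssb <- n1 * (mean(za) - zbar)^2 + n2 * (mean(zb) - zbar)^2
  ssw <- sum((za - mean(za))^2) + sum((zb - mean(zb))^2)
  if (ssw <= 1e-300) return(list(statistic = 0, p = 1))
  w <- (n - 2) * ssb / ssw
  list(statistic = w, p = stats::pf(w, 1, n - 2, lower.tail = FALSE))
}

new_t_result <- function(method, m1, m2, sd1, sd2, n1, n2, se, df,
                         levene_stat = NA_real_, levene_p = NA_real_) {
  mean_diff <- m1 - m2
  if (se <= 0) {
    t <- 0; p <- 1
  } else {
    t <- mean_diff / se
    p <- 2 * stats::pt(-abs(t), df)
  }
  structure(list(method = method, mean_diff = mean_diff, se_diff = se,
                 t = t, df = df, p = p,
                 m1 = m1, m2 = m2, sd1 = sd1, sd2 = sd2, n1 = n1, n2 = n2,
                 levene_stat = levene_stat, levene_p = levene_p),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("%s t-test: diff = %.4g (SE %.4g), t = %.4g, df = %.4g, p = %.4g\n",
              x$method, x$mean_diff, x$se_diff, x$t, x$df, x$p))
  invisible(x)
}

#' Two-sample t test from printed group summaries
#'
#' Reconstructs the test from group means, SDs and sizes, exactly as when
#' working from a published summary table.
#'
#' @param m1,sd1,n1 Mean, SD and size of group 1.
#' @param m2,sd2,n2 Mean, SD and size of group 2.
#' @param method `"pooled"` (equal variances, df = n1 + n2 - 2) or
#'   `"welch"` (Welch-Satterthwaite df).
#' @return A `t_test_result` (two-sided p). The difference is m1 - m2.
#' @export
t_from_summary <- function(m1, sd1, n1, m2, sd2, n2,
                           method = c("pooled", "welch")) {
  method <- match.arg(method)
  if (sd1 <= 0 || sd2 <= 0) stop("group SDs must be positive")
  stopifnot(n1 >= 2, n2 >= 2)
  v1 <- sd1^2; v2 <- sd2^2
  if (method == "pooled") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  new_t_result(method, m1, m2, sd1, sd2, n1, n2, se, df)
}

#' Two-sample t test with optional Levene gate
#'
#' @param a,b Numeric samples (n >= 2 each, NA dropped).
#' @param method `"pooled"`, `"welch"`, or `"auto"` (Welch iff the
#'   mean-centered Levene test rejects equal variances at `alpha`).
#' @param alpha Gate level for `method = "auto"` (default 0.05).
#' @return A `t_test_result`; both samples constant with equal means give
#'   t = 0, p = 1.
#' @export
two_sample_t <- function(a, b, method = c("auto", "pooled", "welch"), alpha = 0.05) {
  method <- match.arg(method)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  stopifnot(length(a) >= 2, length(b) >= 2)
  lev <- levene_test(a, b)
  if (method == "auto") {
    method <- if (lev$p < alpha) "welch" else "pooled"
  }
  n1 <- length(a); n2 <- length(b)
  m1 <- mean(a); m2 <- mean(b)
  v1 <- stats::var(a); v2 <- stats::var(b)
  if (v1 <= 0 && v2 <= 0) {
    res <- new_t_result(method, m1, m2, 0, 0, n1, n2, 0, n1 + n2 - 2,
                        lev$statistic, lev$p)
    return(res)
  }
  if (method == "pooled") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  new_t_result(method, m1, m2, sqrt(v1), sqrt(v2), n1, n2, se, df,
               lev$statistic, lev$p)
}

#' Pearson correlation matrix over exposure columns
#'
#' Pairwise deletion of missing counties; zero-variance columns yield NA
#' entries.
#'
#' @param exposure An `exposure_table` (the buffer-0 scheme x metric columns
#'   are used) or a numeric data frame / matrix.
#' @return Symmetric correlation matrix with unit diagonal where defined.
#' @export
pearson_matrix <- function(exposure) {
  if (inherits(exposure, "exposure_table")) {
    w <- exposure_wide(exposure[exposure$buffer_m == 0, ])
    m <- as.matrix(w[, setdiff(names(w), "county_id")])
  } else {
    m <- as.matrix(exposure)
  }
  if (nrow(m) < 3) stop("need at least 3 complete rows")
  suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
}

#' Significance stars
#'
#' `***` p < 0.001, `**` p < 0.01, `*` p < 0.05, empty otherwise.
#'
#' @param p Numeric vector of p values.
#' @export
signif_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}
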