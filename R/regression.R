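# Ecological regression: county-level OLS and the scheme/buffer model grids.

#' Ordinary least squares with standardized coefficients
#'
#' Fits `outcome ~ predictors` by least squares on the county table
#' (counties are unweighted observations), with listwise deletion of
#' incomplete rows. Reports unstandardized B with SE, standardized beta
#' (B x sd(x)/sd(y)), per-term p values, and the usual fit statistics.
#'
#' @param data Data frame with the outcome and predictor columns.
#' @param outcome Name of the outcome column.
#' @param predictors Character vector of predictor column names.
#' @return A `regression_result`: list with `coefficients` (tibble: term, B,
#'   SE, beta, t, p), `r2`, `adj_r2`, `fstat`, `model_p`, `n`, `outcome`.
#' @export
ols_model <- function(data, outcome, predictors) {
  stopifnot(outcome %in% names(data), all(predictors %in% names(data)))
  d <- data[, c(outcome, predictors), drop = FALSE]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  if (n <= length(predictors) + 1) stop("too few complete counties for the model")
  fml <- stats::reformulate(predictors, response = outcome)
  fit <- stats::lm(fml, data = d)
  if (fit$rank < length(predictors) + 1) {
    aliased <- names(which(is.na(stats::coef(fit))))
    stop("rank-deficient design; offending columns: ", paste(aliased, collapse = ", "))
  }
  sm <- summary(fit)
  co <- sm$coefficients
  terms <- rownames(co)[-1]
  sdy <- stats::sd(d[[outcome]])
  sdx <- vapply(terms, function(v) stats::sd(d[[v]]), numeric(1))
  coefs <- tibble::tibble(
    term = terms,
    B = unname(co[-1, 1]), SE = unname(co[-1, 2]),
    beta = unname(co[-1, 1] * sdx / sdy),
    t = unname(co[-1, 3]), p = unname(co[-1, 4])
  )
  f <- sm$fstatistic
  structure(list(
    coefficients = coefs,
    intercept = co[1, 1],
    r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
    fstat = unname(f[1]),
    model_p = stats::pf(f[1], f[2], f[3], lower.tail = FALSE),
    n = n, outcome = outcome
  ), class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS %s ~ %d predictors: R2 = %.3f (adj %.3f), F = %.3f (p = %.3g), n = %d\n",
              x$outcome, nrow(x$coefficients), x$r2, x$adj_r2, x$fstat, x$model_p, x$n))
  print(x$coefficients)
  invisible(x)
}

join_exposure_col <- function(table, exposure, scheme, metric, buffer_m = 0,
                              col = "greenspace") {
  df <- as_exposure_df(exposure)
  sel <- df[df$scheme == scheme & df$metric == metric & df$buffer_m == buffer_m, ]
  if (nrow(sel) == 0) stop("exposure table has no ", metric, " values for scheme '",
                           scheme, "' at buffer ", buffer_m)
  out <- table
  out[[col]] <- sel$value[match(table$county_id, sel$county_id)]
  out
}

#' Urban/rural comparison of every county-level variable
#'
#' For each variable, group means and SDs, the urban - rural difference with
#' its SE, and a two-sample t test whose pooled/Welch choice is made by the
#' Levene gate at `alpha`.
#'
#' @param table County table with an `urban` column (0/1 or logical).
#' @param variables Columns to compare (default: every numeric column except
#'   the urban flag and county id).
#' @param alpha Levene gate level.
#' @return Tibble with one row per variable.
#' @export
urban_rural_compare <- function(table, variables = NULL, alpha = 0.05) {
  urban <- as.logical(table$urban)
  if (is.null(variables)) {
    variables <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                         c("urban", "county_id"))
  }
  rows <- lapply(variables, function(v) {
    a <- table[[v]][urban]; b <- table[[v]][!urban]
    r <- two_sample_t(a, b, method = "auto", alpha = alpha)
    tibble::tibble(
      variable = v,
      urban_mean = r$m1, urban_sd = r$sd1,
      rural_mean = r$m2, rural_sd = r$sd2,
      mean_diff = r$mean_diff, se_diff = r$se_diff,
      method = r$method, t = r$t, df = r$df, p = r$p,
      stars = signif_stars(r$p)
    )
  })
  dplyr::bind_rows(rows)
}

#' Regression grid over boundary schemes and greenness metrics
#'
#' 24 models: 6 schemes x {MXN, TIN} x {null, adjusted}. The null model
#' regresses exercise on the greenspace exposure alone; the adjusted model
#' adds the urbanicity flag and nine sociodemographic/behavioral covariates.
#' Counties missing a scheme's exposure are dropped for that scheme only.
#'
#' @param table County health table (from [generate_health()] or real data).
#' @param exposure An `exposure_table` with buffer-0 values for all schemes.
#' @param schemes Schemes to include (default all six).
#' @param covariates Adjustment set for the adjusted model.
#' @return Tibble with one row per scheme x metric x model: greenspace B,
#'   SE, p, stars, R2, adjusted R2, n.
#' @export
boundary_grid <- function(table, exposure, schemes = BOUNDARY_SCHEMES,
                          covariates = HEALTH_COVARIATES) {
  rows <- list()
  for (scheme in schemes) for (metric in c("MXN", "TIN")) {
    d <- join_exposure_col(table, exposure, scheme, metric)
    for (model in c("null", "adjusted")) {
      preds <- if (model == "null") "greenspace" else c("greenspace", covariates)
      fit <- ols_model(d, "exercise", preds)
      g <- fit$coefficients[fit$coefficients$term == "greenspace", ]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        scheme = scheme, metric = metric, model = model,
        B = g$B, SE = g$SE, p = g$p, stars = signif_stars(g$p),
        r2 = fit$r2, adj_r2 = fit$adj_r2, n = fit$n
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Regression grid over buffer sizes (scaling effect)
#'
#' Adjusted exercise models on the TIN exposure of one scheme at each buffer
#' distance; the full coefficient table is reported per buffer.
#'
#' @param table County health table.
#' @param exposure An `exposure_table` containing the scheme at the
#'   requested buffers.
#' @param scheme Boundary scheme (default `combined`).
#' @param buffers Buffer distances in meters (default 0/300/500/1000).
#' @param covariates Adjustment set.
#' @return List with `coefficients` (tibble: buffer_m, term, B, SE, beta, p,
#'   stars) and `model_stats` (tibble: buffer_m, fstat, model_p, r2, adj_r2, n).
#' @export
buffer_grid <- function(table, exposure, scheme = "combined",
                        buffers = BUFFER_SIZES, covariates = HEALTH_COVARIATES) {
  coefs <- list(); stats_ <- list()
  for (buf in buffers) {
    d <- join_exposure_col(table, exposure, scheme, "TIN", buffer_m = buf)
    fit <- ols_model(d, "exercise", c("greenspace", covariates))
    co <- fit$coefficients
    co$stars <- signif_stars(co$p)
    coefs[[length(coefs) + 1L]] <- dplyr::bind_cols(tibble::tibble(buffer_m = buf), co)
    stats_[[length(stats_) + 1L]] <- tibble::tibble(
      buffer_m = buf, fstat = fit$fstat, model_p = fit$model_p,
      r2 = fit$r2, adj_r2 = fit$adj_r2, n = fit$n
    )
  }
  list(coefficients = dplyr::bind_rows(coefs), model_stats = dplyr::bind_rows(stats_))
}

#' Adjusted models for exercise and the two health outcomes
#'
#' Three models sharing the greenspace exposure and covariates: exercise
#' (11 predictors), and poor physical / poor mental health (12 predictors,
#' adding exercise). The exercise model is identical in specification to the
#' no-buffer column of [buffer_grid()].
#'
#' @param table County health table with `exercise`, `poor_physical`,
#'   `poor_mental`.
#' @param exposure An `exposure_table`.
#' @param scheme Boundary scheme for the exposure (default `combined`).
#' @param buffer_m Buffer distance (default 0).
#' @param covariates Adjustment set.
#' @return List with `coefficients` (tibble with an `outcome` column) and
#'   `model_stats` per outcome.
#' @export
health_models <- function(table, exposure, scheme = "combined", buffer_m = 0,
                          covariates = HEALTH_COVARIATES) {
  d <- join_exposure_col(table, exposure, scheme, "TIN", buffer_m = buffer_m)
  outcomes <- c("exercise", "poor_physical", "poor_mental")
  coefs <- list(); stats_ <- list()
  for (out in outcomes) {
    preds <- c("greenspace", covariates, if (out != "exercise") "exercise")
    fit <- ols_model(d, out, preds)
    co <- fit$coefficients
    co$stars <- signif_stars(co$p)
    coefs[[length(coefs) + 1L]] <- dplyr::bind_cols(tibble::tibble(outcome = out), co)
    stats_[[length(stats_) + 1L]] <- tibble::tibble(
      outcome = out, fstat = fit$fstat, model_p = fit$model_p,
      r2 = fit$r2, adj_r2 = fit$adj_r2, n = fit$n
    )
  }
  list(coefficients = dplyr::bind_rows(coefs), model_stats = dplyr::bind_rows(stats_))
}
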