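# Published county-survey summary statistics (ICBRFS round five, Illinois),
# used to exercise the summary-statistic t machinery. The printed table
# reports group means with group SDs in parentheses, the urban - rural mean
# difference with its SE, and a p value; 20 urban and 74 rural county units.
# The `welch` flag marks rows whose printed SE difference is reproduced by
# the unequal-variance formula rather than the pooled one.

#' Printed urban/rural summary statistics from the Illinois county survey
#'
#' @return Tibble with one row per variable: group means and SDs, group
#'   sizes, the printed mean difference, SE difference and p value, and
#'   whether the printed row used Welch's test.
#' @export
icbrfs_table1 <- function() {
  tibble::tribble(
    ~variable,        ~urban_mean, ~urban_sd, ~rural_mean, ~rural_sd, ~printed_diff, ~printed_se, ~printed_p, ~welch,
    "female",          52.47,       3.82,      51.01,       4.02,       1.46,          1.00,        0.150,      FALSE,
    "elderly",         17.19,       2.82,      22.66,       3.37,      -5.47,          0.82,        0.000,      FALSE,
    "white",           79.53,       7.97,      95.88,       4.20,     -16.35,          1.85,        0.000,      TRUE,
    "poverty",          8.81,       4.61,       8.84,       3.83,      -0.04,          1.01,        0.969,      FALSE,
    "employed",        57.65,       5.63,      55.08,       6.40,       2.57,          1.58,        0.107,      FALSE,
    "education",       65.09,       7.90,      54.31,       5.90,      10.78,          1.60,        0.000,      FALSE,
    "smoking",         41.65,       6.20,      45.40,       6.37,      -3.76,          1.60,        0.021,      FALSE,
    "alcohol",          4.67,       1.60,       6.41,       3.49,      -1.74,          0.55,        0.002,      TRUE,
    "obesity",         29.40,       5.52,      31.81,       5.50,      -2.42,          1.39,        0.084,      FALSE,
    "exercise",        76.90,       6.21,      74.02,       4.90,       2.88,          1.31,        0.031,      FALSE,
    "poor_physical",   39.72,       5.04,      36.72,       5.44,       3.00,          1.35,        0.029,      FALSE,
    "poor_mental",     39.27,       5.97,      34.10,       5.31,       5.17,          1.37,        0.000,      FALSE,
    "mxn_county",      70.18,       4.27,      72.70,       1.80,      -2.52,          0.98,        0.018,      TRUE,
    "mxn_h1ha",        65.83,       3.00,      67.91,       3.75,      -2.08,          0.91,        0.025,      FALSE,
    "mxn_h10ha",       68.60,       3.81,      70.42,       4.04,      -1.83,          1.01,        0.073,      FALSE,
    "mxn_place",       65.95,       2.91,      68.23,       3.81,      -2.28,          0.92,        0.015,      FALSE,
    "mxn_urban_area",  65.53,       2.89,      66.90,       3.57,      -1.36,          0.87,        0.123,      FALSE,
    "mxn_combined",    66.21,       3.02,      68.30,       3.74,      -2.09,          0.91,        0.024,      FALSE,
    "tin_county",      17.75,       2.95,      18.60,       2.41,      -0.85,          0.64,        0.187,      FALSE,
    "tin_h1ha",        14.26,       1.90,      14.02,       2.13,       0.24,          0.53,        0.654,      FALSE,
    "tin_h10ha",       16.52,       2.56,      16.70,       2.46,      -0.18,          0.63,        0.776,      FALSE,
    "tin_place",       14.59,       2.21,      14.67,       1.86,      -0.08,          0.49,        0.875,      FALSE,
    "tin_urban_area",  14.20,       1.98,      13.48,       2.06,       0.72,          0.52,        0.169,      FALSE,
    "tin_combined",    14.80,       2.20,      14.73,       1.83,       0.07,          0.48,        0.881,      FALSE
  ) |>
    dplyr::mutate(n_urban = 20L, n_rural = 74L)
}

#' Reconstruct the comparison tests from printed group summaries
#'
#' Applies [t_from_summary()] (pooled or Welch per row) to the printed group
#' means, SDs and sizes, returning the recomputed mean difference, SE
#' difference, t, df and p alongside the printed values.
#'
#' @param summaries A tibble in the layout of [icbrfs_table1()] (the
#'   default).
#' @return Tibble with columns `variable`, `method`, `mean_diff`, `se_diff`,
#'   `t`, `df`, `p`, `stars` plus the printed reference columns.
#' @export
reconstruct_table1 <- function(summaries = icbrfs_table1()) {
  rows <- lapply(seq_len(nrow(summaries)), function(i) {
    s <- summaries[i, ]
    r <- t_from_summary(s$urban_mean, s$urban_sd, s$n_urban,
                        s$rural_mean, s$rural_sd, s$n_rural,
                        method = if (s$welch) "welch" else "pooled")
    tibble::tibble(
      variable = s$variable, method = r$method,
      mean_diff = r$mean_diff, se_diff = r$se_diff,
      t = r$t, df = r$df, p = r$p, stars = signif_stars(r$p),
      printed_diff = s$printed_diff, printed_se = s$printed_se,
      printed_p = s$printed_p
    )
  })
  dplyr::bind_rows(rows)
}
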