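# End-to-end synthetic pipeline and report rendering.

#' Run the full synthetic analysis pipeline
#'
#' World -> NDVI stack -> greenness raster -> six boundary schemes ->
#' exposure table (with buffered variants of one scheme) -> county health
#' table -> the full statistical battery (urban/rural comparison, scheme and
#' buffer regression grids, health-outcome models, correlation matrix,
#' coverage accounting). Deterministic for a fixed config.
#'
#' @param config A [world_config()].
#' @param outdir Optional directory; when given, all tables and layers are
#'   written there as CSV/GeoJSON/ASCII-grid files.
#' @param schemes Boundary schemes to build (default all six).
#' @param buffers Buffer distances applied to `buffer_scheme` (default
#'   0/300/500/1000 m).
#' @param buffer_scheme Scheme receiving the buffered variants (default
#'   `combined`).
#' @param write_rasters Also write the NDVI stack and greenness bands
#'   (larger files; default FALSE).
#' @return A bundle (list) with every intermediate and result object.
#' @export
run_pipeline <- function(config = world_config(), outdir = NULL,
                         schemes = BOUNDARY_SCHEMES, buffers = BUFFER_SIZES,
                         buffer_scheme = "combined", write_rasters = FALSE) {
  world <- generate_region(config)
  stack <- generate_ndvi_stack(world, config)
  green <- compute_greenness(stack)
  boundaries <- lapply(schemes, function(s) build_boundary(world, s))
  names(boundaries) <- schemes

  exposure <- build_exposure_table(green, boundaries, buffers = 0)
  extra <- setdiff(buffers, 0)
  if (length(extra) && buffer_scheme %in% schemes) {
    exposure <- dplyr::bind_rows(
      exposure,
      build_exposure_table(green, boundaries[buffer_scheme], buffers = extra)
    )
    class(exposure) <- c("exposure_table", class(tibble::tibble()))
  }

  health <- generate_health(world, exposure, config)
  table <- health$table  # already carries the urban flag as 0/1
  full_table <- dplyr::left_join(table, exposure_wide(exposure), by = "county_id")

  bundle <- list(
    config = config,
    world = world,
    stack = stack,
    greenness = green,
    boundaries = boundaries,
    exposure = exposure,
    health = health,
    table = table,
    compare = urban_rural_compare(full_table),
    correlation = pearson_matrix(exposure),
    scheme_grid = boundary_grid(table, exposure, schemes = schemes),
    buffer_models = if (buffer_scheme %in% schemes)
      buffer_grid(table, exposure, scheme = buffer_scheme, buffers = buffers),
    outcome_models = if (buffer_scheme %in% schemes)
      health_models(table, exposure, scheme = buffer_scheme),
    coverage = coverage_stats(boundaries, world)
  )
  class(bundle) <- "greenspace_bundle"

  if (!is.null(outdir)) write_bundle(bundle, outdir, write_rasters = write_rasters)
  bundle
}

write_csv_q <- function(x, path) utils::write.csv(x, path, row.names = FALSE)

#' Write a pipeline bundle to disk
#'
#' @param bundle A bundle from [run_pipeline()].
#' @param outdir Output directory (created if needed).
#' @param write_rasters Also write NDVI and greenness rasters.
#' @export
write_bundle <- function(bundle, outdir, write_rasters = FALSE) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  write_world(bundle$world, file.path(outdir, "world"))
  write_csv_q(tibble::as_tibble(bundle$exposure), file.path(outdir, "exposure_long.csv"))
  write_csv_q(exposure_wide(bundle$exposure), file.path(outdir, "exposure_wide.csv"))
  write_csv_q(bundle$table, file.path(outdir, "county_health.csv"))
  jsonlite::write_json(bundle$health$truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_csv_q(bundle$compare, file.path(outdir, "urban_rural_comparison.csv"))
  write_csv_q(as.data.frame(bundle$correlation) |>
                tibble::rownames_to_column("column"),
              file.path(outdir, "exposure_correlation.csv"))
  write_csv_q(bundle$scheme_grid, file.path(outdir, "scheme_grid.csv"))
  if (!is.null(bundle$buffer_models)) {
    write_csv_q(bundle$buffer_models$coefficients, file.path(outdir, "buffer_grid.csv"))
    write_csv_q(bundle$buffer_models$model_stats, file.path(outdir, "buffer_grid_model_stats.csv"))
  }
  if (!is.null(bundle$outcome_models)) {
    write_csv_q(bundle$outcome_models$coefficients, file.path(outdir, "health_models.csv"))
    write_csv_q(bundle$outcome_models$model_stats, file.path(outdir, "health_models_stats.csv"))
  }
  write_csv_q(bundle$coverage$schemes, file.path(outdir, "coverage_schemes.csv"))
  write_csv_q(bundle$coverage$union, file.path(outdir, "coverage_union.csv"))
  if (write_rasters) {
    write_ndvi_stack(bundle$stack, file.path(outdir, "ndvi_stack"))
    write_ascii_grid(bundle$greenness$mxn, bundle$greenness$grid,
                     file.path(outdir, "mxn.asc"))
    write_ascii_grid(bundle$greenness$tin, bundle$greenness$grid,
                     file.path(outdir, "tin.asc"))
  }
  invisible(outdir)
}

fmt_num <- function(x, d = 3) formatC(x, format = "f", digits = d)

#' Render a human-readable markdown report of a pipeline bundle
#'
#' Sections mirror the analysis tables: urban/rural comparison, the scheme x
#' metric regression grid, the buffer grid, the health-outcome models, the
#' exposure correlation matrix and the coverage accounting, with the usual
#' significance stars. Missing bundle components produce a partial report
#' with warnings.
#'
#' @param bundle A bundle from [run_pipeline()].
#' @return Character vector of markdown lines (invisibly printable via
#'   `cat(..., sep = "\n")`).
#' @export
render_report <- function(bundle) {
  out <- c("# Community green-space analysis report", "")
  star_note <- "Stars: *** p < 0.001, ** p < 0.01, * p < 0.05."

  if (!is.null(bundle$compare)) {
    out <- c(out, "## Urban/rural comparison", "",
             "| variable | urban mean (SD) | rural mean (SD) | diff (SE) | method | p |",
             "|---|---|---|---|---|---|")
    cmp <- bundle$compare
    for (i in seq_len(nrow(cmp))) {
      out <- c(out, sprintf(
        "| %s | %s (%s) | %s (%s) | %s (%s) | %s | %s%s |",
        cmp$variable[i], fmt_num(cmp$urban_mean[i], 2), fmt_num(cmp$urban_sd[i], 2),
        fmt_num(cmp$rural_mean[i], 2), fmt_num(cmp$rural_sd[i], 2),
        fmt_num(cmp$mean_diff[i], 2), fmt_num(cmp$se_diff[i], 2),
        cmp$method[i], fmt_num(cmp$p[i], 3), cmp$stars[i]
      ))
    }
    out <- c(out, "", star_note, "")
  } else {
    warning("bundle has no urban/rural comparison; section skipped")
    out <- c(out, "## Urban/rural comparison", "", "_not available_", "")
  }

  if (!is.null(bundle$scheme_grid)) {
    out <- c(out, "## Greenness vs exercise across boundary schemes", "",
             "| scheme | metric | model | B (SE) | R2 (adj.) | n |",
             "|---|---|---|---|---|---|")
    g <- bundle$scheme_grid
    for (i in seq_len(nrow(g))) {
      out <- c(out, sprintf(
        "| %s | %s | %s | %s (%s)%s | %s (%s) | %d |",
        g$scheme[i], g$metric[i], g$model[i],
        fmt_num(g$B[i]), fmt_num(g$SE[i]), g$stars[i],
        fmt_num(g$r2[i]), fmt_num(g$adj_r2[i]), g$n[i]
      ))
    }
    out <- c(out, "", star_note, "")
  }

  if (!is.null(bundle$buffer_models)) {
    out <- c(out, "## Buffer (scaling) grid: adjusted exercise models", "",
             "| buffer (m) | term | B (SE) | beta | p |", "|---|---|---|---|---|")
    b <- bundle$buffer_models$coefficients
    for (i in seq_len(nrow(b))) {
      out <- c(out, sprintf(
        "| %g | %s | %s (%s)%s | %s | %s |",
        b$buffer_m[i], b$term[i], fmt_num(b$B[i]), fmt_num(b$SE[i]), b$stars[i],
        fmt_num(b$beta[i], 2), fmt_num(b$p[i], 3)
      ))
    }
    ms <- bundle$buffer_models$model_stats
    for (i in seq_len(nrow(ms))) {
      out <- c(out, sprintf("- buffer %g m: F = %s (p = %s), R2 = %s (adj. %s), n = %d",
                            ms$buffer_m[i], fmt_num(ms$fstat[i]), fmt_num(ms$model_p[i]),
                            fmt_num(ms$r2[i]), fmt_num(ms$adj_r2[i]), ms$n[i]))
    }
    out <- c(out, "")
  }

  if (!is.null(bundle$outcome_models)) {
    out <- c(out, "## Health outcome models", "",
             "| outcome | term | B (SE) | beta | p |", "|---|---|---|---|---|")
    h <- bundle$outcome_models$coefficients
    for (i in seq_len(nrow(h))) {
      out <- c(out, sprintf(
        "| %s | %s | %s (%s)%s | %s | %s |",
        h$outcome[i], h$term[i], fmt_num(h$B[i]), fmt_num(h$SE[i]), h$stars[i],
        fmt_num(h$beta[i], 2), fmt_num(h$p[i], 3)
      ))
    }
    out <- c(out, "", star_note, "")
  }

  if (!is.null(bundle$correlation)) {
    out <- c(out, "## Exposure correlation matrix", "", "```",
             utils::capture.output(print(round(bundle$correlation, 2))), "```", "")
  }

  if (!is.null(bundle$coverage)) {
    cov <- bundle$coverage
    out <- c(out, "## Boundary coverage of the region", "")
    empty_schemes <- cov$schemes$scheme[cov$schemes$area_m2 == 0]
    for (i in seq_len(nrow(cov$schemes))) {
      out <- c(out, sprintf("- %s: %.1f km2 (%.2f%% of region)",
                            cov$schemes$scheme[i], cov$schemes$area_m2[i] / 1e6,
                            cov$schemes$pct_of_region[i]))
    }
    out <- c(out, sprintf("- union of all schemes: %.1f km2 (%.2f%% of region)",
                          cov$union$area_m2 / 1e6, cov$union$pct_of_region))
    if (length(empty_schemes)) {
      out <- c(out, sprintf("- schemes with no qualifying area anywhere: %s",
                            paste(empty_schemes, collapse = ", ")))
    }
    out <- c(out, "")
  }

  out
}
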