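# Monte-Carlo experiments over replicate synthetic worlds.
#
# Each replicate regenerates the full chain (world -> NDVI -> greenness ->
# boundaries -> exposure -> health) under a derived seed, then fits the
# model of interest. The experiment configs default to the study-scale 94
# county units but with 12 x 12 pixel counties, which keeps a full
# replicate cheap while preserving the spatial structure.

#' A compact configuration for replicate experiments
#'
#' Same county count and planted effects as [world_config()], smaller
#' counties (3 km, i.e. 12 x 12 NDVI pixels) so replicate loops stay fast.
#'
#' @param ... Overrides passed to [world_config()].
#' @export
experiment_config <- function(...) {
  args <- list(...)
  defaults <- list(county_size_m = 3000)
  world_config_args <- utils::modifyList(defaults, args)
  do.call(world_config, world_config_args)
}

#' Simulate one study: world, exposure and county table
#'
#' @param config A [world_config()].
#' @param schemes Boundary schemes to build (fewer schemes = faster).
#' @param buffers Buffers for the exposure table.
#' @return List with `world`, `exposure`, `health`, and the modeling `table`
#'   (health covariates/outcomes plus the urban flag).
#' @export
simulate_study <- function(config, schemes = "combined", buffers = 0) {
  world <- generate_region(config)
  stack <- generate_ndvi_stack(world, config)
  green <- compute_greenness(stack)
  boundaries <- lapply(schemes, function(s) build_boundary(world, s))
  exposure <- build_exposure_table(green, boundaries, buffers = buffers)
  health <- generate_health(world, exposure, config)
  table <- health$table
  table$urban <- as.numeric(world$counties$urban[match(table$county_id, world$counties$id)])
  list(world = world, exposure = exposure, health = health, table = table)
}

fit_generating_model <- function(sim, scheme, outcome = "exercise") {
  d <- join_exposure_col(sim$table, sim$exposure, scheme, "TIN")
  ols_model(d, outcome, c("greenspace", HEALTH_COVARIATES))
}

#' Planted-effect recovery experiment
#'
#' Replicate worlds with a planted TIN-on-exercise coefficient; each
#' replicate refits the generating model and records the greenspace
#' estimate, its confidence interval, and whether the interval covers the
#' planted value.
#'
#' @param n_rep Number of replicate worlds.
#' @param config Base config (the planted coefficient comes from it).
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param level Confidence level (default 0.95).
#' @return Tibble with one row per replicate: estimate, SE, p, CI bounds,
#'   `covered`.
#' @export
recovery_experiment <- function(n_rep, config = experiment_config(), seed = 1,
                                level = 0.95) {
  beta <- config$effect_beta_tin_on_exercise
  scheme <- config$effect_scheme
  rows <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- config
    cfg$seed <- as.integer(seed + 7L * r)
    sim <- simulate_study(cfg, schemes = scheme)
    fit <- fit_generating_model(sim, scheme)
    g <- fit$coefficients[fit$coefficients$term == "greenspace", ]
    tcrit <- stats::qt(1 - (1 - level) / 2, df = fit$n - nrow(fit$coefficients) - 1)
    lo <- g$B - tcrit * g$SE; hi <- g$B + tcrit * g$SE
    rows[[r]] <- tibble::tibble(
      rep = r, estimate = g$B, se = g$SE, p = g$p,
      ci_lo = lo, ci_hi = hi, covered = (lo <= beta & beta <= hi)
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "planted_beta") <- beta
  out
}

#' Null-calibration experiment
#'
#' Replicates with a zero planted coefficient; records the greenspace p
#' value of the generating model per replicate, for checking the size of
#' the test at a nominal alpha.
#'
#' @param n_rep Number of replicates.
#' @param config Base config; its planted coefficient is forced to 0.
#' @param seed Base seed.
#' @return Tibble with one row per replicate (estimate, p).
#' @export
null_calibration <- function(n_rep, config = experiment_config(), seed = 1) {
  config$effect_beta_tin_on_exercise <- 0
  scheme <- config$effect_scheme
  rows <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- config
    cfg$seed <- as.integer(seed + 13L * r)
    sim <- simulate_study(cfg, schemes = scheme)
    fit <- fit_generating_model(sim, scheme)
    g <- fit$coefficients[fit$coefficients$term == "greenspace", ]
    rows[[r]] <- tibble::tibble(rep = r, estimate = g$B, p = g$p)
  }
  dplyr::bind_rows(rows)
}

#' TIN-vs-MXN significance comparison across the scheme grid
#'
#' Replicate worlds in which exercise is generated from the season-integrated
#' greenness (TIN) while the annual maximum (MXN) is only partially coupled
#' to it (class-varying amplitudes and county-varying season lengths). Each
#' replicate runs the full scheme x metric x model grid and records which
#' cells reject at alpha.
#'
#' @param n_rep Number of replicates.
#' @param config Base config.
#' @param seed Base seed.
#' @param alpha Rejection level (default 0.05).
#' @param schemes Schemes to include in the grid.
#' @return List with `cells` (per-replicate grid long table) and `rates`
#'   (rejection rate per metric x model).
#' @export
metric_comparison_experiment <- function(n_rep, config = experiment_config(),
                                         seed = 1, alpha = 0.05,
                                         schemes = BOUNDARY_SCHEMES) {
  rows <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- config
    cfg$seed <- as.integer(seed + 17L * r)
    sim <- simulate_study(cfg, schemes = schemes)
    grid <- boundary_grid(sim$table, sim$exposure, schemes = schemes)
    grid$rep <- r
    rows[[r]] <- grid
  }
  cells <- dplyr::bind_rows(rows)
  rates <- cells |>
    dplyr::group_by(.data$metric, .data$model) |>
    dplyr::summarise(reject_rate = mean(.data$p < alpha), .groups = "drop")
  list(cells = cells, rates = rates)
}
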