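# Synthetic study region with known ground truth.
#
# The generator lays counties on a rectangular grid in a planar meter
# coordinate system. Urban counties carry a dense urban core surrounded by a
# residential ring; rural counties get a compact town (in most counties),
# one or two villages, forest patches and an agricultural matrix. Block
# groups tile each county exactly. Census-place and urban-area layers are
# derived from the painted land cover so that villages appear in places but
# rarely in urban areas. Seasonal NDVI follows a per-class double-logistic
# annual curve; county health tables are produced by a linear model with
# planted coefficients, returned alongside the table as a truth sidecar.

LANDCOVER_CLASSES <- c("urban_core", "residential", "agricultural", "forest", "water")

default_density_law <- function() {
  # households per hectare: log-normal (median, sigma) per block-group label
  list(
    urban_core   = c(median = 12,   sigma = 0.30),
    town         = c(median = 1.5,  sigma = 0.30),
    residential  = c(median = 0.8,  sigma = 0.50),
    agricultural = c(median = 0.05, sigma = 0.60),
    forest       = c(median = 0.02, sigma = 0.60)
  )
}

default_ndvi_params <- function() {
  # annual phenology per land-cover class: NDVI percent baseline, seasonal
  # amplitude, season onset/offset (months), and logistic steepness
  data.frame(
    class     = LANDCOVER_CLASSES,
    baseline  = c(38, 42, 32, 48, 0),
    amplitude = c(16, 25, 44, 28, 0),
    onset     = c(4.0, 3.8, 5.0, 3.5, 6.0),
    offset    = c(9.5, 10.0, 9.0, 10.5, 6.0),
    steepness = c(1.2, 1.2, 1.8, 1.0, 1.0)
  )
}

#' Configuration for the synthetic world generator
#'
#' Defaults mirror the scale of the motivating study design: 94 county units
#' of which 20 are urban, 250 m NDVI pixels, 12 periods per year, and a
#' planted greenness-to-exercise coefficient of 0.8 on the time-integrated
#' metric within the combined place/urban-area boundary.
#'
#' @param n_counties Number of counties (>= 2).
#' @param urban_fraction Fraction of counties flagged urban, in \[0, 1\].
#' @param blockgroups_per_county Block groups per county; must be a perfect
#'   square so they tile the square county.
#' @param county_size_m County edge length in meters; must be a multiple of
#'   `pixel_size_m` times the block-group grid side.
#' @param pixel_size_m NDVI pixel size in meters (default 250).
#' @param periods_per_year NDVI periods per year (>= 4, default 12).
#' @param household_density Log-normal (median, sigma) households/hectare per
#'   block-group label; see `communitygreen:::default_density_law`.
#' @param ndvi_params Per-class phenology parameters (baseline, amplitude,
#'   onset, offset, steepness).
#' @param county_amp_range Per-county multiplicative range for seasonal
#'   amplitude (uniform draw); moves the annual maximum and the seasonal
#'   average together.
#' @param county_season_shift Half-range (months) of the per-county uniform
#'   shifts applied independently to season onset and offset.
#' @param county_shape_range Per-county multiplicative range for the
#'   double-logistic steepness (uniform draw). A steeper ("boxier") curve
#'   raises the seasonal average relative to the fixed annual maximum, so
#'   this is the main source of county-level variation in the
#'   time-integrated metric that the maximum cannot see — it decouples the
#'   two greenness measures.
#' @param noise_sd Additive Gaussian noise on NDVI observations (percent).
#' @param effect_beta_tin_on_exercise Planted coefficient of the TIN exposure
#'   on county exercise percent.
#' @param effect_scheme Boundary scheme whose TIN carries the planted effect.
#' @param beta_tin_physical,beta_tin_mental Planted greenness coefficients
#'   for the two health outcomes (default 0).
#' @param health_noise_sd Residual SD of the county health model (percent).
#' @param town_prob Probability that a rural county has a compact town.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return An object of class `world_config`.
#' @export
world_config <- function(n_counties = 94,
                         urban_fraction = 20 / 94,
                         blockgroups_per_county = 16,
                         county_size_m = 12000,
                         pixel_size_m = 250,
                         periods_per_year = 12,
                         household_density = default_density_law(),
                         ndvi_params = default_ndvi_params(),
                         county_amp_range = c(0.92, 1.08),
                         county_season_shift = 0.8,
                         county_shape_range = c(0.55, 1.8),
                         noise_sd = 2,
                         effect_beta_tin_on_exercise = 0.8,
                         effect_scheme = "combined",
                         beta_tin_physical = 0,
                         beta_tin_mental = 0,
                         health_noise_sd = 4,
                         town_prob = 0.92,
                         seed = 1L) {
  stopifnot(n_counties >= 2, urban_fraction >= 0, urban_fraction <= 1,
            pixel_size_m > 0, periods_per_year >= 4,
            blockgroups_per_county >= 1, health_noise_sd >= 0, noise_sd >= 0)
  bgn <- sqrt(blockgroups_per_county)
  if (bgn != round(bgn)) {
    stop("blockgroups_per_county must be a perfect square")
  }
  county_px <- county_size_m / pixel_size_m
  if (abs(county_px - round(county_px)) > 1e-9) {
    stop("county_size_m must be a multiple of pixel_size_m")
  }
  if (round(county_px) %% bgn != 0) {
    stop("the pixel grid cannot host the requested block-group count")
  }
  structure(list(
    n_counties = as.integer(n_counties),
    urban_fraction = urban_fraction,
    blockgroups_per_county = as.integer(blockgroups_per_county),
    county_size_m = county_size_m,
    pixel_size_m = pixel_size_m,
    periods_per_year = as.integer(periods_per_year),
    household_density = household_density,
    ndvi_params = ndvi_params,
    county_amp_range = county_amp_range,
    county_season_shift = county_season_shift,
    county_shape_range = county_shape_range,
    noise_sd = noise_sd,
    effect_beta_tin_on_exercise = effect_beta_tin_on_exercise,
    effect_scheme = effect_scheme,
    beta_tin_physical = beta_tin_physical,
    beta_tin_mental = beta_tin_mental,
    health_noise_sd = health_noise_sd,
    town_prob = town_prob,
    seed = as.integer(seed)
  ), class = "world_config")
}

# classify block groups of one county by normalized distance from the center
bg_labels_urban <- function(bgn) {
  idx <- expand.grid(i = seq_len(bgn), j = seq_len(bgn))
  u <- (idx$i - (bgn + 1) / 2) / bgn
  v <- (idx$j - (bgn + 1) / 2) / bgn
  r <- sqrt(u^2 + v^2)
  lab <- rep("agricultural", nrow(idx))
  lab[r <= 0.42] <- "residential"
  lab[r <= 0.21] <- "urban_core"
  if (!any(lab == "urban_core")) lab[which.min(r)] <- "urban_core"
  lab
}

#' Generate the synthetic region
#'
#' Deterministic for a fixed config (the seed is applied internally).
#'
#' @param config A [world_config()].
#' @return An object of class `synthetic_world` with counties, block groups
#'   (tiling their county), places, urban areas, a land-cover raster, and
#'   per-county phenology modifiers.
#' @export
generate_region <- function(config) {
  stopifnot(inherits(config, "world_config"))
  set.seed(config$seed)
  n <- config$n_counties
  bgn <- as.integer(sqrt(config$blockgroups_per_county))
  csz <- config$county_size_m
  px <- config$pixel_size_m
  county_px <- as.integer(round(csz / px))
  bg_px <- county_px %/% bgn
  bg_sz <- bgn_sz <- csz / bgn

  grid_nx <- ceiling(sqrt(n))
  grid_ny <- ceiling(n / grid_nx)
  ids <- sprintf("c%03d", seq_len(n))
  ix <- (seq_len(n) - 1L) %% grid_nx
  iy <- (seq_len(n) - 1L) %/% grid_nx
  n_urban <- round(config$urban_fraction * n)
  urban_ids <- sample.int(n, n_urban)
  urban <- seq_len(n) %in% urban_ids

  counties <- tibble::tibble(
    id = ids, urban = urban,
    xmin = ix * csz, ymin = iy * csz, xmax = (ix + 1) * csz, ymax = (iy + 1) * csz,
    amp_factor = stats::runif(n, config$county_amp_range[1], config$county_amp_range[2]),
    onset_shift = stats::runif(n, -config$county_season_shift, config$county_season_shift),
    offset_shift = stats::runif(n, -config$county_season_shift, config$county_season_shift),
    shape_factor = exp(stats::runif(n, log(config$county_shape_range[1]),
                                    log(config$county_shape_range[2])))
  )

  lc <- matrix(match("agricultural", LANDCOVER_CLASSES),
               nrow = grid_ny * county_px, ncol = grid_nx * county_px)
  dens_law <- config$household_density

  n_bg <- n * bgn * bgn
  bg_id <- character(n_bg); bg_county <- character(n_bg); bg_label <- character(n_bg)
  bg_xmin <- numeric(n_bg); bg_ymin <- numeric(n_bg)
  bg_xmax <- numeric(n_bg); bg_ymax <- numeric(n_bg)
  bg_hh <- numeric(n_bg)
  bg_k <- 0L
  place_geoms <- list()
  ua_geoms <- list()
  county_pop <- numeric(n)

  # pixel-index painting; coordinates are multiples of the pixel size
  paint <- function(xmin, ymin, xmax, ymax, class) {
    c0 <- as.integer(round(xmin / px)) + 1L
    c1 <- as.integer(round(xmax / px))
    r0 <- as.integer(round(ymin / px)) + 1L
    r1 <- as.integer(round(ymax / px))
    lc[r0:r1, c0:c1] <<- match(class, LANDCOVER_CLASSES)
  }

  for (ci in seq_len(n)) {
    cx0 <- counties$xmin[ci]; cy0 <- counties$ymin[ci]
    idx <- expand.grid(i = seq_len(bgn), j = seq_len(bgn))
    if (urban[ci]) {
      labels <- bg_labels_urban(bgn)
      # a forest corner and a pond corner add class variety inside urban counties
      ag <- which(labels == "agricultural")
      if (length(ag) >= 2) labels[sample(ag, 1)] <- "forest"
      has_town <- FALSE
    } else {
      labels <- rep("agricultural", nrow(idx))
      has_town <- stats::runif(1) < config$town_prob
      open <- seq_along(labels)
      if (has_town && length(open)) {
        town_bg <- sample(open, 1)
        labels[town_bg] <- "town"
        open <- setdiff(open, town_bg)
      }
      n_vill <- min(length(open), sample(1:2, 1))
      if (n_vill > 0) {
        vill <- if (length(open) == 1) open else sample(open, n_vill)
        labels[vill] <- "residential"
        open <- setdiff(open, vill)
      }
      n_forest <- min(length(open), sample(1:3, 1))
      if (n_forest > 0) {
        fo <- if (length(open) == 1) open else sample(open, n_forest)
        labels[fo] <- "forest"
      }
    }

    place_parts <- list()
    ua_parts <- list()
    hh <- numeric(nrow(idx))
    for (b in seq_len(nrow(idx))) {
      bx0 <- cx0 + (idx$i[b] - 1) * bg_sz; by0 <- cy0 + (idx$j[b] - 1) * bg_sz
      bx1 <- bx0 + bg_sz; by1 <- by0 + bg_sz
      lab <- labels[b]
      if (lab == "town") {
        # compact town: central half residential with a small dense core
        half <- floor(bg_px / 4) * px
        tx0 <- bx0 + half; ty0 <- by0 + half
        tx1 <- bx1 - half; ty1 <- by1 - half
        paint(tx0, ty0, tx1, ty1, "residential")
        core <- max(px, floor(bg_px / 6) * px)
        mx <- (tx0 + tx1) / 2; my <- (ty0 + ty1) / 2
        qx0 <- floor((mx - core / 2) / px) * px; qy0 <- floor((my - core / 2) / px) * px
        paint(qx0, qy0, qx0 + core, qy0 + core, "urban_core")
        place_parts[[length(place_parts) + 1L]] <- gs_rect(tx0, ty0, tx1, ty1)
        ua_parts[[length(ua_parts) + 1L]] <- gs_rect(tx0, ty0, tx1, ty1)
      } else if (lab == "residential") {
        if (urban[ci]) {
          paint(bx0, by0, bx1, by1, "residential")
          ua_parts[[length(ua_parts) + 1L]] <- gs_rect(bx0, by0, bx1, by1)
          # incorporated part of the city: central portion of the ring tile
          q <- floor(bg_px / 4) * px
          place_parts[[length(place_parts) + 1L]] <- gs_rect(bx0 + q, by0 + q, bx1 - q, by1 - q)
        } else {
          # village: built-up center inside an agricultural tile
          q <- floor(bg_px / 4) * px
          vx0 <- bx0 + q; vy0 <- by0 + q; vx1 <- bx1 - q; vy1 <- by1 - q
          paint(vx0, vy0, vx1, vy1, "residential")
          place_parts[[length(place_parts) + 1L]] <- gs_rect(vx0, vy0, vx1, vy1)
        }
      } else if (lab == "urban_core") {
        paint(bx0, by0, bx1, by1, "urban_core")
        ua_parts[[length(ua_parts) + 1L]] <- gs_rect(bx0, by0, bx1, by1)
        place_parts[[length(place_parts) + 1L]] <- gs_rect(bx0, by0, bx1, by1)
      } else if (lab == "forest") {
        paint(bx0, by0, bx1, by1, "forest")
      } else {
        # agricultural matrix; occasionally a small pond
        if (stats::runif(1) < 0.2 && bg_px >= 3) {
          pr <- sample.int(bg_px - 2L, 2, replace = TRUE)
          wx0 <- bx0 + (pr[1] - 1) * px; wy0 <- by0 + (pr[2] - 1) * px
          paint(wx0, wy0, wx0 + 2 * px, wy0 + 2 * px, "water")
        }
      }
      law <- dens_law[[lab]]
      density <- stats::rlnorm(1, meanlog = log(law[["median"]]), sdlog = law[["sigma"]])
      area_ha <- (bg_sz / 100)^2
      hh[b] <- round(density * area_ha)
      bg_k <- bg_k + 1L
      bg_id[bg_k] <- sprintf("%s_bg%02d", ids[ci], b)
      bg_county[bg_k] <- ids[ci]
      bg_label[bg_k] <- lab
      bg_xmin[bg_k] <- bx0; bg_ymin[bg_k] <- by0
      bg_xmax[bg_k] <- bx1; bg_ymax[bg_k] <- by1
      bg_hh[bg_k] <- hh[b]
    }
    county_pop[ci] <- round(sum(hh) * 2.56)
    place_geoms[[ids[ci]]] <- gs_geom(place_parts, disjoint = TRUE)
    ua_geoms[[ids[ci]]] <- gs_geom(ua_parts, disjoint = TRUE)
  }

  counties$population <- county_pop
  region_px_x <- grid_nx * county_px
  region_px_y <- grid_ny * county_px
  landcover <- list(
    grid = gs_grid(0, 0, region_px_y, region_px_x, px),
    classes = lc, levels = LANDCOVER_CLASSES
  )
  # pixels beyond the last partial county row exist on the raster but belong
  # to no county; mark them water so they read as empty background
  county_index <- matrix(0L, nrow = region_px_y, ncol = region_px_x)
  for (ci in seq_len(n)) {
    r0 <- iy[ci] * county_px + 1L; r1 <- (iy[ci] + 1L) * county_px
    c0 <- ix[ci] * county_px + 1L; c1 <- (ix[ci] + 1L) * county_px
    county_index[r0:r1, c0:c1] <- ci
  }
  landcover$classes[county_index == 0L] <- match("water", LANDCOVER_CLASSES)

  structure(list(
    config = config,
    counties = counties,
    blockgroups = tibble::tibble(
      id = bg_id, county_id = bg_county, label = bg_label,
      xmin = bg_xmin, ymin = bg_ymin, xmax = bg_xmax, ymax = bg_ymax,
      area_ha = (bg_sz / 100)^2, households = bg_hh
    ),
    places = place_geoms,
    urban_areas = ua_geoms,
    landcover = landcover,
    county_index = county_index
  ), class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "<synthetic_world: %d counties (%d urban), %d block groups, %d x %d land-cover pixels>\n",
    nrow(x$counties), sum(x$counties$urban), nrow(x$blockgroups),
    x$landcover$grid$nrow, x$landcover$grid$ncol
  ))
  invisible(x)
}

#' County geometry as a `gs_geom`
#' @param world A `synthetic_world`.
#' @param county_id County identifier.
#' @export
county_geom <- function(world, county_id) {
  r <- world$counties[world$counties$id == county_id, ]
  if (nrow(r) != 1) stop("unknown county: ", county_id)
  gs_geom(list(gs_rect(r$xmin, r$ymin, r$xmax, r$ymax)), disjoint = TRUE)
}

county_rect <- function(world, county_id) {
  r <- world$counties[world$counties$id == county_id, ]
  c(r$xmin, r$ymin, r$xmax, r$ymax)
}

# double-logistic seasonal shape, normalized so its maximum over the sampled
# periods equals 1 (hence max NDVI = baseline + amplitude exactly)
season_shape <- function(t, onset, offset, k) {
  g <- stats::plogis(k * (t - onset)) + stats::plogis(-k * (t - offset)) - 1
  g <- pmax(g, 0)
  m <- max(g)
  if (m <= 0) rep(0, length(t)) else g / m
}

#' Generate a seasonal NDVI stack for a synthetic world
#'
#' Per pixel, NDVI(t) = baseline + amplitude x shape(t) for the pixel's
#' land-cover class, with per-county amplitude factors and season-shift
#' modifiers, plus additive Gaussian noise, clipped to \[0, 100\]. Water
#' pixels have zero baseline and amplitude.
#'
#' @param world A `synthetic_world`.
#' @param config The [world_config()] used to build the world (defaults to
#'   the config stored in the world).
#' @return An `ndvi_stack` on the land-cover grid.
#' @export
generate_ndvi_stack <- function(world, config = world$config) {
  set.seed(config$seed + 1L)
  grid <- world$landcover$grid
  nt <- config$periods_per_year
  t_mid <- (seq_len(nt) - 0.5) * 12 / nt
  pars <- config$ndvi_params
  n <- nrow(world$counties)
  ncls <- length(LANDCOVER_CLASSES)

  # curve per (county, class, period); county 0 = out-of-region background
  curves <- array(0, dim = c(n + 1L, ncls, nt))
  for (ci in seq_len(n)) {
    af <- world$counties$amp_factor[ci]
    sf <- world$counties$shape_factor[ci]
    d_on <- world$counties$onset_shift[ci]
    d_off <- world$counties$offset_shift[ci]
    for (k in seq_len(ncls)) {
      p <- pars[pars$class == LANDCOVER_CLASSES[k], ]
      if (p$amplitude <= 0 && p$baseline <= 0) next
      shp <- season_shape(t_mid, p$onset + d_on, p$offset + d_off, p$steepness * sf)
      curves[ci + 1L, k, ] <- p$baseline + p$amplitude * af * shp
    }
  }

  cls <- world$landcover$classes
  cidx <- world$county_index
  flat <- (as.vector(cidx)) * ncls + as.vector(cls)  # 1-based lookup below
  vals <- array(NA_real_, dim = c(grid$nrow, grid$ncol, nt))
  for (t in seq_len(nt)) {
    lut <- as.vector(t(curves[, , t]))  # index (county*ncls + class)
    layer <- lut[flat]
    if (config$noise_sd > 0) {
      layer <- layer + stats::rnorm(length(layer), 0, config$noise_sd)
    }
    vals[, , t] <- matrix(pmin(pmax(layer, 0), 100), nrow = grid$nrow)
  }
  ndvi_stack(grid, vals, periods = sprintf("m%02d", seq_len(nt)))
}

# covariate generator: uniform ranges centered on urban/rural means with
# half-width sqrt(3) * sd (so the uniform matches the target mean and SD)
covariate_spec <- function() {
  tibble::tribble(
    ~name,       ~urban_mean, ~rural_mean, ~sd,
    "female",     52.47,       51.01,       3.9,
    "elderly",    17.19,       22.66,       3.1,
    "white",      79.53,       95.88,       6.0,
    "poverty",     8.81,        8.84,       4.2,
    "employed",   57.65,       55.08,       6.0,
    "education",  65.09,       54.31,       6.9,
    "smoking",    41.65,       45.40,       6.3,
    "alcohol",     4.67,        6.41,       2.5,
    "obesity",    29.40,       31.81,       5.5
  )
}

HEALTH_COVARIATES <- c("urban", "female", "elderly", "white", "poverty",
                       "employed", "education", "smoking", "alcohol", "obesity")

default_health_coefs <- function(config) {
  list(
    exercise = c(tin = config$effect_beta_tin_on_exercise, urban = 0,
                 female = 0.16, elderly = -0.39, white = 0.02, poverty = -0.27,
                 employed = -0.04, education = -0.02, smoking = -0.07,
                 alcohol = 0.08, obesity = -0.17),
    poor_physical = c(tin = config$beta_tin_physical, urban = 0,
                      female = 0.62, elderly = -0.38, white = 0, poverty = 0.38,
                      employed = 0.02, education = -0.2, smoking = 0.05,
                      alcohol = -0.3, obesity = 0.08, exercise = -0.2),
    poor_mental = c(tin = config$beta_tin_mental, urban = 0,
                    female = 0.75, elderly = -0.92, white = 0.01, poverty = 0.34,
                    employed = -0.15, education = -0.06, smoking = 0.08,
                    alcohol = 0.04, obesity = 0.03, exercise = 0.1)
  )
}

#' Generate a county health table with planted coefficients
#'
#' Covariates are drawn from uniform ranges with urban/rural mean shifts;
#' exercise is a linear function of the measured TIN exposure in the scheme
#' named by `config$effect_scheme` plus covariates and Gaussian noise; the
#' two health outcomes are linear in the covariates, the realized exercise
#' value, and (by default with zero coefficient) greenness. All percentages
#' are clipped to \[0, 100\]. Ground-truth coefficients are returned in a
#' sidecar so tests never reverse-engineer them from outputs.
#'
#' @param world A `synthetic_world`.
#' @param exposure An exposure table from [build_exposure_table()] that
#'   contains TIN at buffer 0 for `config$effect_scheme`.
#' @param config A [world_config()] (defaults to the world's config).
#' @return List with `table` (county health tibble) and `truth` (planted
#'   coefficients, intercepts, noise SD, effect scheme), class `county_health`.
#' @export
generate_health <- function(world, exposure, config = world$config) {
  set.seed(config$seed + 2L)
  scheme <- config$effect_scheme
  exp_df <- as_exposure_df(exposure)
  tin <- exp_df[exp_df$scheme == scheme & exp_df$buffer_m == 0 & exp_df$metric == "TIN", ]
  if (nrow(tin) == 0) stop("scheme '", scheme, "' not present in the exposure table")
  tin <- tin[match(world$counties$id, tin$county_id), ]
  if (anyNA(tin$county_id)) stop("exposure table lacks TIN values for some counties")

  n <- nrow(world$counties)
  urban <- as.numeric(world$counties$urban)
  spec <- covariate_spec()
  covs <- list(urban = urban)
  for (i in seq_len(nrow(spec))) {
    m <- ifelse(urban == 1, spec$urban_mean[i], spec$rural_mean[i])
    hw <- sqrt(3) * spec$sd[i]
    covs[[spec$name[i]]] <- pmin(pmax(stats::runif(n, m - hw, m + hw), 0), 100)
  }
  covs <- tibble::as_tibble(covs)

  coefs <- default_health_coefs(config)
  targets <- c(exercise = 74.6, poor_physical = 37.4, poor_mental = 35.2)
  sdn <- config$health_noise_sd
  tab <- dplyr::bind_cols(tibble::tibble(county_id = world$counties$id), covs)
  intercepts <- numeric(0)
  for (outcome in names(coefs)) {
    cf <- coefs[[outcome]]
    lin <- cf[["tin"]] * tin$value
    for (nm in setdiff(names(cf), "tin")) lin <- lin + cf[[nm]] * tab[[nm]]
    intercept <- targets[[outcome]] - mean(lin)
    y <- intercept + lin + stats::rnorm(n, 0, sdn)
    tab[[outcome]] <- pmin(pmax(y, 0), 100)
    intercepts[outcome] <- intercept
  }

  structure(list(
    table = tab,
    truth = list(coefs = coefs, intercepts = intercepts,
                 noise_sd = sdn, effect_scheme = scheme,
                 beta_tin_exercise = config$effect_beta_tin_on_exercise)
  ), class = "county_health")
}
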