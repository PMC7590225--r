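# Annual greenness metrics from an NDVI time series.
#
# MXN (maximum NDVI) is the annual maximum per pixel. TIN (time-integrated
# NDVI) summarizes average greenness over the growing season: a 3-period
# circular moving *median* smooths the annual cycle (a median preserves
# abrupt green-up edges that a mean would blur); the smoothed minimum is the
# baseline, the smoothed maximum minus baseline the seasonal amplitude; the
# growing season is the longest contiguous (circularly wrapped) run of
# periods whose smoothed value reaches baseline + 10% of amplitude, ties
# broken toward the earliest run; TIN is the mean of (raw NDVI - baseline)
# over that run, floored at zero. A flat series (zero amplitude) has an
# empty season and TIN 0. Both metrics live on the same 0-100 percent scale
# as the input.

row_mins <- function(m) do.call(pmin, lapply(seq_len(ncol(m)), function(j) m[, j]))
row_maxs <- function(m) do.call(pmax, lapply(seq_len(ncol(m)), function(j) m[, j]))

# circular smoothing of rows; window must be odd
smooth_rows <- function(X, window = 3, method = c("median", "mean")) {
  method <- match.arg(method)
  nt <- ncol(X)
  if (window <= 1) return(X)
  if (window %% 2 != 1) stop("smoothing window must be odd")
  wrap <- function(off) X[, ((seq_len(nt) - 1 + off) %% nt) + 1, drop = FALSE]
  if (window == 3) {
    a <- wrap(-1); b <- X; c <- wrap(1)
    if (method == "mean") return((a + b + c) / 3)
    return(a + b + c - pmax(a, b, c) - pmin(a, b, c))  # median of three
  }
  offs <- seq(-(window - 1) / 2, (window - 1) / 2)
  arr <- vapply(offs, wrap, X)
  apply(arr, c(1, 2), if (method == "mean") mean else stats::median)
}

# Core TIN over complete rows of a pixels x periods matrix.
tin_matrix <- function(X, smooth_window = 3, season_frac = 0.10,
                       smooth = c("median", "mean")) {
  smooth <- match.arg(smooth)
  nt <- ncol(X)
  n <- nrow(X)
  S <- smooth_rows(X, smooth_window, smooth)
  baseline <- row_mins(S)
  amp <- row_maxs(S) - baseline
  thr <- baseline + season_frac * amp
  M <- S >= thr
  flat <- amp <= 1e-12
  all_on <- rowSums(M) == nt

  best_len <- integer(n); best_end <- integer(n)
  r <- integer(n)
  Md <- cbind(M, M)
  for (e in seq_len(2 * nt)) {
    r <- (r + 1L) * Md[, e]
    upd <- r > best_len & r <= nt
    if (any(upd)) {
      best_len[upd] <- r[upd]
      best_end[upd] <- e
    }
  }
  start <- best_end - best_len + 1L

  # season sums over the circular window via doubled cumulative sums
  Xd <- cbind(X, X)
  CS <- Xd
  for (e in 2:(2 * nt)) CS[, e] <- CS[, e - 1] + Xd[, e]
  i <- seq_len(n)
  hi <- CS[cbind(i, pmin(best_end, 2 * nt))]
  lo <- ifelse(start > 1, CS[cbind(i, pmax(start - 1L, 1L))], 0)
  ssum <- hi - lo

  len <- best_len
  len[all_on] <- nt
  start[all_on] <- 1L
  ssum[all_on] <- CS[cbind(i, nt)][all_on]
  tin <- pmax(ssum / len - baseline, 0)

  season_start <- ((start - 1L) %% nt) + 1L
  season_end <- ((start + len - 2L) %% nt) + 1L
  tin[flat] <- 0
  season_start[flat] <- NA_integer_
  season_end[flat] <- NA_integer_
  list(tin = tin, season_start = season_start, season_end = season_end,
       baseline = baseline, amplitude = amp)
}

#' Maximum NDVI of a series
#'
#' @param series Numeric vector of NDVI percent values over the year's
#'   periods; NA marks nodata.
#' @return The maximum over non-nodata periods; NA if every period is nodata.
#' @export
compute_mxn <- function(series) {
  if (all(is.na(series))) return(NA_real_)
  max(series, na.rm = TRUE)
}

#' Time-integrated NDVI of a series
#'
#' See the package vignette for the full definition (smoothed baseline,
#' 10%-of-amplitude season, baseline-excess mean). Needs at least 4
#' non-nodata periods; nodata periods are dropped and the remaining values
#' treated as an evenly spaced annual cycle.
#'
#' @param series Numeric vector of NDVI percent values (one annual cycle).
#' @param smooth_window Odd smoothing window in periods (default 3).
#' @param season_frac Season threshold as a fraction of amplitude (default 0.10).
#' @param smooth Smoother: circular moving `"median"` (default) or `"mean"`.
#' @return List with `tin`, `season_start`, `season_end` (period indices into
#'   the valid series; NA for a flat series). TIN is NA when fewer than 4
#'   periods are valid.
#' @export
compute_tin <- function(series, smooth_window = 3, season_frac = 0.10,
                        smooth = c("median", "mean")) {
  smooth <- match.arg(smooth)
  valid <- which(!is.na(series))
  if (length(valid) < 4) {
    return(list(tin = NA_real_, season_start = NA_integer_, season_end = NA_integer_))
  }
  res <- tin_matrix(matrix(series[valid], nrow = 1), smooth_window, season_frac, smooth)
  list(tin = res$tin[1],
       season_start = if (is.na(res$season_start[1])) NA_integer_ else valid[res$season_start[1]],
       season_end = if (is.na(res$season_end[1])) NA_integer_ else valid[res$season_end[1]])
}

#' Compute the greenness raster (MXN and TIN bands) from an NDVI stack
#'
#' @param stack An `ndvi_stack`.
#' @param smooth_window,season_frac,smooth Passed to the TIN definition.
#' @return An object of class `greenness_raster` with matrices `mxn`, `tin`,
#'   `season_start`, `season_end` on the stack's grid. Nodata propagates:
#'   all-nodata pixels get NA in both bands; pixels with fewer than 4 valid
#'   periods get NA TIN.
#' @export
compute_greenness <- function(stack, smooth_window = 3, season_frac = 0.10,
                              smooth = c("median", "mean")) {
  smooth <- match.arg(smooth)
  stopifnot(inherits(stack, "ndvi_stack"))
  grid <- stack$grid
  nt <- length(stack$periods)
  X <- matrix(stack$values, nrow = grid$nrow * grid$ncol, ncol = nt)

  mxn <- do.call(pmax, c(lapply(seq_len(nt), function(t) X[, t]), na.rm = TRUE))
  mxn[rowSums(!is.na(X)) == 0] <- NA_real_

  tin <- rep(NA_real_, nrow(X))
  sst <- rep(NA_integer_, nrow(X))
  sen <- rep(NA_integer_, nrow(X))
  complete <- rowSums(is.na(X)) == 0
  if (any(complete)) {
    res <- tin_matrix(X[complete, , drop = FALSE], smooth_window, season_frac, smooth)
    tin[complete] <- res$tin
    sst[complete] <- res$season_start
    sen[complete] <- res$season_end
  }
  partial <- which(!complete & rowSums(!is.na(X)) >= 4)
  for (p in partial) {
    r <- compute_tin(X[p, ], smooth_window, season_frac, smooth)
    tin[p] <- r$tin; sst[p] <- r$season_start; sen[p] <- r$season_end
  }

  shape <- function(v) matrix(v, nrow = grid$nrow, ncol = grid$ncol)
  structure(list(grid = grid, mxn = shape(mxn), tin = shape(tin),
                 season_start = shape(sst), season_end = shape(sen)),
            class = "greenness_raster")
}

#' @export
print.greenness_raster <- function(x, ...) {
  cat(sprintf("<greenness_raster: %d x %d pixels; MXN mean %.1f, TIN mean %.1f>\n",
              x$grid$nrow, x$grid$ncol,
              mean(x$mxn, na.rm = TRUE), mean(x$tin, na.rm = TRUE)))
  invisible(x)
}
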