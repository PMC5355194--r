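#' Sediment-core time series
#'
#' One core record: sea-surface temperature (deg C) or sea level (m relative
#' to present) on an age grid in ka BP. After regridding, ages are a regular
#' 1,000-year grid with no missing values.
#'
#' @param core_id character identifier.
#' @param lon,lat core location (degrees).
#' @param kind `"sst"` or `"sea_level"`.
#' @param ages numeric, ka BP, strictly increasing.
#' @param values numeric, same length as `ages`.
#' @return object of class `paleo_series`.
#' @export
paleo_series <- function(core_id, lon, lat, kind = c("sst", "sea_level"),
                         ages, values) {
  kind <- match.arg(kind)
  if (length(ages) != length(values)) stop("ages and values differ in length")
  if (length(ages) < 2) stop("a core must cover at least 2 timesteps")
  if (any(diff(ages) <= 0)) stop("ages must be strictly increasing")
  structure(list(core_id = as.character(core_id), lon = lon, lat = lat,
                 kind = kind, ages = as.numeric(ages),
                 values = as.numeric(values)),
            class = "paleo_series")
}

#' @export
print.paleo_series <- function(x, ...) {
  cat(sprintf("paleo_series %s [%s] at (%.2f, %.2f): %d steps, %g-%g ka BP\n",
              x$core_id, x$kind, x$lon, x$lat, length(x$ages),
              min(x$ages), max(x$ages)))
  invisible(x)
}

#' Reconstruction settings
#'
#' @param thresholds numeric vector of SST thresholds (deg C) to sweep;
#'   default 23:28 by 1 degree.
#' @param depth_window length-2 numeric `(min, max)` water depth in m below
#'   contemporaneous sea level defining reef habitat; reef growth is confined
#'   to roughly the top 100 m, so the default is (0, 100].
#' @param aggregation_factor integer fine-to-analysis cell ratio.
#' @param land_fraction_max analysis cells with at least this land fraction
#'   are dropped (default 0.9).
#' @return list of class `reconstruction_config`.
#' @export
reconstruction_config <- function(thresholds = 23:28,
                                  depth_window = c(0, 100),
                                  aggregation_factor = 1L,
                                  land_fraction_max = 0.9) {
  if (!length(thresholds)) stop("thresholds must be non-empty")
  if (depth_window[1] < 0 || depth_window[2] <= depth_window[1])
    stop("depth_window must satisfy 0 <= min < max")
  if (aggregation_factor < 1) stop("aggregation_factor must be >= 1")
  structure(list(thresholds = sort(as.numeric(thresholds)),
                 depth_window = as.numeric(depth_window),
                 aggregation_factor = as.integer(aggregation_factor),
                 land_fraction_max = land_fraction_max),
            class = "reconstruction_config")
}

#' Regrid cores to a common 1,000-year age grid and cross-correlate
#'
#' Each series is linearly interpolated onto the regular 1 ka grid spanning
#' the window common to all cores; consistency across records is then checked
#' by pairwise Pearson correlation over pairwise-complete timesteps (entries
#' with fewer than 2 overlapping steps are NA).
#'
#' @param cores list of [paleo_series] objects.
#' @return list with elements `cores` (regridded series) and `correlations`
#'   (symmetric matrix of Pearson r, unit diagonal).
#' @export
regrid_and_qc <- function(cores) {
  if (!length(cores)) stop("empty core list")
  a0 <- max(vapply(cores, function(s) min(s$ages), 0))
  a1 <- min(vapply(cores, function(s) max(s$ages), 0))
  grid <- seq(ceiling(a0), floor(a1), by = 1)
  if (length(grid) < 2) stop("cores share fewer than 2 overlapping timesteps")
  reg <- lapply(cores, function(s) {
    v <- stats::approx(s$ages, s$values, xout = grid)$y
    paleo_series(s$core_id, s$lon, s$lat, s$kind, grid, v)
  })
  vals <- vapply(reg, `[[`, numeric(length(grid)), "values")
  r <- suppressWarnings(stats::cor(vals, use = "pairwise.complete.obs"))
  diag(r) <- 1
  dimnames(r) <- rep(list(vapply(cores, `[[`, "", "core_id")), 2)
  list(cores = reg, correlations = r)
}

#' Cross-core SST anomalies and sea level per timestep
#'
#' For each SST core the anomaly at a timestep is core SST minus the baseline
#' (pre-warming) SST at the core's grid cell (nearest sea cell if the core
#' falls on land); the table stores the unweighted mean anomaly across cores
#' plus sea level from the sea-level series (averaged if several).
#'
#' @param cores list of regridded [paleo_series] sharing one age grid.
#' @param baseline `reef_grid` of pre-warming SST (deg C).
#' @param elevation optional `reef_grid` of elevation used to identify sea
#'   cells (h < 0) when snapping core locations; if NULL all cells are
#'   eligible.
#' @return data.frame of class `anomaly_table`: `age` (ka BP), `dsst` (deg C),
#'   `sea_level` (m).
#' @export
compute_anomalies <- function(cores, baseline, elevation = NULL) {
  kinds <- vapply(cores, `[[`, "", "kind")
  if (!any(kinds == "sst")) stop("no SST cores")
  if (!any(kinds == "sea_level")) stop("no sea-level series")
  ages <- cores[[1]]$ages
  for (s in cores) if (!isTRUE(all.equal(s$ages, ages)))
    stop("cores are not on a common age grid; run regrid_and_qc first")

  sea_ok <- if (is.null(elevation)) {
    matrix(TRUE, length(baseline$lat), length(baseline$lon))
  } else elevation$values < 0
  cell_sst <- function(lon, lat) {
    idx <- which(sea_ok, arr.ind = TRUE)
    d <- (baseline$lat[idx[, 1]] - lat)^2 + (baseline$lon[idx[, 2]] - lon)^2
    k <- idx[which.min(d), , drop = FALSE]
    baseline$values[k]
  }
  anoms <- vapply(cores[kinds == "sst"], function(s)
    s$values - cell_sst(s$lon, s$lat), numeric(length(ages)))
  sl <- rowMeans(vapply(cores[kinds == "sea_level"], `[[`,
                        numeric(length(ages)), "values"))
  structure(data.frame(age = ages,
                       dsst = rowMeans(as.matrix(anoms)),
                       sea_level = sl),
            class = c("anomaly_table", "data.frame"))
}

#' Hindcast the SST field at one timestep
#'
#' Applies the cross-core mean anomaly as a single basin-wide additive shift
#' of the baseline map (no spatial interpolation between cores), so the
#' spatial ranking of cells is preserved.
#'
#' @param baseline `reef_grid` of pre-warming SST.
#' @param anomalies an `anomaly_table`.
#' @param age timestep (ka BP) present in the table.
#' @return `reef_grid` of SST at `age`.
#' @export
hindcast_sst <- function(baseline, anomalies, age) {
  i <- match(age, anomalies$age)
  if (is.na(i)) stop("age ", age, " ka BP outside the anomaly table")
  reef_grid(baseline$values + anomalies$dsst[i], baseline$lon, baseline$lat)
}

#' Immersion mask at a given sea level
#'
#' A cell is immerged iff its present-day elevation lies below the
#' contemporaneous sea level (h < s_t); its water depth is then d = s_t - h.
#'
#' @param elevation `reef_grid` of elevation (m; negative below present sea
#'   level).
#' @param sea_level sea level s_t (m relative to present).
#' @return logical matrix, TRUE where immerged.
#' @export
immersion_mask <- function(elevation, sea_level) {
  elevation$values < sea_level
}

#' Build the boolean reef-suitability stack under one thermal threshold
#'
#' For each timestep a cell is suitable iff it is immerged, its
#' contemporaneous depth falls in the configured window, and the hindcast SST
#' meets the threshold. Stacks from higher thresholds are cell- and
#' timestep-wise subsets of stacks from lower thresholds.
#'
#' @param elevation `reef_grid` of elevation.
#' @param baseline `reef_grid` of pre-warming SST.
#' @param anomalies an `anomaly_table`.
#' @param config a [reconstruction_config].
#' @param threshold_C SST threshold (deg C); must be one of
#'   `config$thresholds`.
#' @return object of class `suitability_stack`: logical array
#'   (lat x lon x timestep), `ages`, `sea_level` per timestep, `threshold_C`,
#'   `depth_window`, and the grid coordinates.
#' @export
build_suitability_stack <- function(elevation, baseline, anomalies, config,
                                    threshold_C) {
  if (!any(abs(config$thresholds - threshold_C) < 1e-9))
    stop("threshold_C must be one of config$thresholds")
  nt <- nrow(anomalies)
  S <- array(FALSE, c(length(elevation$lat), length(elevation$lon), nt))
  for (i in seq_len(nt)) {
    s_t <- anomalies$sea_level[i]
    depth <- s_t - elevation$values
    sst <- baseline$values + anomalies$dsst[i]
    S[, , i] <- (depth > config$depth_window[1]) &
      (depth <= config$depth_window[2]) & (sst >= threshold_C)
  }
  structure(list(S = S, ages = anomalies$age, sea_level = anomalies$sea_level,
                 threshold_C = threshold_C, depth_window = config$depth_window,
                 lon = elevation$lon, lat = elevation$lat),
            class = "suitability_stack")
}

#' @export
print.suitability_stack <- function(x, ...) {
  cat(sprintf(
    "suitability_stack: %d x %d cells, %d timesteps, threshold %.1f degC\n",
    dim(x$S)[1], dim(x$S)[2], dim(x$S)[3], x$threshold_C))
  cat(sprintf("  suitable fraction: %.3f (mean over timesteps)\n",
              mean(x$S)))
  invisible(x)
}
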