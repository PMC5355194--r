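#' Scenario configuration for the synthetic Indo-Pacific world
#'
#' Bundles every tunable of the generator: grid geometry, the
#' glacial-interglacial cycle, core sampling, the species pool and the
#' strength of the size/mobility-dependent colonization lag. Defaults are a
#' desk-scale tropical basin: a 48 x 60 half-degree grid spanning +/-12
#' degrees latitude, 40 one-ka timesteps of a 20-ka cycle with a 120 m
#' sea-level amplitude (late-Quaternary low stands reached 120-130 m below
#' present) and a 2.5 degC tropical SST amplitude.
#'
#' @param seed integer master seed.
#' @param n_cores number of SST sediment-core series.
#' @param n_timesteps number of 1,000-year slices (>= 2).
#' @param grid_nrow,grid_ncol fine-grid shape (>= 4 each).
#' @param cell_size cell size in degrees.
#' @param lon_min western edge (cell centers start half a cell in).
#' @param n_species species pool size.
#' @param true_threshold_C thermal threshold (degC) generating the true
#'   habitat stack.
#' @param glacial_cycle_period cycle period in timesteps (= ka).
#' @param sl_amplitude_m peak-to-trough sea-level amplitude (m, > 0...).
#' @param sst_amplitude_C peak-to-trough SST anomaly amplitude (degC).
#' @param size_range_cm range of maximum body size (cm), log-uniform.
#' @param lag_strength >= 0; scales how strongly small/sedentary species
#'   depend on isolation from stable areas (0 switches the effect off).
#' @param noise_sst_sd,noise_sl_sd,ar1 AR(1) noise on the core series
#'   (deg C / m innovation scale; ar1 is the autoregression coefficient).
#' @param sst_equator,sst_lat_gradient baseline SST at the equator and its
#'   decline per degree of latitude.
#' @param aggregation_factor fine-to-analysis cell ratio.
#' @param thresholds threshold sweep (degC) used by the reconstruction.
#' @param depth_window reef depth window (m below contemporaneous sea level).
#' @param prevalence_range target species prevalence range (exclusive of 0/1).
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1, n_cores = 8, n_timesteps = 40,
                            grid_nrow = 48, grid_ncol = 60, cell_size = 0.5,
                            lon_min = 100, n_species = 100,
                            true_threshold_C = 27, glacial_cycle_period = 20,
                            sl_amplitude_m = 120, sst_amplitude_C = 2.5,
                            size_range_cm = c(3, 200), lag_strength = 1.5,
                            noise_sst_sd = 0.3, noise_sl_sd = 1.5, ar1 = 0.5,
                            sst_equator = 30, sst_lat_gradient = 0.35,
                            aggregation_factor = 4, thresholds = 23:28,
                            depth_window = c(0, 100),
                            prevalence_range = c(0.15, 0.6)) {
  if (n_timesteps < 2) stop("invalid config: n_timesteps must be >= 2")
  if (grid_nrow < 4 || grid_ncol < 4)
    stop("invalid config: grid must be at least 4 x 4")
  if (sl_amplitude_m < 0 || sst_amplitude_C < 0)
    stop("invalid config: amplitudes must be non-negative")
  if (lag_strength < 0) stop("invalid config: lag_strength must be >= 0")
  cfg <- as.list(environment())
  class(cfg) <- "scenario_config"
  cfg
}

# analytic (noise-free) anomaly and sea-level curves; age in ka BP
true_sst_anomaly <- function(cfg, ages)
  -cfg$sst_amplitude_C / 2 * (1 - cos(2 * pi * ages / cfg$glacial_cycle_period))
true_sea_level <- function(cfg, ages)
  -cfg$sl_amplitude_m / 2 * (1 - cos(2 * pi * ages / cfg$glacial_cycle_period))

world_geometry <- function(cfg) {
  lat_max <- cfg$grid_nrow * cfg$cell_size / 2 - cfg$cell_size / 2
  list(lon = cfg$lon_min + cfg$cell_size * (seq_len(cfg$grid_ncol) - 0.5),
       lat = seq(lat_max, by = -cfg$cell_size, length.out = cfg$grid_nrow))
}

ar1_noise <- function(n, sd, phi) {
  if (sd == 0) return(rep(0, n))
  as.numeric(stats::filter(stats::rnorm(n, 0, sd * sqrt(1 - phi^2)),
                           phi, method = "recursive",
                           init = stats::rnorm(1, 0, sd)))
}

#' Generate sediment-core SST and sea-level series
#'
#' Each SST core records a sinusoidal glacial-interglacial SST cycle (period
#' and amplitude from the config) around the baseline temperature at the
#' core's location, plus independent AR(1) noise; one sea-level series
#' records the corresponding sea-level cycle. Ages are the regular
#' 1,000-year grid 0..(n_timesteps-1) ka BP, anchored so the present-day
#' anomaly is ~0. The noise-free SST components of all cores are identical
#' up to their means (pairwise Pearson r = 1).
#'
#' @param config a [scenario_config].
#' @param baseline optional `reef_grid` of baseline SST to anchor core means
#'   (cores are placed on its sea cells when `elevation` is given); without
#'   it, core means are drawn uniformly on 26-29 degC at random locations.
#' @param elevation optional `reef_grid` of elevation for sea-cell placement.
#' @return list of [paleo_series] (n_cores SST series + 1 sea-level series).
#' @export
generate_paleo_series <- function(config, baseline = NULL, elevation = NULL) {
  cfg <- config
  ages <- seq(0, cfg$n_timesteps - 1)
  dT <- true_sst_anomaly(cfg, ages)
  geom <- world_geometry(cfg)
  sea <- if (!is.null(elevation)) which(elevation$values < 0, arr.ind = TRUE)
  else cbind(sample(cfg$grid_nrow, cfg$n_cores, replace = TRUE),
             sample(cfg$grid_ncol, cfg$n_cores, replace = TRUE))
  if (!is.null(elevation) && nrow(sea) == 0)
    stop("degenerate geography: no sea cells")
  pick <- sea[sample(nrow(sea), cfg$n_cores, replace = nrow(sea) < cfg$n_cores),
              , drop = FALSE]
  cores <- lapply(seq_len(cfg$n_cores), function(i) {
    r <- pick[i, 1]; cc <- pick[i, 2]
    base <- if (!is.null(baseline)) baseline$values[r, cc]
    else stats::runif(1, 26, 29)
    paleo_series(sprintf("core%02d", i), geom$lon[cc], geom$lat[r], "sst",
                 ages, base + dT + ar1_noise(length(ages), cfg$noise_sst_sd,
                                             cfg$ar1))
  })
  sl <- paleo_series("sl01", geom$lon[1], geom$lat[1], "sea_level", ages,
                     true_sea_level(cfg, ages) +
                       ar1_noise(length(ages), cfg$noise_sl_sd, cfg$ar1))
  c(cores, list(sl))
}

# rank-transform of a smooth field into land / shallow shelf / deep ocean
elevation_from_field <- function(z) {
  r <- rank(z) / (length(z) + 1)
  h <- ifelse(r > 0.80, (r - 0.80) / 0.20 * 800,
              ifelse(r > 0.50, -(0.80 - r) / 0.30 * 150,
                     -150 - (0.50 - r) / 0.50 * 3850))
  matrix(h, nrow(z), ncol(z))
}

#' Generate the full synthetic world with ground truth
#'
#' Builds, from one seed: a smooth bathymetry with land, shallow shelf and
#' deep ocean; a baseline SST field with a latitudinal gradient; correlated
#' smooth contemporary predictor fields (CHL, O2, NI, SSS); sediment cores;
#' the true suitability stack at the configured threshold and the true
#' isolation map; a species pool with log-uniform body sizes,
#' size-correlated mobility, habitat-specialization categories and a
#' birth-death phylogeny carrying Brownian signal in size; and
#' presence/absence sampled cell-wise Bernoulli from a linear-quadratic
#' logit in the (z-scored) predictors, in which the magnitude of the
#' isolation (IREF) coefficient increases stochastically with decreasing
#' body size and mobility, scaled by `lag_strength`. Every drawn coefficient
#' is recorded in the ground truth.
#'
#' @param config a [scenario_config].
#' @return object of class `synthetic_world`; see Details.
#' @details Fields: `config`, `cores`, `bathymetry`, `baseline_sst`,
#'   `predictor_grids` (fine-grid list), `predictors` (analysis-cell table
#'   with `cell_id, row, col, lon, lat, sst, chl, o2, ni, sss, iref`),
#'   `occurrences` (species x cell matrix), `traits` ([trait_table]),
#'   `phylogeny` (`ape::phylo`), `truth` (list: `coefficients` data.frame
#'   with per-species intercept, linear/quadratic contemporary coefficients,
#'   `iref_coef`, `hist_effect` = |iref_coef|, target prevalence; `stack`,
#'   `isolation`, `true_threshold_C`).
#' @export
generate_world <- function(config) {
  cfg <- config
  withr::with_seed(cfg$seed, {
    geom <- world_geometry(cfg)
    elev <- reef_grid(elevation_from_field(
      smooth_field(cfg$grid_nrow, cfg$grid_ncol, sigma = 4)),
      geom$lon, geom$lat)
    if (!any(elev$values < 0)) stop("degenerate geography: no sea cells")
    latg <- matrix(rep(abs(geom$lat), cfg$grid_ncol), cfg$grid_nrow)
    latg_std <- (latg - mean(latg)) / stats::sd(latg)
    sst0 <- reef_grid(cfg$sst_equator - cfg$sst_lat_gradient * latg +
                        0.3 * smooth_field(cfg$grid_nrow, cfg$grid_ncol, 3),
                      geom$lon, geom$lat)
    mk <- function(a, b, mu, sc) reef_grid(
      mu + sc * (a * latg_std +
                   sqrt(max(0, 1 - a^2)) *
                     smooth_field(cfg$grid_nrow, cfg$grid_ncol, b)),
      geom$lon, geom$lat)
    grids <- list(sst = sst0,
                  chl = mk(0.45, 3, 0.25, 0.12),
                  o2 = mk(0.6, 4, 6.2, 0.35),
                  ni = mk(0.3, 3, 2.0, 0.8),
                  sss = mk(-0.4, 4, 34.5, 0.6))

    cores <- generate_paleo_series(cfg, baseline = sst0, elevation = elev)

    ages <- seq(0, cfg$n_timesteps - 1)
    anoms <- structure(data.frame(age = ages,
                                  dsst = true_sst_anomaly(cfg, ages),
                                  sea_level = true_sea_level(cfg, ages)),
                       class = c("anomaly_table", "data.frame"))
    rc <- reconstruction_config(thresholds = cfg$thresholds,
                                depth_window = cfg$depth_window,
                                aggregation_factor = cfg$aggregation_factor)
    stack <- build_suitability_stack(elev, sst0, anoms, rc,
                                     cfg$true_threshold_C)
    iso <- compute_isolation(stack, elev)

    # analysis-cell mask: < 90% land and reef habitat at some point under
    # the generating threshold (cells whose aggregated IREF is defined)
    f <- cfg$aggregation_factor
    land_frac <- aggregate_to_analysis_grid(
      reef_grid((elev$values >= 0) * 1, geom$lon, geom$lat), f)
    iref_agg <- aggregate_to_analysis_grid(
      reef_grid(iso$IREF, geom$lon, geom$lat), f)
    keep <- land_frac$values < 0.9 & is.finite(iref_agg$values)
    idx <- which(keep, arr.ind = TRUE)
    if (nrow(idx) < 4) stop("degenerate geography: too few analysis cells")
    agg_val <- function(g) aggregate_to_analysis_grid(g, f)$values[keep]
    predictors <- data.frame(
      cell_id = sprintf("c%02d_%02d", idx[, 1], idx[, 2]),
      row = idx[, 1], col = idx[, 2],
      lon = iref_agg$lon[idx[, 2]], lat = iref_agg$lat[idx[, 1]],
      sst = agg_val(grids$sst), chl = agg_val(grids$chl),
      o2 = agg_val(grids$o2), ni = agg_val(grids$ni),
      sss = agg_val(grids$sss), iref = iref_agg$values[keep])

    # ---- species pool -------------------------------------------------
    n <- cfg$n_species
    sp <- sprintf("g%02d_sp%03d", ((seq_len(n) - 1) %/% 5) + 1, seq_len(n))
    tree <- ape::rphylo(n, birth = 0.15, death = 0.05)
    # species ids are ordered by body size below; rank-matching them to a
    # Brownian trait evolved on the tree injects phylogenetic signal in size
    bm <- ape::rTraitCont(tree, sigma = 1)
    tree$tip.label <- sp[rank(bm, ties.method = "first")]
    lsz <- sort(stats::runif(n, log(cfg$size_range_cm[1]),
                             log(cfg$size_range_cm[2])))
    size <- stats::setNames(exp(lsz), sp)
    s01 <- (lsz - log(cfg$size_range_cm[1])) /
      diff(log(cfg$size_range_cm))
    mscore <- s01 + stats::rnorm(n, 0, 0.25)
    mobility <- cut(mscore, c(-Inf, 1 / 3, 2 / 3, Inf),
                    labels = c("sedentary", "mobile_within_reef",
                               "mobile_between_reefs"))
    specialization <- sample(c("coral_specialized", "other_specialized",
                               "not_specialized"), n, replace = TRUE,
                             prob = c(0.3, 0.2, 0.5))
    traits <- trait_table(sp, unname(size), as.character(mobility),
                          as.character(specialization))

    # ---- true coefficients and occurrence sampling --------------------
    contemp <- c("sst", "chl", "o2", "ni", "sss")
    Z <- scale(as.matrix(predictors[c(contemp, "iref")]))
    b1 <- matrix(stats::rnorm(n * 5, 0, 0.7), n, 5,
                 dimnames = list(sp, paste0(contemp, "_1")))
    b2 <- matrix(-abs(stats::rnorm(n * 5, 0, 0.3)), n, 5,
                 dimnames = list(sp, paste0(contemp, "_2")))
    mob_mult <- c(sedentary = 1, mobile_within_reef = 0.65,
                  mobile_between_reefs = 0.35)[as.character(mobility)]
    hist_effect <- cfg$lag_strength * mob_mult * (1 - s01) *
      exp(stats::rnorm(n, 0, 0.3))
    iref_coef <- -hist_effect
    prev_target <- stats::runif(n, cfg$prevalence_range[1],
                                cfg$prevalence_range[2])
    occ <- matrix(0L, n, nrow(predictors), dimnames =
                    list(sp, predictors$cell_id))
    alpha <- numeric(n)
    for (i in seq_len(n)) {
      eta0 <- drop(Z[, contemp] %*% b1[i, ] + (Z[, contemp]^2) %*% b2[i, ] +
                     Z[, "iref"] * iref_coef[i])
      alpha[i] <- stats::uniroot(function(a)
        mean(stats::plogis(a + eta0)) - prev_target[i], c(-40, 40))$root
      occ[i, ] <- stats::rbinom(nrow(predictors), 1,
                                stats::plogis(alpha[i] + eta0))
    }

    truth <- list(
      coefficients = data.frame(species = sp, alpha = alpha, b1, b2,
                                iref_coef = iref_coef,
                                hist_effect = hist_effect,
                                prevalence_target = prev_target,
                                row.names = NULL),
      stack = stack, isolation = iso,
      true_threshold_C = cfg$true_threshold_C)

    structure(list(config = cfg, cores = cores, bathymetry = elev,
                   baseline_sst = sst0, predictor_grids = grids,
                   predictors = predictors, occurrences = occ,
                   traits = traits, phylogeny = tree, truth = truth),
              class = "synthetic_world")
  })
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(paste0("synthetic_world: %d species, %d analysis cells, ",
                     "%d timesteps (seed %d)\n"),
              nrow(x$occurrences), ncol(x$occurrences),
              x$config$n_timesteps, x$config$seed))
  cat(sprintf("  true threshold %.1f degC, lag_strength %.2f\n",
              x$truth$true_threshold_C, x$config$lag_strength))
  invisible(x)
}

#' Serialize a synthetic world to a directory of plain-text files
#'
#' Grids as CSV + JSON sidecars, tables as CSV (occurrences in long format:
#' species_id, cell_id, presence), the phylogeny as Newick, config and truth
#' coefficients as JSON.
#'
#' @param world a `synthetic_world`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_grid(world$bathymetry, file.path(dir, "bathymetry.csv"))
  write_grid(world$baseline_sst, file.path(dir, "baseline_sst.csv"))
  utils::write.csv(world$predictors, file.path(dir, "predictors.csv"),
                   row.names = FALSE)
  occ_long <- data.frame(
    species_id = rep(rownames(world$occurrences),
                     times = ncol(world$occurrences)),
    cell_id = rep(colnames(world$occurrences),
                  each = nrow(world$occurrences)),
    presence = as.integer(world$occurrences))
  utils::write.csv(occ_long, file.path(dir, "occurrences.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(world$traits), file.path(dir, "traits.csv"),
                   row.names = FALSE)
  ape::write.tree(world$phylogeny, file.path(dir, "phylogeny.nwk"))
  cores_df <- do.call(rbind, lapply(world$cores, function(s)
    data.frame(core_id = s$core_id, lon = s$lon, lat = s$lat, kind = s$kind,
               age = s$ages, value = s$values)))
  utils::write.csv(cores_df, file.path(dir, "cores.csv"), row.names = FALSE)
  cfg <- world$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(world$truth$coefficients,
                       file.path(dir, "truth_coefficients.json"),
                       dataframe = "columns", digits = NA)
  invisible(dir)
}
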