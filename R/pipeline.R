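#' Run the full analysis on a synthetic world
#'
#' Orchestrates the five stages end to end: regrid + QC the cores, compute
#' anomalies, build the suitability stack and isolation map for every
#' threshold of the sweep, fit the per-species SDM suite per threshold,
#' select the threshold maximizing mean historical-only deviance explained,
#' run the trait analysis (all-subsets averaging, PGLS, quantile regression)
#' at that threshold, and map assemblage summaries with the size-history
#' regression. Every stage seed derives deterministically from the master
#' seed.
#'
#' @param world a `synthetic_world` from [generate_world] (or an equivalent
#'   list built from files).
#' @param thresholds threshold sweep (degC); defaults to the world config's.
#' @param n_auc_repeats repeated splits for AUC (applies to the selected
#'   threshold; the sweep itself uses `n_auc_sweep`).
#' @param n_auc_sweep repeated splits used per threshold during the sweep.
#' @param min_presences species filter floor.
#' @param quantiles quantile-regression levels.
#' @param n_boot bootstrap replicates for quantile-slope standard errors.
#' @param seed master seed; NULL uses the world config seed.
#' @param traits_threshold force the trait-analysis threshold instead of
#'   using the sweep peak.
#' @return list of class `reef_study`: `qc`, `anomalies`, `isolation` (per
#'   threshold), `sweep` (threshold table: mean D2 and AUC of the
#'   historical-only model), `peak_threshold`, `sdm` (full results at the
#'   selected threshold), `trait_models`, `pgls_size`, `quantile_slopes`,
#'   `assemblage`, `size_history`.
#' @export
run_study <- function(world, thresholds = NULL, n_auc_repeats = 50,
                      n_auc_sweep = 10, min_presences = 10,
                      quantiles = c(0.75, 0.9), n_boot = 100, seed = NULL,
                      traits_threshold = NULL) {
  cfg <- world$config
  seed <- seed %||% cfg$seed
  thresholds <- sort(thresholds %||% cfg$thresholds)
  stage_seed <- function(stage) {
    h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
    as.integer((as.numeric(seed) * 1009 + h) %% 2147483647)
  }
  rc <- reconstruction_config(thresholds = thresholds,
                              depth_window = cfg$depth_window,
                              aggregation_factor = cfg$aggregation_factor)

  qc <- regrid_and_qc(world$cores)
  anoms <- compute_anomalies(qc$cores, world$baseline_sst, world$bathymetry)

  f <- cfg$aggregation_factor
  iso <- list(); iref_cols <- list()
  for (th in thresholds) {
    stack <- build_suitability_stack(world$bathymetry, world$baseline_sst,
                                     anoms, rc, th)
    im <- compute_isolation(stack, world$bathymetry)
    iso[[as.character(th)]] <- im
    agg <- aggregate_to_analysis_grid(
      reef_grid(im$IREF, im$lon, im$lat), f)
    iref_cols[[as.character(th)]] <-
      agg$values[cbind(world$predictors$row, world$predictors$col)]
  }

  occ <- world$occurrences
  sweep <- data.frame(threshold = thresholds, mean_d2_historical = NA_real_,
                      mean_auc_historical = NA_real_)
  sdm_by_th <- list()
  for (i in seq_along(thresholds)) {
    th <- as.character(thresholds[i])
    pred <- world$predictors
    pred$iref <- iref_cols[[th]]
    ok <- is.finite(pred$iref)
    res <- run_sdms(occ[, ok, drop = FALSE], pred[ok, ],
                    min_presences = min_presences,
                    n_auc_repeats = n_auc_sweep,
                    seed = stage_seed(paste0("sdm", th)), moran = FALSE)
    sdm_by_th[[th]] <- res
    conv <- res$converged
    sweep$mean_d2_historical[i] <- mean(res$d2_historical[conv])
    sweep$mean_auc_historical[i] <- mean(res$auc_historical[conv])
  }
  peak <- sweep$threshold[which.max(sweep$mean_d2_historical)]
  sel <- traits_threshold %||% peak

  pred <- world$predictors
  pred$iref <- iref_cols[[as.character(sel)]]
  ok <- is.finite(pred$iref)
  sdm <- run_sdms(occ[, ok, drop = FALSE], pred[ok, ],
                  min_presences = min_presences,
                  n_auc_repeats = n_auc_repeats,
                  seed = stage_seed("sdm_final"), moran = TRUE)

  conv <- sdm[sdm$converged, ]
  resp <- stats::setNames(conv$pure_historical, conv$species)
  traits <- world$traits[world$traits$species %in% conv$species, ]
  tm <- all_subsets_averaging(resp, traits)
  pg <- pgls_fit(response ~ size_cm, tm$data, world$phylogeny)
  qs <- quantile_slopes(resp[traits$species], traits$size_cm,
                        quantiles = quantiles, n_boot = n_boot,
                        seed = stage_seed("quantile"))

  vals <- data.frame(species = conv$species,
                     pure_historical = conv$pure_historical,
                     size_cm = traits$size_cm[
                       match(conv$species, traits$species)])
  asm <- cell_means(occ[conv$species, ok, drop = FALSE], vals)
  sh <- size_history_regression(asm)

  structure(list(qc = qc, anomalies = anoms, isolation = iso, sweep = sweep,
                 peak_threshold = peak, selected_threshold = sel,
                 sdm = sdm, sdm_by_threshold = sdm_by_th,
                 trait_models = tm, pgls_size = pg, quantile_slopes = qs,
                 assemblage = asm, size_history = sh, seed = seed),
            class = "reef_study")
}

#' @export
print.reef_study <- function(x, ...) {
  cat("reef_study\n")
  cat(sprintf("  threshold sweep peak: %.0f degC (historical-only mean D2)\n",
              x$peak_threshold))
  cat(sprintf("  species retained: %d (of which %d converged)\n",
              nrow(x$sdm), sum(x$sdm$converged)))
  cat(sprintf("  mean D2 full/contemporary/historical: %.3f / %.3f / %.3f\n",
              mean(x$sdm$d2_full[x$sdm$converged]),
              mean(x$sdm$d2_contemporary[x$sdm$converged]),
              mean(x$sdm$d2_historical[x$sdm$converged])))
  cat(sprintf("  averaged size slope: %.4f; PGLS lambda: %.3f\n",
              x$trait_models$coefficients$estimate[
                x$trait_models$coefficients$term == "size_cm"],
              x$pgls_size$lambda))
  cat(sprintf("  assemblage size-history: slope %.4g, R2 %.3f, t %.2f\n",
              x$size_history$slope, x$size_history$r_squared,
              x$size_history$t))
  invisible(x)
}

#' Write study outputs and a reproducibility manifest
#'
#' Serializes the per-species results table, sweep table, trait tables and
#' assemblage summary as CSV/JSON under `dir` and records a manifest with
#' the master seed, package version and per-file MD5 checksums; rerunning
#' with the same seed and inputs reproduces the files byte for byte.
#'
#' @param study a `reef_study`.
#' @param dir output directory.
#' @return path to the manifest, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(d, f) utils::write.csv(d, file.path(dir, f),
                                        row.names = FALSE)
  wr(as.data.frame(study$sdm), "sdm_results.csv")
  wr(study$sweep, "threshold_sweep.csv")
  wr(study$trait_models$models, "trait_model_set.csv")
  wr(study$trait_models$coefficients, "trait_averaged_coefficients.csv")
  wr(study$quantile_slopes, "quantile_slopes.csv")
  wr(study$assemblage, "assemblage_summary.csv")
  jsonlite::write_json(
    list(lambda = study$pgls_size$lambda,
         coefficients = study$pgls_size$coefficients),
    file.path(dir, "pgls.json"), dataframe = "columns", digits = NA)
  jsonlite::write_json(study$size_history,
                       file.path(dir, "size_history_regression.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- setdiff(list.files(dir), "manifest.json")
  manifest <- list(
    seed = study$seed,
    package_version = as.character(utils::packageVersion("reefshift")),
    selected_threshold = study$selected_threshold,
    checksums = as.list(tools::md5sum(file.path(dir, files))))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(file.path(dir, "manifest.json"))
}
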