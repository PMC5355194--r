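# Shared fixtures, memoized so expensive synthetic runs happen once per
# test session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# Independent shortest-path oracle: Bellman-Ford relaxation over the
# 8-neighbour graph, iterated to fixpoint. Kept deliberately separate from
# the package's Dijkstra implementation.
oracle_distance <- function(traversable, suitable, unit_scale = 1) {
  nr <- nrow(traversable); nc <- ncol(traversable)
  d <- matrix(Inf, nr, nc)
  d[suitable] <- 0
  d[!traversable] <- NA
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  repeat {
    d_old <- d
    for (k in seq_len(nrow(offs))) {
      dr <- offs$dr[k]; dc <- offs$dc[k]
      cost <- sqrt(abs(dr) + abs(dc)) * unit_scale
      src_r <- max(1, 1 - dr):min(nr, nr - dr)
      src_c <- max(1, 1 - dc):min(nc, nc - dc)
      cand <- d[src_r, src_c, drop = FALSE] + cost
      tgt_r <- src_r + dr; tgt_c <- src_c + dc
      cur <- d[tgt_r, tgt_c, drop = FALSE]
      upd <- !is.na(cur) & !is.na(cand) & cand < cur
      cur[upd] <- cand[upd]
      d[tgt_r, tgt_c] <- cur
    }
    if (identical(d, d_old)) break
  }
  d
}

# A tiny suitability stack on a 1-row sea corridor: suitable sets
# {c0}, {c0,c1}, {c0..c3} over three timesteps.
toy_corridor_stack <- function() {
  S <- array(FALSE, c(1, 4, 3))
  S[1, 1, 1] <- TRUE
  S[1, 1:2, 2] <- TRUE
  S[1, 1:4, 3] <- TRUE
  structure(list(S = S, ages = 0:2, sea_level = rep(0, 3), threshold_C = 27,
                 depth_window = c(0, 100), lon = 1:4, lat = 0),
            class = "suitability_stack")
}

# Mid-size world used by the parameter-recovery, closure and nesting checks:
# 200 species on ~250 analysis cells with graded isolation effects.
recovery_world <- function() fixture("recovery_world", function() {
  w <- generate_world(scenario_config(
    seed = 1, n_species = 200, grid_nrow = 64, grid_ncol = 208,
    n_timesteps = 40, lag_strength = 2))
  res <- suppressWarnings(
    run_sdms(w$occurrences, w$predictors, n_auc_repeats = 0, moran = FALSE))
  list(world = w, sdm = res)
})

# Ten seeded replicates of the colonization-lag scenario and ten of the
# no-lag null, at trait-analysis scale; serves the trait-recovery and
# assemblage-mirror checks.
lag_replicate <- function(seed, lag_strength) {
  key <- sprintf("rep_lag%g_seed%d", lag_strength, seed)
  fixture(key, function() {
    w <- generate_world(scenario_config(
      seed = seed, n_species = 120, grid_nrow = 48, grid_ncol = 96,
      n_timesteps = 40, lag_strength = lag_strength))
    s <- suppressWarnings(run_study(
      w, thresholds = 27, traits_threshold = 27, n_auc_repeats = 0,
      n_auc_sweep = 0, n_boot = 100))
    size_row <- s$trait_models$coefficients[
      s$trait_models$coefficients$term == "size_cm", ]
    q90 <- s$quantile_slopes[s$quantile_slopes$q == 0.9, ]
    list(size_slope = size_row$estimate, size_p = size_row$p,
         q90_slope = q90$slope, q90_p = q90$p,
         assemblage = s$size_history, pgls = s$pgls_size)
  })
}

# Lean threshold-sweep replicate: historical-only D2 and AUC per threshold.
sweep_replicate <- function(seed) {
  key <- sprintf("sweep_seed%d", seed)
  fixture(key, function() {
    w <- generate_world(scenario_config(
      seed = seed, n_species = 50, grid_nrow = 48, grid_ncol = 96,
      n_timesteps = 40, lag_strength = 2))
    s <- suppressWarnings(run_study(w, n_auc_repeats = 0, n_auc_sweep = 10,
                                    n_boot = 0, traits_threshold = 27))
    s$sweep
  })
}
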