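make_core <- function(id, ages, values, kind = "sst")
  paleo_series(id, lon = 100, lat = 0, kind = kind, ages = ages,
               values = values)

test_that("core QC correlations follow the product-moment formula", {
  x <- make_core("a", 0:3, c(1, 2, 3, 4))
  y <- make_core("b", 0:3, c(2, 4, 5, 9))
  qc <- regrid_and_qc(list(x, y))
  # hand-computed: Sxy = 11, Sxx = 5, Syy = 26 -> r = 11 / sqrt(130)
  expect_equal(qc$correlations["a", "b"], 11 / sqrt(130), tolerance = 1e-12)

  same <- regrid_and_qc(list(x, x))$correlations
  expect_equal(same[1, 2], 1)
  neg <- regrid_and_qc(list(x, make_core("c", 0:3, -c(1, 2, 3, 4))))
  expect_equal(neg$correlations[1, 2], -1)
})

test_that("QC matrix is symmetric with unit diagonal; regridding clips to the overlap", {
  set.seed(5)
  cores <- list(make_core("a", 0:10, rnorm(11)),
                make_core("b", 2:8, rnorm(7)),
                make_core("c", 0:9, rnorm(10)))
  qc <- regrid_and_qc(cores)
  r <- qc$correlations
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 3))
  for (s in qc$cores) expect_equal(s$ages, 2:8)
  expect_error(regrid_and_qc(list()), "empty")
})

test_that("anomalies are core-minus-baseline means plus sea level", {
  base <- reef_grid(matrix(28, 2, 2), lon = c(100, 101), lat = c(1, 0))
  sl <- make_core("sl", 0:2, c(0, -60, -120), kind = "sea_level")
  one <- make_core("a", 0:2, c(25, 26, 27))
  tab <- compute_anomalies(list(one, sl), base)
  expect_equal(tab$dsst, c(-3, -2, -1))
  expect_equal(tab$sea_level, c(0, -60, -120))

  two <- list(make_core("a", 0:1, c(27, 27)),   # anomalies -1, -1
              make_core("b", 0:1, c(25, 25)),   # anomalies -3, -3
              make_core("sl", 0:1, c(0, 0), kind = "sea_level"))
  expect_equal(compute_anomalies(two, base)$dsst, c(-2, -2))

  ident <- make_core("a", 0:2, rep(28, 3))
  expect_equal(compute_anomalies(list(ident, sl), base)$dsst, rep(0, 3))
  expect_error(compute_anomalies(list(sl), base), "no SST")
  expect_error(compute_anomalies(list(one), base), "sea-level")
})

test_that("hindcast is a uniform shift preserving spatial ranking", {
  base <- reef_grid(matrix(c(24, 26, 27, 29), 2, 2), lon = c(0, 1),
                    lat = c(1, 0))
  tab <- structure(data.frame(age = 0:1, dsst = c(0, -2),
                              sea_level = c(0, -100)),
                   class = c("anomaly_table", "data.frame"))
  expect_equal(hindcast_sst(base, tab, 0)$values, base$values)
  shifted <- hindcast_sst(base, tab, 1)$values
  expect_equal(shifted, base$values - 2)
  expect_equal(order(shifted), order(base$values))
  expect_error(hindcast_sst(base, tab, 5), "outside")
})

test_that("immersion follows h < s_t and is monotone in sea level", {
  elev <- reef_grid(matrix(c(-50, 10, -200, -5), 2, 2), lon = c(0, 1),
                    lat = c(1, 0))
  m0 <- immersion_mask(elev, 0)
  expect_equal(m0, elev$values < 0)
  m_low <- immersion_mask(elev, -120)
  expect_false(m_low[1, 1])                  # h = -50 exposed at -120 m stand
  expect_true(m_low[1, 2])                   # h = -200 still immerged
  expect_true(all(which(m_low) %in% which(m0)))  # raising s_t never removes
})

test_that("suitability requires immersion, depth window and warmth together", {
  elev <- reef_grid(matrix(-30, 1, 1), lon = 0, lat = 0)
  base <- reef_grid(matrix(27.5, 1, 1), lon = 0, lat = 0)
  rc <- reconstruction_config(thresholds = c(27, 28))
  tab <- structure(data.frame(age = 0:1, dsst = c(0, 0),
                              sea_level = c(0, -120)),
                   class = c("anomaly_table", "data.frame"))
  s27 <- build_suitability_stack(elev, base, tab, rc, 27)
  expect_true(s27$S[1, 1, 1])                # depth 30, SST 27.5 >= 27
  expect_false(s27$S[1, 1, 2])               # exposed at the low stand
  s28 <- build_suitability_stack(elev, base, tab, rc, 28)
  expect_false(s28$S[1, 1, 1])               # thermal clause fails
  expect_error(build_suitability_stack(elev, base, tab, rc, 25),
               "thresholds")
})

test_that("higher thresholds give nested suitability stacks", {
  w <- generate_world(scenario_config(seed = 9, n_species = 5,
                                      grid_nrow = 24, grid_ncol = 24,
                                      n_timesteps = 12))
  qc <- regrid_and_qc(w$cores)
  tab <- compute_anomalies(qc$cores, w$baseline_sst, w$bathymetry)
  rc <- reconstruction_config(thresholds = 23:28)
  prev <- NULL
  for (th in rev(rc$thresholds)) {           # 28 down to 23
    s <- build_suitability_stack(w$bathymetry, w$baseline_sst, tab, rc, th)
    if (!is.null(prev)) expect_true(all(s$S >= prev))
    prev <- s$S
  }
})
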