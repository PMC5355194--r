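# small deterministic trait set with all categories represented
toy_traits <- function(n = 40, seed = 8) {
  withr::with_seed(seed, trait_table(
    species = sprintf("g%02d_sp%02d", rep(1:8, length.out = n), 1:n),
    size_cm = exp(runif(n, log(3), log(200))),
    mobility = sample(c("sedentary", "mobile_within_reef",
                        "mobile_between_reefs"), n, TRUE),
    specialization = sample(c("coral_specialized", "other_specialized",
                              "not_specialized"), n, TRUE)))
}

test_that("Akaike weights follow exp(-delta/2) and sum to one", {
  set.seed(61)
  tr <- toy_traits()
  resp <- 0.2 - 0.0005 * tr$size_cm + rnorm(40, 0, 0.03)
  ms <- all_subsets_averaging(resp, tr)
  expect_equal(sum(ms$models$weight), 1, tolerance = 1e-12)
  expect_equal(nrow(ms$models), 8)

  # a Delta-AIC = 2 pair in isolation: weights 1/(1+e^-1), e^-1/(1+e^-1)
  d <- c(0, 2)
  w <- exp(-d / 2) / sum(exp(-d / 2))
  expect_equal(w, c(0.7311, 0.2689), tolerance = 1e-3)

  # importance is invariant to a constant shift of all AICs
  aic <- ms$models$aic
  w1 <- exp(-(aic - min(aic)) / 2)
  w2 <- exp(-((aic + 7) - min(aic + 7)) / 2)
  expect_equal(w1 / sum(w1), w2 / sum(w2), tolerance = 1e-12)

  # duplicating a model halves both copies' weights
  dup <- c(aic, aic[1])
  wd <- exp(-(dup - min(dup)) / 2); wd <- wd / sum(wd)
  expect_equal(wd[length(dup)], wd[1])
  expect_equal(wd[1] / (w1 / sum(w1))[1],
               1 / (1 + (w1 / sum(w1))[1]), tolerance = 1e-12)
})

test_that("strong size effects earn high importance and negative averaged slope", {
  set.seed(62)
  tr <- toy_traits(n = 80)
  resp <- 0.25 - 0.001 * tr$size_cm + rnorm(80, 0, 0.02)
  ms <- all_subsets_averaging(resp, tr)
  expect_gt(ms$importance[["size"]], 0.95)
  sz <- ms$coefficients[ms$coefficients$term == "size_cm", ]
  expect_lt(sz$estimate, 0)
  expect_lt(sz$p, 0.05)
  expect_equal(sz$w_aic, ms$importance[["size"]])
})

test_that("tip grafting forms half-length cherries and preserves ultrametricity", {
  tree <- ape::read.tree(text = "((Ab_x:10,Cd_y:10):5,Ef_z:15);")
  g <- graft_missing_tips(tree, c("Ab_new", "Qq_orphan"), seed = 4)
  expect_true("Ab_new" %in% g$tree$tip.label)
  expect_equal(g$unplaced, "Qq_orphan")
  expect_true(ape::is.ultrametric(g$tree, tol = 1e-8))
  # new cherry: both terminal branches are half the original terminal length
  i_new <- match("Ab_new", g$tree$tip.label)
  e_new <- g$tree$edge.length[g$tree$edge[, 2] == i_new]
  i_old <- match("Ab_x", g$tree$tip.label)
  e_old <- g$tree$edge.length[g$tree$edge[, 2] == i_old]
  expect_equal(e_new, 5)
  expect_equal(e_old, 5)

  # no-op when every species is already present; determinism under one seed
  expect_equal(graft_missing_tips(tree, c("Ab_x", "Ef_z"))$tree$tip.label,
               tree$tip.label)
  big <- ape::rphylo(20, 0.2, 0.05)
  big$tip.label <- sprintf("g%02d_sp%02d", rep(1:5, each = 4), 1:20)
  miss <- c("g01_sp90", "g03_sp91", "g05_sp92")
  t1 <- graft_missing_tips(big, miss, seed = 11)$tree
  t2 <- graft_missing_tips(big, miss, seed = 11)$tree
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
})

test_that("PGLS at lambda = 0 equals OLS; star phylogenies stay OLS", {
  set.seed(63)
  tree <- ape::rphylo(40, 0.2, 0.05)
  d <- data.frame(species = tree$tip.label, x = rnorm(40))
  d$y <- 1 + 0.4 * d$x + rnorm(40, 0, 0.5)
  p0 <- pgls_fit(y ~ x, d, tree, lambda = 0)
  ols <- coef(lm(y ~ x, d))
  expect_equal(p0$coefficients$estimate, unname(ols), tolerance = 1e-8)

  star <- ape::stree(40, "star")
  star$edge.length <- rep(1, nrow(star$edge))
  star$tip.label <- d$species
  ps <- pgls_fit(y ~ x, d, star)
  expect_equal(ps$coefficients$estimate, unname(ols), tolerance = 1e-8)
})

test_that("PGLS estimates agree with nlme::gls(corPagel) on one dataset", {
  set.seed(64)
  tree <- ape::rphylo(50, 0.2, 0.05)
  d <- data.frame(species = tree$tip.label,
                  x = rnorm(50))
  d$y <- 0.5 * d$x + ape::rTraitCont(tree, sigma = 1)[d$species] +
    rnorm(50, 0, 0.2)
  # compare the GLS machinery at a fixed lambda (gls's ML lambda is
  # unconstrained and can exceed 1, so the optima need not coincide)
  for (lam in c(0.3, 0.7)) {
    mine <- pgls_fit(y ~ x, d, tree, lambda = lam)
    ref <- nlme::gls(y ~ x, data = d,
                     correlation = ape::corPagel(lam, tree, form = ~species,
                                                 fixed = TRUE),
                     method = "ML")
    expect_equal(mine$coefficients$estimate, unname(coef(ref)),
                 tolerance = 1e-6)
  }
})

test_that("Brownian-simulated data yield high lambda estimates", {
  lams <- vapply(1:6, function(s) {
    withr::with_seed(100 + s, {
      tree <- ape::rphylo(64, 0.2, 0.05)
      d <- data.frame(species = tree$tip.label,
                      y = ape::rTraitCont(tree, sigma = 1),
                      x = rnorm(64))
      pgls_fit(y ~ x, d, tree)$lambda
    })
  }, 0)
  expect_gte(mean(lams), 0.8)
})

test_that("quantile slopes recover exact lines, constants, and envelopes", {
  x <- seq(1, 50)
  y_line <- 2 + 0.3 * x
  qs <- quantile_slopes(y_line, x, quantiles = c(0.5, 0.75, 0.9))
  expect_equal(qs$slope, rep(0.3, 3), tolerance = 1e-10)
  expect_equal(qs$intercept, rep(2, 3), tolerance = 1e-8)

  qs0 <- quantile_slopes(rep(1, 30), seq_len(30), quantiles = c(0.75, 0.9))
  expect_equal(qs0$slope, c(0, 0))
  expect_error(quantile_slopes(rnorm(20), rep(1, 20)), "degenerate")

  # triangular cloud: declining upper envelope, floor at zero
  set.seed(65)
  xx <- runif(300, 0, 100)
  upper <- pmax(0.02, 0.5 - 0.004 * xx)
  yy <- runif(300, 0, upper)
  qs9 <- quantile_slopes(yy, xx, quantiles = 0.9)
  ols <- coef(lm(yy ~ xx))[2]
  expect_lt(qs9$slope, 0)
  expect_lt(ols, 0)
  expect_gt(abs(qs9$slope), abs(ols))        # envelope steeper than the mean
})

test_that("exact quantile fit beats or ties direct optimization of check loss", {
  set.seed(66)
  x <- rnorm(60); y <- 1 + 0.5 * x + rt(60, df = 3)
  for (q in c(0.75, 0.9)) {
    qs <- quantile_slopes(y, x, quantiles = q)
    loss <- function(b) sum((y - b[1] - b[2] * x) *
                              (q - ((y - b[1] - b[2] * x) < 0)))
    opt <- optim(c(0, 0), loss, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-12))
    expect_lte(loss(c(qs$intercept, qs$slope)), opt$value + 1e-8)
  }
})
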