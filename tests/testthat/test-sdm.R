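test_that("species filter enforces inclusive presence and absence floors", {
  occ <- rbind(nine = c(rep(1, 9), rep(0, 91)),
               ten = c(rep(1, 10), rep(0, 90)),
               everywhere = rep(1, 100),
               fine = rep(c(1, 0), 50))
  flt <- filter_species(occ, min_presences = 10)
  expect_setequal(rownames(flt$occ), c("ten", "fine"))
  expect_equal(flt$removed$reason[flt$removed$species == "nine"],
               "too_few_presences")
  expect_equal(flt$removed$reason[flt$removed$species == "everywhere"],
               "too_few_absences")
  expect_error(filter_species(occ[1, , drop = FALSE]), "no species")
})

test_that("null and signal-free fits give D2 near zero; intercept-only is exact", {
  set.seed(21)
  n <- 4000
  X <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("a", "b")))
  y <- rbinom(n, 1, 0.4)
  f <- fit_glm_logit(y, X)
  expect_lt(f$d2, 0.01)
  expect_true(all(abs(f$coefficients[-1]) < 0.1))
  f0 <- fit_glm_logit(y, label = "null")
  expect_identical(f0$d2, 0)
  expect_error(fit_glm_logit(rep(1, 50), X[1:50, ]), "single class")
})

test_that("coefficients are recovered within 3 SE and match an independent optimizer", {
  set.seed(22)
  n <- 5000
  X <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("a", "b")))
  truth <- c(`(Intercept)` = -0.5, a = 1, a2 = -0.5, b = 0.7, b2 = 0)
  Z <- scale(X)
  eta <- truth[1] + Z %*% truth[c("a", "b")] + Z^2 %*% truth[c("a2", "b2")]
  y <- rbinom(n, 1, plogis(eta))
  f <- fit_glm_logit(y, X)
  est <- f$coefficients[names(truth)]
  # crude SE bound: logistic information at n = 5000 keeps SE < 0.06
  expect_true(all(abs(est - truth) < 3 * 0.06))
  expect_true(f$converged)

  # independent route: direct BFGS on the negative log-likelihood
  D <- cbind(1, Z, Z^2)
  nll <- function(b) {
    e <- drop(D %*% b)
    sum(log1p(exp(e))) - sum(e[y == 1])
  }
  opt <- optim(rep(0, 5), nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  expect_equal(unname(est[c(1, 2, 4, 3, 5)]), opt$par, tolerance = 1e-4)
})

test_that("non-convergent (separable) fits are flagged", {
  x <- c(rnorm(20, -3), rnorm(20, 3))
  y <- rep(c(0, 1), each = 20)
  f <- fit_glm_logit(y, matrix(x, dimnames = list(NULL, "x")))
  expect_false(f$converged)
})

test_that("deviance partition reproduces the arithmetic identities", {
  mk <- function(d2, label) structure(
    list(label = label, d2 = d2, n = 100, null_deviance = 120,
         deviance = 120 * (1 - d2), converged = TRUE), class = "sdm_fit")
  p <- partition_deviance(mk(.53, "full"), mk(.48, "contemporary"),
                          mk(.14, "historical"))
  expect_equal(p$pure_contemporary, .39)
  expect_equal(p$shared, .09)
  expect_equal(p$pure_historical, .05)
  expect_equal(p$unexplained, .47)
  expect_equal(with(p, pure_contemporary + shared + pure_historical +
                      unexplained), 1)

  p2 <- partition_deviance(mk(.5, "full"), mk(.5, "contemporary"),
                           mk(.2, "historical"))
  expect_equal(p2$pure_historical, 0)
  expect_error(partition_deviance(mk(.5, "full"), mk(.4, "contemporary"),
                                  structure(list(label = "historical",
                                                 d2 = .2, n = 99,
                                                 null_deviance = 120,
                                                 deviance = 96,
                                                 converged = TRUE),
                                            class = "sdm_fit")),
               "identical data")
})

test_that("orthogonal predictors give zero shared fraction in the Gaussian analog", {
  set.seed(31)
  n <- 400
  # columns exactly orthogonal to each other AND to the intercept
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n, 3))))[, -1]
  xc <- Q[, 1]; xh <- Q[, 2]
  y <- 2 * xc + 1 * xh + Q[, 3]               # noise orthogonal to both
  r2 <- function(X) summary(lm(y ~ X))$r.squared
  b <- r2(xc) + r2(xh) - r2(cbind(xc, xh))
  expect_lt(abs(b), 1e-10)
})

test_that("AUC follows the rank formulation with ties", {
  # presences {0.9, 0.4}, absences {0.6, 0.1}: 3 of 4 pairs concordant
  expect_equal(reefshift:::rank_auc(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0)),
               0.75)
  expect_equal(reefshift:::rank_auc(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(reefshift:::rank_auc(c(3, 4, 1, 2), c(1, 1, 0, 0)), 1)
  # invariance under strictly monotone transforms of the scores
  set.seed(41)
  s <- rnorm(50); y <- rbinom(50, 1, 0.5)
  expect_equal(reefshift:::rank_auc(s, y),
               reefshift:::rank_auc(exp(2 * s) + 5, y))
  # independent reference implementation
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(reefshift:::rank_auc(s, y), ref, tolerance = 1e-12)
})

test_that("repeated split AUC is 1 for a separable species and ~0.5 under noise", {
  set.seed(51)
  n <- 120
  x <- rnorm(n)
  y_sep <- as.numeric(x > 0)
  a <- auc_repeated_split(y_sep, matrix(x, dimnames = list(NULL, "x")),
                          n_repeats = 20, seed = 3)
  # quadratic curvature under separation can misrank the odd boundary point
  expect_gt(a$mean, 0.99)
  y_noise <- rbinom(n, 1, 0.5)
  a2 <- auc_repeated_split(y_noise, matrix(x, dimnames = list(NULL, "x")),
                           n_repeats = 50, seed = 3)
  expect_lt(abs(a2$mean - 0.5), 0.12)
  expect_error(auc_repeated_split(c(1, rep(0, 10)),
                                  matrix(rnorm(11), dimnames = list(NULL, "x")),
                                  n_repeats = 5, seed = 1),
               "stratify")
})

test_that("Moran's I separates checkerboard, random and block patterns", {
  g <- expand.grid(row = 1:4, col = 1:4)
  checker <- (-1)^(g$row + g$col)
  mi <- morans_i(checker, g$row, g$col, style = "rook")
  expect_lt(mi$observed, -0.9)               # perfect negative autocorrelation
  expect_equal(mi$expected, -1 / 15)

  blocks <- ifelse(g$col <= 2, 1, -1)        # two coherent halves
  expect_gt(morans_i(blocks, g$row, g$col, style = "rook")$observed, 0.4)

  expect_error(morans_i(rep(1, 16), g$row, g$col), "variance")
})

test_that("run_sdms returns a coherent per-species table with nesting", {
  rw <- recovery_world()
  res <- rw$sdm
  expect_s3_class(res, "sdm_results")
  conv <- res[res$converged, ]
  expect_gt(nrow(conv), 150)
  expect_true(all(conv$d2_full >= pmax(conv$d2_contemporary,
                                       conv$d2_historical) - 1e-9))
  closure <- with(conv, pure_contemporary + shared + pure_historical +
                    unexplained)
  expect_true(all(abs(closure - 1) < 1e-9))
  expect_true(all(conv$d2_full >= 0 & conv$d2_full <= 1))
})
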