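#' Filter species by presence and absence floors
#'
#' Retains species with at least `min_presences` presence cells and at least
#' as many absence cells (degenerate responses — a species present in every
#' cell — make the logit model unidentifiable, so an absence floor mirrors
#' the presence floor).
#'
#' @param occ binary species x cell matrix with species ids as row names.
#' @param min_presences minimum presence (and absence) cells; default 10.
#' @return list with `occ` (retained rows) and `removed` (data.frame of
#'   species and reason).
#' @export
filter_species <- function(occ, min_presences = 10) {
  occ <- as.matrix(occ)
  if (is.null(rownames(occ))) rownames(occ) <- paste0("sp", seq_len(nrow(occ)))
  npres <- rowSums(occ == 1)
  nabs <- rowSums(occ == 0)
  reason <- rep(NA_character_, nrow(occ))
  reason[nabs < min_presences] <- "too_few_absences"
  reason[npres < min_presences] <- "too_few_presences"
  keep <- is.na(reason)
  if (!any(keep))
    stop(sprintf(paste0("no species retained (%d too few presences, ",
                        "%d too few absences)"),
                 sum(reason == "too_few_presences", na.rm = TRUE),
                 sum(reason == "too_few_absences", na.rm = TRUE)))
  list(occ = occ[keep, , drop = FALSE],
       removed = data.frame(species = rownames(occ)[!keep],
                            reason = reason[!keep],
                            n_presences = npres[!keep],
                            row.names = NULL))
}

# z-score columns, then append squared terms; returns the expanded model
# matrix with columns <name> and <name>2
quadratic_design <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) == 0) return(X)
  Z <- scale(X)
  Z[, attr(Z, "scaled:scale") == 0] <- 0    # constant columns stay at 0
  Q <- Z^2
  colnames(Q) <- paste0(colnames(X), "2")
  cbind(Z, Q)
}

#' Fit one quadratic logistic species distribution model
#'
#' Maximum-likelihood logistic regression of presence/absence on z-scored
#' predictors with linear and quadratic terms. Reports residual and null
#' deviance and the deviance explained D2 = 1 - dev_res / dev_null. A fit is
#' flagged non-converged when the IRLS optimizer fails, a coefficient is
#' non-finite, or any |coefficient| exceeds 15 on the standardized scale
#' (quasi-separation).
#'
#' @param y binary response vector (both classes required).
#' @param X matrix/data.frame of predictors (raw scale; z-scoring and
#'   quadratic expansion are applied internally).
#' @param label predictor-set label, e.g. "full", "contemporary",
#'   "historical", "null".
#' @return object of class `sdm_fit`: coefficients, `deviance`,
#'   `null_deviance`, `d2`, `converged`, `fitted`, `residuals` (deviance
#'   residuals), `n`.
#' @export
fit_glm_logit <- function(y, X = NULL, label = "full") {
  y <- as.numeric(y)
  if (length(unique(y[!is.na(y)])) < 2 && label != "null")
    stop("response has a single class")
  if (is.null(X) || label == "null" || (!is.null(dim(X)) && ncol(X) == 0)) {
    fit <- suppressWarnings(stats::glm(y ~ 1, family = stats::binomial()))
    D <- quadratic_design(matrix(numeric(0), length(y), 0))
  } else {
    D <- quadratic_design(X)
    fit <- suppressWarnings(
      stats::glm(y ~ D, family = stats::binomial()))
  }
  beta <- stats::coef(fit)
  names(beta) <- sub("^D", "", names(beta))
  d2 <- 1 - fit$deviance / fit$null.deviance
  if (fit$null.deviance == 0) d2 <- 0
  converged <- isTRUE(fit$converged) && all(is.finite(beta)) &&
    all(abs(beta[-1]) <= 15)
  structure(list(label = label, coefficients = beta,
                 deviance = fit$deviance, null_deviance = fit$null.deviance,
                 d2 = d2, converged = converged,
                 fitted = stats::fitted(fit),
                 residuals = stats::residuals(fit, type = "deviance"),
                 n = length(y)),
            class = "sdm_fit")
}

#' @export
print.sdm_fit <- function(x, ...) {
  cat(sprintf("sdm_fit [%s]: n = %d, D2 = %.3f%s\n", x$label, x$n, x$d2,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Partition deviance into pure, shared and unexplained fractions
#'
#' Classical two-group variance partitioning: with D2 of the full,
#' contemporary-only and historical-only models,
#' pure historical c = D2_full - D2_contemp,
#' pure contemporary a = D2_full - D2_hist,
#' shared b = D2_contemp + D2_hist - D2_full,
#' unexplained d = 1 - D2_full; a + b + c + d = 1 by construction.
#' Tiny negative fractions (> -1e-6, numerical noise) are clamped to 0 with a
#' warning; larger negatives are reported as-is, since suppression is real in
#' GLMs.
#'
#' @param full,contemporary,historical `sdm_fit` objects on identical data.
#' @return data.frame with `pure_contemporary`, `shared`, `pure_historical`,
#'   `unexplained`.
#' @export
partition_deviance <- function(full, contemporary, historical) {
  ns <- c(full$n, contemporary$n, historical$n)
  devs <- c(full$null_deviance, contemporary$null_deviance,
            historical$null_deviance)
  if (length(unique(ns)) != 1 || diff(range(devs)) > 1e-8 * max(devs, 1))
    stop("fits were not produced on identical data")
  a <- full$d2 - historical$d2
  b <- contemporary$d2 + historical$d2 - full$d2
  c_ <- full$d2 - contemporary$d2
  d <- 1 - full$d2
  clamp <- function(x) {
    if (x < 0 && x > -1e-6) {
      warning("tiny negative fraction clamped to 0")
      0
    } else x
  }
  data.frame(pure_contemporary = clamp(a), shared = clamp(b),
             pure_historical = clamp(c_), unexplained = clamp(d))
}

# Rank (Mann-Whitney) AUC with tie correction: mean rank of presences.
rank_auc <- function(scores, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Repeated split-sample AUC
#'
#' Repeatedly splits the data into stratified train/test partitions
#' (train_frac of each class to training), refits the quadratic logit model
#' on the training part, scores the held-out part, and computes AUC by the
#' rank (Mann-Whitney) formulation with tie correction.
#'
#' @param y binary response.
#' @param X predictor matrix (raw scale).
#' @param n_repeats number of random splits; default 100.
#' @param train_frac training fraction; default 0.7.
#' @param seed integer seed for the split sequence.
#' @return list with `mean`, `sd` and the per-repeat `auc` vector.
#' @export
auc_repeated_split <- function(y, X, n_repeats = 100, train_frac = 0.7,
                               seed = 1) {
  y <- as.numeric(y)
  i1 <- which(y == 1); i0 <- which(y == 0)
  n1 <- max(1L, min(length(i1) - 1L, round(train_frac * length(i1))))
  n0 <- max(1L, min(length(i0) - 1L, round(train_frac * length(i0))))
  if (length(i1) < 2 || length(i0) < 2)
    stop("need at least 2 cells of each class to stratify the split")
  X <- as.matrix(X)
  aucs <- withr::with_seed(seed, vapply(seq_len(n_repeats), function(r) {
    tr <- c(sample(i1, n1), sample(i0, n0))
    te <- setdiff(seq_along(y), tr)
    ctr <- colMeans(X[tr, , drop = FALSE])
    scl <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    scl[scl == 0] <- 1
    Ztr <- sweep(sweep(X[tr, , drop = FALSE], 2, ctr), 2, scl, "/")
    Zte <- sweep(sweep(X[te, , drop = FALSE], 2, ctr), 2, scl, "/")
    Dtr <- cbind(Ztr, Ztr^2)
    Dte <- cbind(Zte, Zte^2)
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, Dtr), y[tr], family = stats::binomial()))
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    eta <- drop(cbind(1, Dte) %*% beta)
    rank_auc(eta, y[te])
  }, 0))
  list(mean = mean(aucs, na.rm = TRUE), sd = stats::sd(aucs), auc = aucs)
}

#' Queen- (or rook-) adjacency spatial weights for analysis cells
#'
#' Row-standardized binary contiguity weights on the analysis grid: cells are
#' neighbors when their row/column indices differ by at most 1 (queen) or
#' share an edge (rook).
#'
#' @param rows,cols integer grid indices of each retained cell.
#' @param style "queen" or "rook".
#' @return n x n row-standardized weight matrix.
#' @export
grid_weights <- function(rows, cols, style = c("queen", "rook")) {
  style <- match.arg(style)
  dr <- abs(outer(rows, rows, "-")); dc <- abs(outer(cols, cols, "-"))
  W <- if (style == "queen") (dr <= 1 & dc <= 1) else
    ((dr + dc) == 1)
  diag(W) <- FALSE
  W <- W * 1
  rs <- rowSums(W)
  W[rs > 0, ] <- W[rs > 0, , drop = FALSE] / rs[rs > 0]
  W
}

#' Moran's I of model residuals
#'
#' Spatial autocorrelation of residuals under row-standardized contiguity
#' weights, I = (n / sum(w)) * sum_ij w_ij z_i z_j / sum_i z_i^2, with null
#' expectation -1/(n-1). Delegates the statistic to ape::Moran.I on the
#' weight matrix built by [grid_weights].
#'
#' @param residuals numeric residual vector (variance must be positive).
#' @param rows,cols integer analysis-grid indices per cell.
#' @param style contiguity style, see [grid_weights].
#' @return list with `observed`, `expected`, `sd`, `p.value`.
#' @export
morans_i <- function(residuals, rows, cols, style = "queen") {
  if (length(residuals) < 3) stop("need at least 3 cells")
  if (stats::sd(residuals) == 0) stop("zero-variance residuals")
  W <- grid_weights(rows, cols, style)
  ape::Moran.I(residuals, W)
}

#' Fit the SDM suite for every species at one threshold
#'
#' For each retained species fits the full (contemporary + historical),
#' contemporary-only, historical-only and null quadratic logit models,
#' partitions deviance, and (optionally) computes repeated-split AUC and
#' Moran's I of full-model deviance residuals.
#'
#' @param occ binary species x cell matrix (cells must match `predictors`
#'   rows).
#' @param predictors data.frame with contemporary columns `sst, chl, o2, ni,
#'   sss`, historical column `iref`, and grid indices `row`, `col`.
#' @param min_presences species filter floor; see [filter_species].
#' @param n_auc_repeats repeated splits for AUC (0 skips AUC).
#' @param train_frac training fraction for the splits.
#' @param seed integer seed driving the split sequence.
#' @param moran logical: compute Moran's I of full-model residuals?
#' @return data.frame of class `sdm_results`, one row per retained species:
#'   D2 of each predictor set, the four deviance fractions, AUC mean/sd for
#'   full and historical-only models, Moran's I, counts and convergence
#'   flags. Attribute `removed` records filtered species; attribute `fits`
#'   holds the per-species `sdm_fit` lists.
#' @export
run_sdms <- function(occ, predictors, min_presences = 10, n_auc_repeats = 100,
                     train_frac = 0.7, seed = 1, moran = TRUE) {
  contemp_cols <- c("sst", "chl", "o2", "ni", "sss")
  stopifnot(all(c(contemp_cols, "iref") %in% names(predictors)))
  if (ncol(occ) != nrow(predictors))
    stop("occurrence columns and predictor rows differ")
  flt <- filter_species(occ, min_presences)
  occ <- flt$occ
  Xc <- as.matrix(predictors[contemp_cols])
  Xh <- as.matrix(predictors["iref"])
  Xf <- cbind(Xc, Xh)

  res <- vector("list", nrow(occ))
  fits <- vector("list", nrow(occ))
  for (i in seq_len(nrow(occ))) {
    y <- occ[i, ]
    f_full <- fit_glm_logit(y, Xf, "full")
    f_con <- fit_glm_logit(y, Xc, "contemporary")
    f_his <- fit_glm_logit(y, Xh, "historical")
    conv <- f_full$converged && f_con$converged && f_his$converged
    part <- suppressWarnings(partition_deviance(f_full, f_con, f_his))
    auc_f <- auc_h <- list(mean = NA_real_, sd = NA_real_)
    if (n_auc_repeats > 0) {
      auc_f <- auc_repeated_split(y, Xf, n_auc_repeats, train_frac,
                                  seed = seed + i)
      auc_h <- auc_repeated_split(y, Xh, n_auc_repeats, train_frac,
                                  seed = seed + i)
    }
    mi <- if (moran)
      morans_i(f_full$residuals, predictors$row, predictors$col)$observed
    else NA_real_
    fits[[i]] <- list(full = f_full, contemporary = f_con, historical = f_his)
    res[[i]] <- data.frame(
      species = rownames(occ)[i], n_presence = sum(y == 1),
      n_absence = sum(y == 0),
      d2_full = f_full$d2, d2_contemporary = f_con$d2,
      d2_historical = f_his$d2, part,
      auc_full = auc_f$mean, auc_full_sd = auc_f$sd,
      auc_historical = auc_h$mean, auc_historical_sd = auc_h$sd,
      moran_i = mi, converged = conv)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "removed") <- flt$removed
  attr(out, "fits") <- stats::setNames(fits, out$species)
  class(out) <- c("sdm_results", "data.frame")
  out
}
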