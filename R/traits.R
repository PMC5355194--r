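#' Species trait table
#'
#' Validates a per-species trait table: maximum body size (cm), an ordered
#' mobility category and a habitat-specialization category.
#'
#' @param species character ids.
#' @param size_cm positive maximum body sizes (cm).
#' @param mobility factor/character in `sedentary`, `mobile_within_reef`,
#'   `mobile_between_reefs`.
#' @param specialization factor/character in `coral_specialized`,
#'   `other_specialized`, `not_specialized`.
#' @return data.frame of class `trait_table`.
#' @export
trait_table <- function(species, size_cm, mobility, specialization) {
  mob_levels <- c("sedentary", "mobile_within_reef", "mobile_between_reefs")
  spec_levels <- c("coral_specialized", "other_specialized", "not_specialized")
  if (any(!is.finite(size_cm)) || any(size_cm <= 0))
    stop("sizes must be positive and finite")
  if (!all(mobility %in% mob_levels))
    stop("unknown mobility category")
  if (!all(specialization %in% spec_levels))
    stop("unknown specialization category")
  out <- data.frame(
    species = as.character(species), size_cm = as.numeric(size_cm),
    # "mobile within a reef" is the reference level, so the dummy rows are
    # sedentary and mobile-between-reefs (the "very mobile" contrast)
    mobility = factor(mobility,
                      levels = mob_levels[c(2, 1, 3)]),
    specialization = factor(specialization, levels = spec_levels[c(1, 3, 2)]))
  class(out) <- c("trait_table", "data.frame")
  out
}

trait_terms <- c(size = "size_cm", mobility = "mobility",
                 specialization = "specialization")

#' All-subsets linear models with Akaike-weight averaging
#'
#' Fits ordinary linear models of the response on every subset of
#' `{size, mobility, specialization}` (including the intercept-only model),
#' ranks them by AIC = -2 logLik + 2k, converts DeltaAIC to Akaike weights
#' w_m = exp(-Delta_m / 2) / sum(exp(-Delta / 2)), sums weights over models
#' containing each trait (relative importance w_AIC), and model-averages
#' coefficients over the models containing each term (conditional averaging),
#' with unconditional standard errors combining within-model variance and
#' between-model spread.
#'
#' @param response numeric per-species response (e.g. pure-historical
#'   deviance fraction).
#' @param traits a [trait_table] aligned with `response` (matched on
#'   `species` if `names(response)` is set).
#' @param log10_size log10-transform body size before fitting? Default FALSE
#'   (sizes enter in cm).
#' @return object of class `trait_model_set`: `models` (AIC table with
#'   weights), `importance` (summed w_AIC per trait), `coefficients`
#'   (averaged slope, unconditional SE, Z, p per term), `data`.
#' @export
all_subsets_averaging <- function(response, traits, log10_size = FALSE) {
  dat <- as.data.frame(traits)
  if (!is.null(names(response)))
    response <- response[match(dat$species, names(response))]
  dat$response <- as.numeric(response)
  dat <- dat[stats::complete.cases(dat[c("response", trait_terms)]), ]
  if (log10_size) dat$size_cm <- log10(dat$size_cm)
  for (v in c("mobility", "specialization"))
    if (any(table(droplevels(dat[[v]])) < 2) || nlevels(droplevels(dat[[v]])) < 2)
      warning("factor ", v, " has levels with fewer than 2 species")

  subsets <- expand.grid(size = c(FALSE, TRUE), mobility = c(FALSE, TRUE),
                         specialization = c(FALSE, TRUE))
  fits <- vector("list", nrow(subsets))
  tab <- data.frame(formula = character(nrow(subsets)), k = 0, logLik = 0,
                    aic = 0)
  for (m in seq_len(nrow(subsets))) {
    terms_m <- trait_terms[unlist(subsets[m, ])]
    f <- stats::reformulate(if (length(terms_m)) terms_m else "1",
                            response = "response")
    fit <- stats::lm(f, data = dat)
    if (any(is.na(stats::coef(fit))))
      stop("rank-deficient design: collinear terms in ",
           paste(terms_m, collapse = " + "))
    fits[[m]] <- fit
    ll <- stats::logLik(fit)
    tab$formula[m] <- paste(deparse(f), collapse = "")
    tab$k[m] <- attr(ll, "df")
    tab$logLik[m] <- as.numeric(ll)
    tab$aic[m] <- stats::AIC(fit)
  }
  tab$delta_aic <- tab$aic - min(tab$aic)
  w <- exp(-tab$delta_aic / 2)
  tab$weight <- w / sum(w)

  importance <- vapply(names(trait_terms), function(tr)
    sum(tab$weight[subsets[[tr]]]), 0)

  # union of coefficient names over all models (drop intercept)
  coef_names <- unique(unlist(lapply(fits, function(f)
    names(stats::coef(f))[-1])))
  avg <- lapply(coef_names, function(cn) {
    has <- vapply(fits, function(f) cn %in% names(stats::coef(f)), TRUE)
    wi <- tab$weight[has] / sum(tab$weight[has])
    b <- vapply(fits[has], function(f) stats::coef(f)[cn], 0)
    se <- vapply(fits[has], function(f)
      sqrt(stats::vcov(f)[cn, cn]), 0)
    bbar <- sum(wi * b)
    se_u <- sum(wi * sqrt(se^2 + (b - bbar)^2))   # unconditional SE
    z <- abs(bbar) / se_u
    data.frame(term = cn, estimate = bbar, se = se_u, z = z,
               p = 2 * stats::pnorm(-z), w_aic = sum(tab$weight[has]))
  })
  out <- list(models = tab, importance = importance,
              coefficients = do.call(rbind, avg), data = dat, fits = fits)
  class(out) <- "trait_model_set"
  out
}

#' @export
print.trait_model_set <- function(x, ...) {
  cat("All-subsets model averaging over {size, mobility, specialization}\n")
  cat("Relative importance (summed Akaike weights):\n")
  print(round(x$importance, 3))
  cat("Model-averaged coefficients:\n")
  print(x$coefficients, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Graft unsampled species onto congeneric tips
#'
#' Species absent from the phylogeny are attached at the midpoint of a
#' randomly chosen congeneric tip's terminal branch, forming a cherry with
#' two branches of half that terminal length — which preserves
#' ultrametricity. Species with no congeneric tip are returned as
#' unplaceable.
#'
#' @param tree an `ape::phylo` with species ids as tip labels.
#' @param species character vector of species that must end up in the tree.
#' @param genus_of function or named character vector mapping a species id to
#'   its genus; defaults to the prefix before the first `_` or space.
#' @param seed integer seed for the congener choice.
#' @return list with `tree` (augmented phylo) and `unplaced` (character).
#' @export
graft_missing_tips <- function(tree, species, genus_of = NULL, seed = 1) {
  get_genus <- if (is.function(genus_of)) genus_of
  else if (!is.null(genus_of)) function(s) unname(genus_of[s])
  else function(s) sub("[_ ].*$", "", s)
  missing <- setdiff(species, tree$tip.label)
  unplaced <- character(0)
  withr::with_seed(seed, for (sp in missing) {
    g <- get_genus(sp)
    congeners <- tree$tip.label[get_genus(tree$tip.label) == g]
    if (!length(congeners)) { unplaced <- c(unplaced, sp); next }
    anchor <- if (length(congeners) == 1) congeners else sample(congeners, 1)
    tip_idx <- match(anchor, tree$tip.label)
    term_edge <- which(tree$edge[, 2] == tip_idx)
    half <- tree$edge.length[term_edge] / 2
    new_tip <- structure(list(
      edge = matrix(c(2L, 1L), 1, 2), tip.label = sp,
      edge.length = half, Nnode = 1L), class = "phylo")
    tree <- ape::bind.tree(tree, new_tip, where = tip_idx, position = half)
  })
  list(tree = tree, unplaced = unplaced)
}

# Gaussian GLS log-likelihood for covariance sigma2 * V, beta profiled out.
gls_profile <- function(y, X, V) {
  n <- length(y)
  L <- chol(V)
  Xi <- backsolve(L, X, transpose = TRUE)
  yi <- backsolve(L, y, transpose = TRUE)
  fit <- stats::lm.fit(Xi, yi)
  beta <- fit$coefficients
  r <- yi - Xi %*% beta
  sigma2 <- sum(r^2) / n
  ll <- -n / 2 * (log(2 * pi * sigma2) + 1) - sum(log(diag(L)))
  XtX_inv <- chol2inv(qr.R(qr(Xi)))
  se <- sqrt(diag(XtX_inv) * sum(r^2) / (n - ncol(X)))
  list(beta = beta, se = se, sigma2 = sigma2, logLik = ll)
}

#' Phylogenetic generalized least squares with Pagel's lambda
#'
#' GLS regression under the covariance V(lambda) = lambda * V_BM +
#' (1 - lambda) * diag(V_BM), where V_BM is the Brownian-motion covariance
#' implied by the tree. lambda is estimated by maximizing the profile
#' likelihood over [0, 1] (coarse grid plus local refinement); lambda = 0
#' reproduces ordinary least squares, lambda = 1 full Brownian covariance.
#'
#' @param formula model formula, variables found in `data`.
#' @param data data.frame with one row per species; rownames or a `species`
#'   column give species ids matched to tip labels.
#' @param tree `ape::phylo`, ultrametric within tolerance, tips covering the
#'   species.
#' @param lambda fix lambda at a value instead of estimating (NULL = ML).
#' @return object of class `pgls_result`: `lambda`, `coefficients` table
#'   (estimate, se, t, p), `logLik`, `n`.
#' @export
pgls_fit <- function(formula, data, tree, lambda = NULL) {
  ids <- if ("species" %in% names(data)) data$species else rownames(data)
  if (is.null(ids)) stop("data needs a species column or rownames")
  miss <- setdiff(ids, tree$tip.label)
  if (length(miss)) stop("species missing from tree: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  tree <- ape::keep.tip(tree, ids)
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  if (diff(range(depths)) > 1e-6 * max(depths))
    stop("tree is not ultrametric within tolerance")
  Vbm <- ape::vcv(tree)[ids, ids]
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  d <- diag(Vbm)
  V_of <- function(lam) {
    V <- lam * Vbm
    diag(V) <- d
    V
  }
  obj <- function(lam) gls_profile(y, X, V_of(lam))$logLik
  if (is.null(lambda)) {
    grid <- seq(0, 1, by = 0.1)
    ll <- vapply(grid, obj, 0)
    i <- which.max(ll)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    opt <- stats::optimize(obj, c(lo, hi), maximum = TRUE, tol = 1e-6)
    lambda <- if (opt$objective >= max(ll)) opt$maximum else grid[i]
  }
  fit <- gls_profile(y, X, V_of(lambda))
  tval <- fit$beta / fit$se
  ct <- data.frame(term = colnames(X), estimate = as.numeric(fit$beta),
                   se = fit$se, t = as.numeric(tval),
                   p = 2 * stats::pt(-abs(tval), length(y) - ncol(X)))
  structure(list(lambda = lambda, coefficients = ct, logLik = fit$logLik,
                 sigma2 = fit$sigma2, n = length(y)),
            class = "pgls_result")
}

#' @export
print.pgls_result <- function(x, ...) {
  cat(sprintf("PGLS (Pagel's lambda = %.3f, n = %d)\n", x$lambda, x$n))
  print(x$coefficients, digits = 3, row.names = FALSE)
  invisible(x)
}

# check (pinball) loss for residuals at quantile q
check_loss <- function(r, q) sum(r * (q - (r < 0)))

#' Linear quantile regression by exact check-loss minimization
#'
#' Fits response = a + b * x at each requested quantile by minimizing the
#' check loss. For the two-parameter linear fit an optimum lies at a vertex
#' of the LP — a line through two data points with distinct x (or a
#' horizontal line through one point) — so all candidate vertices are
#' enumerated and the loss evaluated exactly.
#'
#' @param response numeric response.
#' @param size numeric covariate (body size, cm).
#' @param quantiles quantile levels; default c(0.75, 0.9).
#' @param n_boot bootstrap replicates for slope standard errors (0 = none).
#' @param seed integer seed for the bootstrap.
#' @return data.frame: `q`, `intercept`, `slope`, and when `n_boot > 0`
#'   `slope_se` and `p` (normal-approximation, H0: slope = 0).
#' @export
quantile_slopes <- function(response, size, quantiles = c(0.75, 0.9),
                            n_boot = 0, seed = 1) {
  x <- as.numeric(size); y <- as.numeric(response)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0) stop("degenerate size variance")
  fit1 <- function(x, y, q) {
    n <- length(x)
    ij <- utils::combn(n, 2)
    dx <- x[ij[1, ]] - x[ij[2, ]]
    keep <- abs(dx) > 1e-12
    b <- (y[ij[1, keep]] - y[ij[2, keep]]) / dx[keep]
    a <- y[ij[1, keep]] - b * x[ij[1, keep]]
    # horizontal candidates through each point
    b <- c(b, rep(0, n)); a <- c(a, y)
    R <- outer(y, rep(1, length(b))) - outer(x, b) -
      matrix(a, length(y), length(b), byrow = TRUE)
    loss <- colSums(R * (q - (R < 0)))
    k <- which.min(loss)
    c(intercept = a[k], slope = b[k])
  }
  out <- lapply(quantiles, function(q) {
    cf <- fit1(x, y, q)
    row <- data.frame(q = q, intercept = cf["intercept"], slope = cf["slope"])
    if (n_boot > 0) {
      bs <- withr::with_seed(seed + round(1000 * q),
        vapply(seq_len(n_boot), function(b) {
          i <- sample(length(x), replace = TRUE)
          if (stats::sd(x[i]) == 0) return(NA_real_)
          fit1(x[i], y[i], q)["slope"]
        }, 0))
      row$slope_se <- stats::sd(bs, na.rm = TRUE)
      row$p <- 2 * stats::pnorm(-abs(row$slope) / row$slope_se)
    }
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
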