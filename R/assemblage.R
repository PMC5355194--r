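#' Per-cell assemblage summaries
#'
#' For each analysis cell: the number of occupant species and the unweighted
#' mean of any per-species value columns (e.g. the pure-historical deviance
#' fraction, body size) over the species present. Cells with no retained
#' occupant are undefined (NA means).
#'
#' @param occ binary species x cell matrix (species ids as row names).
#' @param values data.frame or named vector(s): per-species values with a
#'   `species` column (data.frame) or names matching the occurrence rows.
#' @return data.frame: `cell_id`, `n_species`, and one mean column per value
#'   column.
#' @export
cell_means <- function(occ, values) {
  occ <- as.matrix(occ)
  if (is.null(rownames(occ))) stop("occurrence matrix needs species rownames")
  if (is.vector(values) && !is.list(values))
    values <- data.frame(species = names(values), value = unname(values))
  values <- as.data.frame(values)
  if (!"species" %in% names(values))
    stop("values need a species column")
  common <- intersect(rownames(occ), values$species)
  occ <- occ[common, , drop = FALSE]
  V <- as.matrix(values[match(common, values$species),
                        setdiff(names(values), "species"), drop = FALSE])
  n_sp <- colSums(occ)
  means <- crossprod(occ, V) / n_sp        # NaN where n_sp == 0
  means[n_sp == 0, ] <- NA_real_
  out <- data.frame(cell_id = colnames(occ) %||% seq_len(ncol(occ)),
                    n_species = n_sp, means, row.names = NULL)
  names(out)[-(1:2)] <- paste0("mean_", colnames(V))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cross-cell regression of assemblage history on assemblage size
#'
#' Ordinary least squares of the cell-mean historical fraction on the
#' cell-mean body size across defined cells; both directions have identical
#' R-squared, and slope sign, t and p are reported for the stated direction.
#'
#' @param summary data.frame from [cell_means] with columns
#'   `mean_pure_historical` and `mean_size_cm` (or supply `history` and
#'   `size` column names).
#' @param history,size column names of the two variables.
#' @return list: `slope`, `intercept`, `r_squared`, `t`, `p`, `n`.
#' @export
size_history_regression <- function(summary,
                                    history = "mean_pure_historical",
                                    size = "mean_size_cm") {
  d <- summary[stats::complete.cases(summary[c(history, size)]), ]
  if (nrow(d) < 3) stop("need at least 3 defined cells")
  if (stats::sd(d[[history]]) == 0 || stats::sd(d[[size]]) == 0)
    stop("zero variance in a regression variable")
  fit <- stats::lm(d[[history]] ~ d[[size]])
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = s$r.squared,
       t = s$coefficients[2, "t value"],
       p = s$coefficients[2, "Pr(>|t|)"],
       n = nrow(d))
}
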