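#' Least-cost distance from every sea cell to the nearest suitable cell
#'
#' Multi-source shortest-path distance over the 8-connected traversable graph
#' (sea cells traversable, land cells barriers). Straight and diagonal steps
#' cost the great-circle distance between the two cell centers (km), or unit
#' costs (1 / sqrt(2)) under `metric = "unit"`. Suitable cells get 0;
#' traversable cells with no path to any suitable cell get +Inf; land cells
#' get NA.
#'
#' Implemented as a single-source Dijkstra from a virtual super-source joined
#' by zero-weight edges to every suitable cell.
#'
#' @param traversable logical matrix, TRUE where a cell can be crossed.
#' @param suitable logical matrix, TRUE at source (suitable-habitat) cells;
#'   must be a subset of `traversable`.
#' @param lon,lat cell-center coordinate vectors (ignored under
#'   `metric = "unit"`).
#' @param metric "haversine" (km) or "unit" (cell units).
#' @param unit_scale multiplier for unit-metric step costs.
#' @return numeric matrix of distances, same shape as `traversable`.
#' @export
distance_to_suitable <- function(traversable, suitable, lon = NULL, lat = NULL,
                                 metric = c("haversine", "unit"),
                                 unit_scale = 1) {
  metric <- match.arg(metric)
  if (!identical(dim(traversable), dim(suitable)))
    stop("traversable and suitable grids differ in shape")
  if (any(suitable & !traversable))
    stop("suitable cells must be traversable")
  if (!any(suitable)) stop("no suitable cells: global habitat collapse")
  nr <- nrow(traversable); nc <- ncol(traversable)
  if (metric == "haversine" && (length(lon) != nc || length(lat) != nr))
    stop("lon/lat must match grid dimensions for the haversine metric")

  out <- matrix(NA_real_, nr, nc)
  idx <- which(traversable)                    # column-major cell ids
  if (!length(idx)) return(out)
  node_of <- rep(NA_integer_, nr * nc)
  node_of[idx] <- seq_along(idx)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L

  # 8-neighbor edges, each pair once (E, S, SE, SW offsets)
  offs <- cbind(dr = c(0L, 1L, 1L, 1L), dc = c(1L, 0L, 1L, -1L))
  ef <- integer(0); et <- integer(0); ew <- numeric(0)
  for (k in seq_len(nrow(offs))) {
    r2 <- rows + offs[k, "dr"]; c2 <- cols + offs[k, "dc"]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- (c2[ok] - 1L) * nr + r2[ok]
    keep <- !is.na(node_of[j])
    from <- node_of[idx[ok]][keep]; to <- node_of[j][keep]
    if (!length(from)) next
    w <- if (metric == "haversine") {
      step_distance(lon[cols[ok][keep]], lat[rows[ok][keep]],
                    lon[c2[ok][keep]], lat[r2[ok][keep]], metric = "haversine")
    } else {
      step_distance(cols[ok][keep], rows[ok][keep],
                    c2[ok][keep], r2[ok][keep],
                    metric = "unit", unit_scale = unit_scale)
    }
    ef <- c(ef, from); et <- c(et, to); ew <- c(ew, w)
  }

  n <- length(idx)
  src <- n + 1L                                # virtual super-source
  s_nodes <- node_of[which(suitable)]
  g <- igraph::make_graph(rbind(c(ef, rep(src, length(s_nodes))),
                                c(et, s_nodes)),
                          n = n + 1L, directed = FALSE)
  d <- igraph::distances(g, v = src, weights = c(ew, rep(0, length(s_nodes))),
                         algorithm = "dijkstra")[1, seq_len(n)]
  out[idx] <- d
  out
}

#' Time-integrated isolation from stable areas (IREF)
#'
#' For each cell, sums over timesteps the least-cost distance to the nearest
#' contemporaneously suitable cell (C, km), counts the timesteps in which the
#' cell itself was suitable (K), and returns IREF = C / K — undefined where
#' K = 0. IREF is 0 exactly for cells suitable at every (non-collapsed)
#' timestep; high values mark cells whose local habitat collapsed often and
#' lay far from refugia when it did.
#'
#' Traversability at each timestep uses the contemporaneous land mask
#' (h >= s_t is a barrier), so glacial low stands both remove habitat and
#' create dispersal barriers. Timesteps with no suitable cell anywhere
#' ("global collapse") are skipped and counted. Traversable cells unreachable
#' from any suitable cell at a timestep (isolated seas) contribute a capped
#' penalty — the geodesic length of the grid diagonal — rather than +Inf, so
#' downstream models keep finite predictors.
#'
#' @param stack a `suitability_stack` from [build_suitability_stack].
#' @param elevation `reef_grid` of elevation defining contemporaneous
#'   traversability; NULL makes every cell traversable.
#' @param metric,unit_scale step-cost options passed to
#'   [distance_to_suitable].
#' @return object of class `isolation_map`: matrices `C` (km), `K` (count),
#'   `IREF` (km, NA where K = 0), grid coordinates, the unreachable-cell
#'   `cap` and the number of `skipped` (collapsed) timesteps.
#' @export
compute_isolation <- function(stack, elevation = NULL,
                              metric = c("haversine", "unit"),
                              unit_scale = 1) {
  metric <- match.arg(metric)
  nt <- dim(stack$S)[3]
  if (nt < 1) stop("stack has no timesteps")
  nr <- length(stack$lat); nc <- length(stack$lon)
  cap <- if (metric == "haversine") {
    step_distance(stack$lon[1], stack$lat[1], stack$lon[nc], stack$lat[nr],
                  metric = "haversine")
  } else sqrt((nr - 1)^2 + (nc - 1)^2) * unit_scale

  C <- matrix(0, nr, nc); K <- matrix(0, nr, nc)
  skipped <- 0L
  for (t in seq_len(nt)) {
    s_t <- matrix(stack$S[, , t], nr, nc)
    if (!any(s_t)) { skipped <- skipped + 1L; next }
    trav <- if (is.null(elevation)) matrix(TRUE, nr, nc) else
      elevation$values < stack$sea_level[t]
    trav <- trav | s_t
    d <- distance_to_suitable(trav, s_t, stack$lon, stack$lat,
                              metric = metric, unit_scale = unit_scale)
    d[is.na(d)] <- cap            # land at t: treated as unreachable, capped
    d[is.infinite(d)] <- cap
    C <- C + d
    K <- K + s_t
  }
  if (skipped == nt) stop("all timesteps collapsed: no suitable habitat ever")
  IREF <- ifelse(K > 0, C / K, NA_real_)
  structure(list(C = C, K = K, IREF = IREF, lon = stack$lon, lat = stack$lat,
                 cap = cap, skipped = skipped,
                 threshold_C = stack$threshold_C),
            class = "isolation_map")
}

#' @export
print.isolation_map <- function(x, ...) {
  cat(sprintf("isolation_map (threshold %.1f degC): %d x %d cells\n",
              x$threshold_C, nrow(x$IREF), ncol(x$IREF)))
  v <- x$IREF[is.finite(x$IREF)]
  cat(sprintf("  IREF defined on %d cells; median %.1f, max %.1f\n",
              length(v), stats::median(v), max(v)))
  if (x$skipped > 0)
    cat(sprintf("  %d collapsed timestep(s) skipped\n", x$skipped))
  invisible(x)
}
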