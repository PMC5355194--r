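#' Gridded field on a regular lon/lat lattice
#'
#' A `reef_grid` is a matrix of cell values together with the cell-center
#' coordinates of its rows and columns. Rows run north to south (latitude
#' decreasing), columns west to east (longitude increasing); all grids in an
#' analysis share one extent and resolution. Values are numeric (elevation in
#' m, SST in deg C, ...) or logical (masks).
#'
#' @param values matrix of cell values, `length(lat)` rows by `length(lon)`
#'   columns.
#' @param lon numeric vector of cell-center longitudes (degrees, increasing).
#' @param lat numeric vector of cell-center latitudes (degrees, decreasing).
#' @return an object of class `reef_grid`.
#' @export
reef_grid <- function(values, lon, lat) {
  values <- as.matrix(values)
  if (nrow(values) != length(lat) || ncol(values) != length(lon))
    stop("grid dimensions do not match coordinate vectors")
  if (length(lat) > 1 && any(diff(lat) >= 0))
    stop("latitudes must be strictly decreasing (north to south)")
  if (length(lon) > 1 && any(diff(lon) <= 0))
    stop("longitudes must be strictly increasing")
  structure(list(values = values, lon = as.numeric(lon), lat = as.numeric(lat)),
            class = "reef_grid")
}

#' @export
print.reef_grid <- function(x, ...) {
  cat(sprintf("reef_grid: %d x %d cells, lon [%.2f, %.2f], lat [%.2f, %.2f]\n",
              nrow(x$values), ncol(x$values),
              min(x$lon), max(x$lon), min(x$lat), max(x$lat)))
  v <- x$values[is.finite(x$values)]
  if (length(v))
    cat(sprintf("  values: min %.3g, median %.3g, max %.3g\n",
                min(v), stats::median(v), max(v)))
  invisible(x)
}

#' @export
dim.reef_grid <- function(x) dim(x$values)

same_geometry <- function(a, b) {
  isTRUE(all.equal(a$lon, b$lon)) && isTRUE(all.equal(a$lat, b$lat))
}

#' Block-average a fine grid onto a coarser analysis grid
#'
#' Aggregates by the mean over `factor` x `factor` blocks, ignoring undefined
#' (NA) cells; a block that is entirely undefined stays undefined. Trailing
#' partial blocks (when dimensions are not divisible by `factor`) are averaged
#' over the cells available.
#'
#' @param fine a `reef_grid` or plain matrix.
#' @param factor integer >= 1, fine-to-coarse cell ratio.
#' @return aggregated object of the same class as `fine`.
#' @export
aggregate_to_analysis_grid <- function(fine, factor) {
  if (length(factor) != 1 || is.na(factor) || factor < 1 || factor != round(factor))
    stop("aggregation factor must be a single integer >= 1")
  is_grid <- inherits(fine, "reef_grid")
  m <- if (is_grid) fine$values else as.matrix(fine)
  ri <- ceiling(seq_len(nrow(m)) / factor)
  ci <- ceiling(seq_len(ncol(m)) / factor)
  storage.mode(m) <- "double"
  # block means ignoring NA: sum of defined / count of defined
  grp <- function(x, idx) rowsum(x, idx, reorder = TRUE)
  sums  <- t(grp(t(grp(ifelse(is.na(m), 0, m), ri)), ci))
  cnts  <- t(grp(t(grp((!is.na(m)) * 1, ri)), ci))
  out <- sums / cnts
  out[cnts == 0] <- NA_real_
  dimnames(out) <- NULL
  if (!is_grid) return(out)
  reef_grid(out,
            lon = as.numeric(grp(fine$lon, ci) / tabulate(ci)),
            lat = as.numeric(grp(fine$lat, ri) / tabulate(ri)))
}

#' Great-circle distance between adjacent grid cells
#'
#' Step costs for the 8-connected graph over a grid: the haversine distance in
#' km between cell centers (diagonals cost their true geodesic length), or unit
#' costs (1 for straight steps, sqrt(2) for diagonals) for idealized lattices.
#'
#' @param lon1,lat1,lon2,lat2 coordinates of the two cell centers (degrees).
#' @param metric "haversine" (km) or "unit" (cell units).
#' @param unit_scale multiplier applied to unit-metric costs.
#' @return numeric distance(s).
#' @keywords internal
step_distance <- function(lon1, lat1, lon2, lat2,
                          metric = c("haversine", "unit"), unit_scale = 1) {
  metric <- match.arg(metric)
  if (metric == "haversine") {
    wrap <- function(x) ((x + 180) %% 360) - 180
    return(geosphere::distHaversine(cbind(wrap(lon1), lat1),
                                    cbind(wrap(lon2), lat2)) / 1000)
  }
  sqrt((lon1 != lon2) + (lat1 != lat2)) * unit_scale
}

# Smooth standardized Gaussian random field: white noise convolved with a
# separable Gaussian kernel (edge-normalized), then scaled to unit variance.
smooth_field <- function(nr, nc, sigma = 3) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (sigma > 0) {
    half <- max(1L, ceiling(3 * sigma))
    k <- stats::dnorm(seq(-half, half), sd = sigma)
    conv1 <- function(m, kern) {
      # normalized 1-D convolution down columns, edges renormalized
      nr2 <- nrow(m)
      out <- matrix(0, nr2, ncol(m)); wt <- matrix(0, nr2, ncol(m))
      for (j in seq_along(kern)) {
        off <- j - half - 1L
        src <- seq_len(nr2) + off
        ok <- src >= 1L & src <= nr2
        out[ok, ] <- out[ok, ] + kern[j] * m[src[ok], , drop = FALSE]
        wt[ok, ] <- wt[ok, ] + kern[j]
      }
      out / wt
    }
    z <- conv1(z, k)
    z <- t(conv1(t(z), k))
  }
  (z - mean(z)) / stats::sd(z)
}

#' Write and read grids as plain-text CSV with a JSON sidecar
#'
#' Grids are serialized as headerless CSV matrices; a `<file>.json` sidecar
#' records the lon/lat cell-center vectors (and, for stacks, band ages in
#' ka BP). This keeps all artifacts text-based and diffable.
#'
#' @param grid a `reef_grid`.
#' @param file path to the CSV to write.
#' @return `write_grid` returns `file` invisibly; `read_grid` a `reef_grid`.
#' @export
write_grid <- function(grid, file) {
  utils::write.table(grid$values, file, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(lon = grid$lon, lat = grid$lat),
                       paste0(file, ".json"), digits = NA)
  invisible(file)
}

#' @rdname write_grid
#' @param file path to a CSV written by `write_grid`.
#' @export
read_grid <- function(file) {
  meta <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(file, sep = ",", header = FALSE))
  dimnames(m) <- NULL
  reef_grid(m, lon = meta$lon, lat = meta$lat)
}
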