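# Spatial weight matrices: contiguity (W1), inverse squared great-circle
# distance (W2) and economic distance (W3 = W2 scaled by relative per-capita
# output), with row standardization and the admissible rho interval.

EARTH_RADIUS_KM <- 6371.0

new_spatial_weights <- function(w, labels, kind, row_standardized = FALSE) {
  stopifnot(is.matrix(w), nrow(w) == ncol(w), nrow(w) == length(labels))
  if (any(diag(w) != 0)) stop("weight matrix diagonal must be exactly zero")
  if (any(w < 0)) stop("weight matrix entries must be nonnegative")
  dimnames(w) <- list(labels, labels)
  structure(
    list(labels = labels, w = w, kind = kind,
         row_standardized = row_standardized,
         eigenvalues = eigen(w, only.values = TRUE)$values),
    class = "spatial_weights"
  )
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("Spatial weights: kind=%s, n=%d, row_standardized=%s\n",
              x$kind, length(x$labels), x$row_standardized))
  cat(sprintf("Nonzero links: %d, islands (all-zero rows): %d\n",
              sum(x$w != 0), sum(rowSums(x$w) == 0)))
  invisible(x)
}

#' Binary contiguity weights (W1)
#'
#' Builds the 0-1 first-order contiguity matrix: `w[i, j] = 1` when units
#' share a border, 0 otherwise. Islands (units with no neighbors) are
#' permitted and keep an all-zero row.
#'
#' @param labels Ordered unit labels.
#' @param adjacency Two-column data frame (or matrix) of unordered label
#'   pairs, one border per row.
#' @return A `spatial_weights` object of kind `"contiguity"`, unstandardized.
#' @export
build_contiguity <- function(labels, adjacency) {
  adjacency <- as.data.frame(adjacency, stringsAsFactors = FALSE)
  stopifnot(ncol(adjacency) >= 2L)
  a <- as.character(adjacency[[1L]])
  b <- as.character(adjacency[[2L]])
  if (any(a == b)) {
    stop("self-adjacency is not allowed: ",
         paste(unique(a[a == b]), collapse = ", "))
  }
  unknown <- setdiff(c(a, b), labels)
  if (length(unknown) > 0L) {
    stop("adjacency references unknown labels: ",
         paste(unknown, collapse = ", "))
  }
  n <- length(labels)
  w <- matrix(0, n, n)
  ia <- match(a, labels); ib <- match(b, labels)
  w[cbind(ia, ib)] <- 1
  w[cbind(ib, ia)] <- 1
  new_spatial_weights(w, labels, "contiguity")
}

#' Inverse-distance weights (W2)
#'
#' `w[i, j] = 1 / D[i, j]^power` with `D` the great-circle (haversine)
#' distance in kilometres between unit centroids (Earth radius 6371 km).
#' `distance = "euclidean_degrees"` instead uses the planar distance in
#' decimal degrees, the literal reading of a "longitude and latitude
#' distance".
#'
#' @param labels Ordered unit labels.
#' @param coords Data frame with columns `unit`, `lon`, `lat` (decimal
#'   degrees) covering all labels.
#' @param power Positive exponent on distance; default 2 (inverse squared
#'   distance).
#' @param distance `"haversine"` (default) or `"euclidean_degrees"`.
#' @return A `spatial_weights` object of kind `"inverse_distance"`.
#' @export
build_inverse_distance <- function(labels, coords, power = 2,
                                   distance = c("haversine",
                                                "euclidean_degrees")) {
  distance <- match.arg(distance)
  stopifnot(power > 0, is.data.frame(coords),
            all(c("unit", "lon", "lat") %in% names(coords)))
  idx <- match(labels, as.character(coords$unit))
  if (anyNA(idx)) {
    stop("coordinates missing for labels: ",
         paste(labels[is.na(idx)], collapse = ", "))
  }
  lon <- coords$lon[idx]
  lat <- coords$lat[idx]
  if (any(lat < -90 | lat > 90)) stop("latitudes must lie in [-90, 90]")
  n <- length(labels)
  if (distance == "haversine") {
    D <- geosphere::distm(cbind(lon, lat),
                          fun = function(p1, p2) {
                            geosphere::distHaversine(p1, p2,
                                                     r = EARTH_RADIUS_KM)
                          })
  } else {
    D <- as.matrix(stats::dist(cbind(lon, lat)))
  }
  off <- D[upper.tri(D)]
  if (any(off == 0)) {
    stop("coincident coordinates produce zero distances; ",
         "inverse-distance weights are undefined")
  }
  w <- 1 / D^power
  diag(w) <- 0
  new_spatial_weights(w, labels, "inverse_distance")
}

#' Economic-distance weights (W3)
#'
#' Rescales an inverse-distance matrix by relative mean per-capita output:
#' `W3 = W2 %*% diag(ybar_i / ybar)`, so the weight on neighbor `j` grows
#' with `j`'s economic size. The product as written scales *columns*; the
#' alternative row-scaling reading is available via `side = "row"`.
#'
#' @param base A `spatial_weights` of kind `"inverse_distance"`
#'   (unstandardized).
#' @param percap Strictly positive per-unit mean per-capita output, either a
#'   vector named by unit or aligned to `base$labels`.
#' @param grand_mean Scalar reference level; defaults to `mean(percap)`.
#' @param side `"column"` (the formula as written) or `"row"`.
#' @return A `spatial_weights` object of kind `"economic"` (generally
#'   asymmetric).
#' @export
build_economic <- function(base, percap, grand_mean = NULL,
                           side = c("column", "row")) {
  side <- match.arg(side)
  stopifnot(inherits(base, "spatial_weights"))
  if (base$kind != "inverse_distance") {
    stop("economic weights are built from an inverse_distance base matrix")
  }
  if (!is.null(names(percap))) {
    idx <- match(base$labels, names(percap))
    if (anyNA(idx)) {
      stop("per-capita values missing for labels: ",
           paste(base$labels[is.na(idx)], collapse = ", "))
    }
    percap <- percap[idx]
  } else if (length(percap) != length(base$labels)) {
    stop("per-capita vector not aligned with weight labels")
  }
  if (any(percap <= 0)) stop("per-capita output must be strictly positive")
  if (is.null(grand_mean)) grand_mean <- mean(percap)
  scale <- as.numeric(percap) / grand_mean
  w <- if (side == "column") {
    sweep(base$w, 2L, scale, "*")
  } else {
    sweep(base$w, 1L, scale, "*")
  }
  new_spatial_weights(w, base$labels, "economic")
}

#' Row-standardize a weight matrix
#'
#' Divides each nonzero row by its sum so rows sum to one; all-zero rows
#' (islands) pass through unchanged. Row standardization makes the spatial
#' lag a neighborhood average and bounds the autoregressive parameter's
#' admissible interval above by 1. Idempotent.
#'
#' @param weights A `spatial_weights` object.
#' @return The standardized `spatial_weights` (eigenvalues recomputed).
#' @export
row_standardize <- function(weights) {
  stopifnot(inherits(weights, "spatial_weights"))
  rs <- rowSums(weights$w)
  w <- weights$w
  nz <- rs > 0
  w[nz, ] <- w[nz, , drop = FALSE] / rs[nz]
  out <- new_spatial_weights(w, weights$labels, weights$kind,
                             row_standardized = TRUE)
  out
}

#' Admissible interval for the spatial autoregressive parameter
#'
#' Returns `(1 / omega_min, 1 / omega_max)` over the real parts of the
#' spectrum of the row-standardized matrix; `I - rho * W` is nonsingular for
#' `rho` strictly inside. For a row-stochastic matrix the upper bound is the
#' Perron root 1 (snapped exactly).
#'
#' @param weights A row-standardized `spatial_weights`.
#' @return Numeric vector `c(rho_min, rho_max)`.
#' @export
rho_interval <- function(weights) {
  stopifnot(inherits(weights, "spatial_weights"))
  if (!weights$row_standardized) {
    stop("rho_interval requires a row-standardized weight matrix")
  }
  if (all(weights$w == 0)) {
    stop("all-zero weight matrix has no admissible interval")
  }
  re <- Re(weights$eigenvalues)
  w_min <- min(re)
  w_max <- max(re)
  if (w_min >= 0 || w_max <= 0) {
    stop("degenerate spectrum; cannot form admissible interval")
  }
  hi <- 1 / w_max
  if (abs(w_max - 1) < 1e-8) hi <- 1   # Perron root of a row-stochastic matrix
  c(1 / w_min, hi)
}

#' Write a weight matrix as dense delimited text
#'
#' @param weights A `spatial_weights` object.
#' @param path Output path. Labels appear as header row and first column.
#' @return `path`, invisibly.
#' @export
write_weights <- function(weights, path) {
  df <- data.frame(unit = weights$labels,
                   as.data.frame(weights$w),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_table(df, path)
}

#' Read a dense weight matrix written by [write_weights()]
#'
#' @param path Input path.
#' @param kind Construction tag to attach.
#' @param row_standardized Is the stored matrix row-standardized?
#' @return A `spatial_weights` object.
#' @export
read_weights <- function(path, kind = "contiguity",
                         row_standardized = FALSE) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(df[[1L]])
  w <- as.matrix(df[, -1L, drop = FALSE])
  new_spatial_weights(unname(w), labels, kind,
                      row_standardized = row_standardized)
}

#' Read an edge list (`unitA,unitB` per line, no header)
#'
#' @param path Input path.
#' @return Two-column data frame of label pairs.
#' @export
read_adjacency <- function(path) {
  read.csv(path, header = FALSE, stringsAsFactors = FALSE,
           col.names = c("from", "to"))
}

#' Read unit coordinates (`unit,lon,lat` with header)
#'
#' @param path Input path.
#' @return Data frame with columns `unit`, `lon`, `lat`.
#' @export
read_coordinates <- function(path) {
  co <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("unit", "lon", "lat") %in% names(co)))
  co
}
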