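# Small fixtures built in code, shared across test files.

# Balanced toy panel on the transformed scale (GDP + the six regressors).
toy_panel <- function(n = 4L, T = 3L, seed = 1L) {
  set.seed(seed)
  units <- sprintf("U%02d", seq_len(n))
  grid <- expand.grid(unit = units, year = 2005L + seq_len(T) - 1L,
                      stringsAsFactors = FALSE)
  k <- length(sdmspill:::PANEL_REGRESSORS)
  vals <- matrix(rnorm(nrow(grid) * (k + 1L)), nrow(grid))
  colnames(vals) <- c("GDP", sdmspill:::PANEL_REGRESSORS)
  out <- cbind(grid, as.data.frame(vals))
  out$Urb <- stats::plogis(out$Urb)
  panel_dataset(out)
}

# Raw-scale delimited panel file for loader tests; returns the path.
toy_panel_file <- function(path, n = 3L, T = 2L, seed = 2L,
                           urb_scale = c("proportion", "percent")) {
  urb_scale <- match.arg(urb_scale)
  set.seed(seed)
  units <- sprintf("U%02d", seq_len(n))
  grid <- expand.grid(unit = units, year = 2005L + seq_len(T) - 1L,
                      stringsAsFactors = FALSE)
  df <- data.frame(grid,
                   gdp = exp(rnorm(nrow(grid), 9, 1)),
                   heal = exp(rnorm(nrow(grid), 5, 1)),
                   cap = exp(rnorm(nrow(grid), 8, 1)),
                   con = exp(rnorm(nrow(grid), 8, 1)),
                   exp = exp(rnorm(nrow(grid), 7, 1)),
                   hum = exp(rnorm(nrow(grid), 13, 0.5)),
                   urb = runif(nrow(grid), 0.3, 0.9))
  if (urb_scale == "percent") df$urb <- df$urb * 100
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# Random valid spatial weights (row-standardized) on n units.
random_weights <- function(n, seed, p_edge = 0.5) {
  set.seed(seed)
  labels <- sprintf("U%02d", seq_len(n))
  w <- matrix(runif(n * n) < p_edge, n, n) * matrix(runif(n * n), n, n)
  w <- (w + t(w)) / 2          # symmetric nonneg
  diag(w) <- 0
  if (any(rowSums(w) == 0)) w[1, 2] <- w[2, 1] <- 0.5
  row_standardize(sdmspill:::new_spatial_weights(w, labels, "contiguity"))
}

# Independent double-loop Moran's I oracle, straight from the definition.
moran_bruteforce <- function(y, w) {
  n <- length(y)
  ybar <- mean(y)
  num <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- num + w[i, j] * (y[i] - ybar) * (y[j] - ybar)
    }
  }
  s2 <- mean((y - ybar)^2)
  num / (s2 * sum(w))
}

# Independent haversine distance (km), hand-coded from the formula.
haversine_km <- function(lon1, lat1, lon2, lat2, R = 6371.0) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * R * asin(sqrt(pmin(1, a)))
}

# Contiguity weights for a small standardized graph given an edge matrix.
contiguity_std <- function(labels, edges) {
  row_standardize(build_contiguity(labels, edges))
}
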