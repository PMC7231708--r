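# Global Moran's I with randomization-moment and permutation inference.

# Raw statistic: I = sum_ij w_ij (y_i - ybar)(y_j - ybar) / (S2 * sum_ij w_ij)
# with S2 = mean((y - ybar)^2). Equivalent to the familiar (n/S0) form.
moran_stat <- function(yd, w, S0) {
  n <- length(yd)
  n * drop(crossprod(yd, w %*% yd)) / (drop(crossprod(yd)) * S0)
}

#' Global Moran's I for one cross-section
#'
#' Computes Moran's I of `y` under the supplied weights (used as provided,
#' standardized or not) with inference under either the randomization null
#' (analytic permutation moments, normal approximation) or a seeded
#' permutation null. The upper tail is the default alternative: the screening
#' question is whether similar values cluster in space.
#'
#' @param y Numeric vector of length `n >= 3`, aligned with `weights`.
#' @param weights A `spatial_weights` object.
#' @param null_kind `"randomization"` (default) or `"permutation"`.
#' @param variance For the randomization null, which analytic variance to
#'   use: `"randomization"` (permutation moments, default) or `"normality"`.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @param n_permutations Number of permutations for the permutation null.
#' @param seed Integer seed; mandatory for the permutation null.
#' @return An object of class `moran_result` with fields `I`, `expected`,
#'   `variance`, `z`, `p`, `null_kind`, `n_permutations`.
#' @export
morans_i <- function(y, weights, null_kind = c("randomization", "permutation"),
                     variance = c("randomization", "normality"),
                     alternative = c("greater", "two.sided"),
                     n_permutations = 9999L, seed = NULL) {
  null_kind <- match.arg(null_kind)
  variance <- match.arg(variance)
  alternative <- match.arg(alternative)
  stopifnot(inherits(weights, "spatial_weights"))
  w <- weights$w
  n <- length(y)
  if (n < 3L) stop("Moran's I requires n >= 3")
  if (n != nrow(w)) stop("y is not aligned with the weight matrix")
  S0 <- sum(w)
  if (S0 == 0) stop("all-zero weight matrix; Moran's I undefined")
  yd <- y - mean(y)
  m2 <- drop(crossprod(yd))
  if (m2 == 0) stop("y is constant; Moran's I has degenerate variance")

  I_obs <- moran_stat(yd, w, S0)
  EI <- -1 / (n - 1)

  if (null_kind == "randomization") {
    S1 <- sum((w + t(w))^2) / 2
    S2 <- sum((rowSums(w) + colSums(w))^2)
    if (variance == "randomization") {
      b2 <- n * sum(yd^4) / m2^2
      VI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
               b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
        ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
    } else {
      VI <- (n^2 * S1 - n * S2 + 3 * S0^2) / (S0^2 * (n^2 - 1)) - EI^2
    }
    z <- (I_obs - EI) / sqrt(VI)
    p <- if (alternative == "greater") {
      pnorm(z, lower.tail = FALSE)
    } else {
      2 * pnorm(-abs(z))
    }
    nperm <- NA_integer_
  } else {
    if (is.null(seed)) stop("a seed is required for the permutation null")
    set.seed(as.integer(seed))
    nperm <- as.integer(n_permutations)
    sims <- vapply(seq_len(nperm),
                   function(i) moran_stat(yd[sample.int(n)], w, S0),
                   numeric(1L))
    VI <- var(sims)
    z <- (I_obs - mean(sims)) / sqrt(VI)
    p_up <- (1 + sum(sims >= I_obs)) / (1 + nperm)
    p <- if (alternative == "greater") {
      p_up
    } else {
      p_lo <- (1 + sum(sims <= I_obs)) / (1 + nperm)
      min(1, 2 * min(p_up, p_lo))
    }
  }
  structure(list(I = I_obs, expected = EI, variance = VI, z = z, p = p,
                 null_kind = null_kind, n_permutations = nperm,
                 alternative = alternative, n = n),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (E[I] = %.4f, Var = %.5f)\n",
              x$I, x$expected, x$variance))
  cat(sprintf("z = %.3f, p = %.4g  [%s null, %s]\n", x$z, x$p,
              x$null_kind, x$alternative))
  invisible(x)
}

#' Yearly Moran's I across a panel
#'
#' Applies [morans_i()] to the outcome cross-section of every period,
#' mirroring the yearly autocorrelation screening table.
#'
#' @param panel A `panel_dataset` whose units match `weights`.
#' @param weights A `spatial_weights` object.
#' @param ... Passed to [morans_i()] (null kind, alternative, permutations).
#' @param seed Base seed; period `t` uses `seed + t - 1` so rows are
#'   independently reproducible.
#' @return Data frame with columns `year`, `I`, `expected`, `variance`, `z`,
#'   `p`, ordered by year.
#' @export
moran_by_year <- function(panel, weights, ..., seed = NULL) {
  stopifnot(inherits(panel, "panel_dataset"))
  if (!identical(panel$units, weights$labels)) {
    stop("panel units and weight labels are not aligned")
  }
  rows <- lapply(seq_along(panel$periods), function(t) {
    yr <- panel$periods[t]
    d <- panel$data[panel$data$year == yr, , drop = FALSE]
    y <- d[[panel$outcome]][match(panel$units, d$unit)]
    s <- if (is.null(seed)) NULL else as.integer(seed) + t - 1L
    m <- morans_i(y, weights, ..., seed = s)
    data.frame(year = yr, I = m$I, expected = m$expected,
               variance = m$variance, z = m$z, p = m$p)
  })
  do.call(rbind, rows)
}
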