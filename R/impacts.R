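# Direct / indirect / total effect decomposition by partial derivatives.
#
# The reduced form y = (I - rho W)^{-1} (X beta + W X lambda + ...) gives,
# for regressor s, the n x n derivative matrix
#   K_s(W) = M(W) (I beta_s + W lambda_s),  M(W) = (I - rho W)^{-1}.
# The direct effect is the average diagonal of K_s, the indirect (spillover)
# effect the average off-diagonal row sum, and the total their sum. For a
# row-standardized W the total collapses to (beta_s + lambda_s) / (1 - rho).

#' Spatial multiplier matrix
#'
#' `M(W) = (I - rho W)^{-1}`, the Neumann series
#' `I + rho W + rho^2 W^2 + ...` summed exactly.
#'
#' @param weights A `spatial_weights` object.
#' @param rho Scalar strictly inside the admissible interval.
#' @return Dense `n x n` matrix.
#' @export
multiplier_matrix <- function(weights, rho) {
  stopifnot(inherits(weights, "spatial_weights"))
  int <- rho_interval(weights)
  if (rho <= int[1L] || rho >= int[2L]) {
    stop(sprintf("rho = %g at or beyond the admissible interval (%g, %g)",
                 rho, int[1L], int[2L]))
  }
  n <- nrow(weights$w)
  solve(diag(n) - rho * weights$w)
}

#' Per-regressor derivative matrix K_s(W)
#'
#' `K_s(W) = M(W) (I beta_s + W lambda_s)`: entry `(i, j)` is the derivative
#' of unit `i`'s outcome with respect to unit `j`'s regressor `s`.
#'
#' @inheritParams multiplier_matrix
#' @param beta_s Coefficient on the regressor itself.
#' @param lambda_s Coefficient on its spatial lag.
#' @return Dense `n x n` matrix.
#' @export
impact_matrix <- function(weights, rho, beta_s, lambda_s) {
  M <- multiplier_matrix(weights, rho)
  beta_s * M + lambda_s * (M %*% weights$w)
}

#' Point decomposition into direct, indirect and total effects
#'
#' Averages `K_s(W)` over units: direct = mean diagonal, indirect = mean
#' off-diagonal row sum, total = direct + indirect (exact by construction).
#'
#' @param fit An `sdm_fit` (or any list with `rho`, `beta`, `lambda`).
#' @param weights The `spatial_weights` used in the fit.
#' @return Data frame of class `impact_result` with one row per regressor
#'   and columns `regressor`, `direct`, `indirect`, `total`.
#' @export
decompose_effects <- function(fit, weights) {
  if (inherits(fit, "sdm_fit") && !fit$converged) {
    stop("fit did not converge; refusing to decompose")
  }
  decompose_at(weights, fit$rho, fit$beta, fit$lambda)
}

# Core decomposition at explicit parameter values; lambda entries may be
# missing for regressors whose lag was dropped (treated as zero).
decompose_at <- function(weights, rho, beta, lambda) {
  M <- multiplier_matrix(weights, rho)
  MW <- M %*% weights$w
  regs <- names(beta)
  lam <- setNames(rep(0, length(regs)), regs)
  lam[sub("^W\\.", "", names(lambda))] <- lambda
  rows <- lapply(regs, function(s) {
    K <- beta[[s]] * M + lam[[s]] * MW
    direct <- mean(diag(K))
    indirect <- mean(rowSums(K) - diag(K))
    data.frame(regressor = s, direct = direct, indirect = indirect,
               total = direct + indirect, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("impact_result", "data.frame")
  out
}

#' Monte-Carlo inference for the effect decomposition
#'
#' Simulates `(beta, lambda, rho)` from a multivariate normal centred at the
#' estimates with covariance `fit$vcov`, rejects draws with `rho` outside
#' the admissible interval, recomputes the decomposition per retained draw,
#' and summarizes dispersion (`*_sd`), standardized effects (`*_z` =
#' point / sd) and two-sided normal p-values.
#'
#' @param fit A converged `sdm_fit` with a positive-semidefinite `vcov`.
#' @param weights The `spatial_weights` used in the fit.
#' @param draws Number of Monte-Carlo draws (default 1000, minimum 100).
#' @param seed Integer seed (mandatory: results are bitwise reproducible).
#' @return An `impact_result` data frame with columns
#'   `direct/indirect/total` plus `_sd`, `_z`, `_p` for each; attributes
#'   `draws_used`, `rejection_rate`, `seed`.
#' @export
impact_inference <- function(fit, weights, draws = 1000L, seed) {
  stopifnot(inherits(fit, "sdm_fit"))
  if (draws < 100L) stop("at least 100 draws are required")
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  nm <- c(names(fit$beta), names(fit$lambda), "rho")
  V <- fit$vcov[nm, nm, drop = FALSE]
  if (!psd_check(V)) {
    stop("fit$vcov is not positive semidefinite; inference unavailable")
  }
  mu <- c(fit$beta, fit$lambda, rho = fit$rho)
  int <- rho_interval(weights)
  set.seed(as.integer(seed))
  sims <- MASS::mvrnorm(draws, mu = mu, Sigma = (V + t(V)) / 2)
  ok <- sims[, "rho"] > int[1L] & sims[, "rho"] < int[2L]
  if (mean(ok) < 0.5) {
    warning(sprintf("%.0f%% of rho draws fell outside the admissible %s",
                    100 * mean(!ok), "interval; inference may be unstable"))
  }
  sims <- sims[ok, , drop = FALSE]
  point <- decompose_at(weights, fit$rho, fit$beta, fit$lambda)
  regs <- point$regressor
  arr <- array(NA_real_, c(nrow(sims), length(regs), 3L),
               dimnames = list(NULL, regs, c("direct", "indirect", "total")))
  bn <- names(fit$beta); ln <- names(fit$lambda)
  for (r in seq_len(nrow(sims))) {
    dec <- decompose_at(weights, sims[r, "rho"], sims[r, bn], sims[r, ln])
    arr[r, , ] <- as.matrix(dec[, c("direct", "indirect", "total")])
  }
  for (comp in c("direct", "indirect", "total")) {
    sdv <- apply(arr[, , comp, drop = FALSE], 2L, sd)
    zv <- point[[comp]] / sdv
    point[[paste0(comp, "_sd")]] <- sdv
    point[[paste0(comp, "_z")]] <- zv
    point[[paste0(comp, "_p")]] <- 2 * pnorm(-abs(zv))
  }
  attr(point, "draws_used") <- nrow(sims)
  attr(point, "rejection_rate") <- mean(!ok)
  attr(point, "seed") <- as.integer(seed)
  point
}
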