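# Maximum-likelihood spatial Durbin panel models.
#
# Model: y_t = rho * W y_t + X_t beta + (W X_t) lambda + effects + eps_t.
# Fixed effects are absorbed by the within transformation; random effects use
# the quasi-demeaning weight theta in (0, 1] (theta = 1 is the pooled model,
# theta -> 0 approaches the within estimator). In both cases beta, lambda and
# sigma^2 concentrate out analytically, leaving a low-dimensional profile
# likelihood with the Jacobian term T * log|det(I - rho W)| evaluated through
# the eigenvalues of W.

#' Model specification for the spatial Durbin panel estimators
#'
#' @param outcome Outcome variable name.
#' @param regressors Regressor names, order fixed; each enters both directly
#'   and through its spatial lag.
#' @param effects `"fixed"`, `"random"` or `"pooled"`.
#' @param time_effects Also include period effects (two-way within
#'   transformation)? Default `FALSE`: the selected specification uses
#'   individual effects only.
#' @return An object of class `sdm_spec`.
#' @export
sdm_spec <- function(outcome = PANEL_OUTCOME, regressors = PANEL_REGRESSORS,
                     effects = c("fixed", "random", "pooled"),
                     time_effects = FALSE) {
  effects <- match.arg(effects)
  if (length(regressors) == 0L) stop("at least one regressor is required")
  structure(list(outcome = outcome, regressors = regressors,
                 effects = effects, time_effects = time_effects),
            class = "sdm_spec")
}

#' Spatial lag of a vector or matrix
#'
#' Returns `W %*% values`; for a panel laid out as an `n x T` matrix this
#' applies the lag period by period.
#'
#' @param weights A `spatial_weights` object.
#' @param values Numeric vector of length `n` or matrix with `n` rows.
#' @return The lagged vector/matrix.
#' @export
spatial_lag <- function(weights, values) {
  stopifnot(inherits(weights, "spatial_weights"))
  v <- as.matrix(values)
  if (nrow(v) != nrow(weights$w)) {
    stop("values are not aligned with the weight matrix (",
         nrow(v), " rows vs n = ", nrow(weights$w), ")")
  }
  out <- weights$w %*% v
  if (is.vector(values)) drop(out) else out
}

# Lay the panel out as n x T matrices in the frozen unit order, with spatial
# lags of the outcome and every regressor.
panel_arrays <- function(panel, spec, weights) {
  if (!identical(panel$units, weights$labels)) {
    stop("panel units and weight labels are not aligned")
  }
  n <- n_units(panel)
  Tn <- n_periods(panel)
  d <- panel$data  # sorted by (year, unit in frozen order)
  Y <- matrix(d[[spec$outcome]], n, Tn)
  X <- lapply(spec$regressors, function(v) matrix(d[[v]], n, Tn))
  names(X) <- spec$regressors
  WY <- weights$w %*% Y
  WX <- lapply(X, function(m) weights$w %*% m)
  list(n = n, Tn = Tn, Y = Y, X = X, WY = WY, WX = WX)
}

demean_mat <- function(M, time_effects = FALSE) {
  M <- M - rowMeans(M)
  if (time_effects) M <- sweep(M, 2L, colMeans(M))
  M
}

# Stack n x T matrices into the nT design: [X, WX], dropping columns with
# (numerically) zero variance after the transformation.
build_design <- function(arr, transform = identity, drop_tol = 1e-10) {
  Zc <- c(lapply(arr$X, transform), lapply(arr$WX, transform))
  names(Zc) <- c(names(arr$X), paste0("W.", names(arr$X)))
  Z <- vapply(Zc, as.vector, numeric(arr$n * arr$Tn))
  keep <- apply(Z, 2L, function(x) sd(x) > drop_tol)
  if (!all(keep)) {
    warning("dropping degenerate regressor(s) with no within variation: ",
            paste(colnames(Z)[!keep], collapse = ", "))
    Z <- Z[, keep, drop = FALSE]
  }
  Z
}

#' Log-determinant term of the spatial likelihood
#'
#' `log|det(I - rho W)| = sum_k Re(log(1 - rho * omega_k))` over the
#' (possibly complex) eigenvalues of `W`; imaginary parts cancel for real
#' matrices.
#'
#' @param rho Scalar, strictly inside the admissible interval implied by the
#'   eigenvalues.
#' @param eigenvalues Eigenvalues of the weight matrix.
#' @return Real scalar.
#' @export
log_det_term <- function(rho, eigenvalues) {
  re <- Re(eigenvalues)
  lo <- 1 / min(re)
  hi <- 1 / max(re)
  if (rho <= lo || rho >= hi) {
    stop(sprintf("rho = %g is outside the admissible interval (%g, %g)",
                 rho, lo, hi))
  }
  sum(Re(log(1 - rho * eigenvalues)))
}

#' Concentrated (profile) log-likelihood in rho
#'
#' For fixed `rho`, regresses `y - rho * Wy` on the design `Z`, plugs the
#' implied `sigma^2(rho)` back in, and adds the Jacobian term
#' `T * log|det(I - rho W)|`:
#' `L(rho) = -(nT/2) log(2 pi sigma^2(rho)) + T log|det(I - rho W)| - nT/2`.
#'
#' @param rho Scalar inside the admissible interval.
#' @param y Stacked (transformed) outcome, length `nT`, period-major.
#' @param Z Stacked design matrix (`nT x 2k`).
#' @param wy Stacked spatial lag of the outcome.
#' @param weights The `spatial_weights` used (supplies `n` and the spectrum).
#' @return The profile log-likelihood value.
#' @export
concentrated_loglik <- function(rho, y, Z, wy, weights) {
  n <- length(weights$labels)
  Tn <- length(y) / n
  if (Tn != round(Tn)) stop("length(y) is not a multiple of n")
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) stop("singular design matrix")
  e0 <- qr.resid(qz, y)
  e1 <- qr.resid(qz, wy)
  e <- e0 - rho * e1
  s2 <- sum(e^2) / (n * Tn)
  -(n * Tn / 2) * log(2 * pi * s2) + Tn * log_det_term(rho, weights$eigenvalues) -
    n * Tn / 2
}

# Central-difference Hessian; relative step per coordinate.
num_hessian <- function(f, x, rel_step = 1e-5) {
  p <- length(x)
  h <- rel_step * pmax(1, abs(x))
  H <- matrix(0, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    for (j in i:p) {
      if (i == j) {
        xp <- x; xp[i] <- x[i] + h[i]
        xm <- x; xm[i] <- x[i] - h[i]
        H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / h[i]^2
      } else {
        xpp <- x; xpp[i] <- x[i] + h[i]; xpp[j] <- x[j] + h[j]
        xpm <- x; xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
        xmp <- x; xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
        xmm <- x; xmm[i] <- x[i] - h[i]; xmm[j] <- x[j] - h[j]
        H[i, j] <- H[j, i] <-
          (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

psd_check <- function(V, tol = 1e-7) {
  ev <- eigen((V + t(V)) / 2, symmetric = TRUE, only.values = TRUE)$values
  all(ev > -tol * max(abs(ev), 1e-300))
}

# Expected-information vcov of (delta, rho) for the within/pooled spatial
# likelihood, evaluated at the optimum. G = W (I - rho W)^{-1}.
sdm_info_vcov <- function(w, rho, sigma2, Z, delta, n, Tn) {
  A <- diag(n) - rho * w
  G <- w %*% solve(A)
  mu <- matrix(as.vector(Z %*% delta), n, Tn)
  Gmu <- as.vector(G %*% mu)
  k2 <- ncol(Z)
  Idd <- crossprod(Z) / sigma2
  Idr <- crossprod(Z, Gmu) / sigma2
  Irr <- Tn * (sum(G * t(G)) + sum(G * G)) + sum(Gmu^2) / sigma2
  Irs <- Tn * sum(diag(G)) / sigma2
  Iss <- n * Tn / (2 * sigma2^2)
  info <- rbind(cbind(Idd, Idr, rep(0, k2)),
                c(Idr, Irr, Irs),
                c(rep(0, k2), Irs, Iss))
  V <- solve(info)
  V[seq_len(k2 + 1L), seq_len(k2 + 1L), drop = FALSE]
}

new_sdm_fit <- function(effects, coef, rho, sigma2, loglik, vcov, r2, n, Tn,
                        regressors, rho_int, boundary, theta = NA_real_,
                        sigma2_mu = NA_real_, converged = TRUE,
                        weights_kind = NA_character_) {
  nm <- c(names(coef), "rho")
  dimnames(vcov) <- list(nm, nm)
  est <- c(coef, rho = rho)
  se <- sqrt(pmax(diag(vcov), 0))
  z <- est / se
  p <- 2 * pnorm(-abs(z))
  is_reg <- names(coef) %in% regressors
  structure(
    list(effects = effects, coefficients = coef,
         beta = coef[is_reg],
         lambda = coef[names(coef) %in% paste0("W.", regressors)],
         rho = rho, sigma2 = sigma2, theta = theta, sigma2_mu = sigma2_mu,
         loglik = loglik, vcov = vcov, se = se, zval = z, pval = p,
         r2 = r2, n = n, T = Tn, converged = converged,
         rho_interval = rho_int, boundary = boundary,
         regressors = regressors, weights_kind = weights_kind),
    class = "sdm_fit"
  )
}

#' Significance stars at the 1% / 5% / 10% levels
#'
#' @param p Vector of p-values.
#' @param levels Strictly increasing significance thresholds.
#' @return Character vector of `"***"`, `"**"`, `"*"` or `""`.
#' @export
significance_stars <- function(p, levels = c(0.01, 0.05, 0.10)) {
  stopifnot(all(diff(levels) > 0))
  out <- rep("", length(p))
  out[p < levels[3L]] <- "*"
  out[p < levels[2L]] <- "**"
  out[p < levels[1L]] <- "***"
  out
}

#' Coefficient table of a spatial Durbin fit
#'
#' @param fit An `sdm_fit`.
#' @param levels Significance thresholds for the stars.
#' @return Data frame with columns `term`, `estimate`, `se`, `z`, `p`,
#'   `stars` (spatial-lag terms prefixed `W.`, `rho` last).
#' @export
coef_table <- function(fit, levels = c(0.01, 0.05, 0.10)) {
  est <- c(fit$coefficients, rho = fit$rho)
  data.frame(term = names(est), estimate = unname(est),
             se = unname(fit$se), z = unname(fit$zval), p = unname(fit$pval),
             stars = significance_stars(fit$pval, levels),
             stringsAsFactors = FALSE)
}

#' @export
print.sdm_fit <- function(x, ...) {
  cat(sprintf("Spatial Durbin model (%s effects), n = %d, T = %d\n",
              x$effects, x$n, x$T))
  print(coef_table(x), digits = 4, row.names = FALSE)
  cat(sprintf("sigma2 = %.5f", x$sigma2))
  if (!is.na(x$theta)) cat(sprintf(", theta = %.4f", x$theta))
  cat(sprintf("\nlog-likelihood = %.3f, pseudo-R2 = %.4f\n", x$loglik, x$r2))
  if (x$boundary) cat("NOTE: estimate at/near a parameter boundary\n")
  invisible(x)
}

#' @export
coef.sdm_fit <- function(object, ...) c(object$coefficients, rho = object$rho)

#' @export
logLik.sdm_fit <- function(object, ...) object$loglik

#' @export
vcov.sdm_fit <- function(object, ...) object$vcov

# Fitted values on the original scale (effects recovered from the residual
# unit/period means) and the squared-correlation pseudo-R2.
pseudo_r2 <- function(arr, Zo, keep, delta, rho, time_effects) {
  yo <- as.vector(arr$Y)
  wyo <- as.vector(arr$WY)
  resid <- matrix(yo - rho * wyo - as.vector(Zo[, keep, drop = FALSE] %*% delta),
                  arr$n, arr$Tn)
  eff <- matrix(rowMeans(resid), arr$n, arr$Tn)
  if (time_effects) {
    eff <- eff + rep(colMeans(resid), each = arr$n) - mean(resid)
  }
  fitted <- rho * wyo + as.vector(Zo[, keep, drop = FALSE] %*% delta) +
    as.vector(eff)
  cor(yo, fitted)^2
}

#' Fit the spatial Durbin model with individual fixed effects
#'
#' Within-transforms the data, maximizes the concentrated log-likelihood over
#' `rho` by bounded scalar search on the admissible interval (tolerance
#' 1e-8), recovers `beta`/`lambda` by generalized least squares at the
#' optimum, and computes standard errors from the analytic information
#' matrix (numerical-Hessian fallback if ill-conditioned).
#'
#' @param panel A `panel_dataset`.
#' @param spec An [sdm_spec()] (effects must be `"fixed"`).
#' @param weights A row-standardized `spatial_weights` aligned to the panel.
#' @param rho_fixed Optional: skip the search and evaluate at this `rho`
#'   (e.g. `0` reduces the estimator to within-OLS on `[X, WX]`).
#' @return An `sdm_fit`.
#' @export
fit_sdm_fe <- function(panel, spec = sdm_spec(), weights, rho_fixed = NULL) {
  stopifnot(inherits(panel, "panel_dataset"), inherits(spec, "sdm_spec"))
  if (!weights$row_standardized) {
    stop("weights must be row-standardized before fitting")
  }
  arr <- panel_arrays(panel, spec, weights)
  n <- arr$n; Tn <- arr$Tn
  Zo <- build_design(arr, transform = identity, drop_tol = -1)  # keep all
  Z <- build_design(arr,
                    transform = function(m) demean_mat(m, spec$time_effects))
  keep <- match(colnames(Z), colnames(Zo))
  y <- as.vector(demean_mat(arr$Y, spec$time_effects))
  wy <- as.vector(demean_mat(arr$WY, spec$time_effects))

  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    stop("collinear regressors after the within transformation")
  }
  e0 <- qr.resid(qz, y); d0 <- qr.coef(qz, y)
  e1 <- qr.resid(qz, wy); d1 <- qr.coef(qz, wy)
  ev <- weights$eigenvalues
  int <- rho_interval(weights)
  lo <- int[1L] + 1e-6; hi <- int[2L] - 1e-6
  cll <- function(rho) {
    s2 <- sum((e0 - rho * e1)^2) / (n * Tn)
    -(n * Tn / 2) * log(2 * pi * s2) + Tn * log_det_term(rho, ev) - n * Tn / 2
  }
  if (is.null(rho_fixed)) {
    opt <- optimize(cll, c(lo, hi), maximum = TRUE, tol = 1e-8)
    rho <- opt$maximum
    loglik <- opt$objective
  } else {
    if (rho_fixed <= int[1L] || rho_fixed >= int[2L]) {
      stop("rho_fixed outside the admissible interval")
    }
    rho <- rho_fixed
    loglik <- cll(rho)
  }
  boundary <- is.null(rho_fixed) && (rho - lo < 1e-6 || hi - rho < 1e-6)

  delta <- d0 - rho * d1
  e <- e0 - rho * e1
  sigma2 <- sum(e^2) / (n * Tn)
  # ML sigma2 enters the likelihood; the information matrix for standard
  # errors is evaluated at the degrees-of-freedom-consistent variance (the
  # within transformation removes n unit means, plus T-1 period means when
  # time effects are on), else FE standard errors shrink by ~(T-1)/T and the
  # FE/RE variance comparison degenerates.
  df_lost <- n + ncol(Z) + if (spec$time_effects) Tn - 1L else 0L
  sigma2_se <- sum(e^2) / (n * Tn - df_lost)

  V <- tryCatch(
    sdm_info_vcov(weights$w, rho, sigma2_se, Z, delta, n, Tn),
    error = function(e) NULL
  )
  if (is.null(V) || any(!is.finite(diag(V))) || any(diag(V) <= 0)) {
    prof <- function(par) {
      d <- par[seq_len(ncol(Z))]; r <- par[ncol(Z) + 1L]
      res <- (y - r * wy) - as.vector(Z %*% d)
      s2 <- sum(res^2) / (n * Tn)
      -(n * Tn / 2) * log(2 * pi * s2) - n * Tn / 2 +
        Tn * log_det_term(r, ev)
    }
    H <- num_hessian(prof, c(delta, rho))
    V <- solve(-H)
  }
  if (!psd_check(V)) warning("variance matrix is not positive semidefinite")

  r2 <- pseudo_r2(arr, Zo, keep, delta, rho, spec$time_effects)
  names(delta) <- colnames(Z)
  new_sdm_fit("fixed", delta, rho, sigma2, loglik, V, r2, n, Tn,
              spec$regressors, int, boundary,
              weights_kind = weights$kind)
}

#' Fit the spatial Durbin model with individual random effects
#'
#' Error-components ML: the unit effect is a random draw with variance
#' `sigma2_mu`, handled by quasi-demeaning with weight
#' `theta = sqrt(sigma2 / (sigma2 + T * sigma2_mu))` in `(0, 1]`; `theta = 1`
#' collapses to the pooled spatial model and small `theta` approaches the
#' within estimator. `rho` and `theta` are maximized jointly (L-BFGS-B) with
#' `beta`, `lambda`, `sigma^2` concentrated out; standard errors come from a
#' central-difference Hessian of the profile likelihood.
#'
#' @inheritParams fit_sdm_fe
#' @return An `sdm_fit` with `theta` and the implied `sigma2_mu`.
#' @export
fit_sdm_re <- function(panel, spec = sdm_spec(effects = "random"), weights) {
  stopifnot(inherits(panel, "panel_dataset"), inherits(spec, "sdm_spec"))
  if (!weights$row_standardized) {
    stop("weights must be row-standardized before fitting")
  }
  arr <- panel_arrays(panel, spec, weights)
  n <- arr$n; Tn <- arr$Tn
  Z <- build_design(arr, transform = identity)
  Z <- cbind("(Intercept)" = 1, Z)
  y <- as.vector(arr$Y)
  wy <- as.vector(arr$WY)
  ev <- weights$eigenvalues
  int <- rho_interval(weights)
  lo <- int[1L] + 1e-6; hi <- int[2L] - 1e-6

  idx <- rep(seq_len(n), Tn)
  ybar <- tapply(y, idx, mean)[idx]
  wybar <- tapply(wy, idx, mean)[idx]
  Zbar <- apply(Z, 2L, function(col) tapply(col, idx, mean)[idx])

  qd_fit <- function(rho, theta) {
    a <- 1 - theta
    Zt <- Z - a * Zbar
    yt <- (y - a * ybar) - rho * (wy - a * wybar)
    fit <- lm.fit(Zt, yt)
    s2 <- sum(fit$residuals^2) / (n * Tn)
    list(delta = fit$coefficients, s2 = s2)
  }
  obj <- function(par) {
    f <- qd_fit(par[1L], par[2L])
    -(n * Tn / 2) * log(2 * pi * f$s2) - n * Tn / 2 +
      (n / 2) * log(par[2L]^2) + Tn * log_det_term(par[1L], ev)
  }
  opt <- optim(c(min(max(0.2, lo + 0.05), hi - 0.05), 0.5), obj,
               method = "L-BFGS-B",
               lower = c(lo, 1e-4), upper = c(hi, 1),
               control = list(fnscale = -1, maxit = 500L))
  rho <- opt$par[1L]; theta <- opt$par[2L]
  converged <- opt$convergence == 0L
  if (!converged) {
    warning("random-effects optimizer did not converge: ", opt$message)
  }
  f <- qd_fit(rho, theta)
  delta <- f$delta; sigma2 <- f$s2
  sigma2_mu <- sigma2 * (1 / theta^2 - 1) / Tn
  loglik <- opt$value
  boundary <- theta > 1 - 1e-5 || rho - lo < 1e-6 || hi - rho < 1e-6

  k2 <- ncol(Z)
  prof <- function(par) {
    d <- par[seq_len(k2)]; r <- par[k2 + 1L]
    th <- if (length(par) > k2 + 1L) par[k2 + 2L] else 1
    a <- 1 - th
    res <- (y - a * ybar) - r * (wy - a * wybar) -
      as.vector((Z - a * Zbar) %*% d)
    s2 <- sum(res^2) / (n * Tn)
    -(n * Tn / 2) * log(2 * pi * s2) - n * Tn / 2 + (n / 2) * log(th^2) +
      Tn * log_det_term(r, ev)
  }
  par_hat <- if (theta > 1 - 1e-5) c(delta, rho) else c(delta, rho, theta)
  H <- num_hessian(prof, par_hat)
  V <- tryCatch(solve(-H), error = function(e) MASS::ginv(-H))
  V <- V[seq_len(k2 + 1L), seq_len(k2 + 1L), drop = FALSE]
  if (!psd_check(V)) warning("variance matrix is not positive semidefinite")

  yo <- y
  fitted <- rho * wy + as.vector(Z %*% delta)
  # posterior unit effect: shrink unit-mean residuals toward zero
  rmat <- matrix(yo - fitted, n, Tn)
  shrink <- (Tn * sigma2_mu) / (Tn * sigma2_mu + sigma2)
  fitted <- fitted + as.vector(matrix(shrink * rowMeans(rmat), n, Tn))
  r2 <- cor(yo, fitted)^2

  names(delta) <- colnames(Z)
  new_sdm_fit("random", delta, rho, sigma2, loglik, V, r2, n, Tn,
              spec$regressors, int, boundary, theta = theta,
              sigma2_mu = sigma2_mu, converged = converged,
              weights_kind = weights$kind)
}

#' Non-spatial within-OLS baseline
#'
#' The fixed-effects panel regression of the outcome on the regressors with
#' no spatial terms: within-demeaned least squares with conventional
#' standard errors (`df = nT - n - k`).
#'
#' @inheritParams fit_sdm_fe
#' @param weights Ignored; present so the call signature matches the spatial
#'   fitters.
#' @return Data frame with columns `term`, `estimate`, `se`, `statistic`,
#'   `p`.
#' @export
fit_baseline_within <- function(panel, spec = sdm_spec(), weights = NULL) {
  stopifnot(inherits(panel, "panel_dataset"))
  n <- n_units(panel); Tn <- n_periods(panel)
  d <- panel$data
  Xm <- lapply(spec$regressors, function(v) {
    demean_mat(matrix(d[[v]], n, Tn), spec$time_effects)
  })
  Xd <- vapply(Xm, as.vector, numeric(n * Tn))
  colnames(Xd) <- spec$regressors
  sds <- apply(Xd, 2L, sd)
  if (any(sds <= 1e-10)) {
    stop("within transformation annihilates time-invariant regressor(s): ",
         paste(spec$regressors[sds <= 1e-10], collapse = ", "))
  }
  y <- as.vector(demean_mat(matrix(d[[spec$outcome]], n, Tn),
                            spec$time_effects))
  fit <- lm.fit(Xd, y)
  if (fit$rank < ncol(Xd)) stop("collinear regressors after demeaning")
  df <- n * Tn - n - ncol(Xd) - if (spec$time_effects) Tn - 1L else 0L
  s2 <- sum(fit$residuals^2) / df
  V <- chol2inv(qr.R(fit$qr)) * s2
  se <- sqrt(diag(V))
  stat <- fit$coefficients / se
  data.frame(term = spec$regressors, estimate = unname(fit$coefficients),
             se = se, statistic = stat,
             p = 2 * stats::pt(-abs(stat), df),
             stringsAsFactors = FALSE)
}

#' Hausman comparison of fixed- and random-effects SDM fits
#'
#' `H = d' [V_FE - V_RE]^{-1} d` over the shared `beta` and `lambda` blocks
#' (`rho` and the RE intercept excluded), `df = 2k`, compared with a
#' chi-squared distribution. When the variance difference is not positive
#' definite the statistic is reported as computed (possibly negative) with
#' `valid = FALSE` and no p-value — never silently repaired.
#'
#' @param fe,re `sdm_fit` objects from the same data and weights.
#' @return An object of class `hausman_result` with `statistic`, `df`, `p`,
#'   `valid`.
#' @export
hausman_test <- function(fe, re) {
  stopifnot(inherits(fe, "sdm_fit"), inherits(re, "sdm_fit"))
  nm <- intersect(names(fe$coefficients), names(re$coefficients))
  nm <- setdiff(nm, "(Intercept)")
  if (length(nm) == 0L) stop("fits share no comparable coefficients")
  if (fe$n != re$n || fe$T != re$T) {
    stop("fits come from different panels; comparison undefined")
  }
  d <- fe$coefficients[nm] - re$coefficients[nm]
  Vd <- fe$vcov[nm, nm, drop = FALSE] - re$vcov[nm, nm, drop = FALSE]
  Vd <- (Vd + t(Vd)) / 2
  if (all(abs(d) < 1e-12)) {
    return(structure(list(statistic = 0, df = length(nm), p = 1,
                          valid = TRUE), class = "hausman_result"))
  }
  ev <- eigen(Vd, symmetric = TRUE, only.values = TRUE)$values
  # positive definite up to numerical noise: eigenvalues that are tiny
  # relative to the dominant one are treated as zeros, and the statistic is
  # then formed with a pseudo-inverse that drops them
  valid <- max(ev) > 0 && min(ev) > -1e-3 * max(ev)
  stat <- if (all(ev > 1e-12 * max(abs(ev)))) {
    drop(crossprod(d, solve(Vd, d)))
  } else {
    drop(crossprod(d, MASS::ginv(Vd, tol = 1e-3) %*% d))
  }
  structure(list(statistic = stat, df = length(nm),
                 p = if (valid) pchisq(stat, length(nm), lower.tail = FALSE)
                     else NA_real_,
                 valid = valid),
            class = "hausman_result")
}

#' @export
print.hausman_result <- function(x, ...) {
  cat(sprintf("Hausman: statistic = %.3f, df = %d, ", x$statistic, x$df))
  if (x$valid) {
    cat(sprintf("p = %.4g\n", x$p))
  } else {
    cat("INVALID (variance difference not positive definite)\n")
  }
  invisible(x)
}
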