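std_grid <- function(n, seed = 1L) {
  g <- generate_geography(n, "grid", seed = seed)
  contiguity_std(g$labels, g$adjacency)
}

test_that("spatial_lag is the weighted neighbor average", {
  swap <- contiguity_std(c("A", "B"), data.frame(from = "A", to = "B"))
  expect_equal(spatial_lag(swap, c(3, 7)), c(7, 3), ignore_attr = TRUE)
  island <- row_standardize(build_contiguity(
    c("A", "B", "C"), data.frame(from = "A", to = "B")))
  expect_equal(spatial_lag(island, c(1, 2, 9))[3L], 0, ignore_attr = TRUE)
  w <- random_weights(6L, seed = 3)
  v <- matrix(rnorm(12), 6L)
  expect_equal(spatial_lag(w, v), w$w %*% v, tolerance = 1e-14)
  expect_error(spatial_lag(w, rnorm(4)), "aligned")
})

test_that("within-OLS baseline recovers a noiseless DGP exactly", {
  w <- std_grid(9L)
  cfg <- synthetic_config(n = 9L, T = 5L, rho = 0,
                          beta = c(A = 2), lambda = c(W.A = 0),
                          sigma_mu = 1, sigma_eps = 0,
                          x_means = c(A = 0), x_sds = c(A = 1))
  sim <- simulate_sdm_panel(cfg, w, seed = 4L)
  tab <- fit_baseline_within(sim$panel, sdm_spec(regressors = "A"))
  expect_equal(tab$estimate, 2, tolerance = 1e-10)
})

test_that("baseline errors on time-invariant regressors, naming them", {
  p <- toy_panel(n = 4L, T = 3L)
  d <- p$data
  d$Cap <- rep(rnorm(4), times = 3L)    # constant over time per unit
  p2 <- panel_dataset(d)
  expect_error(fit_baseline_within(p2, sdm_spec()), "Cap")
})

test_that("baseline matches the normal-equations oracle on demeaned data", {
  p <- toy_panel(n = 6L, T = 5L, seed = 11L)
  spec <- sdm_spec()
  tab <- fit_baseline_within(p, spec)
  n <- 6L; Tn <- 5L
  Xd <- sapply(spec$regressors, function(v) {
    m <- matrix(p$data[[v]], n, Tn); as.vector(m - rowMeans(m))
  })
  ym <- matrix(p$data$GDP, n, Tn)
  y <- as.vector(ym - rowMeans(ym))
  bhat <- solve(crossprod(Xd), crossprod(Xd, y))
  expect_equal(tab$estimate, drop(bhat), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("log_det_term matches closed forms and the dense determinant", {
  swap <- contiguity_std(c("A", "B"), data.frame(from = "A", to = "B"))
  expect_equal(log_det_term(0, swap$eigenvalues), 0)
  expect_equal(log_det_term(0.5, swap$eigenvalues), log(0.75),
               tolerance = 1e-12)
  # asymmetric economic-style matrix against the dense oracle
  base <- random_weights(6L, seed = 17)
  w3 <- sdmspill:::new_spatial_weights(
    sweep(base$w, 2L, runif(6, 0.5, 2), "*"), base$labels, "economic")
  w3 <- row_standardize(w3)
  for (rho in c(-0.4, 0.2, 0.6)) {
    expect_equal(log_det_term(rho, w3$eigenvalues),
                 log(abs(det(diag(6L) - rho * w3$w))), tolerance = 1e-10)
  }
  expect_error(log_det_term(1, swap$eigenvalues), "outside")
})

test_that("the concentrated likelihood has an interior maximum found by the scalar search", {
  w <- std_grid(16L)
  cfg <- synthetic_config(n = 16L, T = 8L, rho = 0.4,
                          beta = c(A = 1, B = -0.5),
                          lambda = c(W.A = 0.2, W.B = 0),
                          sigma_mu = 0.3, sigma_eps = 0.2,
                          x_means = c(A = 0, B = 0), x_sds = c(A = 1, B = 1))
  sim <- simulate_sdm_panel(cfg, w, seed = 21L)
  spec <- sdm_spec(regressors = c("A", "B"))
  arr <- sdmspill:::panel_arrays(sim$panel, spec, w)
  Z <- sdmspill:::build_design(arr, function(m) sdmspill:::demean_mat(m))
  y <- as.vector(sdmspill:::demean_mat(arr$Y))
  wy <- as.vector(sdmspill:::demean_mat(arr$WY))
  fit <- fit_sdm_fe(sim$panel, spec, w)
  # 0.001-step grid search oracle
  grid <- seq(-0.9, 0.99, by = 0.001)
  ll <- vapply(grid, concentrated_loglik, numeric(1L), y = y, Z = Z,
               wy = wy, weights = w)
  expect_lt(abs(fit$rho - grid[which.max(ll)]), 0.002)
  # likelihood dominance over a 21-point grid
  expect_true(all(fit$loglik >= ll[seq(1L, length(ll), length.out = 21L)] - 1e-8))
  # sigma2(rho) > 0 across the interior
  expect_true(all(is.finite(ll)))
})

test_that("FE fit at rho = 0 reduces to within-OLS on [X, WX]", {
  w <- std_grid(9L)
  sim <- simulate_sdm_panel(synthetic_config(n = 9L, T = 6L, rho = 0.3),
                            w, seed = 23L)
  fe0 <- fit_sdm_fe(sim$panel, sdm_spec(), w, rho_fixed = 0)
  arr <- sdmspill:::panel_arrays(sim$panel, sdm_spec(), w)
  Z <- sdmspill:::build_design(arr, function(m) sdmspill:::demean_mat(m))
  y <- as.vector(sdmspill:::demean_mat(arr$Y))
  ols <- qr.coef(qr(Z), y)
  expect_equal(fe0$coefficients, ols, tolerance = 1e-6)
})

test_that("FE estimates are invariant to adding a constant to the outcome", {
  w <- std_grid(9L)
  sim <- simulate_sdm_panel(synthetic_config(n = 9L, T = 6L), w, seed = 25L)
  f1 <- fit_sdm_fe(sim$panel, sdm_spec(), w)
  shifted <- sim$panel
  shifted$data$GDP <- shifted$data$GDP + 5
  f2 <- fit_sdm_fe(panel_dataset(shifted$data), sdm_spec(), w)
  expect_equal(f2$coefficients, f1$coefficients, tolerance = 1e-6)
  expect_equal(f2$rho, f1$rho, tolerance = 1e-6)
})

test_that("every FE fit satisfies its structural invariants", {
  w <- std_grid(16L)
  for (seed in c(31L, 32L)) {
    sim <- simulate_sdm_panel(synthetic_config(n = 16L), w, seed = seed)
    fit <- fit_sdm_fe(sim$panel, sdm_spec(), w)
    int <- rho_interval(w)
    expect_gt(fit$rho, int[1L]); expect_lt(fit$rho, int[2L])
    expect_gt(fit$sigma2, 0)
    ev <- eigen((fit$vcov + t(fit$vcov)) / 2, symmetric = TRUE,
                only.values = TRUE)$values
    expect_true(all(ev > -1e-8 * max(ev)))
    # optimum dominates the rho = 0 interior point
    f0 <- fit_sdm_fe(sim$panel, sdm_spec(), w, rho_fixed = 0)
    expect_gte(fit$loglik, f0$loglik)
    expect_true(fit$r2 > 0 && fit$r2 <= 1)
  }
})

test_that("a regressor with no within variation is dropped with a warning", {
  p <- toy_panel(n = 5L, T = 4L, seed = 41L)
  d <- p$data
  d$Exp <- rep(rnorm(5), times = 4L)
  w <- random_weights(5L, seed = 42L)
  expect_warning(fit <- fit_sdm_fe(panel_dataset(d), sdm_spec(), w), "Exp")
  expect_false("Exp" %in% names(fit$coefficients))
})

test_that("RE fit: theta near 1 without unit effects, near FE with strong ones", {
  w <- std_grid(16L)
  cfg0 <- synthetic_config(n = 16L, sigma_mu = 0)
  sim0 <- simulate_sdm_panel(cfg0, w, seed = 51L)
  re0 <- suppressWarnings(fit_sdm_re(sim0$panel,
                                     sdm_spec(effects = "random"), w))
  expect_gt(re0$theta, 0.9)
  cfgL <- synthetic_config(n = 16L, sigma_mu = 2)
  simL <- simulate_sdm_panel(cfgL, w, seed = 52L)
  reL <- suppressWarnings(fit_sdm_re(simL$panel,
                                     sdm_spec(effects = "random"), w))
  feL <- fit_sdm_fe(simL$panel, sdm_spec(), w)
  expect_lt(reL$theta, 0.2)
  expect_equal(reL$coefficients[names(feL$coefficients)],
               feL$coefficients, tolerance = 0.05)
  expect_gt(reL$sigma2_mu, 0.5)
})

test_that("the RE likelihood dominates the pooled model nested at theta = 1", {
  w <- std_grid(9L)
  sim <- simulate_sdm_panel(synthetic_config(n = 9L, T = 8L), w, seed = 53L)
  re <- suppressWarnings(fit_sdm_re(sim$panel, sdm_spec(effects = "random"),
                                    w))
  # pooled ML log-likelihood by direct grid search (theta = 1: no demeaning)
  arr <- sdmspill:::panel_arrays(sim$panel, sdm_spec(), w)
  Z <- cbind(1, sdmspill:::build_design(arr))
  y <- as.vector(arr$Y); wy <- as.vector(arr$WY)
  n <- 9L; Tn <- 8L
  pooled <- max(vapply(seq(-0.8, 0.95, by = 0.005), function(rho) {
    e <- lm.fit(Z, y - rho * wy)$residuals
    s2 <- sum(e^2) / (n * Tn)
    -(n * Tn / 2) * log(2 * pi * s2) - n * Tn / 2 +
      Tn * log_det_term(rho, w$eigenvalues)
  }, numeric(1L)))
  expect_gte(re$loglik, pooled - 1e-6)
})

test_that("rho recovery sharpens as the panel lengthens", {
  w <- std_grid(16L)
  rmse <- vapply(c(4L, 10L, 24L), function(Tn) {
    errs <- vapply(1:40, function(r) {
      cfg <- synthetic_config(n = 16L, T = Tn,
                              periods = seq_len(Tn) + 2000L)
      sim <- simulate_sdm_panel(cfg, w, seed = 6000L + 100L * Tn + r)
      fit_sdm_fe(sim$panel, sdm_spec(), w)$rho - 0.5
    }, numeric(1L))
    sqrt(mean(errs^2))
  }, numeric(1L))
  expect_true(all(diff(rmse) < 0))
})

test_that("hausman_test handles identity, misalignment and indefiniteness", {
  w <- std_grid(16L)
  sim <- simulate_sdm_panel(synthetic_config(n = 16L), w, seed = 61L)
  fe <- fit_sdm_fe(sim$panel, sdm_spec(), w)
  h0 <- hausman_test(fe, fe)
  expect_identical(h0$statistic, 0)
  expect_identical(h0$p, 1)
  expect_true(h0$valid)
  expect_equal(h0$df, 12L)
  # constructed indefinite variance difference -> invalid, statistic reported
  re <- suppressWarnings(fit_sdm_re(sim$panel, sdm_spec(effects = "random"),
                                    w))
  re$vcov <- re$vcov * 5   # force V_FE - V_RE strongly indefinite
  h <- hausman_test(fe, re)
  expect_false(h$valid)
  expect_true(is.finite(h$statistic))
  expect_true(is.na(h$p))
  sim2 <- simulate_sdm_panel(synthetic_config(n = 16L, T = 5L), w, seed = 62L)
  fe2 <- fit_sdm_fe(sim2$panel, sdm_spec(), w)
  expect_error(hausman_test(fe, fe2), "different panels")
})

test_that("significance stars follow the 1%/5%/10% thresholds", {
  expect_equal(significance_stars(c(0.005, 0.03, 0.08, 0.2)),
               c("***", "**", "*", ""))
  w <- std_grid(9L)
  sim <- simulate_sdm_panel(synthetic_config(n = 9L), w, seed = 63L)
  tab <- coef_table(fit_sdm_fe(sim$panel, sdm_spec(), w))
  expect_equal(tab$stars, significance_stars(tab$p))
})
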