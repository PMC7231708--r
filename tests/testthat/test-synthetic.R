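test_that("grid geography is a rook lattice with 2-neighbor corners", {
  g <- generate_geography(9L, "grid", seed = 1L)
  w <- build_contiguity(g$labels, g$adjacency)
  deg <- rowSums(w$w)
  corners <- c("U01", "U03", "U07", "U09")
  expect_equal(unname(deg[corners]), rep(2, 4L))
  expect_equal(sum(deg), 2 * nrow(g$adjacency))
  expect_error(generate_geography(3L, "grid", seed = 1L), "at least 4")
})

test_that("geography generation is deterministic and connected", {
  skip_if_not_installed("igraph")
  g1 <- generate_geography(31L, "random_planar", seed = 5L)
  g2 <- generate_geography(31L, "random_planar", seed = 5L)
  expect_identical(g1, g2)
  gi <- igraph::graph_from_data_frame(g1$adjacency, directed = FALSE,
                                      vertices = data.frame(name = g1$labels))
  expect_true(igraph::is_connected(gi))
})

test_that("default study dimensions give a 403-record balanced panel", {
  b <- synthetic_bundle(synthetic_config(seed = 81L))
  expect_equal(nrow(b$panel$data), 403L)
  expect_equal(length(b$panel$units), 31L)
  expect_equal(b$panel$periods, 2005:2017)
})

test_that("noiseless non-spatial DGP returns y = X beta exactly", {
  g <- generate_geography(9L, "grid", seed = 1L)
  w <- contiguity_std(g$labels, g$adjacency)
  cfg <- synthetic_config(n = 9L, T = 3L, rho = 0,
                          beta = c(A = 1.5, B = -2),
                          lambda = c(W.A = 0, W.B = 0),
                          sigma_mu = 0, sigma_eps = 0,
                          x_means = c(A = 0, B = 0), x_sds = c(A = 1, B = 1))
  sim <- simulate_sdm_panel(cfg, w, seed = 82L)
  d <- sim$panel$data
  expect_equal(d$GDP, 1.5 * d$A - 2 * d$B, tolerance = 1e-12)
})

test_that("simulated panels satisfy the reduced-form identity", {
  g <- generate_geography(16L, "grid", seed = 1L)
  w <- contiguity_std(g$labels, g$adjacency)
  cfg <- synthetic_config(n = 16L)
  sim <- simulate_sdm_panel(cfg, w, seed = 83L)
  arr <- sdmspill:::panel_arrays(sim$panel, sdm_spec(), w)
  for (t in c(1L, 7L, 13L)) {
    X <- vapply(arr$X, function(m) m[, t], numeric(16L))
    resid <- (diag(16L) - cfg$rho * w$w) %*% arr$Y[, t] -
      X %*% cfg$beta - (w$w %*% X) %*% cfg$lambda
    expect_equal(drop(resid), unname(sim$truth$mu) + sim$truth$eps[, t],
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("same config and seed reproduce the panel bitwise", {
  g <- generate_geography(9L, "grid", seed = 1L)
  w <- contiguity_std(g$labels, g$adjacency)
  cfg <- synthetic_config(n = 9L)
  s1 <- simulate_sdm_panel(cfg, w, seed = 84L)
  s2 <- simulate_sdm_panel(cfg, w, seed = 84L)
  expect_identical(s1$panel$data, s2$panel$data)
  expect_identical(s1$truth$mu, s2$truth$mu)
})

test_that("generated regressor means sit within 3 SDs of their targets", {
  b <- synthetic_bundle(synthetic_config(seed = 85L))
  cfg <- synthetic_config()
  for (v in names(cfg$x_means)) {
    se <- cfg$x_sds[[v]] / sqrt(403)
    expect_lt(abs(mean(b$panel$data[[v]]) - cfg$x_means[[v]]), 3 * se)
  }
})

test_that("an inadmissible rho is refused", {
  g <- generate_geography(9L, "grid", seed = 1L)
  w <- contiguity_std(g$labels, g$adjacency)
  expect_error(simulate_sdm_panel(synthetic_config(n = 9L, rho = 1.1), w,
                                  seed = 1L), "inadmissible")
})

test_that("yearly Moran's I under rho = 0.5 matches the covariance oracle and is positive", {
  geo <- generate_geography(31L, "random_planar", seed = 7L)
  w <- contiguity_std(geo$labels, geo$adjacency)
  rho <- 0.5
  # analytic expectation for y = (I - rho W)^{-1} u with u iid:
  # ratio of expected quadratic forms under the centered covariance
  Ainv <- solve(diag(31L) - rho * w$w)
  Sig <- Ainv %*% t(Ainv)
  M <- diag(31L) - matrix(1 / 31, 31L, 31L)
  I_exp <- (31 / sum(w$w)) * sum(diag(w$w %*% M %*% Sig %*% M)) /
    sum(diag(M %*% Sig %*% M))
  cfg <- synthetic_config(rho = rho,
                          beta = c(A = 1, B = 0.5),
                          lambda = c(W.A = 0, W.B = 0),
                          x_means = c(A = 0, B = 0), x_sds = c(A = 1, B = 1))
  Is <- unlist(lapply(1:40, function(r) {
    sim <- simulate_sdm_panel(cfg, w, seed = 8600L + r)
    moran_by_year(sim$panel, w)$I
  }))
  expect_gt(I_exp, 0)
  expect_lt(abs(mean(Is) - I_exp), 0.05)
  expect_gt(mean(Is > 0), 0.95)
})

test_that("recovery_experiment summarizes bias, RMSE and coverage", {
  cfg <- synthetic_config(n = 16L, T = 8L,
                          beta = c(A = 1, B = -0.5),
                          lambda = c(W.A = 0.2, W.B = 0.1),
                          x_means = c(A = 0, B = 0), x_sds = c(A = 1, B = 1),
                          geography = "grid")
  expect_error(recovery_experiment(cfg, replicates = 10L, seed = 1L),
               "at least 50")
  rec <- recovery_experiment(cfg, replicates = 50L, seed = 87L)
  expect_equal(rec$parameter, c("rho", "A", "B", "W.A", "W.B"))
  expect_true(all(is.finite(rec$rmse)))
  expect_lt(abs(rec$bias[rec$parameter == "rho"]), 0.1)
  expect_true(all(rec$coverage >= 0.8))
})

test_that("doubling the panel length shrinks coefficient RMSE like root-T", {
  mk <- function(Tn) synthetic_config(n = 16L, T = Tn,
                                      periods = 2000L + seq_len(Tn),
                                      beta = c(A = 1), lambda = c(W.A = 0.2),
                                      x_means = c(A = 0), x_sds = c(A = 1),
                                      geography = "grid")
  r1 <- recovery_experiment(mk(6L), replicates = 60L, seed = 88L)
  r2 <- recovery_experiment(mk(12L), replicates = 60L, seed = 89L)
  ratio <- r2$rmse[r2$parameter == "A"] / r1$rmse[r1$parameter == "A"]
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 0.95)
})

test_that("write_bundle emits the files the loaders consume", {
  dir <- withr::local_tempdir()
  b <- synthetic_bundle(synthetic_config(seed = 90L))
  write_bundle(b, dir)
  p <- load_panel(file.path(dir, "panel.csv"))
  expect_equal(p$data$GDP, b$panel$data$GDP, tolerance = 1e-10)
  adj <- read_adjacency(file.path(dir, "edges.csv"))
  w <- contiguity_std(p$units, adj)
  expect_equal(w$w, b$weights$w, tolerance = 1e-12)
  expect_true(file.exists(file.path(dir, "coords.csv")))
  expect_true(file.exists(file.path(dir, "percap.csv")))
  expect_true(file.exists(file.path(dir, "partition.csv")))
})
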