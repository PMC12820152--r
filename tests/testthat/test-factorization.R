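test_that("objective components match the brute-force oracle", {
  for (s in 1:20) {
    set.seed(300 + s)
    n <- 5 + s %% 10; p <- 4 + s %% 8; r <- 2 + s %% 3
    ds <- rand_dataset(n = n, p = p, seed = 300 + s)
    g <- rand_graph(ds)
    W <- matrix(runif(n * r), n, r)
    H <- matrix(runif(r * p), r, p)
    pss <- runif(r)
    pr <- spatmf_params(alpha = 0.7, p = p, beta = 0.05, gamma = 0.3,
                        r = r, n_cluster = 2, N1 = 0, N2 = 0)
    got <- spatmf_objective(ds$X, W, H, g, pr, pss)
    want <- oracle_objective(ds$X, W, H, g$A, 0.7, 0.05, 0.3, pss)
    for (comp in c("total", "recon", "spatial", "sparsity", "ortho"))
      expect_equal(got[[comp]], want[[comp]], tolerance = 1e-12)
    expect_equal(got$total,
                 got$recon + got$spatial + got$sparsity + got$ortho)
  }
})

test_that("degenerate objective limits are exact", {
  ds <- rand_dataset(n = 6, p = 5, seed = 11)
  g <- rand_graph(ds)
  pr0 <- spatmf_params(alpha = 0, beta = 0, gamma = 0, p = 5, r = 2,
                       n_cluster = 2, N1 = 0, N2 = 0)
  set.seed(1)
  W <- matrix(runif(12), 6, 2); H <- matrix(runif(10), 2, 5)
  X <- W %*% H
  expect_equal(spatmf_objective(X, W, H, g, pr0, c(1, 1))$total, 0)
  expect_equal(
    spatmf_objective(X, matrix(0, 6, 2), matrix(0, 2, 5), g, pr0,
                     c(1, 1))$total,
    sum(X^2))
})

test_that("PSS matches its definition, conventions and oracle", {
  set.seed(21)
  # exact rank-1 outer product: profile is proportional to the signature
  w <- runif(8); h <- runif(5)
  X <- w %o% h
  expect_equal(compute_pss(X, cbind(w), rbind(h)), 1)

  # degenerate conventions
  W <- cbind(w, 0)
  H <- rbind(h, runif(5))
  expect_equal(compute_pss(X, W, H)[2], 0)
  H2 <- rbind(c(1, 1, 0, 0, 0), c(0, 0, 0, 1, 1))
  X2 <- cbind(1, 1, 0, 0, 0)[rep(1, 6), ]
  expect_equal(compute_pss(X2, matrix(runif(12), 6, 2), H2)[2], 0)

  for (s in 1:20) {
    set.seed(400 + s)
    n <- 6 + s %% 8; p <- 5 + s %% 6; r <- 2 + s %% 3
    X <- matrix(runif(n * p), n, p)
    W <- matrix(runif(n * r), n, r)
    H <- matrix(runif(r * p), r, p)
    expect_equal(compute_pss(X, W, H), oracle_pss(X, W, H),
                 tolerance = 1e-12)
    expect_true(all(compute_pss(X, W, H) >= 0 &
                      compute_pss(X, W, H) <= 1 + 1e-12))
  }
})

test_that("PSS is invariant to the (c*w, h/c) scale exchange", {
  set.seed(5)
  X <- matrix(runif(60, 0, 3), 10, 6)
  W <- matrix(runif(30), 10, 3)
  H <- matrix(runif(18), 3, 6)
  base <- compute_pss(X, W, H)
  for (c in c(0.01, 0.5, 7, 400)) {
    W2 <- W; H2 <- H
    W2[, 2] <- c * W[, 2]; H2[2, ] <- H[2, ] / c
    expect_equal(compute_pss(X, W2, H2), base, tolerance = 1e-12)
  }
})

test_that("multiplicative updates keep zeros, stay non-negative and have
           the multiplicative fixed-point property", {
  ds <- rand_dataset(n = 12, p = 8, seed = 31)
  g <- rand_graph(ds)
  pr <- spatmf_params(alpha = 0.5, p = 8, r = 3, n_cluster = 2,
                      N1 = 0, N2 = 0)
  set.seed(31)
  W <- matrix(runif(36), 12, 3); W[3, 2] <- 0; W[7, 1] <- 0
  H <- matrix(runif(24), 3, 8); H[2, 5] <- 0
  pss <- compute_pss(ds$X, W, H)
  W2 <- spatmf:::update_w(ds$X, W, H, g, pr, pss)
  H2 <- spatmf:::update_h(ds$X, W, H, pr)
  expect_identical(unname(W2[3, 2]), 0)
  expect_identical(unname(W2[7, 1]), 0)
  expect_identical(unname(H2[2, 5]), 0)
  expect_true(all(W2 >= 0) && all(H2 >= 0))

  # an exact factorization with no penalties is a fixed point
  pr0 <- spatmf_params(alpha = 0, beta = 0, gamma = 0, p = 8, r = 3,
                       n_cluster = 2, N1 = 0, N2 = 0)
  Xf <- W %*% H
  expect_equal(spatmf:::update_w(Xf, W, H, g, pr0, pss), W,
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(spatmf:::update_h(Xf, W, H, pr0), H, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("each half-step does not increase the objective with PSS frozen", {
  for (s in 1:10) {
    ds <- rand_dataset(n = 15, p = 10, seed = 500 + s)
    g <- rand_graph(ds)
    pr <- spatmf_params(alpha = 0.8, p = 10, r = 4, seed = s,
                        n_cluster = 2, N1 = 0, N2 = 0)
    set.seed(s)
    W <- matrix(runif(60), 15, 4); H <- matrix(runif(40), 4, 10)
    for (it in 1:30) {
      pss <- compute_pss(ds$X, W, H)
      o0 <- spatmf_objective(ds$X, W, H, g, pr, pss)$total
      W <- spatmf:::update_w(ds$X, W, H, g, pr, pss)
      o1 <- spatmf_objective(ds$X, W, H, g, pr, pss)$total
      H <- spatmf:::update_h(ds$X, W, H, pr)
      o2 <- spatmf_objective(ds$X, W, H, g, pr, pss)$total
      expect_lte(o1, o0 * (1 + 1e-9))
      expect_lte(o2, o1 * (1 + 1e-9))
    }
  }
})

test_that("fits are bit-reproducible under the same seed", {
  ds <- rand_dataset(n = 20, p = 10, seed = 77)
  g <- rand_graph(ds)
  pr <- spatmf_params(alpha = 0.5, p = 10, r = 4, seed = 99, max_iter = 40,
                      n_cluster = 2, N1 = 0, N2 = 0)
  f1 <- spatmf(ds, g, pr)
  f2 <- spatmf(ds, g, pr)
  expect_identical(f1$W, f2$W)
  expect_identical(f1$H, f2$H)
  expect_identical(f1$objective_trace, f2$objective_trace)
})

test_that("noiseless rank-1 data is factorized essentially exactly", {
  set.seed(13)
  w <- runif(25, 0.5, 2); h <- runif(12, 0.5, 2)
  side <- 5
  ds <- spatial_dataset(w %o% h,
                        as.matrix(expand.grid(0:4, 0:4)), validate = FALSE)
  # rank-1 rows are all parallel, so the bandwidth floor kicks in
  g <- suppressWarnings(spatial_graph(ds, predefined_radius = 1.5))
  pr <- spatmf_params(alpha = 0, beta = 0, gamma = 0, p = 12, r = 1,
                      seed = 2, max_iter = 500, tol = 1e-12,
                      n_cluster = 1, N1 = 0, N2 = 0)
  fit <- spatmf(ds, g, pr)
  relerr <- norm(ds$X - fit$W %*% fit$H, "F") / norm(ds$X, "F")
  expect_lt(relerr, 1e-3)
})

test_that("factors remain non-negative across the whole fit trajectory", {
  ds <- rand_dataset(n = 16, p = 8, seed = 8)
  g <- rand_graph(ds)
  pr <- spatmf_params(alpha = 0.6, p = 8, r = 3, seed = 3, max_iter = 60,
                      n_cluster = 2, N1 = 0, N2 = 0)
  set.seed(3)
  scl <- sqrt(mean(ds$X) / 3)
  W <- matrix(runif(48), 16, 3) * scl
  H <- matrix(runif(24), 3, 8) * scl
  for (it in 1:60) {
    pss <- compute_pss(ds$X, W, H)
    W <- spatmf:::update_w(ds$X, W, H, g, pr, pss)
    H <- spatmf:::update_h(ds$X, W, H, pr)
    expect_true(all(W >= 0) && all(H >= 0) &&
                  all(is.finite(W)) && all(is.finite(H)))
  }
})

test_that("the trace records consistent totals and patterns sort by PSS", {
  ds <- rand_dataset(n = 20, p = 10, seed = 55)
  g <- rand_graph(ds)
  fit <- spatmf(ds, g, r = 4, alpha = 0.5, seed = 1, max_iter = 30,
                n_cluster = 2, N1 = 0, N2 = 0)
  tr <- fit$objective_trace
  expect_equal(tr$total, tr$recon + tr$spatial + tr$sparsity + tr$ortho,
               tolerance = 1e-12)
  expect_true(all(diff(fit$pss) <= 1e-12))
  expect_equal(sort(fit$pss, decreasing = TRUE), fit$pss)
})

test_that("multislice with one slice reproduces the single-slice fit", {
  sim <- simulate_layers(n_side = 10, r_true = 3, p = 40, n_background = 8,
                         noise_sd = 0.2, seed = 2)
  g <- spatial_graph(sim$dataset, lambda = 1.8, n_c = 3)
  pr <- spatmf_params(alpha = 0.5, p = 40, r = 4, seed = 5, max_iter = 50,
                      n_cluster = 3, N1 = 0, N2 = 0)
  f1 <- spatmf(sim$dataset, g, pr)
  fm <- spatmf_multi(list(sim$dataset), list(g), pr)
  expect_identical(fm$W_list[[1]], f1$W)
  expect_identical(fm$H, f1$H)
  expect_identical(fm$objective_trace, f1$objective_trace)
})

test_that("duplicated slices converge to near-identical patterns", {
  sim <- simulate_layers(n_side = 12, r_true = 3, p = 60, n_background = 12,
                         noise_sd = 0.3, seed = 6)
  g <- spatial_graph(sim$dataset, lambda = 1.8, n_c = 3)
  pr <- spatmf_params(alpha = 0.5, p = 60, r = 5, seed = 4, max_iter = 300,
                      tol = 1e-7, n_cluster = 3, N1 = 0, N2 = 0)
  fd <- spatmf_multi(list(sim$dataset, sim$dataset), list(g, g), pr)
  reldiff <- norm(fd$W_list[[1]] - fd$W_list[[2]], "F") /
    norm(fd$W_list[[1]], "F")
  expect_lt(reldiff, 0.05)
})

test_that("multislice summed objective is non-increasing with PSS frozen
           within each iteration", {
  sims <- simulate_multislice(M = 2, seed = 9, n_side = 8, r_true = 2,
                              p = 20, n_background = 4, noise_sd = 0.2)
  dss <- lapply(sims, `[[`, "dataset")
  gs <- lapply(dss, spatial_graph, lambda = 1.8, n_c = 2)
  pr <- spatmf_params(alpha = 0.5, p = 20, r = 3, seed = 2, max_iter = 40,
                      n_cluster = 2, N1 = 0, N2 = 0)
  fd <- spatmf_multi(dss, gs, pr)
  expect_true(all(diff(fd$objective_trace$total) <= 1e-9))
})

test_that("feature-axis mismatch across slices errors", {
  sim <- simulate_layers(n_side = 8, r_true = 2, p = 20, n_background = 4,
                         seed = 1)
  ds2 <- sim$dataset
  ds2$feature_ids <- rev(ds2$feature_ids)
  expect_error(spatmf_multi(list(sim$dataset, ds2)), "feature axis")
})

test_that("stationarity at convergence (KKT residual vs finite differences)", {
  set.seed(7)
  coords <- cbind(runif(10, 0, 3), runif(10, 0, 3))
  X <- matrix(runif(80, 0, 4), 10, 8)
  ds <- spatial_dataset(X, coords, validate = FALSE)
  g <- spatial_graph(ds, predefined_radius = 2)
  pr <- spatmf_params(alpha = 0.5, p = 8, r = 3, seed = 7, tol = 1e-13,
                      max_iter = 6000, n_cluster = 2, N1 = 0, N2 = 0)
  fit <- spatmf(ds, g, pr)
  W <- fit$W; H <- fit$H; pss <- fit$pss
  f <- function(W, H) spatmf_objective(X, W, H, g, pr, pss)$total
  h <- 1e-6
  gW <- W * 0; gH <- H * 0
  for (i in seq_len(nrow(W))) for (j in seq_len(ncol(W))) {
    Wp <- W; Wm <- W
    Wp[i, j] <- W[i, j] + h; Wm[i, j] <- W[i, j] - h
    gW[i, j] <- (f(Wp, H) - f(Wm, H)) / (2 * h)
  }
  for (i in seq_len(nrow(H))) for (j in seq_len(ncol(H))) {
    Hp <- H; Hm <- H
    Hp[i, j] <- H[i, j] + h; Hm[i, j] <- H[i, j] - h
    gH[i, j] <- (f(W, Hp) - f(W, Hm)) / (2 * h)
  }
  thr <- 1e-4 * sum(X^2)
  expect_lt(max(abs(W * gW)), thr)
  expect_lt(max(abs(H * gH)), thr)
})
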