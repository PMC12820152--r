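fit_small <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      sim <- simulate_layers(n_side = 12, r_true = 3, p = 40,
                             n_background = 8, noise_sd = 0.2, seed = 1)
      g <- spatial_graph(sim$dataset, lambda = 1.8, n_c = 3)
      memo <<- list(fit = spatmf(sim$dataset, g, r = 5, alpha = 0.5,
                                 seed = 1, max_iter = 80, n_cluster = 3,
                                 N1 = 0, N2 = 0),
                    sim = sim)
    }
    memo
  }
})

test_that("pattern contributions normalize columns and match the oracle", {
  fs <- fit_small()
  Pr <- pattern_contributions(fs$fit)
  cs <- colSums(Pr)
  expect_true(all(abs(cs - 1) < 1e-12 | cs == 0))
  expect_true(all(Pr >= 0))
  expect_equal(unname(Pr), oracle_pr(fs$fit$W, fs$fit$H),
               tolerance = 1e-12, ignore_attr = TRUE)

  # a column with a single nonzero source becomes a unit vector
  W <- matrix(runif(12, 0.5, 1), 6, 2)
  H <- rbind(c(2, 0), c(0, 3))
  Pr2 <- pattern_contributions(structure(list(W = W, H = H),
                                         class = "spatmf"))
  expect_equal(unname(Pr2[, 1]), c(1, 0))
  expect_equal(unname(Pr2[, 2]), c(0, 1))

  # all-zero H column is flagged and zeroed
  H3 <- rbind(c(2, 0), c(1, 0))
  Pr3 <- pattern_contributions(structure(list(W = W, H = H3),
                                         class = "spatmf"))
  expect_identical(attr(Pr3, "zero_columns"), 2L)
  expect_equal(unname(Pr3[, 2]), c(0, 0))
})

test_that("pattern contributions are invariant to the factor scale
           exchange", {
  fs <- fit_small()
  W <- fs$fit$W; H <- fs$fit$H
  base <- pattern_contributions(structure(list(W = W, H = H),
                                          class = "spatmf"))
  W2 <- W; H2 <- H
  W2[, 3] <- 5 * W[, 3]; H2[3, ] <- H[3, ] / 5
  again <- pattern_contributions(structure(list(W = W2, H = H2),
                                           class = "spatmf"))
  expect_equal(base, again, tolerance = 1e-12)
})

test_that("pattern-specific selection is a strict threshold with ordering", {
  Pr <- rbind(c(0.40, 0.31, 0.30), c(0.35, 0.39, 0.30),
              c(0.25, 0.30, 0.40))
  colnames(Pr) <- c("g1", "g2", "g3")
  rownames(Pr) <- paste0("pattern", 1:3)
  pg <- pattern_genes(Pr, eps_pattern = 0.3)
  expect_identical(pg$pattern1$feature, c("g1", "g2"))  # 0.40, 0.31 > 0.3
  expect_identical(pg$pattern2$feature, c("g2", "g1"))  # descending Pr
  expect_identical(pg$pattern3$feature, "g3")
  # g1 belongs to patterns 1 and 2 only; 0.30 exactly is excluded
  expect_false("g3" %in% pg$pattern1$feature)
  expect_false("g3" %in% pg$pattern2$feature)
})

test_that("SVG errors match their definition and conventions", {
  fs <- fit_small()
  err <- svg_scores(fs$fit)
  expect_equal(unname(err), oracle_err(fs$sim$dataset$X, fs$fit$W,
                                       fs$fit$H), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(err >= 0))

  W <- matrix(runif(12, 0.5, 1), 6, 2)
  H <- matrix(runif(6, 0.5, 1), 2, 3)
  X <- W %*% H
  m <- structure(list(W = W, H = H), class = "spatmf")
  expect_equal(max(svg_scores(m, X = X)), 0, tolerance = 1e-12)

  # zero reconstruction of a nonzero column gives error exactly 1
  m0 <- structure(list(W = W * 0, H = H), class = "spatmf")
  expect_equal(unname(svg_scores(m0, X = X)), rep(1, 3),
               ignore_attr = TRUE)

  # an all-zero data column gets the Inf sentinel and a flag
  X2 <- X; X2[, 2] <- 0
  e2 <- svg_scores(m, X = X2)
  expect_identical(unname(e2[2]), Inf)
  expect_identical(attr(e2, "zero_columns"), 2L)
})

test_that("SVG selection uses a strict cutoff ordered by error", {
  err <- c(0.1, 0.8, 0.69)
  expect_identical(select_svgs(err, eps_svg = 0.7), c(1L, 3L))
  expect_identical(select_svgs(c(0, 0.7), eps_svg = 0.7), 1L)  # 0.7 excluded
  expect_identical(select_svgs(c(Inf, 0.2), eps_svg = 0.7), 2L)
})

test_that("pattern filtering drops by norm then PSS with stated tie-breaks", {
  W <- matrix(0, 4, 6)
  norms <- c(5, 1, 3, 1, 4, 2)
  for (k in 1:6) W[, k] <- norms[k] / 2   # column norms = norms
  model <- structure(list(W = W, pss = c(0.9, 0.8, 0.1, 0.2, 0.15, 0.7),
                          params = list(N1 = 0, N2 = 0)),
                     class = "spatmf")
  # N1=2 drops the two smallest norms (ties: lower index first -> 2, 4)
  # N2=2 then drops lowest PSS among {1,3,5,6} -> 3, 5
  W_star <- filter_patterns(model, N1 = 2, N2 = 2)
  expect_identical(attr(W_star, "kept"), c(1L, 6L))

  expect_identical(attr(filter_patterns(model, N1 = 0, N2 = 0), "kept"),
                   1:6)
  expect_error(filter_patterns(model, N1 = 4, N2 = 2), "smaller than r")

  # documented defaults: r = 30, n_cluster = 8 keep exactly 10 patterns
  pr <- spatmf_params(alpha = 0.5, p = 100)
  expect_identical(pr$N1, 17L)
  expect_identical(pr$N2, 3L)
  expect_identical(pr$r - pr$N1 - pr$N2, 10L)
  # the N1 formula clamps at zero for small r
  pr2 <- spatmf_params(alpha = 0.5, p = 100, r = 10, n_cluster = 8)
  expect_identical(pr2$N1, 0L)
})

test_that("domain clustering is deterministic and exact on separated
           point masses", {
  set.seed(2)
  centers <- matrix(c(0, 0, 10, 0, 0, 10), 3, 2, byrow = TRUE)
  truth <- rep(1:3, each = 20)
  W_star <- centers[truth, ] + matrix(rnorm(120, 0, 0.05), 60, 2)
  l1 <- cluster_domains(W_star, 3, seed = 4)
  l2 <- cluster_domains(W_star, 3, seed = 4)
  expect_identical(l1, l2)
  expect_equal(adjusted_rand_index(l1, truth), 1)
  expect_error(cluster_domains(matrix(1, 5, 2), 3), "distinct")
  expect_error(cluster_domains(W_star, 61), "exceeds")
})

test_that("denoising is the factor product and improves Moran's I on noisy
           planted data", {
  fs <- fit_small()
  Xhat <- denoise(fs$fit)
  expect_equal(Xhat, fs$fit$W %*% fs$fit$H)
  expect_true(all(Xhat >= 0))
  rr <- refinement_report(fs$fit)
  expect_gt(rr$fraction_improved, 0.9)
  expect_gt(rr$mean_after, rr$mean_before)
})

test_that("refinement report conventions: identity and constant features", {
  fs <- fit_small()
  g <- fs$fit$graph
  X <- as.matrix(fs$sim$dataset$X)
  rr <- refinement_report(fs$fit, X = X, X_hat = X, g = g)
  expect_equal(max(abs(rr$per_feature$delta)), 0)

  Xc <- X; Xc[, 1] <- 2
  rr2 <- refinement_report(fs$fit, X = Xc, X_hat = Xc, g = g)
  expect_identical(rr2$per_feature$morans_before[1], 0)
  expect_identical(rr2$per_feature$morans_after[1], 0)
})

test_that("co-expression pairs rank by correlation with exclusions", {
  set.seed(6)
  base <- rnorm(40)
  X <- cbind(a = base, b = base, c = -base + mean(base) * 2,
             d = rnorm(40), e = rep(1, 40))
  cp <- coexpression_pairs(X, 1:5, threshold = 0.5)
  expect_identical(attr(cp, "excluded"), "e")
  expect_identical(cp$feature1[1], "a")
  expect_identical(cp$feature2[1], "b")
  expect_equal(cp$correlation[1], 1)
  expect_false(any(cp$feature1 == "a" & cp$feature2 == "c"))
  expect_true(all(diff(cp$correlation) <= 0))
  expect_error(coexpression_pairs(X, 1), "at least 2")
})

test_that("same-pattern pairs dominate the co-expression list on refined
           planted data", {
  fs <- fit_small()
  Xhat <- denoise(fs$fit)
  sup <- apply(fs$sim$truth$H_true, 2, which.max)
  svg <- fs$sim$truth$svg_true
  cp <- coexpression_pairs(Xhat, svg, threshold = 0.5)
  i1 <- match(cp$feature1, fs$sim$dataset$feature_ids)
  i2 <- match(cp$feature2, fs$sim$dataset$feature_ids)
  same <- sum(sup[i1] == sup[i2])
  expect_gt(same, nrow(cp) - same)
})
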