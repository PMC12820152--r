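#' Simulate a layered spatial dataset with planted truth
#'
#' Generates spots on an `n_side` x `n_side` unit-spaced grid with `r_true`
#' horizontal expression bands emulating laminar (cortex-like) tissue.
#' Planted pattern columns `W_true` are smoothed band indicators
#' (`exp(-d^2 / (2 s^2))` of the vertical distance `d` to the band, so
#' adjacent bands overlap softly at their boundary); metagene rows `H_true`
#' carry disjoint blocks of `p - n_background` structured ("SVG") features
#' with `Uniform(1, 2)` loadings.  The observed matrix is
#' `X = max(0, W_true H_true + Normal(0, noise_sd))`, optionally
#' Poisson-resampled.  Each of the `n_background` background features is a
#' spot-permuted copy of a structured feature: identical marginal
#' distribution, destroyed spatial signal.
#'
#' The alternative `geometry = "bumps"` plants smooth radial bumps at random
#' centers instead of bands, for non-laminar tissue.
#'
#' @param n_side grid side length (default 30; `n = n_side^2` spots).
#' @param r_true number of planted patterns/bands (default 6).
#' @param p total number of features (default 300).
#' @param n_background number of spatially-permuted noise features
#'   (default 60).
#' @param noise_sd Gaussian noise standard deviation (default 0.3).
#' @param seed RNG seed (default 0).
#' @param poisson if `TRUE`, resample `X ~ Poisson(scale * X) / scale` for
#'   count-like noise (default `FALSE`).
#' @param poisson_scale rate multiplier for Poisson resampling (default 10).
#' @param geometry `"bands"` (default) or `"bumps"`.
#' @param smooth_sd band-edge smoothing bandwidth in grid units (default 1).
#' @return list with `dataset` (a [spatial_dataset()]) and `truth` (class
#'   `"spatmf_truth"`: `W_true` (n x r_true), `H_true` (r_true x p, zero on
#'   background columns), `domain_labels` (band index per spot, 1-based),
#'   `svg_true` (structured feature indices), `background` (the rest),
#'   `generator_params`).
#' @export
#' @examples
#' sim <- simulate_layers(n_side = 10, r_true = 3, p = 30, n_background = 6,
#'                        noise_sd = 0, seed = 1)
#' range(sim$dataset$X - sim$truth$W_true %*% sim$truth$H_true)  # exact
simulate_layers <- function(n_side = 30, r_true = 6, p = 300,
                            n_background = 60, noise_sd = 0.3, seed = 0,
                            poisson = FALSE, poisson_scale = 10,
                            geometry = c("bands", "bumps"), smooth_sd = 1) {
  geometry <- match.arg(geometry)
  if (r_true < 2) stopf("r_true must be at least 2")
  n_struct <- p - n_background
  if (n_struct < r_true)
    stopf("p - n_background (%d) must be at least r_true (%d)",
          n_struct, r_true)
  set.seed(seed)
  coords <- as.matrix(expand.grid(x = seq_len(n_side) - 1,
                                  y = seq_len(n_side) - 1))
  n <- nrow(coords)

  if (geometry == "bands") {
    # band k covers y in [(k-1), k) * n_side / r_true
    band_width <- n_side / r_true
    band_idx <- pmin(r_true, floor(coords[, "y"] / band_width) + 1L)
    W_true <- vapply(seq_len(r_true), function(k) {
      lo <- (k - 1) * band_width; hi <- k * band_width - 1
      d <- pmax(0, pmax(lo - coords[, "y"], coords[, "y"] - hi))
      exp(-d^2 / (2 * smooth_sd^2))
    }, numeric(n))
    labels <- as.integer(band_idx)
  } else {
    centers <- cbind(runif(r_true, 0, n_side - 1),
                     runif(r_true, 0, n_side - 1))
    width <- n_side / sqrt(r_true) / 1.5
    W_true <- vapply(seq_len(r_true), function(k) {
      d2 <- (coords[, 1] - centers[k, 1])^2 +
        (coords[, 2] - centers[k, 2])^2
      exp(-d2 / (2 * width^2))
    }, numeric(n))
    labels <- as.integer(max.col(W_true))
  }

  # disjoint round-robin supports over the structured features
  svg_true <- seq_len(n_struct)
  support <- rep(seq_len(r_true), length.out = n_struct)
  H_true <- matrix(0, r_true, p)
  for (k in seq_len(r_true))
    H_true[k, svg_true[support == k]] <-
      runif(sum(support == k), 1, 2)

  X <- W_true %*% H_true
  if (noise_sd > 0) X <- X + matrix(rnorm(n * p, 0, noise_sd), n, p)
  X <- pmax(X, 0)
  # background features: spot-permuted copies of structured features
  if (n_background > 0) {
    src <- rep(svg_true, length.out = n_background)
    for (b in seq_len(n_background))
      X[, n_struct + b] <- X[sample.int(n), src[b]]
  }
  if (poisson)
    X <- matrix(rpois(n * p, poisson_scale * X), n, p) / poisson_scale

  feature_ids <- c(sprintf("svg%03d", svg_true),
                   sprintf("bg%03d", seq_len(n_background)))
  ds <- spatial_dataset(X, coords,
                        spot_ids = sprintf("s%04d", seq_len(n)),
                        feature_ids = feature_ids, validate = FALSE)
  truth <- structure(list(
    W_true = W_true, H_true = H_true, domain_labels = labels,
    svg_true = svg_true,
    background = setdiff(seq_len(p), svg_true),
    generator_params = list(n_side = n_side, r_true = r_true, p = p,
                            n_background = n_background,
                            noise_sd = noise_sd, seed = seed,
                            poisson = poisson, geometry = geometry)),
    class = "spatmf_truth")
  list(dataset = ds, truth = truth)
}

#' Simulate multiple slices sharing one metagene matrix
#'
#' Generates `M` slices from the same planted `H_true` and band geometry,
#' each with independent observation noise and optional slice-specific
#' coordinate jitter — the setting the multislice fit ([spatmf_multi()])
#' assumes.
#'
#' @param M number of slices (at least 2).
#' @param jitter_sd standard deviation of per-slice coordinate jitter
#'   (default 0; slices then share coordinates exactly).
#' @param seed RNG seed.
#' @param ... passed to [simulate_layers()] (n_side, r_true, p, ...).
#' @return list of per-slice lists `(dataset, truth)`; all truths share
#'   `H_true`.
#' @export
simulate_multislice <- function(M = 2, jitter_sd = 0, seed = 0, ...) {
  stopifnot(M >= 2)
  base <- simulate_layers(seed = seed, ...)
  H <- base$truth$H_true
  gp <- base$truth$generator_params
  set.seed(seed + 1L)
  lapply(seq_len(M), function(s) {
    sl <- simulate_layers(n_side = gp$n_side, r_true = gp$r_true, p = gp$p,
                          n_background = gp$n_background,
                          noise_sd = gp$noise_sd,
                          seed = seed + 1000L * s, poisson = gp$poisson,
                          geometry = gp$geometry)
    # replant the shared H so every slice uses identical metagenes
    sl$truth$H_true <- H
    X <- sl$truth$W_true %*% H
    set.seed(seed + 1000L * s + 1L)
    if (gp$noise_sd > 0)
      X <- X + matrix(rnorm(length(X), 0, gp$noise_sd), nrow(X), ncol(X))
    X <- pmax(X, 0)
    nb <- gp$n_background; ns <- gp$p - nb
    if (nb > 0) {
      src <- rep(seq_len(ns), length.out = nb)
      for (b in seq_len(nb))
        X[, ns + b] <- X[sample.int(nrow(X)), src[b]]
    }
    sl$dataset$X <- X
    if (jitter_sd > 0)
      sl$dataset$coords <- sl$dataset$coords +
        matrix(rnorm(length(sl$dataset$coords), 0, jitter_sd),
               ncol = 2)
    sl
  })
}

#' Simulate co-localized multi-omics modalities
#'
#' Generates one dataset per modality over the same spots: all modalities
#' share the planted spatial patterns `W_true` but carry modality-specific
#' metagene blocks and noise scales, emulating co-localized gene-protein or
#' gene-peak pairs.
#'
#' @param p_per_modality named integer vector of feature counts, e.g.
#'   `c(rna = 200, protein = 30)`; needs at least 2 modalities.
#' @param noise_sds noise level per modality (recycled; default 0.3).
#' @param n_side,r_true grid and pattern counts as in [simulate_layers()].
#' @param background_frac fraction of features per modality that are
#'   spot-permuted background (default 0.2).
#' @param seed RNG seed.
#' @return list with `datasets` (one [spatial_dataset()] per modality,
#'   tagged) and `truth` (shared `W_true`, per-modality `H_true` blocks,
#'   labels, per-modality `svg_true`).
#' @export
simulate_multiomics <- function(p_per_modality = c(rna = 200, protein = 40),
                                noise_sds = 0.3, n_side = 30, r_true = 6,
                                background_frac = 0.2, seed = 0) {
  stopifnot(length(p_per_modality) >= 2)
  noise_sds <- rep(noise_sds, length.out = length(p_per_modality))
  mods <- names(p_per_modality) %||%
    paste0("mod", seq_along(p_per_modality))
  base <- simulate_layers(n_side = n_side, r_true = r_true,
                          p = max(r_true + 1, 20), n_background = 0,
                          noise_sd = 0, seed = seed)
  W <- base$truth$W_true
  labels <- base$truth$domain_labels
  datasets <- list(); H_list <- list(); svg_list <- list()
  for (m in seq_along(mods)) {
    p_m <- p_per_modality[[m]]
    nb <- floor(background_frac * p_m)
    ns <- p_m - nb
    if (ns < r_true)
      stopf("modality %s too small for %d patterns", mods[m], r_true)
    set.seed(seed + 17L * m)
    support <- rep(seq_len(r_true), length.out = ns)
    H <- matrix(0, r_true, p_m)
    for (k in seq_len(r_true))
      H[k, which(support == k)] <- runif(sum(support == k), 1, 2)
    X <- W %*% H
    if (noise_sds[m] > 0)
      X <- X + matrix(rnorm(length(X), 0, noise_sds[m]), nrow(X), ncol(X))
    X <- pmax(X, 0)
    if (nb > 0) {
      src <- rep(seq_len(ns), length.out = nb)
      for (b in seq_len(nb))
        X[, ns + b] <- X[sample.int(nrow(X)), src[b]]
    }
    fid <- sprintf("%s_f%03d", mods[m], seq_len(p_m))
    datasets[[mods[m]]] <- spatial_dataset(
      X, base$dataset$coords, spot_ids = base$dataset$spot_ids,
      feature_ids = fid, modality_tags = mods[m], validate = FALSE)
    H_list[[mods[m]]] <- H
    svg_list[[mods[m]]] <- seq_len(ns)
  }
  list(datasets = datasets,
       truth = structure(list(W_true = W, H_true = H_list,
                              domain_labels = labels,
                              svg_true = svg_list,
                              generator_params = list(
                                p_per_modality = p_per_modality,
                                noise_sds = noise_sds, n_side = n_side,
                                r_true = r_true, seed = seed)),
                         class = "spatmf_truth"))
}
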