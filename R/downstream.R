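#' Normalized pattern-contribution matrix
#'
#' Two-step normalization of the metagene matrix `H`: rows are first scaled
#' by the spatial abundance of their pattern,
#' \eqn{H' = \Lambda H,\ \Lambda = \mathrm{diag}(\|w_1\|_2, \ldots,
#' \|w_r\|_2)}, then each column is normalized to sum to one,
#' \eqn{Pr_{ij} = H'_{ij} / \sum_k |H'_{kj}|}.  Column j of `Pr` gives the
#' relative contribution of every pattern to feature j; it is invariant to
#' the scale exchange \eqn{(w_i, h_i) \to (c\,w_i, h_i / c)}.  Columns whose
#' `H'` column is entirely zero are set to 0 and flagged in the
#' `"zero_columns"` attribute.
#'
#' @param model a fitted [spatmf()] model.
#' @return r x p matrix `Pr` with non-negative entries; nonzero columns sum
#'   to 1.
#' @export
pattern_contributions <- function(model) {
  lam <- sqrt(colSums(model$W^2))
  Hp <- lam * model$H
  cs <- colSums(abs(Hp))
  zero <- cs == 0
  Pr <- sweep(Hp, 2, ifelse(zero, 1, cs), `/`)
  Pr[, zero] <- 0
  structure(Pr, zero_columns = which(zero))
}

#' Pattern-specific features
#'
#' A feature is specific to pattern i when its normalized contribution
#' `Pr[i, j]` strictly exceeds the threshold `eps_pattern`; a feature may be
#' specific to several patterns, or to none.  Within each pattern, features
#' are ordered by descending contribution.
#'
#' @param model a fitted [spatmf()] model, or a precomputed `Pr` matrix from
#'   [pattern_contributions()].
#' @param eps_pattern threshold in (0, 1); default from the model's params,
#'   else 0.3.
#' @return named list, one element per pattern, each a data frame with
#'   columns `feature`, `contribution` (and `modality` when the model
#'   carries modality tags), ordered by descending contribution.
#' @export
pattern_genes <- function(model, eps_pattern = NULL) {
  if (inherits(model, "spatmf")) {
    Pr <- pattern_contributions(model)
    eps_pattern <- eps_pattern %||% model$params$eps_pattern
    tags <- model$dataset$modality_tags
  } else {
    Pr <- model
    eps_pattern <- eps_pattern %||% 0.3
    tags <- NULL
  }
  stopifnot(eps_pattern > 0, eps_pattern < 1)
  feats <- colnames(Pr) %||% paste0("feat", seq_len(ncol(Pr)))
  out <- lapply(seq_len(nrow(Pr)), function(i) {
    j <- which(Pr[i, ] > eps_pattern)
    j <- j[order(-Pr[i, j], j)]
    df <- data.frame(feature = feats[j], contribution = Pr[i, j],
                     row.names = NULL)
    if (!is.null(tags)) df$modality <- tags[j]
    df
  })
  names(out) <- rownames(Pr) %||% paste0("pattern", seq_len(nrow(Pr)))
  out
}

#' Relative reconstruction error per feature
#'
#' For feature i, `err_i = ||X[, i] - (WH)[, i]||_2 / ||X[, i]||_2`: how
#' poorly the discovered pattern basis explains the feature.  Features whose
#' expression is well captured by the spatial patterns get small errors;
#' spatially unstructured features approach 1 (or beyond).  All-zero
#' columns get `Inf` (never selectable) and are flagged in the
#' `"zero_columns"` attribute.
#'
#' @param model a fitted [spatmf()] model.
#' @param X optional matrix to score against; defaults to the matrix the
#'   model was fitted on.
#' @return length-p non-negative numeric vector of errors.
#' @export
svg_scores <- function(model, X = NULL) {
  X <- as.matrix(X %||% model$dataset$X)
  R <- X - model$W %*% model$H
  num <- sqrt(colSums(R^2))
  den <- sqrt(colSums(X^2))
  zero <- den == 0
  err <- ifelse(zero, Inf, num / den)
  names(err) <- colnames(X)
  structure(err, zero_columns = which(zero))
}

#' Select spatially variable features
#'
#' Features whose relative reconstruction error is strictly below `eps_svg`
#' are classified as spatially variable: their expression is well explained
#' by the discovered spatial pattern basis.  Unlike pattern-specific
#' features, an SVG may load on several patterns.
#'
#' @param err numeric vector from [svg_scores()], or a fitted [spatmf()]
#'   model.
#' @param eps_svg positive threshold; default from the model's params, else
#'   0.7.
#' @return integer vector of selected feature indices, ordered by ascending
#'   error.
#' @export
select_svgs <- function(err, eps_svg = NULL) {
  if (inherits(err, "spatmf")) {
    eps_svg <- eps_svg %||% err$params$eps_svg
    err <- svg_scores(err)
  }
  eps_svg <- eps_svg %||% 0.7
  stopifnot(eps_svg > 0)
  sel <- which(err < eps_svg)
  sel[order(err[sel], sel)]
}

#' Sequential pattern filtering before domain clustering
#'
#' Not every discovered pattern reflects tissue architecture: low-abundance
#' patterns and low-PSS (noise) patterns degrade domain clustering.  This
#' drops first the `N1` patterns with the smallest \eqn{\|w_i\|_2} (ties:
#' lower index dropped first), then from the remainder the `N2` patterns
#' with the lowest PSS (same tie-break), returning the surviving columns of
#' `W` in their original order.
#'
#' @param model a fitted [spatmf()] model.
#' @param N1,N2 counts of patterns to drop; defaults from the model's
#'   params (`N1 = max(0, r - 5 - n_cluster)`, `N2 = 3`).
#' @return the reduced matrix `W*` with the kept pattern indices in the
#'   `"kept"` attribute.
#' @export
filter_patterns <- function(model, N1 = NULL, N2 = NULL) {
  N1 <- N1 %||% model$params$N1
  N2 <- N2 %||% model$params$N2
  r <- ncol(model$W)
  if (N1 + N2 >= r)
    stopf("N1 + N2 (%d) must be smaller than r (%d)", N1 + N2, r)
  norms <- sqrt(colSums(model$W^2))
  keep <- seq_len(r)
  if (N1 > 0) {
    drop1 <- keep[order(norms, keep)][seq_len(N1)]
    keep <- setdiff(keep, drop1)
  }
  if (N2 > 0) {
    drop2 <- keep[order(model$pss[keep], keep)][seq_len(N2)]
    keep <- setdiff(keep, drop2)
  }
  structure(model$W[, keep, drop = FALSE], kept = keep)
}

#' Identify spatial domains by clustering filtered patterns
#'
#' Runs seeded k-means (10 restarts, best inertia kept) on the rows of the
#' filtered pattern matrix `W*` (see [filter_patterns()]) to partition
#' spots into spatial domains.
#'
#' @param W_star spot-by-pattern matrix, typically from [filter_patterns()],
#'   or a fitted [spatmf()] model (filtered with its default `N1`, `N2`).
#' @param n_cluster number of domains; default from the model's params,
#'   else 8.
#' @param seed RNG seed (default 1).
#' @param nstart k-means restarts (default 10).
#' @return integer vector of domain labels (1-based), one per spot.
#' @export
cluster_domains <- function(W_star, n_cluster = NULL, seed = 1L,
                            nstart = 10L) {
  if (inherits(W_star, "spatmf")) {
    n_cluster <- n_cluster %||% W_star$params$n_cluster
    W_star <- filter_patterns(W_star)
  }
  n_cluster <- n_cluster %||% 8L
  if (n_cluster > nrow(W_star))
    stopf("n_cluster (%d) exceeds number of spots (%d)", n_cluster,
          nrow(W_star))
  if (nrow(unique(W_star)) < n_cluster)
    stopf("fewer distinct spot profiles (%d) than clusters (%d)",
          nrow(unique(W_star)), n_cluster)
  set.seed(seed)
  km <- kmeans(W_star, centers = n_cluster, nstart = nstart,
               iter.max = 100L)
  labels <- as.integer(km$cluster)
  names(labels) <- rownames(W_star)
  labels
}

#' Denoised expression matrix
#'
#' The reconstruction `W %*% H`: the expression each spot would show if it
#' followed the discovered low-dimensional spatial structure exactly.
#' Non-negative by construction.
#'
#' @param model a fitted [spatmf()] model.
#' @return n x p non-negative matrix.
#' @export
denoise <- function(model) fitted(model)

#' Spatial-autocorrelation gain from denoising
#'
#' Computes Moran's I per feature on the raw and the denoised matrix with
#' the same graph, and summarizes how many features gained spatial
#' coherence.
#'
#' @param model a fitted [spatmf()] model.
#' @param X,X_hat optional raw and denoised matrices (default: the model's
#'   data and reconstruction).
#' @param g optional [spatial_graph()] (default: the model's graph).
#' @return list with `per_feature` (data frame: `feature`, `morans_before`,
#'   `morans_after`, `delta`), `fraction_improved`, `mean_before`,
#'   `mean_after`.
#' @export
refinement_report <- function(model, X = NULL, X_hat = NULL, g = NULL) {
  X <- as.matrix(X %||% model$dataset$X)
  X_hat <- X_hat %||% denoise(model)
  g <- g %||% model$graph
  stopifnot(all(dim(X) == dim(X_hat)))
  before <- morans_i_columns(X, g)
  after <- morans_i_columns(X_hat, g)
  df <- data.frame(feature = colnames(X) %||% seq_len(ncol(X)),
                   morans_before = before, morans_after = after,
                   delta = after - before, row.names = NULL)
  list(per_feature = df,
       fraction_improved = mean(df$delta > 0),
       mean_before = mean(before), mean_after = mean(after))
}

#' Highly co-expressed feature pairs
#'
#' Pearson correlations over spots for all unordered pairs within a feature
#' subset, returning pairs whose correlation strictly exceeds the threshold,
#' sorted descending.  Zero-variance features are excluded and flagged in
#' the `"excluded"` attribute.
#'
#' @param X_hat expression matrix (typically denoised; spots x features).
#' @param feature_subset indices or names of at least 2 features.
#' @param threshold correlation cutoff (default 0.5).
#' @return data frame with columns `feature1`, `feature2`, `correlation`.
#' @export
coexpression_pairs <- function(X_hat, feature_subset, threshold = 0.5) {
  X_hat <- as.matrix(X_hat)
  if (length(feature_subset) < 2L)
    stopf("need at least 2 features in the subset")
  S <- X_hat[, feature_subset, drop = FALSE]
  sds <- apply(S, 2, sd)
  excluded <- colnames(S)[sds == 0] %||% which(sds == 0)
  S <- S[, sds > 0, drop = FALSE]
  if (ncol(S) < 2L)
    return(structure(data.frame(feature1 = character(0),
                                feature2 = character(0),
                                correlation = numeric(0)),
                     excluded = excluded))
  C <- cor(S)
  ut <- which(upper.tri(C) & C > threshold, arr.ind = TRUE)
  nm <- colnames(S) %||% as.character(seq_len(ncol(S)))
  df <- data.frame(feature1 = nm[ut[, 1]], feature2 = nm[ut[, 2]],
                   correlation = C[ut], row.names = NULL)
  df <- df[order(-df$correlation), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, excluded = excluded)
}
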