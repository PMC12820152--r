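#' Library-size normalization followed by log transform
#'
#' Scales each spot (row) to a common total `target_sum`, then applies
#' `log(1 + x)` elementwise — the standard normalization for sequencing-based
#' spatial data.  Zeros map to zeros and the output is non-negative.
#'
#' @param ds a [spatial_dataset()] of raw counts, or a bare matrix.
#' @param target_sum common row total after scaling (default 1e4).
#' @return the same type as the input, with `X` normalized.
#' @export
normalize_log_libsize <- function(ds, target_sum = 1e4) {
  is_ds <- inherits(ds, "spatial_dataset")
  X <- if (is_ds) ds$X else ds
  lib <- Matrix::rowSums(X)
  if (any(lib == 0))
    stopf("spot(s) with zero library size: %s",
          paste(which(lib == 0)[seq_len(min(5L, sum(lib == 0)))],
                collapse = ", "))
  Xn <- log1p(as.matrix(X) * (target_sum / lib))
  dimnames(Xn) <- dimnames(as.matrix(X))
  if (is_ds) { ds$X <- Xn; ds } else Xn
}

#' Moran's I spatial autocorrelation
#'
#' Computes Moran's I of a per-spot value vector on a spatial graph, using
#' the graph's weighted adjacency as the spatial weight matrix:
#' \deqn{I = \frac{n}{S_0} \frac{\sum_{ij} A_{ij} (v_i - \bar v)(v_j - \bar
#' v)}{\sum_i (v_i - \bar v)^2}, \quad S_0 = \sum_{ij} A_{ij}.}
#' Values near +1 indicate smooth spatial structure, near 0 spatial noise,
#' negative values checkerboard-like alternation.  A constant vector returns
#' 0 by convention.
#'
#' @param values numeric vector, one value per spot.
#' @param g a [spatial_graph()] over the same spots.
#' @return scalar Moran's I.
#' @export
morans_i <- function(values, g) {
  n <- length(values)
  if (n != nrow(g$A)) stopf("length(values) must equal number of spots")
  s0 <- sum(g$A)
  if (s0 == 0) stopf("Moran's I undefined on an edgeless graph")
  z <- values - mean(values)
  denom <- sum(z^2)
  if (denom == 0) return(0)
  num <- as.numeric(Matrix::crossprod(z, g$A %*% z))
  (n / s0) * num / denom
}

# Moran's I for every column of a matrix on the same graph (vectorized)
morans_i_columns <- function(X, g) {
  X <- as.matrix(X)
  n <- nrow(X)
  s0 <- sum(g$A)
  if (s0 == 0) stopf("Moran's I undefined on an edgeless graph")
  Z <- sweep(X, 2, colMeans(X))
  num <- colSums(Z * as.matrix(g$A %*% Z))
  den <- colSums(Z^2)
  ifelse(den == 0, 0, (n / s0) * num / den)
}

#' Select features with the highest spatial autocorrelation
#'
#' Ranks features by Moran's I on the analysis graph and returns the indices
#' of the top `k`, in descending order of Moran's I; ties are broken by
#' ascending original index.
#'
#' @param ds a [spatial_dataset()].
#' @param g a [spatial_graph()] over the same spots.
#' @param k number of features to keep (`k <= p`).
#' @return integer vector of feature indices, length `k`, with the Moran's I
#'   values attached as the `"morans_i"` attribute.
#' @export
select_spatial_features <- function(ds, g, k) {
  p <- ncol(ds$X)
  if (k > p) stopf("k (%d) exceeds number of features (%d)", k, p)
  mi <- morans_i_columns(ds$X, g)
  ord <- order(-mi, seq_len(p))[seq_len(k)]
  structure(ord, morans_i = mi[ord])
}

#' Smooth expression by neighbor averaging
#'
#' Replaces each spot's expression by the unweighted mean over its closed
#' neighborhood (itself plus all graph neighbors).  Isolated spots pass
#' through unchanged.  Used for sequencing-based platforms before fitting.
#'
#' @param ds a [spatial_dataset()].
#' @param g a [spatial_graph()] over the same spots.
#' @return the dataset with smoothed `X`.
#' @export
neighbor_average <- function(ds, g) {
  n <- nrow(ds$X)
  M <- (g$A > 0) * 1 + Matrix::Diagonal(n)
  M <- M / Matrix::rowSums(M)
  Xs <- as.matrix(M %*% ds$X)
  dimnames(Xs) <- dimnames(as.matrix(ds$X))
  ds$X <- Xs
  ds
}

#' Concatenate modality matrices over the same spots
#'
#' Horizontally concatenates several datasets measured on the same spots
#' (e.g. RNA + protein, RNA + ATAC), preserving input order.  Each modality
#' should already be preprocessed independently.  The modality of each
#' output feature is recorded in `modality_tags`.
#'
#' @param datasets list of [spatial_dataset()]s with identical `spot_ids`
#'   in identical order.
#' @return a single [spatial_dataset()] with `p = sum(p_m)` features.
#' @export
concat_modalities <- function(datasets) {
  stopifnot(length(datasets) >= 1L)
  if (length(datasets) == 1L) return(datasets[[1L]])
  ref <- datasets[[1L]]
  for (m in seq_along(datasets)[-1L]) {
    ids <- datasets[[m]]$spot_ids
    if (length(ids) != length(ref$spot_ids))
      stopf("modality %d has %d spots, expected %d", m, length(ids),
            length(ref$spot_ids))
    diffm <- which(ids != ref$spot_ids)
    if (length(diffm))
      stopf("modality %d spot mismatch at position %d ('%s' vs '%s')",
            m, diffm[1], ids[diffm[1]], ref$spot_ids[diffm[1]])
  }
  X <- do.call(cbind, lapply(datasets, function(d) as.matrix(d$X)))
  spatial_dataset(
    X, ref$coords, spot_ids = ref$spot_ids,
    feature_ids = make.unique(
      unlist(lapply(datasets, `[[`, "feature_ids"), use.names = FALSE)),
    modality_tags = unlist(lapply(datasets, `[[`, "modality_tags"),
                           use.names = FALSE),
    validate = FALSE)
}
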