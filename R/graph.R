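#' Neighborhood radius from the coordinate bounding box
#'
#' Computes the graph radius r* = lambda * sqrt((x_max - x_min) *
#' (y_max - y_min) / n), i.e. `lambda` times the side of the average square
#' area per spot; a user-supplied `predefined` radius is passed through
#' unchanged.
#'
#' @param coords n x 2 numeric matrix of spot positions.
#' @param lambda positive scale parameter (default 1.2).
#' @param predefined optional positive radius overriding the formula.
#' @return a positive scalar radius.
#' @export
#' @examples
#' g <- as.matrix(expand.grid(x = 0:9, y = 0:9))
#' compute_radius(g, lambda = 1.2)   # 1.08
compute_radius <- function(coords, lambda = 1.2, predefined = NULL) {
  if (!is.null(predefined)) {
    if (predefined <= 0) stopf("predefined radius must be positive")
    return(predefined)
  }
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2L) stopf("need at least 2 spots to compute a radius")
  area <- diff(range(coords[, 1])) * diff(range(coords[, 2]))
  if (area <= 0)
    stopf(paste("degenerate (zero-area) coordinate bounding box;",
                "supply a predefined radius"))
  lambda * sqrt(area / n)
}

# Cosine distance between rows of X: 1 - cos similarity.  All-zero rows get
# distance 1 to everything (maximal dissimilarity, never NaN).
cosine_distance_rows <- function(X, Y = NULL) {
  X <- as.matrix(X)
  nx <- sqrt(rowSums(X^2))
  if (is.null(Y)) {
    S <- tcrossprod(X / pmax(nx, .Machine$double.xmin))
    S[nx == 0, ] <- 0
    S[, nx == 0] <- 0
    d <- 1 - S
    diag(d) <- 0
    pmin(pmax(d, 0), 2)
  } else {
    Y <- as.matrix(Y)
    ny <- sqrt(rowSums(Y^2))
    S <- tcrossprod(X / pmax(nx, .Machine$double.xmin),
                    Y / pmax(ny, .Machine$double.xmin))
    S[nx == 0, ] <- 0
    S[, ny == 0] <- 0
    pmin(pmax(1 - S, 0), 2)
  }
}

#' Build the expression-weighted spatial neighborhood graph
#'
#' Connects spots whose Euclidean distance is strictly below the radius r*
#' (see [compute_radius()]) and weights each edge by the similarity of the
#' two spots' expression profiles: `A_ij = exp(-d_cos(i,j)^2 / (2 d*^2))`,
#' where `d_cos` is the cosine distance between expression rows and the
#' bandwidth `d*` is the 1/n_c quantile of the cosine-distance population.
#' The graph Laplacian `L = D - A` drives the spatial regularization in
#' [spatmf()].
#'
#' For up to `quantile_cutoff` spots the quantile is taken over all
#' off-diagonal pairwise cosine distances (the formula as stated); for larger
#' datasets it is taken over the cosine distances of spatially adjacent pairs
#' only, which scales linearly.  `quantile_pop` forces either mode.
#' Self-pairs are excluded from both the graph (no self-loops) and the
#' quantile population.  If the quantile is zero (duplicated profiles) the
#' smallest positive observed distance is used instead, with a warning; if
#' every distance is zero the weights degrade to a radius indicator.
#'
#' @param ds a [spatial_dataset()].
#' @param lambda radius scale (default 1.2); see [compute_radius()].
#' @param n_c estimated number of clusters; the bandwidth is the `1/n_c`
#'   quantile of the cosine distances (default 8).
#' @param predefined_radius optional fixed radius overriding the formula.
#' @param quantile_pop `"auto"` (default), `"all"` or `"edges"`: population
#'   over which the bandwidth quantile is computed.
#' @param quantile_cutoff spot count above which `"auto"` switches from all
#'   pairs to adjacent pairs (default 5000).
#' @return An object of class `"spatial_graph"`: list with sparse symmetric
#'   adjacency `A` (zero diagonal, weights in (0, 1]), diagonal degree matrix
#'   `D`, Laplacian `L = D - A`, and scalars `radius`, `lambda`, `bandwidth`,
#'   `n_c`.
#' @seealso [neighbor_stats()], [morans_i()], [spatmf()]
#' @export
spatial_graph <- function(ds, lambda = 1.2, n_c = 8,
                          predefined_radius = NULL,
                          quantile_pop = c("auto", "all", "edges"),
                          quantile_cutoff = 5000) {
  quantile_pop <- match.arg(quantile_pop)
  coords <- as.matrix(ds$coords)
  n <- nrow(coords)
  rstar <- compute_radius(coords, lambda, predefined_radius)

  # spatial edges: 0 < d_euc < r*, strict at the radius
  ed <- edges_within_radius(coords, rstar)
  if (nrow(ed) == 0L)
    stopf(paste("spatial graph has no edges at radius %.4g;",
                "increase lambda or supply a larger predefined radius"),
          rstar)
  dcos_edges <- cosine_distance_pairs(ds$X, ed[, 1], ed[, 2])

  use_all <- quantile_pop == "all" ||
    (quantile_pop == "auto" && n <= quantile_cutoff)
  pop <- if (use_all) {
    Dc <- cosine_distance_rows(ds$X)
    Dc[upper.tri(Dc)]
  } else dcos_edges
  dstar <- unname(stats::quantile(pop, probs = 1 / n_c))
  if (dstar == 0) {
    pos <- pop[pop > 0]
    dstar <- if (length(pos)) min(pos) else 1
    warnf("bandwidth quantile is 0 (duplicated profiles); floored to %.4g",
          dstar)
  }

  w <- exp(-dcos_edges^2 / (2 * dstar^2))
  A <- Matrix::sparseMatrix(i = c(ed[, 1], ed[, 2]),
                            j = c(ed[, 2], ed[, 1]),
                            x = c(w, w), dims = c(n, n),
                            dimnames = list(ds$spot_ids, ds$spot_ids))
  deg <- Matrix::rowSums(A)
  D <- Matrix::Diagonal(n, deg)
  structure(list(A = A, D = D, L = D - A,
                 radius = rstar, lambda = lambda, bandwidth = dstar,
                 n_c = n_c),
            class = "spatial_graph")
}

# all unordered pairs (i < j) with 0 < euclidean distance < radius, found
# block-wise so no dense n x n matrix is materialized
edges_within_radius <- function(coords, radius, block = 2048L) {
  n <- nrow(coords)
  out_i <- list(); out_j <- list(); k <- 0L
  for (s in seq(1L, n, by = block)) {
    e <- min(n, s + block - 1L)
    d2 <- outer(coords[s:e, 1], coords[, 1], "-")^2 +
          outer(coords[s:e, 2], coords[, 2], "-")^2
    hit <- which(d2 < radius^2 & d2 > 0, arr.ind = TRUE)
    if (nrow(hit)) {
      gi <- hit[, 1] + s - 1L
      gj <- hit[, 2]
      keep <- gi < gj
      if (any(keep)) {
        k <- k + 1L
        out_i[[k]] <- gi[keep]; out_j[[k]] <- gj[keep]
      }
    }
  }
  cbind(i = unlist(out_i) %||% integer(0),
        j = unlist(out_j) %||% integer(0))
}

# cosine distances for specific row pairs of X
cosine_distance_pairs <- function(X, i, j) {
  X <- as.matrix(X)
  nr <- sqrt(rowSums(X^2))
  num <- rowSums(X[i, , drop = FALSE] * X[j, , drop = FALSE])
  den <- nr[i] * nr[j]
  d <- ifelse(den > 0, 1 - num / den, 1)
  pmin(pmax(d, 0), 2)
}

#' Neighbor-count diagnostics for a spatial graph
#'
#' Reports the per-spot neighbor count (number of incident positive-weight
#' edges), its mean and histogram, and whether the mean falls outside the
#' recommended 6-10 range; when it does, the radius scale `lambda` should be
#' adjusted before fitting.
#'
#' @param g a [spatial_graph()].
#' @return list with `mean_neighbors`, `histogram` (table of degrees) and
#'   `flag` (`TRUE` when the mean is outside `[6, 10]`).
#' @export
neighbor_stats <- function(g) {
  deg <- Matrix::rowSums(g$A > 0)
  m <- mean(deg)
  list(mean_neighbors = m,
       histogram = table(factor(deg, levels = 0:max(deg))),
       flag = m < 6 || m > 10)
}

#' @export
print.spatial_graph <- function(x, ...) {
  ns <- neighbor_stats(x)
  cat(sprintf("spatial_graph: %d spots, %d edges\n",
              nrow(x$A), Matrix::nnzero(x$A) / 2))
  cat(sprintf("  radius %.4g (lambda = %.3g), bandwidth d* = %.4g\n",
              x$radius, x$lambda, x$bandwidth))
  cat(sprintf("  mean neighbors %.2f%s\n", ns$mean_neighbors,
              if (ns$flag) "  [outside recommended 6-10: adjust lambda]"
              else ""))
  invisible(x)
}

#' Export graph edges as a coordinate-triplet table
#'
#' @param g a [spatial_graph()].
#' @param file optional path; when given, the triplets are written as TSV
#'   with columns `i`, `j`, `weight` (unordered pairs, i < j).
#' @return invisibly, the data frame of edge triplets.
#' @export
graph_edges <- function(g, file = NULL) {
  trip <- Matrix::summary(Matrix::triu(g$A))
  df <- data.frame(i = trip$i, j = trip$j, weight = trip$x)
  df <- df[order(df$i, df$j), , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(file))
    write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
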