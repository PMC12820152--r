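#' Adjusted Rand index between two labelings
#'
#' Chance-adjusted agreement between two partitions of the same spots:
#' 1 for identical partitions (up to label permutation), about 0 for
#' independent ones.
#'
#' @param a,b integer or factor vectors of equal length.
#' @return scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  mclust::adjustedRandIndex(a, b)
}

# Exact minimum-cost assignment (Hungarian / shortest augmenting path,
# O(n^3)).  cost may be rectangular with nrow <= ncol; returns for each row
# the assigned column.  Used to match recovered patterns to planted ones.
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost); m <- ncol(cost)
  if (n > m) stopf("assignment needs nrow <= ncol")
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1L); v <- numeric(m + 1L)
  p <- integer(m + 1L)            # p[j]: row assigned to column j (0 = none)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L                       # columns are offset by 1 (j0=1 means virtual)
    minv <- rep(INF, m + 1L)
    used <- rep(FALSE, m + 1L)
    way <- integer(m + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0L
      for (j in seq_len(m) + 1L) {
        if (used[j]) next
        cur <- cost[i0, j - 1L] - u[i0 + 0L] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(m + 1L)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(m) + 1L) if (p[j] > 0L) assign[p[j]] <- j - 1L
  assign
}

#' Match recovered patterns to planted patterns
#'
#' Finds the one-to-one assignment of planted pattern columns to distinct
#' recovered columns that maximizes the total cosine similarity (exact
#' assignment, not greedy), and reports the per-pattern and mean matched
#' similarity.
#'
#' @param W_hat recovered n x r matrix (columns = patterns).
#' @param W_true planted n x r_true matrix, `r_true <= r`.
#' @return list with `assignment` (recovered column index per planted
#'   pattern), `cosine` (per planted pattern) and `mean_cosine`.
#' @export
match_patterns <- function(W_hat, W_true) {
  S <- cosine_similarity_cols(W_true, W_hat)   # r_true x r
  a <- solve_assignment(1 - S)
  cs <- S[cbind(seq_len(nrow(S)), a)]
  list(assignment = a, cosine = cs, mean_cosine = mean(cs))
}

cosine_similarity_cols <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  na <- sqrt(colSums(A^2)); nb <- sqrt(colSums(B^2))
  S <- crossprod(A, B) / (pmax(na, .Machine$double.xmin) %o%
                            pmax(nb, .Machine$double.xmin))
  S[na == 0, ] <- 0
  S[, nb == 0] <- 0
  S
}

#' Precision and recall of an index selection
#'
#' @param selected integer vector of selected indices.
#' @param truth integer vector of true-positive indices.
#' @param p total number of candidates (unused, kept for clarity).
#' @return list with `precision`, `recall`, `n_selected`, `n_true`.
#' @export
selection_scores <- function(selected, truth, p = NULL) {
  tp <- length(intersect(selected, truth))
  list(precision = if (length(selected)) tp / length(selected) else NA_real_,
       recall = if (length(truth)) tp / length(truth) else NA_real_,
       n_selected = length(selected), n_true = length(truth))
}

#' Score a fit against planted truth
#'
#' Runs the full downstream evaluation of a fitted model against the truth
#' produced by [simulate_layers()]: exact-assignment matched cosine
#' similarity of recovered vs planted pattern columns, adjusted Rand index
#' of the clustered domains vs planted labels, precision/recall of the SVG
#' selection, and the fraction of features whose Moran's I increases after
#' denoising.
#'
#' @param model a fitted [spatmf()] model.
#' @param truth the `truth` element from [simulate_layers()].
#' @param n_cluster domains to request; defaults to the planted band count.
#' @param seed seed for the domain k-means (default 1).
#' @return list with `mean_cosine`, `ari`, `svg_precision`, `svg_recall`,
#'   `fraction_morans_improved`, `domains`, `matching`.
#' @export
score_recovery <- function(model, truth, n_cluster = NULL, seed = 1L) {
  n_cluster <- n_cluster %||% max(truth$domain_labels)
  mt <- match_patterns(model$W, truth$W_true)
  W_star <- filter_patterns(
    model, N1 = max(0, ncol(model$W) - 5 - n_cluster),
    N2 = min(model$params$N2, ncol(model$W) - 1 -
               max(0, ncol(model$W) - 5 - n_cluster)))
  labels <- cluster_domains(W_star, n_cluster, seed = seed)
  svgs <- select_svgs(model)
  sc <- selection_scores(svgs, truth$svg_true)
  rr <- refinement_report(model)
  list(mean_cosine = mt$mean_cosine,
       ari = adjusted_rand_index(labels, truth$domain_labels),
       svg_precision = sc$precision, svg_recall = sc$recall,
       fraction_morans_improved = rr$fraction_improved,
       domains = labels, matching = mt)
}
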