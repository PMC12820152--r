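# Independent brute-force oracles (explicit loops, no shared code with the
# package internals) plus small fixture builders.

oracle_objective <- function(X, W, H, A, alpha, beta, gamma, pss) {
  X <- as.matrix(X); A <- as.matrix(A)
  n <- nrow(X); p <- ncol(X); r <- ncol(W)
  recon <- 0
  for (i in seq_len(n)) for (j in seq_len(p)) {
    pred <- 0
    for (k in seq_len(r)) pred <- pred + W[i, k] * H[k, j]
    recon <- recon + (X[i, j] - pred)^2
  }
  spatial <- 0   # tr(Omega W^T L W) = 1/2 sum_ij A_ij sum_k pss_k (W_ik-W_jk)^2
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (A[i, j] == 0) next
    for (k in seq_len(r))
      spatial <- spatial + 0.5 * A[i, j] * pss[k] * (W[i, k] - W[j, k])^2
  }
  spatial <- alpha * spatial
  sparsity <- beta * sum(abs(W))
  ortho <- 0
  for (i in seq_len(r - 1)) for (j in (i + 1):r)
    ortho <- ortho + sum(H[i, ] * H[j, ])^2
  ortho <- (gamma / 2) * ortho
  list(total = recon + spatial + sparsity + ortho, recon = recon,
       spatial = spatial, sparsity = sparsity, ortho = ortho)
}

oracle_morans <- function(v, A) {
  A <- as.matrix(A)
  n <- length(v)
  vb <- mean(v)
  s0 <- 0; num <- 0; den <- 0
  for (i in seq_len(n)) {
    den <- den + (v[i] - vb)^2
    for (j in seq_len(n)) {
      s0 <- s0 + A[i, j]
      num <- num + A[i, j] * (v[i] - vb) * (v[j] - vb)
    }
  }
  if (den == 0) return(0)
  (n / s0) * num / den
}

oracle_pss <- function(X, W, H) {
  X <- as.matrix(X)
  r <- ncol(W)
  out <- numeric(r)
  for (k in seq_len(r)) {
    w1 <- sum(abs(W[, k]))
    if (w1 == 0) next
    pk <- as.numeric(t(X) %*% W[, k]) / w1
    hk <- H[k, ]
    d <- sqrt(sum(pk^2)) * sqrt(sum(hk^2))
    if (d == 0) next
    out[k] <- sum(pk * hk) / d
  }
  out
}

oracle_pr <- function(W, H) {
  r <- nrow(H); p <- ncol(H)
  Pr <- matrix(0, r, p)
  for (j in seq_len(p)) {
    col <- numeric(r)
    for (k in seq_len(r)) col[k] <- sqrt(sum(W[, k]^2)) * H[k, j]
    s <- sum(abs(col))
    if (s > 0) Pr[, j] <- col / s
  }
  Pr
}

oracle_err <- function(X, W, H) {
  X <- as.matrix(X)
  p <- ncol(X)
  out <- numeric(p)
  for (j in seq_len(p)) {
    pred <- as.numeric(W %*% H[, j])
    nx <- sqrt(sum(X[, j]^2))
    out[j] <- if (nx == 0) Inf else sqrt(sum((X[, j] - pred)^2)) / nx
  }
  out
}

# exhaustive minimum-cost assignment for small rectangular cost matrices
brute_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  best <- Inf; best_a <- NULL
  for (cols in utils::combn(m, n, simplify = FALSE)) {
    for (q in perms(cols)) {
      v <- sum(cost[cbind(seq_len(n), q)])
      if (v < best) { best <- v; best_a <- q }
    }
  }
  list(cost = best, assignment = best_a)
}

# small random non-negative dataset on jittered grid coordinates
rand_dataset <- function(n = 12, p = 8, seed = 1, scale = 3) {
  set.seed(seed)
  side <- ceiling(sqrt(n))
  coords <- as.matrix(expand.grid(x = seq_len(side) - 1,
                                  y = seq_len(side) - 1))[seq_len(n), ]
  coords <- coords + matrix(runif(2 * n, -0.05, 0.05), n, 2)
  X <- matrix(runif(n * p, 0, scale), n, p)
  spatial_dataset(X, coords, validate = FALSE)
}

rand_graph <- function(ds, radius = 1.6) {
  spatial_graph(ds, predefined_radius = radius)
}

# graph from an explicit dense adjacency (for hand-built cases)
graph_from_adjacency <- function(A, ids = NULL) {
  A <- methods::as(Matrix::Matrix(A, sparse = TRUE), "generalMatrix")
  n <- nrow(A)
  D <- Matrix::Diagonal(n, Matrix::rowSums(A))
  structure(list(A = A, D = D, L = D - A, radius = NA_real_,
                 lambda = NA_real_, bandwidth = NA_real_, n_c = NA_real_),
            class = "spatial_graph")
}
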