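#' Control parameters for the factorization
#'
#' Assembles the full hyperparameter set with the documented defaults.  The
#' spatial weight `alpha` is the one genuinely user-chosen parameter
#' (recommended 0.3-1.0 for tissue-level domain analysis, 0.1-0.3 for
#' high-resolution niches); the others follow fixed rules unless overridden:
#' sparsity `beta = alpha / 15`, orthogonality `gamma = 1.5e-4 * p` (scales
#' with feature count to offset the dimension dependence of inner products),
#' `r = 30` patterns, graph scale `lambda = 1.2`, pattern-specific threshold
#' `eps_pattern = 0.3`, SVG threshold `eps_svg = 0.7`, domain filtering
#' `N1 = max(0, r - 5 - n_cluster)` and `N2 = 3`, and
#' `n_c = n_cluster = 8`.
#'
#' @param alpha spatial regularization weight (default 0.5).
#' @param p number of features; required to resolve the default `gamma`.
#' @param beta sparsity weight; default `alpha / 15`.
#' @param gamma metagene orthogonality weight; default `1.5e-4 * p`.
#' @param r number of patterns (default 30).
#' @param max_iter maximum outer iterations (default 200).
#' @param tol relative objective-change convergence tolerance (default 1e-5).
#' @param seed RNG seed for the random initialization (default 1).
#' @param eps_pattern pattern-specific gene threshold on normalized
#'   contributions (default 0.3).
#' @param eps_svg SVG threshold on relative reconstruction error
#'   (default 0.7).
#' @param n_cluster target number of spatial domains (default 8).
#' @param N1 count of smallest-norm patterns dropped before clustering;
#'   default `max(0, r - 5 - n_cluster)`.
#' @param N2 count of lowest-PSS patterns dropped next (default 3).
#' @param lambda graph radius scale (default 1.2).
#' @param n_c quantile parameter for the graph bandwidth; default
#'   `n_cluster`.
#' @return a list of class `"spatmf_params"`.
#' @export
#' @examples
#' pr <- spatmf_params(alpha = 0.6, p = 2000)
#' pr$beta * 15 == pr$alpha
spatmf_params <- function(alpha = 0.5, p = NULL, beta = alpha / 15,
                          gamma = if (is.null(p)) NULL else 1.5e-4 * p,
                          r = 30, max_iter = 200, tol = 1e-5, seed = 1,
                          eps_pattern = 0.3, eps_svg = 0.7,
                          n_cluster = 8, N1 = max(0, r - 5 - n_cluster),
                          N2 = 3, lambda = 1.2, n_c = n_cluster) {
  if (is.null(gamma))
    stopf("supply p (feature count) or gamma explicitly")
  stopifnot(alpha >= 0, beta >= 0, gamma >= 0, r >= 1,
            eps_pattern > 0, eps_pattern < 1, eps_svg > 0,
            N1 >= 0, N2 >= 0, max_iter >= 1, tol > 0)
  if (N1 + N2 >= r)
    stopf("N1 + N2 (%d) must be smaller than r (%d)", N1 + N2, r)
  structure(list(alpha = alpha, beta = beta, gamma = gamma, r = as.integer(r),
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed),
                 eps_pattern = eps_pattern, eps_svg = eps_svg,
                 n_cluster = as.integer(n_cluster),
                 N1 = as.integer(N1), N2 = as.integer(N2),
                 lambda = lambda, n_c = n_c),
            class = "spatmf_params")
}

#' Objective function of the factorization
#'
#' Evaluates the penalized reconstruction objective
#' \deqn{\|X - WH\|_F^2 + \alpha\,\mathrm{tr}(\Omega W^\top L W) +
#'   \beta \|W\|_1 + \frac{\gamma}{2}\sum_{i<j} \langle h_i, h_j\rangle^2}
#' where \eqn{\Omega = \mathrm{diag}(pss)} weights the graph smoothing per
#' pattern, \eqn{\|W\|_1} promotes localized sparse patterns, and the last
#' term penalizes similarity between metagene signatures (rows of H).
#'
#' @param X n x p expression matrix.
#' @param W n x r non-negative pattern matrix.
#' @param H r x p non-negative metagene matrix.
#' @param g a [spatial_graph()] (only `L` is used).
#' @param params a [spatmf_params()] (uses `alpha`, `beta`, `gamma`).
#' @param pss length-r vector of pattern significance scores in `[0, 1]`.
#' @return list with components `total`, `recon`, `spatial`, `sparsity`,
#'   `ortho`; `total` is their sum.
#' @export
spatmf_objective <- function(X, W, H, g, params, pss) {
  R <- as.matrix(X) - W %*% H
  recon <- sum(R^2)
  LW <- as.matrix(g$L %*% W)
  spatial <- params$alpha * sum(pss * colSums(W * LW))
  sparsity <- params$beta * sum(abs(W))
  G <- tcrossprod(H)
  ortho <- (params$gamma / 2) * (sum(G^2) - sum(diag(G)^2)) / 2
  list(total = recon + spatial + sparsity + ortho,
       recon = recon, spatial = spatial, sparsity = sparsity, ortho = ortho)
}

#' Pattern significance scores
#'
#' For each pattern i, `p_i = X^T w_i / ||w_i||_1` is the mean expression
#' profile over the locations where the pattern is active, and
#' `PSS_i = <p_i, h_i> / (||p_i||_2 ||h_i||_2)` is the cosine similarity
#' between that observed profile and the pattern's metagene signature.
#' High PSS indicates the pattern's signature matches what is actually
#' expressed where the pattern lives; low PSS flags noise components.
#' Degenerate patterns (zero `w_i`, `h_i` or `p_i`) score 0 by convention.
#' Scores lie in `[0, 1]` for non-negative inputs.
#'
#' @inheritParams spatmf_objective
#' @return length-r numeric vector of scores.
#' @export
compute_pss <- function(X, W, H) {
  r <- ncol(W)
  P <- crossprod(as.matrix(X), W)            # p x r, columns X^T w_i
  w1 <- colSums(abs(W))
  out <- numeric(r)
  for (i in seq_len(r)) {
    if (w1[i] == 0) next
    pi <- P[, i] / w1[i]
    hi <- H[i, ]
    np <- sqrt(sum(pi^2)); nh <- sqrt(sum(hi^2))
    if (np == 0 || nh == 0) next
    out[i] <- sum(pi * hi) / (np * nh)
  }
  out
}

# One multiplicative W step.  Derived from the KKT conditions of the
# objective: the gradient 2(WHH^T - XH^T) + 2*alpha*L W Omega + beta splits
# into positive and negative parts, giving
#   W <- W * (XH^T + alpha*AW*Omega) / (WHH^T + alpha*DW*Omega + beta/2 + d)
# with a small floor d guarding the division.  Zeros are absorbing and the
# step never increases the objective when Omega (pss) is held fixed.
update_w <- function(X, W, H, g, params, pss, delta = 1e-12) {
  HHt <- tcrossprod(H)
  num <- as.matrix(X %*% t(H)) +
    params$alpha * sweep(as.matrix(g$A %*% W), 2, pss, `*`)
  den <- W %*% HHt +
    params$alpha * sweep(as.matrix(g$D %*% W), 2, pss, `*`) +
    params$beta / 2 + delta
  Wn <- W * num / den
  if (any(!is.finite(Wn))) {
    bad <- which(!is.finite(Wn), arr.ind = TRUE)[1, ]
    stopf("non-finite W update at entry (%d,%d)", bad[1], bad[2])
  }
  Wn
}

# One multiplicative H step.  KKT split of the gradient
# 2(W^TWH - W^TX) + gamma*(HH^T H - diag(HH^T) H):
#   H <- H * (W^TX) / (W^TWH + (gamma/2)(HH^T H - diag(HH^T) H) + d)
# The orthogonality part sums <h_i, h_k> H_kj over k != i, coupling rows.
update_h <- function(X, W, H, params, delta = 1e-12) {
  num <- crossprod(W, as.matrix(X))
  G <- tcrossprod(H)
  ortho <- G %*% H - diag(G) * H
  den <- crossprod(W) %*% H + (params$gamma / 2) * ortho + delta
  Hn <- H * num / den
  if (any(!is.finite(Hn))) {
    bad <- which(!is.finite(Hn), arr.ind = TRUE)[1, ]
    stopf("non-finite H update at entry (%d,%d)", bad[1], bad[2])
  }
  Hn
}

# Shared fitting engine for one or several slices.  Slices share H; each
# slice keeps its own W_s, graph and PSS vector.  PSS is refreshed once per
# outer iteration, before the W steps.
fit_engine <- function(Xs, graphs, params, trace_every = 1L) {
  M <- length(Xs)
  p <- ncol(Xs[[1L]])
  r <- params$r
  set.seed(params$seed)
  scl <- sqrt(mean(vapply(Xs, function(X) mean(as.matrix(X)), 0)) / r)
  Ws <- lapply(Xs, function(X)
    matrix(runif(nrow(X) * r), nrow(X), r) * scl)
  H <- matrix(runif(r * p), r, p) * scl

  trace <- vector("list", params$max_iter)
  prev <- Inf
  iters <- 0L
  pss_list <- NULL
  for (it in seq_len(params$max_iter)) {
    pss_list <- lapply(seq_len(M), function(s)
      compute_pss(Xs[[s]], Ws[[s]], H))
    for (s in seq_len(M))
      Ws[[s]] <- update_w(Xs[[s]], Ws[[s]], H, graphs[[s]], params,
                          pss_list[[s]])
    H <- update_h_multi(Xs, Ws, H, params)

    obj <- objective_multi(Xs, Ws, H, graphs, params, pss_list)
    if (!is.finite(obj$total))
      stopf("objective diverged (non-finite) at iteration %d", it)
    trace[[it]] <- c(iter = it, unlist(obj))
    iters <- it
    if (is.finite(prev) && prev > 0 &&
        abs(prev - obj$total) / prev < params$tol) break
    prev <- obj$total
  }
  trace <- as.data.frame(do.call(rbind, trace[seq_len(iters)]))
  list(Ws = Ws, H = H, pss_list = pss_list, trace = trace,
       converged = iters < params$max_iter, iterations = iters)
}

# H step aggregating all slices: numerator sum_s W_s^T X_s, denominator
# sum_s W_s^T W_s H plus the shared orthogonality term.
update_h_multi <- function(Xs, Ws, H, params, delta = 1e-12) {
  num <- Reduce(`+`, Map(function(X, W) crossprod(W, as.matrix(X)), Xs, Ws))
  WtW <- Reduce(`+`, lapply(Ws, crossprod))
  G <- tcrossprod(H)
  den <- WtW %*% H + (params$gamma / 2) * (G %*% H - diag(G) * H) + delta
  Hn <- H * num / den
  if (any(!is.finite(Hn))) stopf("non-finite H update (multislice)")
  Hn
}

objective_multi <- function(Xs, Ws, H, graphs, params, pss_list) {
  parts <- Map(function(X, W, g, pss) {
    R <- as.matrix(X) - W %*% H
    LW <- as.matrix(g$L %*% W)
    c(recon = sum(R^2),
      spatial = params$alpha * sum(pss * colSums(W * LW)),
      sparsity = params$beta * sum(abs(W)))
  }, Xs, Ws, graphs, pss_list)
  s <- Reduce(`+`, parts)
  G <- tcrossprod(H)
  ortho <- (params$gamma / 2) * (sum(G^2) - sum(diag(G)^2)) / 2
  list(total = unname(s["recon"] + s["spatial"] + s["sparsity"]) + ortho,
       recon = unname(s["recon"]), spatial = unname(s["spatial"]),
       sparsity = unname(s["sparsity"]), ortho = ortho)
}

#' Fit the spatial metagene factorization
#'
#' Factorizes a non-negative spot-by-feature expression matrix as
#' \eqn{X \approx W H} with `W` (spots x r) holding spatial metagene
#' expression patterns and `H` (r x p) the metagene signatures, minimizing
#' the graph-regularized objective of [spatmf_objective()] by seeded
#' multiplicative updates.  The per-pattern spatial weights
#' \eqn{\Omega = \mathrm{diag}(PSS)} are refreshed once per outer iteration
#' (see [compute_pss()]), so coherent patterns are smoothed strongly while
#' noise components are left to be shrunk away by the sparsity penalty.
#'
#' Iteration stops when the relative change of the total objective falls
#' below `params$tol` or after `params$max_iter` iterations.  `W` and `H`
#' are initialized `Uniform(0,1) * sqrt(mean(X)/r)` from `params$seed`, so
#' fits are bit-reproducible.  Returned patterns are ordered by descending
#' PSS.
#'
#' @param ds a [spatial_dataset()] (preprocessed as appropriate for the
#'   platform; see [normalize_log_libsize()], [neighbor_average()]).
#' @param graph a [spatial_graph()] over the same spots; built with default
#'   settings from `ds` when omitted.
#' @param params a [spatmf_params()]; built from `...` when omitted.
#' @param ... used to build `params` when it is not supplied (e.g.
#'   `alpha = 0.5, r = 30, seed = 1`).
#' @return An object of class `"spatmf"`: list with `W`, `H`, `pss`
#'   (descending), `objective_trace` (data frame with columns `iter`,
#'   `total`, `recon`, `spatial`, `sparsity`, `ortho`), `params`, `graph`,
#'   `dataset`, `converged`, `iterations`.
#' @seealso [pattern_contributions()], [svg_scores()], [cluster_domains()],
#'   [denoise()], [spatmf_multi()]
#' @export
#' @examples
#' sim <- simulate_layers(n_side = 12, r_true = 3, p = 40,
#'                        n_background = 8, seed = 1)
#' g <- spatial_graph(sim$dataset, lambda = 1.8)
#' fit <- spatmf(sim$dataset, g, r = 5, alpha = 0.5, seed = 1, max_iter = 60)
#' fit
spatmf <- function(ds, graph = NULL, params = NULL, ...) {
  if (is.null(graph)) graph <- spatial_graph(ds)
  if (is.null(params)) params <- spatmf_params(p = ncol(ds$X), ...)
  check_fit_inputs(ds, graph)
  res <- fit_engine(list(ds$X), list(graph), params)
  ord <- order(-res$pss_list[[1L]], seq_len(params$r))
  structure(list(W = name_w(res$Ws[[1L]][, ord, drop = FALSE], ds),
                 H = name_h(res$H[ord, , drop = FALSE], ds),
                 pss = res$pss_list[[1L]][ord],
                 objective_trace = res$trace,
                 params = params, graph = graph, dataset = ds,
                 converged = res$converged, iterations = res$iterations),
            class = "spatmf")
}

#' Fit the multislice extension
#'
#' Jointly factorizes several tissue sections measured on the same feature
#' panel: each slice `s` keeps its own spatial pattern matrix `W_s` and
#' spatial graph, while a single metagene matrix `H` is shared across all
#' slices.  Each `W_s` follows the slice-specific multiplicative rule (with
#' slice PSS weights) and `H` aggregates all slices: numerator
#' \eqn{\sum_s W_s^\top X_s}, denominator \eqn{\sum_s W_s^\top W_s H} plus
#' the orthogonality term.  Convergence is judged on the summed objective.
#' With one slice this reduces exactly to [spatmf()] (same code path, same
#' RNG stream).
#'
#' @param datasets list of [spatial_dataset()]s with identical feature axes.
#' @param graphs list of [spatial_graph()]s, one per slice; built from each
#'   dataset when omitted.
#' @param params a [spatmf_params()]; built from `...` when omitted.
#' @param ... used to build `params` when it is not supplied.
#' @return An object of class `"spatmf_multi"`: list with `W_list`, `H`,
#'   `pss_list`, `objective_trace`, `params`, `graphs`, `datasets`,
#'   `converged`, `iterations`.  Pattern order (by descending mean PSS over
#'   slices) is shared across slices so columns remain comparable.
#' @export
spatmf_multi <- function(datasets, graphs = NULL, params = NULL, ...) {
  stopifnot(length(datasets) >= 1L)
  fid <- datasets[[1L]]$feature_ids
  for (s in seq_along(datasets)[-1L]) {
    if (!identical(datasets[[s]]$feature_ids, fid))
      stopf("slice %d feature axis differs from slice 1", s)
  }
  if (is.null(graphs)) graphs <- lapply(datasets, spatial_graph)
  if (length(graphs) != length(datasets))
    stopf("need one graph per slice")
  if (is.null(params)) params <- spatmf_params(p = length(fid), ...)
  Map(check_fit_inputs, datasets, graphs)
  res <- fit_engine(lapply(datasets, `[[`, "X"), graphs, params)
  mean_pss <- Reduce(`+`, res$pss_list) / length(res$pss_list)
  ord <- order(-mean_pss, seq_len(params$r))
  structure(list(
    W_list = Map(function(W, d) name_w(W[, ord, drop = FALSE], d),
                 res$Ws, datasets),
    H = name_h(res$H[ord, , drop = FALSE], datasets[[1L]]),
    pss_list = lapply(res$pss_list, `[`, ord),
    objective_trace = res$trace,
    params = params, graphs = graphs, datasets = datasets,
    converged = res$converged, iterations = res$iterations),
    class = "spatmf_multi")
}

check_fit_inputs <- function(ds, graph) {
  if (nrow(graph$A) != nrow(ds$X))
    stopf("graph has %d spots but dataset has %d", nrow(graph$A),
          nrow(ds$X))
  if (any(Matrix::colSums(ds$X) == 0))
    stopf("dataset has all-zero features; drop them first (see %s)",
          "drop_zero_features()")
  invisible(TRUE)
}

name_w <- function(W, ds) {
  dimnames(W) <- list(ds$spot_ids, paste0("pattern", seq_len(ncol(W))))
  W
}

name_h <- function(H, ds) {
  dimnames(H) <- list(paste0("pattern", seq_len(nrow(H))), ds$feature_ids)
  H
}
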