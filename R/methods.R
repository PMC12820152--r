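#' @export
print.spatmf <- function(x, ...) {
  cat(sprintf("spatmf fit: %d spots x %d features, r = %d patterns\n",
              nrow(x$W), ncol(x$H), ncol(x$W)))
  cat(sprintf("  %s after %d iterations (objective %.6g)\n",
              if (x$converged) "converged" else "stopped at max_iter",
              x$iterations, tail_total(x)))
  cat(sprintf("  alpha = %.3g, beta = %.4g, gamma = %.4g\n",
              x$params$alpha, x$params$beta, x$params$gamma))
  cat("  PSS (descending): ",
      paste(sprintf("%.3f", x$pss[seq_len(min(8L, length(x$pss)))]),
            collapse = " "),
      if (length(x$pss) > 8L) "...\n" else "\n")
  invisible(x)
}

tail_total <- function(x) {
  tr <- x$objective_trace
  tr$total[nrow(tr)]
}

#' Summarize a fitted spatial factorization
#'
#' @param object a fitted [spatmf()] model.
#' @param ... unused.
#' @return a list of class `"summary.spatmf"` with per-pattern statistics
#'   (PSS, l2-norm, sparsity of `w_i`), the final objective decomposition,
#'   and the relative reconstruction error.
#' @export
summary.spatmf <- function(object, ...) {
  tr <- object$objective_trace
  Xhat <- object$W %*% object$H
  X <- as.matrix(object$dataset$X)
  pat <- data.frame(
    pattern = colnames(object$W),
    pss = object$pss,
    w_norm = sqrt(colSums(object$W^2)),
    w_frac_zero = colMeans(object$W < 1e-10))
  structure(list(
    patterns = pat,
    objective = as.list(tr[nrow(tr), -1]),
    rel_recon_error = sqrt(sum((X - Xhat)^2) / sum(X^2)),
    iterations = object$iterations,
    converged = object$converged), class = "summary.spatmf")
}

#' @export
print.summary.spatmf <- function(x, ...) {
  cat(sprintf("relative reconstruction error: %.4f (%d iterations%s)\n",
              x$rel_recon_error, x$iterations,
              if (x$converged) "" else ", not converged"))
  cat("objective: ", paste(sprintf("%s = %.5g", names(x$objective),
                                   unlist(x$objective)), collapse = ", "),
      "\n")
  print(x$patterns, digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
coef.spatmf <- function(object, ...) object$H

#' @export
fitted.spatmf <- function(object, ...) object$W %*% object$H

#' @export
residuals.spatmf <- function(object, ...) {
  as.matrix(object$dataset$X) - fitted(object)
}

#' Predictions from a fitted spatial factorization
#'
#' @param object a fitted [spatmf()] model.
#' @param type `"denoised"` for the reconstruction `W %*% H` (default),
#'   `"patterns"` for the spot-by-pattern matrix `W`, or
#'   `"contributions"` for the normalized pattern-contribution matrix
#'   (see [pattern_contributions()]).
#' @param ... unused.
#' @return a matrix of the requested type.
#' @export
predict.spatmf <- function(object,
                           type = c("denoised", "patterns", "contributions"),
                           ...) {
  switch(match.arg(type),
         denoised = fitted(object),
         patterns = object$W,
         contributions = pattern_contributions(object))
}

#' Plot diagnostics for a fitted spatial factorization
#'
#' `which = "trace"` draws the objective decomposition across iterations;
#' `which = "pattern"` draws one spatial metagene expression pattern (a
#' column of `W`) over the spot coordinates.
#'
#' @param x a fitted [spatmf()] model.
#' @param which `"trace"` or `"pattern"`.
#' @param pattern pattern index to draw when `which = "pattern"`.
#' @param ... passed to the underlying plot call.
#' @return invisibly, `x`.
#' @export
plot.spatmf <- function(x, which = c("trace", "pattern"), pattern = 1L,
                        ...) {
  which <- match.arg(which)
  if (which == "trace") {
    tr <- x$objective_trace
    plot(tr$iter, tr$total, type = "l", lwd = 2, log = "y",
         xlab = "iteration", ylab = "objective (log scale)", ...)
    lines(tr$iter, tr$recon, lty = 2)
    legend("topright", c("total", "reconstruction"), lty = c(1, 2),
           lwd = c(2, 1), bty = "n")
  } else {
    co <- x$dataset$coords
    w <- x$W[, pattern]
    cols <- hcl.colors(100, "viridis")
    idx <- pmin(100L, 1L + floor(99 * (w - min(w)) /
                                   max(max(w) - min(w), 1e-12)))
    plot(co[, 1], co[, 2], col = cols[idx], pch = 15,
         xlab = "x", ylab = "y",
         main = sprintf("pattern %d (PSS %.3f)", pattern, x$pss[pattern]),
         ...)
  }
  invisible(x)
}

#' @export
print.spatmf_multi <- function(x, ...) {
  cat(sprintf(
    "spatmf multislice fit: %d slices, %d features, r = %d patterns\n",
    length(x$W_list), ncol(x$H), ncol(x$H) * 0 + nrow(x$H)))
  cat(sprintf("  spots per slice: %s\n",
              paste(vapply(x$W_list, nrow, 0L), collapse = ", ")))
  cat(sprintf("  %s after %d iterations (summed objective %.6g)\n",
              if (x$converged) "converged" else "stopped at max_iter",
              x$iterations, tail_total(x)))
  invisible(x)
}

#' @export
fitted.spatmf_multi <- function(object, ...) {
  lapply(object$W_list, function(W) W %*% object$H)
}

#' @export
coef.spatmf_multi <- function(object, ...) object$H

#' Extract one slice of a multislice fit as a single-slice model
#'
#' @param object a [spatmf_multi()] fit.
#' @param slice slice index.
#' @return an object of class `"spatmf"` for that slice (sharing `H`).
#' @export
slice_model <- function(object, slice = 1L) {
  stopifnot(inherits(object, "spatmf_multi"))
  structure(list(W = object$W_list[[slice]], H = object$H,
                 pss = object$pss_list[[slice]],
                 objective_trace = object$objective_trace,
                 params = object$params, graph = object$graphs[[slice]],
                 dataset = object$datasets[[slice]],
                 converged = object$converged,
                 iterations = object$iterations),
            class = "spatmf")
}
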