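#' Construct a spatial expression dataset
#'
#' Bundles a non-negative spot-by-feature expression matrix with 2-D spot
#' coordinates and feature/modality metadata.  This is the input container
#' for graph construction ([spatial_graph()]), preprocessing and model
#' fitting ([spatmf()]).
#'
#' Rows of `X` are spots (or cells, for imaging platforms) and columns are
#' features (genes, proteins, peaks).  Coordinates are continuous 2-D
#' Euclidean positions in whatever length unit the platform reports; no
#' array or pixel convention is imposed.  Spot order defines row order and
#' feature order defines column order throughout the package.
#'
#' @param X numeric matrix (dense or `Matrix` sparse), n spots x p features,
#'   non-negative and finite.
#' @param coords numeric matrix or data frame with n rows and 2 columns
#'   (x, y positions).
#' @param spot_ids character vector of n unique spot identifiers.  Defaults
#'   to rownames of `X` or `spot1..spotn`.
#' @param feature_ids character vector of p unique feature identifiers.
#'   Defaults to colnames of `X` or `feat1..featp`.
#' @param modality_tags character vector of length p naming the modality of
#'   each feature (e.g. `"rna"`, `"protein"`, `"atac"`).  A single value is
#'   recycled.
#' @param validate logical; if `TRUE` (default) the constructor stops on any
#'   invariant violation reported by [validate_dataset()].
#'
#' @return An object of class `"spatial_dataset"`: a list with elements
#'   `X`, `coords`, `spot_ids`, `feature_ids`, `modality_tags`.
#' @seealso [validate_dataset()], [spatial_graph()], [spatmf()]
#' @export
#' @examples
#' X <- matrix(rpois(20, 5), 4, 5)
#' ds <- spatial_dataset(X, cbind(x = c(0, 1, 0, 1), y = c(0, 0, 1, 1)))
#' ds
spatial_dataset <- function(X, coords, spot_ids = NULL, feature_ids = NULL,
                            modality_tags = "rna", validate = TRUE) {
  if (is.data.frame(X)) X <- as.matrix(X)
  coords <- as.matrix(coords)
  n <- nrow(X); p <- ncol(X)
  if (is.null(spot_ids)) {
    spot_ids <- rownames(X) %||% paste0("spot", seq_len(n))
  }
  if (is.null(feature_ids)) {
    feature_ids <- colnames(X) %||% paste0("feat", seq_len(p))
  }
  if (length(modality_tags) == 1L) modality_tags <- rep(modality_tags, p)
  colnames(coords) <- c("x", "y")[seq_len(min(2L, ncol(coords)))]
  ds <- structure(
    list(X = X, coords = coords,
         spot_ids = as.character(spot_ids),
         feature_ids = as.character(feature_ids),
         modality_tags = as.character(modality_tags)),
    class = "spatial_dataset")
  if (validate) {
    issues <- validate_dataset(ds)
    if (length(issues))
      stopf("invalid spatial_dataset:\n%s",
            paste0("  - ", issues, collapse = "\n"))
  }
  ds
}

#' Validate a spatial dataset
#'
#' Checks every structural invariant of a [spatial_dataset()] and returns a
#' character vector of human-readable issue descriptions (empty when the
#' dataset is well formed).  Each issue names the violated invariant and the
#' offending index so callers can locate the problem.  This is a reporting
#' operation: it never throws.
#'
#' Checked invariants: `X` non-negative and finite; at least 2 spots;
#' coordinates finite, 2-column, matching row count; unique spot and feature
#' ids; modality tags of length p.  Features with zero total expression and
#' duplicated coordinates are flagged (they are legal but degrade downstream
#' steps: all-zero columns make relative reconstruction errors undefined, and
#' duplicate coordinates create zero-distance pairs).
#'
#' @param ds a [spatial_dataset()] (or a bare list with the same fields).
#' @return character vector of issues; `character(0)` if all invariants hold.
#' @export
validate_dataset <- function(ds) {
  issues <- character(0)
  X <- ds$X
  n <- nrow(X); p <- ncol(X)
  if (is.null(n) || n < 2L)
    issues <- c(issues, sprintf("need at least 2 spots, got %s", n %||% 0))
  vals <- if (inherits(X, "sparseMatrix")) X@x else as.numeric(X)
  if (anyNA(vals) || any(!is.finite(vals))) {
    bad <- which(!is.finite(as.matrix(X)), arr.ind = TRUE)[1, , drop = TRUE]
    issues <- c(issues, sprintf(
      "expression must be finite; non-finite entry at (%d,%d)",
      bad[1], bad[2]))
  } else if (any(vals < 0)) {
    bad <- which(as.matrix(X) < 0, arr.ind = TRUE)[1, , drop = TRUE]
    issues <- c(issues, sprintf(
      "expression must be non-negative; negative entry at (%d,%d)",
      bad[1], bad[2]))
  }
  if (!is.matrix(ds$coords) || ncol(ds$coords) != 2L) {
    issues <- c(issues, "coords must be an n x 2 matrix")
  } else {
    if (nrow(ds$coords) != n)
      issues <- c(issues, sprintf(
        "coords rows (%d) do not match spots (%d)", nrow(ds$coords), n))
    if (any(!is.finite(ds$coords)))
      issues <- c(issues, sprintf(
        "coords must be finite; first bad row %d",
        which(!stats::complete.cases(ds$coords) |
                rowSums(!is.finite(ds$coords)) > 0)[1]))
    dup <- duplicated(ds$coords)
    if (any(dup))
      issues <- c(issues, sprintf(
        "duplicate coordinates at spot(s) %s (flagged, not merged)",
        paste(which(dup)[seq_len(min(3L, sum(dup)))], collapse = ", ")))
  }
  if (length(ds$spot_ids) != n)
    issues <- c(issues, "spot_ids length does not match rows of X")
  if (anyDuplicated(ds$spot_ids))
    issues <- c(issues, sprintf(
      "spot_ids must be unique; first duplicate at index %d",
      anyDuplicated(ds$spot_ids)))
  if (length(ds$feature_ids) != p)
    issues <- c(issues, "feature_ids length does not match columns of X")
  if (anyDuplicated(ds$feature_ids))
    issues <- c(issues, sprintf(
      "feature_ids must be unique; first duplicate at index %d",
      anyDuplicated(ds$feature_ids)))
  if (length(ds$modality_tags) != p)
    issues <- c(issues, sprintf(
      "modality_tags length (%d) must equal number of features (%d)",
      length(ds$modality_tags), p))
  zero <- which(Matrix::colSums(X) == 0)
  if (length(zero))
    issues <- c(issues, sprintf(
      "feature(s) with zero total expression: %s (drop before factorization)",
      paste(zero[seq_len(min(5L, length(zero)))], collapse = ", ")))
  issues
}

#' Drop all-zero features
#'
#' Removes features with zero total expression.  All-zero columns carry no
#' signal and make relative reconstruction errors (and cosine similarities)
#' undefined, so they are dropped before factorization.
#'
#' @param ds a [spatial_dataset()].
#' @return the dataset with zero-total features removed (possibly unchanged).
#' @export
drop_zero_features <- function(ds) {
  keep <- Matrix::colSums(ds$X) > 0
  if (all(keep)) return(ds)
  spatial_dataset(ds$X[, keep, drop = FALSE], ds$coords,
                  spot_ids = ds$spot_ids,
                  feature_ids = ds$feature_ids[keep],
                  modality_tags = ds$modality_tags[keep],
                  validate = FALSE)
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat(sprintf("spatial_dataset: %d spots x %d features (%s)\n",
              nrow(x$X), ncol(x$X),
              paste(sprintf("%s: %d", names(table(x$modality_tags)),
                            table(x$modality_tags)), collapse = ", ")))
  cat(sprintf("  coords: x in [%.3g, %.3g], y in [%.3g, %.3g]\n",
              min(x$coords[, 1]), max(x$coords[, 1]),
              min(x$coords[, 2]), max(x$coords[, 2])))
  cat(sprintf("  %.1f%% non-zero entries\n",
              100 * Matrix::nnzero(x$X) / prod(dim(x$X))))
  invisible(x)
}

#' @export
dim.spatial_dataset <- function(x) dim(x$X)
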