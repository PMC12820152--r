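#' Read a spatial dataset from disk
#'
#' Reads an expression matrix plus a coordinate table into a
#' [spatial_dataset()].  `format = "mtx"` expects the Matrix Market sidecar
#' trio — `matrix.mtx` stored features x spots (the common on-disk
#' convention; transposed on load), `features.tsv` and `barcodes.tsv` —
#' either as a directory or as the path to the `.mtx` file.  `"csv"`/`"tsv"`
#' expect a dense table with a header row of feature ids and a first column
#' of spot ids.  The coordinate CSV must carry columns `x` and `y` plus a
#' first column of spot ids; coordinates are reordered to match the
#' expression row order.
#'
#' @param expression_path path to the matrix file or MTX directory.
#' @param coords_path path to the coordinates CSV.
#' @param format one of `"mtx"`, `"csv"`, `"tsv"`.
#' @param modality_tags modality tag(s) for the features (default "rna").
#' @return a [spatial_dataset()].
#' @export
read_spatial_dataset <- function(expression_path, coords_path,
                                 format = c("mtx", "csv", "tsv"),
                                 modality_tags = "rna") {
  format <- match.arg(format)
  if (format == "mtx") {
    dir <- if (dir.exists(expression_path)) expression_path
           else dirname(expression_path)
    mtx <- if (dir.exists(expression_path))
      file.path(dir, "matrix.mtx") else expression_path
    fpath <- file.path(dir, "features.tsv")
    bpath <- file.path(dir, "barcodes.tsv")
    for (f in c(mtx, fpath, bpath))
      if (!file.exists(f))
        stopf("missing MTX component: %s", f)
    M <- Matrix::readMM(mtx)                  # features x spots on disk
    feats <- read.delim(fpath, header = FALSE,
                        stringsAsFactors = FALSE)
    bcs <- read.delim(bpath, header = FALSE, stringsAsFactors = FALSE)
    if (nrow(feats) != nrow(M))
      stopf("features.tsv has %d rows but matrix has %d features",
            nrow(feats), nrow(M))
    if (nrow(bcs) != ncol(M))
      stopf("barcodes.tsv has %d rows but matrix has %d spots",
            nrow(bcs), ncol(M))
    X <- Matrix::t(M)
    spot_ids <- bcs[[1]]
    feature_ids <- feats[[1]]
    if (ncol(feats) >= 3) modality_tags <- feats[[3]]
  } else {
    sep <- if (format == "csv") "," else "\t"
    tab <- read.table(expression_path, header = TRUE, sep = sep,
                      row.names = 1, check.names = FALSE,
                      stringsAsFactors = FALSE)
    X <- as.matrix(tab)
    spot_ids <- rownames(tab)
    feature_ids <- colnames(tab)
  }
  if (min(X) < 0)
    stopf("expression matrix has negative entries (min %.4g)", min(X))

  co <- read.csv(coords_path, stringsAsFactors = FALSE)
  if (!all(c("x", "y") %in% names(co)))
    stopf("coords file must have columns 'x' and 'y' (found: %s)",
          paste(names(co), collapse = ", "))
  key <- co[[setdiff(names(co), c("x", "y"))[1] %||% 1]]
  idx <- match(spot_ids, key)
  if (anyNA(idx))
    stopf("coords missing spot id(s): %s",
          paste(spot_ids[which(is.na(idx))[seq_len(min(3, sum(is.na(idx))))]],
                collapse = ", "))
  coords <- as.matrix(co[idx, c("x", "y")])
  spatial_dataset(X, coords, spot_ids = spot_ids,
                  feature_ids = feature_ids,
                  modality_tags = modality_tags, validate = FALSE)
}

#' Write a spatial dataset to disk
#'
#' Writes the expression matrix (MTX trio or dense CSV), a `coords.csv`
#' keyed by spot id, and a `manifest.json` recording shapes, modality tags
#' and md5 checksums of every written file.  MTX is stored features x spots
#' on disk (the sidecar-trio convention) and transposed back on load.
#'
#' @param ds a [spatial_dataset()].
#' @param out_dir output directory (created if needed).
#' @param format `"mtx"` (default) or `"csv"`.
#' @return invisibly, a named character vector of written paths.
#' @export
write_spatial_dataset <- function(ds, out_dir, format = c("mtx", "csv")) {
  format <- match.arg(format)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  if (format == "mtx") {
    mtx <- file.path(out_dir, "matrix.mtx")
    Matrix::writeMM(methods::as(methods::as(
      Matrix::t(Matrix::Matrix(ds$X, sparse = TRUE)), "CsparseMatrix"),
      "generalMatrix"), mtx)
    write.table(data.frame(ds$feature_ids, ds$feature_ids,
                           ds$modality_tags),
                file.path(out_dir, "features.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    write.table(data.frame(ds$spot_ids),
                file.path(out_dir, "barcodes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    paths <- c(matrix = mtx,
               features = file.path(out_dir, "features.tsv"),
               barcodes = file.path(out_dir, "barcodes.tsv"))
  } else {
    expr <- file.path(out_dir, "expression.csv")
    tab <- as.data.frame(as.matrix(ds$X))
    colnames(tab) <- ds$feature_ids
    write.csv(cbind(spot = ds$spot_ids, tab), expr, row.names = FALSE,
              quote = FALSE)
    paths <- c(expression = expr)
  }
  cpath <- file.path(out_dir, "coords.csv")
  write.csv(data.frame(spot = ds$spot_ids, x = ds$coords[, 1],
                       y = ds$coords[, 2]),
            cpath, row.names = FALSE, quote = FALSE)
  paths <- c(paths, coords = cpath)
  manifest <- list(
    n_spots = nrow(ds$X), n_features = ncol(ds$X), format = format,
    orientation = if (format == "mtx") "features x spots on disk" else
      "spots x features",
    modalities = as.list(table(ds$modality_tags)),
    files = as.list(stats::setNames(unname(tools::md5sum(paths)),
                                    basename(paths))))
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, manifest = mpath))
}

#' Write a fitted model to CSV files
#'
#' Emits `W.csv` (spots x patterns, spot ids as row labels), `H.csv`
#' (patterns x features, feature ids as column labels), `pss.csv` and
#' `trace.csv` under `out_dir`.
#'
#' @param model a fitted [spatmf()] model.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
write_model <- function(model, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wp <- file.path(out_dir, "W.csv")
  hp <- file.path(out_dir, "H.csv")
  write.csv(as.data.frame(model$W), wp, row.names = TRUE, quote = FALSE)
  write.csv(as.data.frame(model$H), hp, row.names = TRUE, quote = FALSE)
  write.csv(data.frame(pattern = colnames(model$W), pss = model$pss),
            file.path(out_dir, "pss.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(model$objective_trace, file.path(out_dir, "trace.csv"),
            row.names = FALSE, quote = FALSE)
  invisible(c(W = wp, H = hp, pss = file.path(out_dir, "pss.csv"),
              trace = file.path(out_dir, "trace.csv")))
}

#' Read a fitted model written by [write_model()]
#'
#' Restores `W`, `H` and `pss` (the trace if present) as a lightweight
#' object usable by the downstream operators that only need the factors.
#'
#' @param dir directory containing `W.csv`, `H.csv`, `pss.csv`.
#' @return an object of class `"spatmf"` without `dataset`/`graph` fields.
#' @export
read_model <- function(dir) {
  need <- file.path(dir, c("W.csv", "H.csv", "pss.csv"))
  miss <- need[!file.exists(need)]
  if (length(miss))
    stopf("no fitted model at '%s': missing %s", dir,
          paste(basename(miss), collapse = ", "))
  W <- as.matrix(read.csv(need[1], row.names = 1, check.names = FALSE))
  H <- as.matrix(read.csv(need[2], row.names = 1, check.names = FALSE))
  pss <- read.csv(need[3])$pss
  tracef <- file.path(dir, "trace.csv")
  structure(list(W = W, H = H, pss = pss,
                 objective_trace = if (file.exists(tracef))
                   read.csv(tracef) else NULL,
                 params = NULL, graph = NULL, dataset = NULL),
            class = "spatmf")
}
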