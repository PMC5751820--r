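# On-disk formats: Matrix Market coordinate files for the sparse binary
# association matrix, TSV with an ID column for dense feature matrices,
# TSV pairs + JSON sidecar for fitted factors. All writers are
# deterministic: sorted entries, fixed 10-significant-digit float format.

#' Read a binary association matrix from Matrix Market
#'
#' Accepts coordinate files with pattern or real entries; real values are
#' binarized by `value > 0`. Duplicate entries collapse to a single 1 with
#' a warning. On-disk indices are 1-based per the Matrix Market standard.
#'
#' @param path file path.
#' @param row_ids,col_ids optional entity identifiers (the format itself
#'   carries none); defaults are generated.
#' @return an [association_matrix()].
#' @export
read_association_mtx <- function(path, row_ids = NULL, col_ids = NULL) {
  M_ <- Matrix::readMM(path)
  if (inherits(M_, "TsparseMatrix")) {
    if (anyDuplicated(cbind(M_@i, M_@j))) {
      warning("duplicate entries in ", path, "; collapsed to single 1s")
    }
  }
  A <- as.matrix(M_)
  A[] <- as.numeric(A > 0)
  association_matrix(A, row_ids, col_ids)
}

#' Write a binary association matrix as Matrix Market pattern format
#'
#' Coordinate pattern format, 1-based, entries sorted by (row, column);
#' byte-stable across runs for identical input.
#'
#' @param A binary matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_association_mtx <- function(A, path) {
  A <- as.matrix(A)
  if (!all(A %in% c(0, 1))) stop("association matrix entries must be 0 or 1")
  cells <- which(A == 1)
  i <- ((cells - 1L) %% nrow(A)) + 1L
  j <- ((cells - 1L) %/% nrow(A)) + 1L
  ord <- order(i, j)
  lines <- c("%%MatrixMarket matrix coordinate pattern general",
             sprintf("%d %d %d", nrow(A), ncol(A), length(cells)),
             sprintf("%d %d", i[ord], j[ord]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a dense feature matrix from TSV
#'
#' Expects a header row of feature names and a first column of entity IDs.
#'
#' @param path file path.
#' @return a [feature_matrix()].
#' @export
read_features_tsv <- function(path) {
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) != 1) {
    stop("ragged rows in ", path, ": lines ",
         paste(which(nf != nf[1]), collapse = ", "))
  }
  df <- read.delim(path, check.names = FALSE, colClasses = "character")
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicate entity IDs in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell in %s at row %d (id %s), column '%s'",
                 path, bad[1], ids[bad[1]], colnames(vals)[bad[2]]))
  }
  feature_matrix(num, ids, colnames(vals))
}

#' Write a dense feature matrix as TSV
#'
#' First column `id`, header row of feature names, floats with 10
#' significant digits; deterministic.
#'
#' @param F_ a [feature_matrix()] or numeric matrix with dimnames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_features_tsv <- function(F_, path) {
  F_ <- as.matrix(F_)
  ids <- rownames(F_) %||% paste0("E", seq_len(nrow(F_)))
  fn <- colnames(F_) %||% paste0("F", seq_len(ncol(F_)))
  body <- apply(F_, 1, function(rw) {
    paste(formatC(rw, digits = 10, format = "g"), collapse = "\t")
  })
  writeLines(c(paste(c("id", fn), collapse = "\t"),
               paste(ids, body, sep = "\t")), path)
  invisible(path)
}

#' Export a synthetic dataset to a directory
#'
#' Writes `A.mtx` (Matrix Market pattern), `X.tsv` and `Y.tsv` (features
#' with IDs), and `params.tsv` (flat key-value pairs, including outlier row
#' indices if any).
#'
#' @param ds a `synthetic_dataset`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_association_mtx(ds$A, file.path(dir, "A.mtx"))
  write_features_tsv(ds$X, file.path(dir, "X.tsv"))
  write_features_tsv(ds$Y, file.path(dir, "Y.tsv"))
  p <- ds$params
  p$outlier_rows <- paste(ds$outlier_rows, collapse = ",")
  keys <- sort(names(p))
  writeLines(sprintf("%s\t%s", keys,
                     vapply(p[keys], function(v)
                       formatC(v, digits = 10, format = "g"), character(1))),
             file.path(dir, "params.tsv"))
  invisible(dir)
}

#' Persist fitted factors with a metadata sidecar
#'
#' Writes `W.tsv`, `H.tsv`, `trace.tsv` (per-iteration objective) and
#' `meta.json` (method, rank, iterations, convergence, KKT residual).
#'
#' @param fit an `imc_fit`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fit <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  W <- fit$W; H <- fit$H
  rownames(W) <- rownames(W) %||% paste0("wrow", seq_len(nrow(W)))
  rownames(H) <- rownames(H) %||% paste0("hrow", seq_len(nrow(H)))
  colnames(W) <- colnames(H) <- paste0("r", seq_len(ncol(W)))
  write_features_tsv(W, file.path(dir, "W.tsv"))
  write_features_tsv(H, file.path(dir, "H.tsv"))
  writeLines(c("iter\tobjective",
               sprintf("%d\t%s", seq_along(fit$objective_trace) - 1L,
                       formatC(fit$objective_trace, digits = 10, format = "g"))),
             file.path(dir, "trace.tsv"))
  meta <- list(method = fit$method, rank = ncol(W), n_iter = fit$n_iter,
               converged = fit$converged, kkt_inf_norm = fit$kkt_inf_norm,
               final_objective = fit$objective_trace[length(fit$objective_trace)])
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read factors written by [write_fit()]
#'
#' @param dir directory containing `W.tsv`, `H.tsv`, `meta.json`.
#' @return list with `W`, `H`, and the metadata fields.
#' @export
read_fit <- function(dir) {
  W <- unclass(read_features_tsv(file.path(dir, "W.tsv")))
  H <- unclass(read_features_tsv(file.path(dir, "H.tsv")))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  c(list(W = W, H = H), meta)
}
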