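# Ranking evaluation: precision@k / recall@k over hidden positives,
# cross-validation over the positive entries, and the three cold-start
# hold-out designs (new rows, new columns, both). A "split" hides a set of
# known associations; solvers are fit on the remaining training matrix and
# judged by how highly they rank the hidden positives.

new_holdout_split <- function(A_train, hidden_sets, mode, held_rows = integer(),
                              held_cols = integer(), fold_id = 1L, seed = NA_integer_) {
  structure(list(A_train = A_train, hidden_sets = hidden_sets, mode = mode,
                 held_rows = held_rows, held_cols = held_cols,
                 fold_id = fold_id, seed = seed),
            class = "holdout_split")
}

#' Rank candidate columns for one row by descending score
#'
#' Ties are broken by ascending column index, so rankings are
#' deterministic and bit-reproducible.
#'
#' @param scores_row numeric vector of scores for every column.
#' @param exclude integer indices of columns to remove from the candidate
#'   set (typically the row's training positives).
#' @return integer vector of candidate column indices, best first.
#' @export
rank_columns_for_row <- function(scores_row, exclude = integer()) {
  if (any(!is.finite(scores_row))) stop("scores must be finite")
  cand <- setdiff(seq_along(scores_row), exclude)
  if (!length(cand)) stop("exclusion set covers all columns")
  cand[order(-scores_row[cand], cand)]
}

intersect_topk <- function(split, rankings, k) {
  rows <- names(split$hidden_sets)
  if (!all(rows %in% names(rankings))) {
    stop("rankings must cover every row with a nonempty hidden set")
  }
  vapply(rows, function(l) {
    rk <- rankings[[l]]
    if (k > length(rk)) stop("k exceeds the number of candidate columns")
    hid <- split$hidden_sets[[l]]
    if (!length(hid)) stop("empty hidden set encountered for row ", l)
    length(intersect(rk[seq_len(k)], hid))
  }, numeric(1))
}

#' Precision at k over the evaluated rows of a hold-out split
#'
#' `mean_l |topk_l intersect hidden_l| / k` over the rows with nonempty
#' hidden sets.
#'
#' @param split a `holdout_split` (see [make_cv_folds()] and the holdout
#'   constructors).
#' @param rankings named list: for each evaluated row (name = row index),
#'   the ranked candidate columns from [rank_columns_for_row()].
#' @param k cutoff, >= 1.
#' @return scalar in \[0, 1\].
#' @export
precision_at_k <- function(split, rankings, k) {
  mean(intersect_topk(split, rankings, k) / k)
}

#' Recall at k over the evaluated rows of a hold-out split
#'
#' `mean_l |topk_l intersect hidden_l| / |hidden_l|`.
#'
#' @inheritParams precision_at_k
#' @return scalar in \[0, 1\].
#' @export
recall_at_k <- function(split, rankings, k) {
  sizes <- lengths(split$hidden_sets)
  mean(intersect_topk(split, rankings, k) / sizes)
}

positives_by_row <- function(A, cells) {
  # cells: linear indices into A; returns named list row-index -> col indices
  rows <- ((cells - 1L) %% nrow(A)) + 1L
  cols <- ((cells - 1L) %/% nrow(A)) + 1L
  split(cols, factor(rows, levels = sort(unique(rows))))
}

#' Cross-validation folds over the positive entries
#'
#' Partitions the positive cells of `A` uniformly at random into `n_folds`
#' disjoint folds of near-equal size (differing by at most one). Each split
#' zeroes one fold in the training matrix and places it in the hidden sets
#' (transductive evaluation).
#'
#' @param A binary association matrix with at least `n_folds` positives.
#' @param n_folds number of folds, >= 2 (the reference protocol uses 10).
#' @param seed integer seed; identical inputs give identical folds.
#' @return list of `holdout_split`, one per fold.
#' @export
make_cv_folds <- function(A, n_folds = 10L, seed = 1L) {
  A <- as.matrix(A)
  pos <- which(A == 1)
  if (length(pos) < n_folds) stop("fewer positives than folds")
  if (n_folds < 2) stop("n_folds must be >= 2")
  set.seed(seed)
  fold <- sample(rep(seq_len(n_folds), length.out = length(pos)))
  lapply(seq_len(n_folds), function(f) {
    hide <- pos[fold == f]
    A_train <- A
    A_train[hide] <- 0
    new_holdout_split(A_train, positives_by_row(A, hide), "transductive_cv",
                      fold_id = f, seed = seed)
  })
}

sample_held <- function(n_total, fraction, seed, ok, max_retries = 20L) {
  # draw ceil(fraction * n_total) indices until predicate ok() accepts
  set.seed(seed)
  n_held <- ceiling(fraction * n_total)
  for (try in seq_len(max_retries)) {
    held <- sort(sample(n_total, n_held))
    if (ok(held)) return(held)
  }
  stop("could not draw a hold-out containing hidden positives after ",
       max_retries, " retries")
}

#' Cold-start hold-out of entire rows (new row entities)
#'
#' Selects `ceiling(fraction * M)` rows and zeroes their rows in the
#' training matrix; their original positives become the hidden sets. The
#' corresponding feature rows of `X` are used at prediction time only.
#'
#' @param A binary association matrix.
#' @param X,Y feature matrices (carried along for interface symmetry; the
#'   split itself only uses `A`).
#' @param fraction fraction of rows to hold out, in (0, 1).
#' @param seed integer seed.
#' @return a `holdout_split` with mode `"new_rows"`.
#' @export
holdout_new_rows <- function(A, X = NULL, Y = NULL, fraction = 0.1, seed = 1L) {
  A <- as.matrix(A)
  stopifnot(fraction > 0, fraction < 1)
  held <- sample_held(nrow(A), fraction, seed,
                      function(h) any(A[h, , drop = FALSE] == 1))
  A_train <- A
  A_train[held, ] <- 0
  hidden <- lapply(held, function(i) which(A[i, ] == 1))
  names(hidden) <- held
  hidden <- hidden[lengths(hidden) > 0]
  new_holdout_split(A_train, hidden, "new_rows", held_rows = held, seed = seed)
}

#' Cold-start hold-out of entire columns (new column entities)
#'
#' Mirror of [holdout_new_rows()]: zeroes `ceiling(fraction * N)` columns in
#' training. Hidden sets map each row with a hidden positive to its
#' positives among the held columns.
#'
#' @inheritParams holdout_new_rows
#' @return a `holdout_split` with mode `"new_cols"`.
#' @export
holdout_new_cols <- function(A, X = NULL, Y = NULL, fraction = 0.1, seed = 1L) {
  A <- as.matrix(A)
  stopifnot(fraction > 0, fraction < 1)
  held <- sample_held(ncol(A), fraction, seed,
                      function(h) any(A[, h, drop = FALSE] == 1))
  A_train <- A
  A_train[, held] <- 0
  rows <- which(rowSums(A[, held, drop = FALSE]) > 0)
  hidden <- lapply(rows, function(i) held[A[i, held] == 1])
  names(hidden) <- rows
  new_holdout_split(A_train, hidden, "new_cols", held_cols = held, seed = seed)
}

#' Cold-start hold-out of both rows and columns
#'
#' Holds out `row_fraction` of rows and `col_fraction` of columns. All
#' entries touching a held row or column are zeroed in training; the hidden
#' sets contain only the (held row, held column) pairs that were positive,
#' i.e. links between two entities both unseen in training.
#'
#' @inheritParams holdout_new_rows
#' @param row_fraction,col_fraction fractions in (0, 1).
#' @return a `holdout_split` with mode `"new_both"`.
#' @export
holdout_both <- function(A, X = NULL, Y = NULL, row_fraction = 0.05,
                         col_fraction = 0.05, seed = 1L) {
  A <- as.matrix(A)
  stopifnot(row_fraction > 0, row_fraction < 1,
            col_fraction > 0, col_fraction < 1)
  n_hr <- ceiling(row_fraction * nrow(A))
  n_hc <- ceiling(col_fraction * ncol(A))
  set.seed(seed)
  for (try in seq_len(20L)) {
    held_rows <- sort(sample(nrow(A), n_hr))
    held_cols <- sort(sample(ncol(A), n_hc))
    if (any(A[held_rows, held_cols, drop = FALSE] == 1)) break
    if (try == 20L) stop("no positive (held row, held col) pair after 20 retries")
  }
  A_train <- A
  A_train[held_rows, ] <- 0
  A_train[, held_cols] <- 0
  rows <- held_rows[rowSums(A[held_rows, held_cols, drop = FALSE]) > 0]
  hidden <- lapply(rows, function(i) held_cols[A[i, held_cols] == 1])
  names(hidden) <- rows
  new_holdout_split(A_train, hidden, "new_both", held_rows = held_rows,
                    held_cols = held_cols, seed = seed)
}

build_split <- function(A, X, Y, mode, fraction, col_fraction, n_folds, seed) {
  switch(mode,
    cv = make_cv_folds(A, n_folds, seed)[[1L]],
    new_rows = holdout_new_rows(A, X, Y, fraction, seed),
    new_cols = holdout_new_cols(A, X, Y, fraction, seed),
    new_both = holdout_both(A, X, Y, fraction, col_fraction, seed),
    stop("unknown mode: ", mode))
}

# Fit one method on the training side of a split and return the full M x N
# score matrix. Induction modes drop held rows/cols from BOTH the training
# association matrix and the feature matrices, then score with the full
# feature matrices, so held entities are never seen during training.
fit_and_score <- function(method, split, X, Y, config) {
  A_tr <- split$A_train
  keep_r <- setdiff(seq_len(nrow(A_tr)), split$held_rows)
  keep_c <- setdiff(seq_len(ncol(A_tr)), split$held_cols)
  if (method == "nmf") {
    if (split$mode != "transductive_cv") {
      stop("nmf is transductive and cannot run induction modes")
    }
    fit <- fit_nmf(A_tr, config)
    return(fit$W %*% t(fit$H))
  }
  A_fit <- A_tr[keep_r, keep_c, drop = FALSE]
  X_fit <- X[keep_r, , drop = FALSE]
  Y_fit <- Y[keep_c, , drop = FALSE]
  fit <- switch(method,
    imc = fit_imc(A_fit, X_fit, Y_fit, config),
    rimc = fit_rimc(A_fit, X_fit, Y_fit, config),
    srimc = fit_srimc(A_fit, X_fit, Y_fit, config),
    stop("unknown method: ", method))
  predict_scores(X, fit, Y)
}

rank_split <- function(split, scores) {
  lapply(stats::setNames(names(split$hidden_sets), names(split$hidden_sets)),
         function(l) {
    i <- as.integer(l)
    rank_columns_for_row(scores[i, ], exclude = which(split$A_train[i, ] == 1))
  })
}

#' Benchmark solvers under a hold-out design
#'
#' For each repeat: build a split of the requested mode (repeat index
#' offsets the seed), fit each method on the training data, rank candidates
#' for every evaluated row (excluding its training positives), and compute
#' precision@k and recall@k at each cutoff. All methods share each repeat's
#' split and initialization seed.
#'
#' @param methods character subset of `c("imc", "rimc", "srimc", "nmf")`;
#'   `"nmf"` only supports `mode = "cv"`.
#' @param dataset a `synthetic_dataset` (see [generate_planted_dataset()])
#'   or any list with elements `A`, `X`, `Y`.
#' @param mode one of `"cv"`, `"new_rows"`, `"new_cols"`, `"new_both"`.
#' @param k_grid integer cutoffs (default `seq(5, 100, by = 5)`).
#' @param n_repeats number of independent splits.
#' @param seed base seed; repeat i uses `seed + i - 1`.
#' @param config a [train_config()] shared by all methods.
#' @param fraction held fraction for the induction modes (rows and, for
#'   `"new_both"`, also columns unless `col_fraction` given).
#' @param col_fraction optional separate column fraction for `"new_both"`.
#' @param n_folds folds used when `mode = "cv"` (one fold is evaluated per
#'   repeat).
#' @return data.frame with columns method, mode, k, metric, mean, sd,
#'   n_repeats.
#' @export
run_benchmark <- function(methods, dataset, mode = "cv",
                          k_grid = seq(5L, 100L, by = 5L), n_repeats = 1L,
                          seed = 1L, config = train_config(),
                          fraction = 0.1, col_fraction = NULL,
                          n_folds = 10L) {
  stopifnot(all(methods %in% c("imc", "rimc", "srimc", "nmf")))
  k_grid <- sort(unique(as.integer(k_grid)))
  X <- as.matrix(dataset$X); Y <- as.matrix(dataset$Y)
  A <- as.matrix(dataset$A)
  vals <- array(NA_real_,
                dim = c(length(methods), length(k_grid), 2L, n_repeats),
                dimnames = list(methods, k_grid, c("precision", "recall"), NULL))
  for (rep_i in seq_len(n_repeats)) {
    rs <- seed + rep_i - 1L
    split <- build_split(A, X, Y, mode, fraction,
                         col_fraction %||% fraction, n_folds, rs)
    for (meth in methods) {
      cfg <- config
      cfg$seed <- rs
      scores <- fit_and_score(meth, split, X, Y, cfg)
      rks <- rank_split(split, scores)
      for (ki in seq_along(k_grid)) {
        vals[meth, ki, "precision", rep_i] <-
          precision_at_k(split, rks, k_grid[ki])
        vals[meth, ki, "recall", rep_i] <-
          recall_at_k(split, rks, k_grid[ki])
      }
    }
  }
  out <- expand.grid(method = methods, k = k_grid,
                     metric = c("precision", "recall"),
                     stringsAsFactors = FALSE)
  out$mode <- mode
  out$mean <- mapply(function(m, k, met) {
    mean(vals[m, as.character(k), met, ])
  }, out$method, out$k, out$metric)
  out$sd <- mapply(function(m, k, met) {
    if (n_repeats > 1) sd(vals[m, as.character(k), met, ]) else NA_real_
  }, out$method, out$k, out$metric)
  out$n_repeats <- n_repeats
  out[, c("method", "mode", "k", "metric", "mean", "sd", "n_repeats")]
}

#' Write a benchmark metrics table as TSV
#'
#' Deterministic output: rows sorted by (method, mode, metric, k), floats
#' formatted with 10 significant digits.
#'
#' @param metrics data.frame from [run_benchmark()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_metrics_tsv <- function(metrics, path) {
  metrics <- metrics[order(metrics$method, metrics$mode, metrics$metric,
                           metrics$k), ]
  fmt <- function(x) ifelse(is.na(x), "NA", formatC(x, digits = 10, format = "g"))
  lines <- c(paste(c("method", "mode", "k", "metric", "mean", "sd",
                     "n_repeats"), collapse = "\t"),
             sprintf("%s\t%s\t%d\t%s\t%s\t%s\t%d", metrics$method,
                     metrics$mode, metrics$k, metrics$metric,
                     fmt(metrics$mean), fmt(metrics$sd), metrics$n_repeats))
  writeLines(lines, path)
  invisible(path)
}
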