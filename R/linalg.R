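# Core containers, norms, objectives and score prediction shared by all
# solvers. All containers are plain dense base matrices wrapped in light
# validating constructors; solvers accept any conformable numeric matrix.

#' Construct a binary association matrix
#'
#' Wraps an M x N matrix of 0/1 association indicators together with unique
#' row- and column-entity identifiers (stored as dimnames).
#'
#' @param values numeric matrix with entries in \{0, 1\}; 1 marks a known
#'   association.
#' @param row_ids,col_ids character vectors of unique entity identifiers;
#'   default to existing dimnames or `"R<i>"` / `"C<j>"`.
#' @return a numeric matrix of class `association_matrix` with dimnames set.
#' @export
association_matrix <- function(values, row_ids = NULL, col_ids = NULL) {
  values <- as.matrix(values)
  if (!all(values %in% c(0, 1))) {
    stop("association matrix entries must be exactly 0 or 1")
  }
  storage.mode(values) <- "double"
  row_ids <- row_ids %||% rownames(values) %||% paste0("R", seq_len(nrow(values)))
  col_ids <- col_ids %||% colnames(values) %||% paste0("C", seq_len(ncol(values)))
  if (length(row_ids) != nrow(values) || length(col_ids) != ncol(values)) {
    stop("id lengths must match matrix dimensions")
  }
  if (anyDuplicated(row_ids) || anyDuplicated(col_ids)) {
    stop("entity identifiers must be unique")
  }
  dimnames(values) <- list(as.character(row_ids), as.character(col_ids))
  class(values) <- c("association_matrix", class(values))
  values
}

#' Construct a side-information feature matrix
#'
#' @param values entities x features numeric matrix; all entries finite.
#' @param entity_ids,feature_names identifiers; default to dimnames or
#'   generated labels.
#' @param nonneg assert that all entries are >= 0 (required by the
#'   multiplicative-update solvers; see [shift_nonneg()]).
#' @return numeric matrix of class `feature_matrix` with a `nonneg`
#'   attribute.
#' @export
feature_matrix <- function(values, entity_ids = NULL, feature_names = NULL,
                           nonneg = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!all(is.finite(values))) {
    stop("feature matrix contains non-finite entries")
  }
  if (nonneg && min(values) < 0) {
    stop("nonneg = TRUE but feature matrix has negative entries")
  }
  entity_ids <- entity_ids %||% rownames(values) %||% paste0("E", seq_len(nrow(values)))
  feature_names <- feature_names %||% colnames(values) %||% paste0("F", seq_len(ncol(values)))
  if (anyDuplicated(entity_ids)) stop("entity identifiers must be unique")
  dimnames(values) <- list(as.character(entity_ids), as.character(feature_names))
  attr(values, "nonneg") <- nonneg
  class(values) <- c("feature_matrix", class(values))
  values
}

#' Construct a nonnegative factor pair
#'
#' Holds the factors `W` (m x r) and `H` (n x r) whose product
#' `Z = W %*% t(H)` is the low-rank coefficient matrix of the inductive
#' model.
#'
#' @param W,H nonnegative numeric matrices with the same number of columns.
#' @return list of class `factor_pair` with elements `W`, `H`, `rank`.
#' @export
factor_pair <- function(W, H) {
  W <- as.matrix(W); H <- as.matrix(H)
  if (ncol(W) != ncol(H)) stop("W and H must have the same number of columns")
  if (min(W) < 0 || min(H) < 0) stop("factors must be nonnegative")
  structure(list(W = W, H = H, rank = ncol(W)), class = "factor_pair")
}

#' Construct positive diagonal reweighting weights
#'
#' Houses the diagonals of the iteratively reweighted least-squares
#' matrices: the residual row weights D, and the factor row weights P (for
#' W) and Q (for H). Each weight is `1 / max(row norm, eps)`, so all weights
#' are positive and bounded by `1 / eps`.
#'
#' @param d strictly positive numeric vector.
#' @param eps the positivity floor that was applied to the row norms.
#' @return numeric vector of class `diag_weights` with an `eps` attribute.
#' @export
diag_weights <- function(d, eps) {
  if (any(!is.finite(d)) || any(d <= 0)) stop("weights must be finite and > 0")
  if (any(d > 1 / eps + 1e-9)) stop("weights exceed 1/eps bound")
  structure(as.numeric(d), eps = eps, class = "diag_weights")
}

#' Training configuration for the matrix-completion solvers
#'
#' @param rank target factorization rank r >= 1.
#' @param lambda1,lambda2 nonnegative regularization weights on W and H.
#' @param max_iter maximum number of outer iterations.
#' @param tol convergence threshold on the relative change of the objective
#'   between consecutive iterations.
#' @param eps denominator floor added inside the multiplicative updates and
#'   used to floor row norms when forming reweighting diagonals.
#' @param seed integer seed for the factor initialization.
#' @param init initialization scheme. `"uniform"` draws i.i.d. uniform(0,1)
#'   entries scaled to match the scale of the target matrix; `"nndsvd"`
#'   starts from the nonnegative parts of the target's leading singular
#'   triples (for the inductive solvers the target is the ridge-stabilized
#'   closed-form coefficient estimate), which avoids the local stalls of
#'   random starts on well-structured inputs.
#' @return list of class `train_config`.
#' @export
train_config <- function(rank = 5L, lambda1 = 0.01, lambda2 = 0.01,
                         max_iter = 500L, tol = 1e-6, eps = 1e-10,
                         seed = 1L, init = c("uniform", "nndsvd")) {
  init <- match.arg(init)
  stopifnot(rank >= 1, lambda1 >= 0, lambda2 >= 0, max_iter >= 1,
            tol > 0, eps > 0)
  structure(list(rank = as.integer(rank), lambda1 = lambda1,
                 lambda2 = lambda2, max_iter = as.integer(max_iter),
                 tol = tol, eps = eps, seed = as.integer(seed), init = init),
            class = "train_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @exportS3Method base::print
print.imc_fit <- function(x, ...) {
  cat(sprintf("<%s fit> rank %d, %d iterations (%s), objective %.6g, KKT residual %.3g\n",
              x$method, ncol(x$W), x$n_iter,
              if (x$converged) "converged" else "max_iter reached",
              x$objective_trace[length(x$objective_trace)],
              x$kkt_inf_norm))
  invisible(x)
}

#' Euclidean norms of matrix rows
#'
#' @param M_ numeric matrix with finite entries.
#' @return numeric vector; entry i is `sqrt(sum(M_[i, ]^2))`.
#' @export
row_l2_norms <- function(M_) {
  M_ <- as.matrix(M_)
  bad <- which(!apply(is.finite(M_), 1, all))
  if (length(bad)) {
    stop("non-finite entries in row(s): ", paste(bad, collapse = ", "))
  }
  sqrt(rowSums(M_^2))
}

#' The l2,1 norm: sum of row-wise Euclidean norms
#'
#' `||M||_{2,1} = sum_i sqrt(sum_j M[i,j]^2)`. Penalizing rows un-squared is
#' what damps the influence of outlier rows in the robust solvers.
#'
#' @inheritParams row_l2_norms
#' @return scalar.
#' @export
l21_norm <- function(M_) sum(row_l2_norms(M_))

check_shapes <- function(A, X, W, H, Y) {
  ok <- nrow(X) == nrow(A) && ncol(X) == nrow(W) &&
    ncol(W) == ncol(H) && nrow(H) == ncol(Y) && nrow(Y) == ncol(A)
  if (!ok) {
    stop(sprintf(
      "non-conformable shapes: A %dx%d, X %dx%d, W %dx%d, H %dx%d, Y %dx%d",
      nrow(A), ncol(A), nrow(X), ncol(X), nrow(W), ncol(W),
      nrow(H), ncol(H), nrow(Y), ncol(Y)))
  }
  invisible(TRUE)
}

as_factors <- function(factors) {
  if (inherits(factors, "factor_pair") || (is.list(factors) &&
      all(c("W", "H") %in% names(factors)))) {
    list(W = as.matrix(factors$W), H = as.matrix(factors$H))
  } else {
    stop("`factors` must be a factor_pair or a list with W and H")
  }
}

#' Model residual A - X W H' Y'
#'
#' @param A M x N association matrix.
#' @param X M x m row-entity features; `Y` N x n column-entity features.
#' @param factors a [factor_pair()] (or list) with `W` (m x r), `H` (n x r).
#' @param Y column-entity feature matrix.
#' @return M x N residual matrix, computed densely in double precision.
#' @export
imc_residual <- function(A, X, factors, Y) {
  f <- as_factors(factors)
  A <- as.matrix(A); X <- as.matrix(X); Y <- as.matrix(Y)
  check_shapes(A, X, f$W, f$H, Y)
  A - X %*% f$W %*% t(f$H) %*% t(Y)
}

#' Standard inductive matrix completion objective
#'
#' `0.5 * ||A - XWH'Y'||_F^2 + (lambda1/2) ||W||_F^2 + (lambda2/2) ||H||_F^2`.
#'
#' @inheritParams imc_residual
#' @param lambda1,lambda2 nonnegative ridge weights.
#' @return scalar objective value.
#' @export
objective_imc <- function(A, X, Y, factors, lambda1 = 0, lambda2 = 0) {
  f <- as_factors(factors)
  R <- imc_residual(A, X, f, Y)
  0.5 * sum(R^2) + lambda1 / 2 * sum(f$W^2) + lambda2 / 2 * sum(f$H^2)
}

#' Robust inductive matrix completion objective
#'
#' `||A - XWH'Y'||_{2,1} + lambda1 ||W||_{2,1} + lambda2 ||H||_{2,1}`.
#'
#' @inheritParams objective_imc
#' @return scalar objective value.
#' @export
objective_rimc <- function(A, X, Y, factors, lambda1 = 0, lambda2 = 0) {
  f <- as_factors(factors)
  R <- imc_residual(A, X, f, Y)
  l21_norm(R) + lambda1 * l21_norm(f$W) + lambda2 * l21_norm(f$H)
}

#' Robust NMF objective on a recovered coefficient matrix
#'
#' `||Z - WH'||_{2,1} + lambda1 ||W||_{2,1} + lambda2 ||H||_{2,1}`, the
#' second-step objective of the stable robust solver.
#'
#' @param Z m x n target matrix.
#' @inheritParams objective_imc
#' @return scalar objective value.
#' @export
objective_rnmf <- function(Z, factors, lambda1 = 0, lambda2 = 0) {
  f <- as_factors(factors)
  Z <- as.matrix(Z)
  if (nrow(Z) != nrow(f$W) || ncol(Z) != nrow(f$H)) {
    stop(sprintf("non-conformable shapes: Z %dx%d, W %dx%d, H %dx%d",
                 nrow(Z), ncol(Z), nrow(f$W), ncol(f$W), nrow(f$H), ncol(f$H)))
  }
  l21_norm(Z - f$W %*% t(f$H)) + lambda1 * l21_norm(f$W) +
    lambda2 * l21_norm(f$H)
}

#' Predicted association scores X W H' Y'
#'
#' Unthresholded real-valued scores; larger means a more likely association.
#' Because the factors live in feature space, scores can be produced for
#' feature vectors of entities unseen during training.
#'
#' @inheritParams imc_residual
#' @return M x N score matrix.
#' @export
predict_scores <- function(X, factors, Y) {
  f <- as_factors(factors)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != nrow(f$W) || ncol(Y) != nrow(f$H) || ncol(f$W) != ncol(f$H)) {
    stop(sprintf("non-conformable shapes: X %dx%d, W %dx%d, H %dx%d, Y %dx%d",
                 nrow(X), ncol(X), nrow(f$W), ncol(f$W), nrow(f$H), ncol(f$H),
                 nrow(Y), ncol(Y)))
  }
  X %*% f$W %*% t(f$H) %*% t(Y)
}
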