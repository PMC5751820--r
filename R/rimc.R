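# Robust inductive matrix completion: l2,1 loss and l2,1 regularizers,
# minimized by iteratively reweighted multiplicative updates. Each outer
# iteration refreshes the diagonal weights D (residual rows), P (W rows)
# and Q (H rows), then applies one multiplicative W update and one H
# update with those weights held fixed.

#' Residual row weights D
#'
#' `D[i] = 1 / max(||R[i, ]||_2, eps)`: rows with large residual norm —
#' outlier candidates — receive small weight, which is the mechanism by
#' which the l2,1 loss damps outliers.
#'
#' @param R M x N residual matrix.
#' @param eps positivity floor for the row norms (default 1e-8).
#' @return a [diag_weights()] vector of length M.
#' @export
compute_residual_weights <- function(R, eps = 1e-8) {
  diag_weights(1 / pmax(row_l2_norms(R), eps), eps)
}

#' Factor row weights P (for W) or Q (for H)
#'
#' `d[i] = 1 / max(||B[i, ]||_2, eps)`, the reweighting that linearizes the
#' l2,1 regularizer on a factor matrix.
#'
#' @param B factor matrix (W or H).
#' @inheritParams compute_residual_weights
#' @return a [diag_weights()] vector with one weight per row of `B`.
#' @export
compute_factor_weights <- function(B, eps = 1e-8) {
  diag_weights(1 / pmax(row_l2_norms(B), eps), eps)
}

#' One multiplicative W update of the robust solver
#'
#' `W'[i,j] = W[i,j] * (X'DAYH)[i,j] /
#'   ((X'DXWH'Y'YH + lambda1 * PW)[i,j] + eps)`.
#' `D` and `P` are passed as weight vectors (diagonals).
#'
#' @param A,X,Y nonnegative data matrices.
#' @param W,H current nonnegative factors.
#' @param D residual row weights (length M); `P` W-row weights (length m).
#' @param lambda1 regularization weight; `eps` denominator floor.
#' @return updated W, nonnegative.
#' @export
update_W <- function(A, X, Y, W, H, D, P, lambda1, eps = 1e-10) {
  A <- as.matrix(A); X <- as.matrix(X); Y <- as.matrix(Y)
  check_shapes(A, X, W, H, Y)
  check_nonneg(A = A, X = X, Y = Y, W = W, H = H)
  d <- as.numeric(D); p <- as.numeric(P)
  YH <- Y %*% H
  num <- crossprod(X, d * (A %*% YH))
  den <- crossprod(X, d * (X %*% (W %*% (t(H) %*% crossprod(Y) %*% H)))) +
    lambda1 * p * W
  W * num / (den + eps)
}

#' One multiplicative H update of the robust solver
#'
#' `H'[i,j] = H[i,j] * (Y'A'DXW)[i,j] /
#'   ((Y'YHW'X'DXW + lambda2 * QH)[i,j] + eps)`.
#'
#' @inheritParams update_W
#' @param Q H-row weights (length n); `lambda2` regularization weight.
#' @return updated H, nonnegative.
#' @export
update_H <- function(A, X, Y, W, H, D, Q, lambda2, eps = 1e-10) {
  A <- as.matrix(A); X <- as.matrix(X); Y <- as.matrix(Y)
  check_shapes(A, X, W, H, Y)
  check_nonneg(A = A, X = X, Y = Y, W = W, H = H)
  d <- as.numeric(D); q <- as.numeric(Q)
  XW <- X %*% W
  num <- crossprod(Y, crossprod(A, d * XW))
  den <- crossprod(Y) %*% H %*% crossprod(XW, d * XW) + lambda2 * q * H
  H * num / (den + eps)
}

#' Scaled KKT complementarity residual of the robust objective
#'
#' Maximum over all factor entries of |gradient term x entry|, where the
#' gradients are those of the reweighted quadratic surrogate
#' (`-X'DAYH + X'DXWH'Y'YH + lambda1 PW` for W and
#' `-Y'A'DXW + Y'YHW'X'DXW + lambda2 QH` for H), divided by `||A||_F` for
#' comparability across problem sizes. Zero at a stationary point of the
#' constrained problem.
#'
#' @inheritParams update_W
#' @param Q H-row weights; `lambda2` H regularization weight.
#' @return scalar >= 0.
#' @export
kkt_residual <- function(A, X, Y, W, H, D, P, Q, lambda1, lambda2) {
  A <- as.matrix(A); X <- as.matrix(X); Y <- as.matrix(Y)
  check_shapes(A, X, W, H, Y)
  d <- as.numeric(D); p <- as.numeric(P); q <- as.numeric(Q)
  YH <- Y %*% H; XW <- X %*% W
  gW <- -crossprod(X, d * (A %*% YH)) +
    crossprod(X, d * (X %*% (W %*% (t(H) %*% crossprod(Y) %*% H)))) +
    lambda1 * p * W
  gH <- -crossprod(Y, crossprod(A, d * XW)) +
    crossprod(Y) %*% H %*% crossprod(XW, d * XW) + lambda2 * q * H
  max(abs(c(gW * W, gH * H))) / sqrt(sum(A^2))
}

#' Fit robust inductive matrix completion
#'
#' Minimizes `||A - XWH'Y'||_{2,1} + lambda1 ||W||_{2,1} +
#' lambda2 ||H||_{2,1}` over nonnegative `W`, `H`. Each iteration
#' recomputes the diagonal weights D, P, Q from the current iterate (once,
#' before the W update; the paired H update reuses them), applies
#' [update_W()] then [update_H()], and records the l2,1 objective. The
#' trace is monotonically non-increasing; iteration stops when its relative
#' change drops below `config$tol` or at `config$max_iter`.
#'
#' @inheritParams fit_imc
#' @param weight_eps floor for the reweighting row norms (default 1e-8);
#'   distinct from `config$eps`, the multiplicative-update denominator
#'   floor.
#' @return an `imc_fit`; `kkt_inf_norm` holds the scaled complementarity
#'   residual at exit.
#' @export
fit_rimc <- function(A, X, Y, config = train_config(), weight_eps = 1e-8) {
  A <- as.matrix(A); X <- as.matrix(X); Y <- as.matrix(Y)
  m <- ncol(X); n <- ncol(Y); r <- config$rank
  if (r > min(m, n)) stop("rank must satisfy r <= min(m, n)")
  check_nonneg(A = A, X = X, Y = Y)
  f <- if (config$init == "nndsvd") {
    init_factors_nndsvd(clamp_nonneg(solve_Z(A, X, Y))$Z_hat, r, config$seed)
  } else {
    init_factors(A, m, n, r, config$seed)
  }
  W <- f$W; H <- f$H
  check_shapes(A, X, W, H, Y)
  trace <- numeric(config$max_iter + 1)
  trace[1] <- objective_rimc(A, X, Y, list(W = W, H = H),
                             config$lambda1, config$lambda2)
  converged <- FALSE; it <- 0
  D <- P <- Q <- NULL
  for (it in seq_len(config$max_iter)) {
    R <- A - X %*% W %*% t(H) %*% t(Y)
    D <- compute_residual_weights(R, weight_eps)
    P <- compute_factor_weights(W, weight_eps)
    Q <- compute_factor_weights(H, weight_eps)
    W <- update_W(A, X, Y, W, H, D, P, config$lambda1, config$eps)
    H <- update_H(A, X, Y, W, H, D, Q, config$lambda2, config$eps)
    trace[it + 1] <- objective_rimc(A, X, Y, list(W = W, H = H),
                                    config$lambda1, config$lambda2)
    if (rel_change(trace[it], trace[it + 1]) < config$tol) {
      converged <- TRUE
      break
    }
  }
  R <- A - X %*% W %*% t(H) %*% t(Y)
  D <- compute_residual_weights(R, weight_eps)
  P <- compute_factor_weights(W, weight_eps)
  Q <- compute_factor_weights(H, weight_eps)
  kkt <- kkt_residual(A, X, Y, W, H, D, P, Q, config$lambda1, config$lambda2)
  finish_fit(W, H, trace, it, converged, kkt, "rimc")
}
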