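# Two-step stable robust solver: (1) recover the coefficient matrix Z in
# closed form from the feature-space normal equations X'X Z Y'Y = X'AY;
# (2) factorize the (clamped) Z by robust l2,1 NMF. Each step is stable in
# isolation, avoiding the joint nonconvex search of the one-shot solver.

#' Closed-form recovery of the coefficient matrix Z
#'
#' Solves `X'X Z Y'Y = X'AY`, i.e. `Z_hat = (X'X + ridge I)^-1 X'AY
#' (Y'Y + ridge I)^-1`. Gram systems are solved with a linear solver, never
#' an explicit inverse. Requires `X` and `Y` to have full column rank when
#' `ridge = 0`; near-deficiency (smallest singular value of a Gram matrix
#' below 1e-10 times its largest) is flagged.
#'
#' @param A M x N association matrix (binary or real).
#' @param X,Y feature matrices (M x m, N x n); may contain negative values.
#' @param ridge nonnegative Tikhonov stabilizer added to each Gram
#'   diagonal; `NULL` (default) uses `1e-8 * trace(G)/dim(G)` per side.
#' @return a `z_estimate`: list with `Z_hat` (m x n), `clamped` (FALSE),
#'   `rank_deficient_X`, `rank_deficient_Y`, `ridge` (the two values used).
#' @export
solve_Z <- function(A, X, Y, ridge = NULL) {
  A <- as.matrix(A); X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(A) || nrow(Y) != ncol(A)) {
    stop(sprintf("non-conformable shapes: A %dx%d, X %dx%d, Y %dx%d",
                 nrow(A), ncol(A), nrow(X), ncol(X), nrow(Y), ncol(Y)))
  }
  Gx <- crossprod(X); Gy <- crossprod(Y)
  def <- function(G) {
    ev <- svd(G, nu = 0, nv = 0)$d
    ev[length(ev)] < 1e-10 * ev[1]
  }
  rdx <- def(Gx); rdy <- def(Gy)
  if (is.null(ridge)) {
    ridge_x <- 1e-8 * sum(diag(Gx)) / ncol(Gx)
    ridge_y <- 1e-8 * sum(diag(Gy)) / ncol(Gy)
  } else {
    stopifnot(ridge >= 0)
    ridge_x <- ridge_y <- ridge
  }
  if ((rdx && ridge_x == 0) || (rdy && ridge_y == 0)) {
    stop("Gram matrix is (near-)singular; supply ridge > 0")
  }
  Gx <- Gx + diag(ridge_x, ncol(Gx))
  Gy <- Gy + diag(ridge_y, ncol(Gy))
  B <- solve(Gx, crossprod(X, A %*% Y))  # m x n
  Z <- t(solve(Gy, t(B)))
  structure(list(Z_hat = Z, clamped = FALSE, rank_deficient_X = rdx,
                 rank_deficient_Y = rdy, ridge = c(x = ridge_x, y = ridge_y)),
            class = "z_estimate")
}

#' Clamp a recovered Z to the nonnegative orthant
#'
#' The robust NMF step factorizes into nonnegative factors, so negative
#' entries of the closed-form estimate are set to zero (the minimal
#' intervention); the `clamped` flag records that this happened.
#'
#' @param Z_hat a `z_estimate` from [solve_Z()] or a plain matrix.
#' @return a `z_estimate` with `min(Z_hat) >= 0` and `clamped = TRUE`.
#' @export
clamp_nonneg <- function(Z_hat) {
  if (inherits(Z_hat, "z_estimate")) {
    Z_hat$Z_hat <- pmax(Z_hat$Z_hat, 0)
    Z_hat$clamped <- TRUE
    Z_hat
  } else {
    structure(list(Z_hat = pmax(as.matrix(Z_hat), 0), clamped = TRUE,
                   rank_deficient_X = NA, rank_deficient_Y = NA,
                   ridge = c(x = NA_real_, y = NA_real_)),
              class = "z_estimate")
  }
}

#' Robust NMF multiplicative W update
#'
#' Specializes [update_W()] to identity features:
#' `W'[i,j] = W[i,j] * (DZH)[i,j] / ((DWH'H + lambda1 PW)[i,j] + eps)`,
#' with `D` from the rows of `Z - WH'` and `P` from the rows of `W`.
#'
#' @param Z m x n nonnegative target matrix.
#' @param W,H current nonnegative factors (m x r, n x r).
#' @param D,P weight vectors of length m.
#' @param lambda1 regularization weight; `eps` denominator floor.
#' @return updated W.
#' @export
update_W_rnmf <- function(Z, W, H, D, P, lambda1, eps = 1e-10) {
  Z <- as.matrix(Z)
  check_nonneg(Z = Z, W = W, H = H)
  d <- as.numeric(D); p <- as.numeric(P)
  num <- (d * Z) %*% H
  den <- (d * (W %*% crossprod(H))) + lambda1 * p * W
  W * num / (den + eps)
}

#' Robust NMF multiplicative H update
#'
#' `H'[i,j] = H[i,j] * (Z'DW)[i,j] / ((HW'DW + lambda2 QH)[i,j] + eps)`.
#'
#' @inheritParams update_W_rnmf
#' @param Q weight vector of length n; `lambda2` regularization weight.
#' @return updated H.
#' @export
update_H_rnmf <- function(Z, W, H, D, Q, lambda2, eps = 1e-10) {
  Z <- as.matrix(Z)
  check_nonneg(Z = Z, W = W, H = H)
  d <- as.numeric(D); q <- as.numeric(Q)
  num <- crossprod(Z, d * W)
  den <- H %*% crossprod(W, d * W) + lambda2 * q * H
  H * num / (den + eps)
}

#' Robust l2,1 nonnegative matrix factorization
#'
#' Minimizes `||Z - WH'||_{2,1} + lambda1 ||W||_{2,1} + lambda2 ||H||_{2,1}`
#' by iteratively reweighted multiplicative updates (the second step of the
#' stable robust solver). Same weight-refresh schedule as [fit_rimc()].
#'
#' @param Z m x n nonnegative matrix (use [clamp_nonneg()] first if needed).
#' @inheritParams fit_rimc
#' @return an `imc_fit` with `W` (m x r), `H` (n x r).
#' @export
fit_robust_nmf <- function(Z, config = train_config(), weight_eps = 1e-8) {
  Z <- as.matrix(Z)
  check_nonneg(Z = Z)
  r <- config$rank
  f <- if (config$init == "nndsvd") {
    init_factors_nndsvd(Z, r, config$seed)
  } else {
    init_factors(Z, nrow(Z), ncol(Z), r, config$seed)
  }
  W <- f$W; H <- f$H
  trace <- numeric(config$max_iter + 1)
  trace[1] <- objective_rnmf(Z, list(W = W, H = H),
                             config$lambda1, config$lambda2)
  converged <- FALSE; it <- 0
  for (it in seq_len(config$max_iter)) {
    D <- compute_residual_weights(Z - W %*% t(H), weight_eps)
    P <- compute_factor_weights(W, weight_eps)
    Q <- compute_factor_weights(H, weight_eps)
    W <- update_W_rnmf(Z, W, H, D, P, config$lambda1, config$eps)
    H <- update_H_rnmf(Z, W, H, D, Q, config$lambda2, config$eps)
    trace[it + 1] <- objective_rnmf(Z, list(W = W, H = H),
                                    config$lambda1, config$lambda2)
    if (rel_change(trace[it], trace[it + 1]) < config$tol) {
      converged <- TRUE
      break
    }
  }
  D <- compute_residual_weights(Z - W %*% t(H), weight_eps)
  P <- compute_factor_weights(W, weight_eps)
  Q <- compute_factor_weights(H, weight_eps)
  Im <- diag(nrow(Z)); In <- diag(ncol(Z))
  kkt <- kkt_residual(Z, Im, In, W, H, D, P, Q,
                      config$lambda1, config$lambda2)
  finish_fit(W, H, trace, it, converged, kkt, "rnmf")
}

#' Fit stable robust inductive matrix completion (two-step)
#'
#' Composes [solve_Z()] (closed-form recovery of Z from the feature-space
#' normal equations), [clamp_nonneg()], and [fit_robust_nmf()]. The
#' resulting factors live in feature space, so [predict_scores()] gives
#' association scores including for unseen entities.
#'
#' @inheritParams fit_rimc
#' @param ridge passed to [solve_Z()].
#' @return an `imc_fit` with an extra `z_estimate` element carrying the
#'   step-1 diagnostics (clamping and rank-deficiency flags).
#' @export
fit_srimc <- function(A, X, Y, config = train_config(), ridge = NULL,
                      weight_eps = 1e-8) {
  ze <- solve_Z(A, X, Y, ridge)
  ze <- clamp_nonneg(ze)
  fit <- fit_robust_nmf(ze$Z_hat, config, weight_eps)
  fit$method <- "srimc"
  fit$z_estimate <- ze
  fit
}
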