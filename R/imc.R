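# Baseline solvers: standard inductive matrix completion (squared Frobenius
# loss + ridge penalties) and plain NMF, both by multiplicative updates.

#' Shift feature columns to be nonnegative
#'
#' Multiplicative updates keep factors nonnegative only when `A`, `X`, `Y`
#' are nonnegative. Features derived from SVD coordinates can be negative;
#' this preprocessor subtracts each column's minimum when it is negative.
#' It must be invoked explicitly: shifting changes the affine geometry of
#' the feature space, so the caller should opt in knowingly.
#'
#' @param F_ numeric feature matrix.
#' @return matrix of the same shape with all entries >= 0.
#' @export
shift_nonneg <- function(F_) {
  F_ <- as.matrix(F_)
  mins <- pmin(apply(F_, 2, min), 0)
  sweep(F_, 2, mins, "-")
}

init_factors <- function(A, m, n, rank, seed, scale_target = NULL) {
  set.seed(seed)
  scale_target <- scale_target %||% mean(A)
  sc <- sqrt(max(scale_target, .Machine$double.eps) / rank)
  W <- matrix(runif(m * rank), m, rank) * sc
  H <- matrix(runif(n * rank), n, rank) * sc
  list(W = W, H = H)
}

# NNDSVD-style initialization for factorizing a nonnegative target T ~ WH':
# nonnegative parts of the leading singular triples, the standard remedy
# for the local minima / slow starts of random multiplicative updates.
# A tiny seeded jitter breaks exact zeros (absorbing under multiplicative
# updates).
init_factors_nndsvd <- function(T_, rank, seed) {
  s <- svd(T_, nu = rank, nv = rank)
  W <- matrix(0, nrow(T_), rank)
  H <- matrix(0, ncol(T_), rank)
  for (k in seq_len(rank)) {
    u <- s$u[, k]; v <- s$v[, k]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    npos <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
    nneg <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
    if (npos >= nneg) {
      W[, k] <- sqrt(s$d[k] * npos) * up / max(sqrt(sum(up^2)), 1e-12)
      H[, k] <- sqrt(s$d[k] * npos) * vp / max(sqrt(sum(vp^2)), 1e-12)
    } else {
      W[, k] <- sqrt(s$d[k] * nneg) * un / max(sqrt(sum(un^2)), 1e-12)
      H[, k] <- sqrt(s$d[k] * nneg) * vn / max(sqrt(sum(vn^2)), 1e-12)
    }
  }
  set.seed(seed)
  floor_w <- 1e-6 * max(W); floor_h <- 1e-6 * max(H)
  W <- W + floor_w * matrix(runif(length(W)), nrow(W))
  H <- H + floor_h * matrix(runif(length(H)), nrow(H))
  list(W = W, H = H)
}

check_nonneg <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    if (min(args[[nm]]) < 0) {
      stop(nm, " has negative entries; multiplicative updates require ",
           "nonnegative inputs (see shift_nonneg())")
    }
  }
  invisible(TRUE)
}

finish_fit <- function(W, H, trace, it, converged, kkt, method) {
  structure(list(W = W, H = H, factors = factor_pair(W, H),
                 objective_trace = trace[seq_len(it + 1)], n_iter = it,
                 converged = converged, kkt_inf_norm = kkt, method = method),
            class = "imc_fit")
}

#' Fit standard inductive matrix completion
#'
#' Minimizes `0.5||A - XWH'Y'||_F^2 + (lambda1/2)||W||_F^2 +
#' (lambda2/2)||H||_F^2` over nonnegative `W`, `H` by the KKT-derived
#' multiplicative updates
#' \deqn{W \gets W \circ \frac{X'AYH}{X'XWH'Y'YH + \lambda_1 W},\qquad
#'       H \gets H \circ \frac{Y'A'XW}{Y'YHW'X'XW + \lambda_2 H},}
#' with a small `eps` floor added to each denominator. The objective trace
#' is non-increasing and nonnegativity is preserved exactly.
#'
#' @param A M x N nonnegative (typically binary) association matrix.
#' @param X,Y nonnegative feature matrices (M x m and N x n); negative
#'   features must first be passed through [shift_nonneg()].
#' @param config a [train_config()].
#' @return an `imc_fit`: list with factors `W`, `H`, `objective_trace`,
#'   `n_iter`, `converged`, `kkt_inf_norm`.
#' @export
fit_imc <- function(A, X, Y, config = train_config()) {
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
  Gx <- crossprod(X); Gy <- crossprod(Y)
  XtA <- crossprod(X, A)            # m x N
  trace <- numeric(config$max_iter + 1)
  trace[1] <- objective_imc(A, X, Y, list(W = W, H = H),
                            config$lambda1, config$lambda2)
  converged <- FALSE; it <- 0
  for (it in seq_len(config$max_iter)) {
    YH <- Y %*% H
    numW <- XtA %*% YH
    denW <- Gx %*% W %*% (t(H) %*% Gy %*% H) + config$lambda1 * W
    W <- W * numW / (denW + config$eps)
    XW <- X %*% W
    numH <- crossprod(Y, crossprod(A, XW))
    denH <- Gy %*% H %*% crossprod(XW) + config$lambda2 * H
    H <- H * numH / (denH + config$eps)
    trace[it + 1] <- objective_imc(A, X, Y, list(W = W, H = H),
                                   config$lambda1, config$lambda2)
    if (rel_change(trace[it], trace[it + 1]) < config$tol) {
      converged <- TRUE
      break
    }
  }
  kkt <- kkt_residual_imc(A, X, Y, W, H, config$lambda1, config$lambda2)
  finish_fit(W, H, trace, it, converged, kkt, "imc")
}

rel_change <- function(prev, cur) {
  abs(prev - cur) / max(abs(prev), .Machine$double.eps)
}

# Scaled complementarity residual of the standard (Frobenius) objective.
kkt_residual_imc <- function(A, X, Y, W, H, lambda1, lambda2) {
  R <- A - X %*% W %*% t(H) %*% t(Y)
  gW <- -crossprod(X, R %*% Y %*% H) + lambda1 * W
  gH <- -crossprod(Y, crossprod(R, X %*% W)) + lambda2 * H
  max(abs(c(gW * W, gH * H))) / sqrt(sum(A^2))
}

#' Fit plain nonnegative matrix factorization
#'
#' Classic multiplicative-update NMF of `A ~ W %*% t(H)` under the squared
#' Frobenius loss (no side information; transductive). Serves as the
#' feature-free baseline.
#'
#' @param A M x N nonnegative matrix.
#' @param config a [train_config()]; `lambda1`/`lambda2` act as ridge
#'   penalties as in [fit_imc()].
#' @return an `imc_fit` with `W` (M x r) and `H` (N x r).
#' @export
fit_nmf <- function(A, config = train_config()) {
  A <- as.matrix(A)
  check_nonneg(A = A)
  r <- config$rank
  f <- if (config$init == "nndsvd") {
    init_factors_nndsvd(A, r, config$seed)
  } else {
    init_factors(A, nrow(A), ncol(A), r, config$seed)
  }
  W <- f$W; H <- f$H
  obj <- function(W, H) {
    0.5 * sum((A - W %*% t(H))^2) +
      config$lambda1 / 2 * sum(W^2) + config$lambda2 / 2 * sum(H^2)
  }
  trace <- numeric(config$max_iter + 1)
  trace[1] <- obj(W, H)
  converged <- FALSE; it <- 0
  for (it in seq_len(config$max_iter)) {
    W <- W * (A %*% H) / (W %*% crossprod(H) + config$lambda1 * W + config$eps)
    H <- H * crossprod(A, W) / (H %*% crossprod(W) + config$lambda2 * H + config$eps)
    trace[it + 1] <- obj(W, H)
    if (rel_change(trace[it], trace[it + 1]) < config$tol) {
      converged <- TRUE
      break
    }
  }
  R <- A - W %*% t(H)
  gW <- -R %*% H + config$lambda1 * W
  gH <- -crossprod(R, W) + config$lambda2 * H
  kkt <- max(abs(c(gW * W, gH * H))) / sqrt(sum(A^2))
  finish_fit(W, H, trace, it, converged, kkt, "nmf")
}
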