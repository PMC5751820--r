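# Independent oracles, deliberately written with explicit loops / generic
# optimizers so they share no code path with the package implementation.

# scalar-loop l2,1 norm
loop_l21 <- function(M_) {
  total <- 0
  for (i in seq_len(nrow(M_))) {
    s <- 0
    for (j in seq_len(ncol(M_))) s <- s + M_[i, j]^2
    total <- total + sqrt(s)
  }
  total
}

# element-wise triple-loop residual A - X W H' Y'
loop_residual <- function(A, X, W, H, Y) {
  M <- nrow(A); N <- ncol(A)
  out <- matrix(0, M, N)
  for (i in seq_len(M)) for (j in seq_len(N)) {
    s <- 0
    for (a in seq_len(ncol(X))) for (b in seq_len(ncol(Y))) {
      for (k in seq_len(ncol(W))) {
        s <- s + X[i, a] * W[a, k] * H[b, k] * Y[j, b]
      }
    }
    out[i, j] <- A[i, j] - s
  }
  out
}

# index-by-index robust W update (mirrors the printed formula literally)
loop_update_W <- function(A, X, Y, W, H, d, p, lambda1, eps) {
  D <- diag(d, length(d)); P <- diag(p, length(p))
  num <- t(X) %*% D %*% A %*% Y %*% H
  den <- t(X) %*% D %*% X %*% W %*% t(H) %*% t(Y) %*% Y %*% H +
    lambda1 * P %*% W
  Wn <- W
  for (i in seq_len(nrow(W))) for (j in seq_len(ncol(W))) {
    Wn[i, j] <- W[i, j] * num[i, j] / (den[i, j] + eps)
  }
  Wn
}

loop_update_H <- function(A, X, Y, W, H, d, q, lambda2, eps) {
  D <- diag(d, length(d)); Q <- diag(q, length(q))
  num <- t(Y) %*% t(A) %*% D %*% X %*% W
  den <- t(Y) %*% Y %*% H %*% t(W) %*% t(X) %*% D %*% X %*% W +
    lambda2 * Q %*% H
  Hn <- H
  for (i in seq_len(nrow(H))) for (j in seq_len(ncol(H))) {
    Hn[i, j] <- H[i, j] * num[i, j] / (den[i, j] + eps)
  }
  Hn
}

# projected gradient descent with backtracking line search on (W, H),
# projecting onto the nonnegative orthant; generic in the objective.
pgd_minimize <- function(objfun, gradfun, W, H, iters = 5000, tol = 1e-12) {
  step <- 1
  f <- objfun(W, H)
  for (it in seq_len(iters)) {
    g <- gradfun(W, H)
    repeat {
      W2 <- pmax(W - step * g$W, 0)
      H2 <- pmax(H - step * g$H, 0)
      f2 <- objfun(W2, H2)
      if (f2 <= f || step < 1e-15) break
      step <- step / 2
    }
    if (abs(f - f2) < tol * max(1, abs(f))) {
      W <- W2; H <- H2; f <- f2
      break
    }
    W <- W2; H <- H2; f <- f2
    step <- step * 1.5
  }
  list(W = W, H = H, objective = f)
}

# gradients of the standard (Frobenius + ridge) objective
imc_gradients <- function(A, X, Y, lambda1, lambda2) {
  function(W, H) {
    R <- A - X %*% W %*% t(H) %*% t(Y)
    list(W = -crossprod(X, R %*% Y %*% H) + lambda1 * W,
         H = -crossprod(Y, crossprod(R, X %*% W)) + lambda2 * H)
  }
}

# eps-smoothed l2,1 objective and gradients: sqrt(||row||^2 + delta)
rimc_smoothed <- function(A, X, Y, lambda1, lambda2, delta = 1e-12) {
  obj <- function(W, H) {
    R <- A - X %*% W %*% t(H) %*% t(Y)
    sum(sqrt(rowSums(R^2) + delta)) +
      lambda1 * sum(sqrt(rowSums(W^2) + delta)) +
      lambda2 * sum(sqrt(rowSums(H^2) + delta))
  }
  grad <- function(W, H) {
    R <- A - X %*% W %*% t(H) %*% t(Y)
    d <- 1 / sqrt(rowSums(R^2) + delta)
    p <- 1 / sqrt(rowSums(W^2) + delta)
    q <- 1 / sqrt(rowSums(H^2) + delta)
    list(W = -crossprod(X, (d * R) %*% Y %*% H) + lambda1 * p * W,
         H = -crossprod(Y, crossprod(d * R, X %*% W)) + lambda2 * q * H)
  }
  list(obj = obj, grad = grad)
}

# brute-force per-row set-intersection ranking metrics
loop_metrics <- function(split, rankings, k) {
  precs <- c(); recs <- c()
  for (l in names(split$hidden_sets)) {
    hid <- split$hidden_sets[[l]]
    top <- rankings[[l]][1:k]
    hit <- 0
    for (col in top) if (col %in% hid) hit <- hit + 1
    precs <- c(precs, hit / k)
    recs <- c(recs, hit / length(hid))
  }
  list(precision = mean(precs), recall = mean(recs))
}

# power iteration for the leading singular triple of F
power_leading <- function(F_, iters = 2000) {
  set.seed(99)
  v <- runif(ncol(F_))
  for (i in seq_len(iters)) {
    v <- crossprod(F_, F_ %*% v)
    v <- v / sqrt(sum(v^2))
  }
  u <- F_ %*% v
  s <- sqrt(sum(u^2))
  list(u = as.numeric(u / s), d = s)
}
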