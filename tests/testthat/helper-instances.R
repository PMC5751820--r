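# Small seeded problem instances built in code.

# random binary association instance with uniform nonnegative features
tiny_instance <- function(seed, M = 6, N = 5, m = 3, n = 3, density = 0.3) {
  set.seed(seed)
  list(A = matrix(rbinom(M * N, 1, density), M, N),
       X = matrix(runif(M * m), M, m),
       Y = matrix(runif(N * n), N, n))
}

# noiseless planted instance: A = X W* H*' Y' (real-valued, nonnegative)
planted_instance <- function(seed, M = 20, N = 15, m = 6, n = 5, r = 2) {
  set.seed(seed)
  X <- matrix(runif(M * m), M, m)
  Y <- matrix(runif(N * n), N, n)
  W <- matrix(runif(m * r), m, r)
  H <- matrix(runif(n * r), n, r)
  list(A = X %*% W %*% t(H) %*% t(Y), X = X, Y = Y, W = W, H = H)
}

rel_err <- function(est, truth) {
  norm(as.matrix(est - truth), "F") / norm(as.matrix(truth), "F")
}
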