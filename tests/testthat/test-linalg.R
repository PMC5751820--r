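test_that("row norms and the l2,1 norm match hand values and the loop oracle", {
  expect_equal(row_l2_norms(rbind(c(3, 4), c(0, 0))), c(5, 0))
  expect_equal(row_l2_norms(matrix(0, 3, 4)), rep(0, 3))
  expect_equal(row_l2_norms(diag(2)), c(1, 1))
  expect_equal(l21_norm(rbind(c(3, 4), c(0, 0))), 5)
  expect_equal(l21_norm(diag(2)), 2)
  expect_equal(l21_norm(rbind(c(3, 4), c(5, 12))), 18)
  for (s in 1:5) {
    set.seed(s)
    M_ <- matrix(rnorm(35), 7, 5)
    expect_equal(l21_norm(M_), loop_l21(M_), tolerance = 1e-12)
    expect_equal(l21_norm(M_), sum(row_l2_norms(M_)))
  }
  bad <- matrix(1, 2, 2); bad[2, 1] <- NaN
  expect_error(row_l2_norms(bad), "row")
})

test_that("the l2,1 norm is absolutely homogeneous", {
  for (s in 1:5) {
    set.seed(s)
    M_ <- matrix(rnorm(24), 6, 4)
    c_ <- rnorm(1)
    expect_equal(l21_norm(c_ * M_), abs(c_) * l21_norm(M_),
                 tolerance = 1e-12)
  }
})

test_that("residual reduces to A for zero factors and to zero for exact fits", {
  d <- tiny_instance(1)
  W0 <- matrix(0, 3, 2); H0 <- matrix(0, 3, 2)
  expect_equal(imc_residual(d$A, d$X, list(W = W0, H = H0), d$Y), d$A,
               ignore_attr = TRUE)
  set.seed(2)
  W <- matrix(runif(8), 4, 2); H <- matrix(runif(6), 3, 2)
  A <- W %*% t(H)
  expect_equal(imc_residual(A, diag(4), list(W = W, H = H), diag(3)),
               matrix(0, 4, 3), ignore_attr = TRUE)
})

test_that("residual and scores match the element-wise loop oracle", {
  set.seed(7)
  A <- matrix(rbinom(12, 1, 0.4), 4, 3)
  X <- matrix(runif(8), 4, 2); Y <- matrix(runif(6), 3, 2)
  W <- matrix(runif(4), 2, 2); H <- matrix(runif(4), 2, 2)
  R <- imc_residual(A, X, list(W = W, H = H), Y)
  expect_equal(R, loop_residual(A, X, W, H, Y), tolerance = 1e-12)
  expect_equal(predict_scores(X, list(W = W, H = H), Y), A - R,
               tolerance = 1e-12)
  expect_equal(predict_scores(diag(2), list(W = W, H = H), diag(2)),
               W %*% t(H))
  expect_equal(predict_scores(X, list(W = W * 0, H = H), Y),
               matrix(0, 4, 3))
})

test_that("shape mismatches are reported with all five shapes", {
  d <- tiny_instance(1)
  err <- expect_error(
    imc_residual(d$A, d$X, list(W = matrix(1, 4, 2), H = matrix(1, 3, 2)), d$Y))
  expect_match(conditionMessage(err), "A 6x5.*X 6x3.*W 4x2.*H 3x2.*Y 5x3")
})

test_that("objectives take their closed-form values in degenerate cases", {
  d <- tiny_instance(3)
  W0 <- matrix(0, 3, 2); H0 <- matrix(0, 3, 2)
  # zero factors: half the number of ones for the Frobenius objective
  expect_equal(objective_imc(d$A, d$X, d$Y, list(W = W0, H = H0)),
               0.5 * sum(d$A))
  # perfect fit
  p <- planted_instance(4)
  expect_equal(objective_imc(p$A, p$X, p$Y, list(W = p$W, H = p$H)), 0,
               tolerance = 1e-12)
  expect_equal(objective_rimc(p$A, p$X, p$Y, list(W = p$W, H = p$H)), 0,
               tolerance = 1e-6)
  # one positive per row: the l2,1 loss of zero factors is M
  A1 <- diag(4)
  expect_equal(objective_rimc(A1, diag(4), diag(4),
                              list(W = matrix(0, 4, 2), H = matrix(0, 4, 2))),
               4)
  Z <- matrix(runif(12), 3, 4)
  expect_equal(objective_rnmf(Z, list(W = matrix(0, 3, 2),
                                      H = matrix(0, 4, 2))), l21_norm(Z))
})

test_that("objectives match scalar-loop oracles on seeded instances and are nonnegative", {
  for (s in 1:4) {
    set.seed(s)
    A <- matrix(rbinom(20, 1, 0.4), 5, 4)
    X <- matrix(runif(15), 5, 3); Y <- matrix(runif(8), 4, 2)
    W <- matrix(runif(6), 3, 2); H <- matrix(runif(4), 2, 2)
    R <- loop_residual(A, X, W, H, Y)
    l1 <- 0.3; l2 <- 0.7
    expect_equal(objective_imc(A, X, Y, list(W = W, H = H), l1, l2),
                 0.5 * sum(R^2) + l1 / 2 * sum(W^2) + l2 / 2 * sum(H^2),
                 tolerance = 1e-12)
    o_r <- loop_l21(R) + l1 * loop_l21(W) + l2 * loop_l21(H)
    expect_equal(objective_rimc(A, X, Y, list(W = W, H = H), l1, l2), o_r,
                 tolerance = 1e-12)
    Z <- W %*% t(H) + matrix(rnorm(6, sd = 0.1), 3, 2)
    expect_equal(objective_rnmf(Z, list(W = W, H = H), l1, l2),
                 loop_l21(Z - W %*% t(H)) + l1 * loop_l21(W) +
                   l2 * loop_l21(H), tolerance = 1e-12)
    expect_gte(objective_imc(A, X, Y, list(W = W, H = H), l1, l2), 0)
    expect_gte(objective_rimc(A, X, Y, list(W = W, H = H), l1, l2), 0)
  }
})

test_that("an l2,1 residual with one nonzero per row reduces to an l1 norm", {
  set.seed(11)
  vals <- rnorm(4)
  R <- matrix(0, 4, 3)
  R[cbind(1:4, sample(3, 4, replace = TRUE))] <- vals
  # objective_rimc of A = R with zero factors equals l21(R) = sum |vals|
  expect_equal(objective_rimc(R, diag(4), diag(3),
                              list(W = matrix(0, 4, 2), H = matrix(0, 3, 2))),
               sum(abs(vals)), tolerance = 1e-12)
})

test_that("container constructors enforce their invariants", {
  expect_error(association_matrix(matrix(c(0, 2), 1, 2)), "0 or 1")
  expect_error(association_matrix(diag(2), row_ids = c("a", "a")), "unique")
  expect_error(feature_matrix(matrix(c(1, Inf), 1, 2)), "finite")
  expect_error(feature_matrix(matrix(-1, 1, 1), nonneg = TRUE), "negative")
  expect_error(factor_pair(matrix(-1, 2, 2), matrix(1, 2, 2)), "nonnegative")
  expect_error(factor_pair(matrix(1, 2, 2), matrix(1, 2, 3)), "same number")
  expect_error(diag_weights(c(1, 0), 1e-8), "> 0")
  expect_error(diag_weights(2e8, 1e-8), "1/eps")
  expect_error(train_config(tol = 0))
  cfg <- train_config(rank = 3, seed = 9)
  expect_s3_class(cfg, "train_config")
  expect_identical(cfg$rank, 3L)
})
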