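test_that("column ranking sorts by descending score with index tie-breaks", {
  expect_equal(rank_columns_for_row(c(0.1, 0.9, 0.5)), c(2, 3, 1))
  expect_equal(rank_columns_for_row(rep(0.5, 4)), 1:4)
  expect_equal(rank_columns_for_row(c(0.1, 0.9, 0.5), exclude = 2), c(3, 1))
  expect_error(rank_columns_for_row(c(1, 2), exclude = 1:2), "covers all")
  expect_error(rank_columns_for_row(c(1, NA)), "finite")
  for (s in 1:5) {
    set.seed(s)
    sc <- sample(round(runif(20), 1))  # deliberate ties
    rk <- rank_columns_for_row(sc)
    expect_equal(rk, order(-sc, seq_along(sc)))
  }
})

# a minimal hand-built split: 1 evaluated row with hidden columns {1, 3}
toy_split <- function() {
  A <- rbind(c(1, 0, 1, 0, 1), c(0, 1, 0, 0, 0))
  A_train <- A; A_train[1, c(1, 3)] <- 0
  robimc:::new_holdout_split(A_train, list(`1` = c(1L, 3L)), "transductive_cv")
}

test_that("precision and recall at k count hidden hits as defined", {
  sp <- toy_split()
  rk <- list(`1` = c(1L, 2L, 3L, 4L))  # candidate 5 is a training positive
  expect_equal(precision_at_k(sp, rk, 2), 0.5)
  expect_equal(recall_at_k(sp, rk, 2), 0.5)
  expect_equal(recall_at_k(sp, rk, 3), 1.0)
  expect_equal(precision_at_k(sp, rk, 1), 1.0)  # ceiling when topk all hidden
  expect_error(precision_at_k(sp, rk, 5), "exceeds")
})

test_that("metrics match a brute-force oracle over random ranking instances", {
  for (s in 1:100) {
    set.seed(s)
    N <- 12
    n_rows <- sample(2:4, 1)
    hidden <- lapply(seq_len(n_rows), function(i)
      sort(sample(N, sample(1:4, 1))))
    names(hidden) <- seq_len(n_rows)
    split <- robimc:::new_holdout_split(matrix(0, n_rows, N), hidden, "test")
    rankings <- lapply(hidden, function(h) sample(N))
    k <- sample(1:8, 1)
    oracle <- loop_metrics(split, rankings, k)
    expect_equal(precision_at_k(split, rankings, k), oracle$precision)
    expect_equal(recall_at_k(split, rankings, k), oracle$recall)
    # consistency identity: both metrics count the same intersections
    sizes <- lengths(hidden)
    expect_equal(precision_at_k(split, rankings, k) * k * n_rows,
                 sum(sapply(names(hidden), function(l)
                   length(intersect(rankings[[l]][1:k], hidden[[l]])))))
  }
})

test_that("recall and scaled precision are non-decreasing in k", {
  set.seed(42)
  N <- 15
  hidden <- list(`1` = c(2L, 5L, 9L), `2` = c(1L, 14L))
  split <- robimc:::new_holdout_split(matrix(0, 2, N), hidden, "test")
  rankings <- lapply(hidden, function(h) sample(N))
  recs <- sapply(1:N, function(k) recall_at_k(split, rankings, k))
  precs_k <- sapply(1:N, function(k) precision_at_k(split, rankings, k) * k)
  expect_true(all(diff(recs) >= -1e-12))
  expect_true(all(diff(precs_k) >= -1e-12))
  expect_equal(recs[N], 1)
})

test_that("random scores achieve recall@k near k over the candidate count", {
  # expectation check over 200 seeded draws, within 3 standard errors
  N <- 30; k <- 6
  hidden <- list(`1` = c(3L, 11L, 20L))
  split <- robimc:::new_holdout_split(matrix(0, 1, N), hidden, "test")
  vals <- vapply(1:200, function(s) {
    set.seed(s)
    recall_at_k(split, list(`1` = rank_columns_for_row(runif(N))), k)
  }, numeric(1))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - k / N), 3 * se)
})

test_that("CV folds partition the positives into near-equal hidden sets", {
  set.seed(2)
  A <- matrix(rbinom(400, 1, 0.15), 20, 20)
  folds <- make_cv_folds(A, n_folds = 5, seed = 3)
  pos <- which(A == 1)
  hidden_cells <- lapply(folds, function(f) which(A == 1 & f$A_train == 0))
  all_hidden <- sort(unlist(hidden_cells))
  expect_equal(all_hidden, pos)                        # union = positives
  expect_equal(sum(lengths(hidden_cells)), length(pos)) # disjoint
  expect_lte(diff(range(lengths(hidden_cells))), 1)     # balanced
  for (f in folds) {
    for (l in names(f$hidden_sets)) {
      i <- as.integer(l)
      expect_true(all(A[i, f$hidden_sets[[l]]] == 1))
      expect_true(all(f$A_train[i, f$hidden_sets[[l]]] == 0))
    }
  }
  expect_error(make_cv_folds(matrix(0, 3, 3), 2, 1), "positives")
})

test_that("row hold-outs zero held rows and hide exactly their positives", {
  set.seed(5)
  A <- matrix(rbinom(100 * 40, 1, 0.1), 100, 40)
  sp <- holdout_new_rows(A, fraction = 0.1, seed = 6)
  expect_length(sp$held_rows, 10)
  expect_true(all(sp$A_train[sp$held_rows, ] == 0))
  hidden_pairs <- sum(lengths(sp$hidden_sets))
  expect_equal(hidden_pairs, sum(A[sp$held_rows, ]))
  # reproducible
  sp2 <- holdout_new_rows(A, fraction = 0.1, seed = 6)
  expect_identical(sp, sp2)
})

test_that("column hold-outs mirror row hold-outs on the transpose", {
  set.seed(7)
  A <- matrix(rbinom(50 * 60, 1, 0.1), 50, 60)
  sp <- holdout_new_cols(A, fraction = 0.1, seed = 8)
  expect_length(sp$held_cols, 6)
  expect_true(all(sp$A_train[, sp$held_cols] == 0))
  for (l in names(sp$hidden_sets)) {
    i <- as.integer(l)
    expect_true(all(sp$hidden_sets[[l]] %in% sp$held_cols))
    expect_true(all(A[i, sp$hidden_sets[[l]]] == 1))
  }
  expect_equal(sum(lengths(sp$hidden_sets)), sum(A[, sp$held_cols]))
})

test_that("double hold-outs hide only held-row x held-col positives", {
  set.seed(9)
  A <- matrix(rbinom(200 * 200, 1, 0.05), 200, 200)
  sp <- holdout_both(A, row_fraction = 0.05, col_fraction = 0.05, seed = 10)
  expect_length(sp$held_rows, 10)
  expect_length(sp$held_cols, 10)
  expect_true(all(sp$A_train[sp$held_rows, ] == 0))
  expect_true(all(sp$A_train[, sp$held_cols] == 0))
  for (l in names(sp$hidden_sets)) {
    expect_true(as.integer(l) %in% sp$held_rows)
    expect_true(all(sp$hidden_sets[[l]] %in% sp$held_cols))
  }
  expect_equal(sum(lengths(sp$hidden_sets)),
               sum(A[sp$held_rows, sp$held_cols]))
})

test_that("benchmark output is well-formed and a ground-truth scorer hits the ceiling", {
  ds <- generate_planted_dataset(list(M = 40L, N = 60L, m = 6L, n = 5L,
                                      r = 2L, density = 0.08, seed = 20))
  cfg <- train_config(rank = 2, lambda1 = 0.01, lambda2 = 0.01,
                      max_iter = 60, tol = 1e-6, seed = 20)
  tb <- run_benchmark(c("imc", "nmf"), ds, mode = "cv", k_grid = c(5L, 10L),
                      n_repeats = 2L, seed = 20, config = cfg, n_folds = 5L)
  expect_equal(nrow(tb), 2 * 2 * 2)  # methods x k x metrics
  expect_true(all(tb$mean >= 0 & tb$mean <= 1))
  expect_true(all(tb$sd >= 0))
  expect_gt(max(tb$sd), 0)  # repeats with different splits vary generically
  expect_error(run_benchmark("nmf", ds, mode = "new_rows", k_grid = 5L,
                             seed = 1, config = cfg), "transductive")
  # an oracle given the latent surface recovers every hidden positive early:
  # hidden positives are top-surface cells, so recall at large k reaches 1
  sp <- make_cv_folds(unclass(ds$A), 5L, 21L)[[1]]
  rks <- lapply(stats::setNames(nm = names(sp$hidden_sets)), function(l) {
    i <- as.integer(l)
    rank_columns_for_row(ds$S[i, ], exclude = which(sp$A_train[i, ] == 1))
  })
  expect_equal(recall_at_k(sp, rks, 55), 1)
  expect_gt(recall_at_k(sp, rks, 10), 0.9)
})

test_that("metric tables round-trip through the TSV writer deterministically", {
  tb <- data.frame(method = c("imc", "rimc"), mode = "cv", k = 5L,
                   metric = "recall", mean = c(1 / 3, 2 / 3),
                   sd = c(0.01, NA), n_repeats = 2L)
  f1 <- tempfile(); f2 <- tempfile()
  write_metrics_tsv(tb, f1)
  write_metrics_tsv(tb[2:1, ], f2)  # row order must not matter
  expect_identical(readLines(f1), readLines(f2))
  back <- read.delim(f1)
  expect_equal(back$mean, tb$mean, tolerance = 1e-9)
})
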