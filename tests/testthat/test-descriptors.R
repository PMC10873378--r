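test_that("pooled descriptor widths are 1x, 1x, 4x, 6x the model width", {
  for (d in c(16, 512)) {
    mem <- matrix(rnorm(7 * d), 7, d)
    expect_length(pool_memory(mem, "mean"), d)
    expect_length(pool_memory(mem, "first_token"), d)
    expect_length(pool_memory(mem, "concat4"), 4 * d)
    expect_length(pool_memory(mem, "concat6"), 6 * d)
  }
})

test_that("pooling segments equal independently recomputed column statistics", {
  set.seed(12)
  mem <- matrix(rnorm(7 * 16), 7, 16)
  v6 <- pool_memory(mem, "concat6")
  seg <- function(k) v6[((k - 1) * 16 + 1):(k * 16)]
  for (j in 1:16) {
    col <- mem[, j]
    expect_equal(seg(1)[j], sum(col) / 7)
    expect_equal(seg(2)[j], max(col))
    expect_equal(seg(3)[j], min(col))
    expect_equal(seg(4)[j], sqrt(mean((col - mean(col))^2)))  # population sd
    expect_equal(seg(5)[j], mem[1, j])
    expect_equal(seg(6)[j], mem[7, j])
  }
  v4 <- pool_memory(mem, "concat4")
  expect_equal(v4, v6[c(1:32, 65:96)], ignore_attr = TRUE)
})

test_that("single-position memory pools degenerately (sd = 0)", {
  mem <- matrix(rnorm(16), 1, 16)
  v <- pool_memory(mem, "concat6")
  expect_equal(v[1:16], mem[1, ], ignore_attr = TRUE)       # mean
  expect_equal(v[17:32], mem[1, ], ignore_attr = TRUE)      # max
  expect_equal(v[49:64], rep(0, 16), ignore_attr = TRUE)    # sd
  expect_error(pool_memory(matrix(numeric(0), 0, 4)), "nrow")
})

test_that("order-statistic pools are permutation-invariant; positional are not", {
  set.seed(4)
  mem <- matrix(rnorm(6 * 8), 6, 8)
  perm <- mem[c(3, 1, 6, 2, 5, 4), ]
  expect_equal(pool_memory(mem, "mean"), pool_memory(perm, "mean"))
  for (k in 1:4) {  # mean,max,min,sd segments of concat6 are invariant
    i <- ((k - 1) * 8 + 1):(k * 8)
    expect_equal(pool_memory(mem, "concat6")[i],
                 pool_memory(perm, "concat6")[i])
  }
  expect_false(isTRUE(all.equal(pool_memory(mem, "first_token"),
                                pool_memory(perm, "first_token"))))
})

test_that("baseline descriptors behave as documented", {
  set.seed(9)
  r1 <- baseline_descriptor("random_uniform")
  expect_length(r1, 2048)
  expect_true(all(r1 >= 0 & r1 <= 1))
  set.seed(9)
  expect_identical(baseline_descriptor("random_uniform"), r1)
  e1 <- baseline_descriptor("ecfp", "CCO")
  e2 <- baseline_descriptor("ecfp", "OCC")
  expect_equal(tanimoto(e1, e2), 1)
  expect_error(baseline_descriptor("ecfp", "C1CC"), "invalid")
})

test_that("encoder memory has one row per non-pad source position", {
  x <- fixture_tiny_model()
  ids <- tokenize(x$corpus$canonical_smiles[1], x$vocab)
  mem <- encoder_memory(x$model, c(ids, 0L, 0L))
  expect_equal(dim(mem), c(length(ids), x$cfg$d_model))
})

test_that("downstream folds are disjoint, exhaustive, and scores sane", {
  set.seed(21)
  n <- 160
  X <- matrix(rnorm(n * 12), n, 12)
  y <- as.integer(runif(n) < 0.5)            # labels independent of X
  res <- downstream_eval(X, y, "classification", n_folds = 5, n_trials = 2)
  expect_length(res$fold_scores, 5)
  expect_equal(res$metric, "AUROC")
  expect_gt(res$mean, 0.35); expect_lt(res$mean, 0.65)
  # leakage: label present as a column is found immediately
  Xleak <- cbind(X, y)
  res2 <- downstream_eval(Xleak, y, "classification", n_folds = 5,
                          n_trials = 2)
  expect_gte(res2$mean, 0.99)
  expect_error(downstream_eval(X, rep(1L, n), "classification"),
               "degenerate")
})

test_that("noise-free linear signal is recovered nearly exactly", {
  set.seed(22)
  n <- 200
  X <- matrix(rnorm(n * 6), n, 6)
  y <- 2 * X[, 1] - 3 * X[, 4]
  res <- downstream_eval(X, y, "regression", n_folds = 5, n_trials = 4)
  expect_equal(res$metric, "RMSE")
  expect_lt(res$mean, 0.35 * stats::sd(y))
})
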