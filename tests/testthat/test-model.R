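tiny_cfg <- function(...) {
  model_config(d_model = 8, d_ff = 12, n_layers_enc = 1, n_layers_dec = 1,
               n_heads = 2, dropout = 0, warmup_steps = 50, max_len = 16,
               seed = 3, ...)
}

tiny_batch <- function() {
  list(source = matrix(c(1, 4, 5, 6, 2, 0,
                         1, 7, 8, 2, 0, 0), 2, 6, byrow = TRUE),
       target = matrix(c(1, 5, 6, 7, 8, 2,
                         1, 8, 4, 2, 0, 0), 2, 6, byrow = TRUE))
}

test_that("model building is reproducible and init schemes differ", {
  cfg <- tiny_cfg()
  m1 <- build_model(cfg, 9, 9)
  m2 <- build_model(cfg, 9, 9)
  expect_identical(m1$params, m2$params)
  m3 <- build_model(tiny_cfg(init_scheme = "he_normal"), 9, 9)
  expect_false(identical(m1$params$src_emb, m3$params$src_emb))
  # he-normal linear weights have roughly the expected scale
  w <- m3$params$enc_l1_ff_W1
  expect_equal(stats::sd(as.numeric(w)), sqrt(2 / nrow(w)), tolerance = 0.3)
})

test_that("pre-LN and post-LN configurations have equal parameter counts", {
  post <- build_model(tiny_cfg(), 9, 9)
  pre <- build_model(tiny_cfg(norm_placement = "pre_ln"), 9, 9)
  # pre-LN adds only the two final normalizations (2 * 2 * d_model scalars)
  expect_equal(n_params(pre) - n_params(post), 4 * 8)
  att_ff_ln <- function(m) sum(vapply(
    m$params[grep("^(enc|dec)_l", names(m$params))], length, numeric(1)))
  expect_equal(att_ff_ln(post), att_ff_ln(pre))
})

test_that("parameter count of a tiny model equals the closed-form sum", {
  d <- 8; ff <- 12; Vs <- 10; Vt <- 10
  m <- build_model(model_config(d_model = d, d_ff = ff, n_layers_enc = 1,
                                n_layers_dec = 1, n_heads = 2, dropout = 0,
                                max_len = 16, seed = 1), Vs, Vt)
  emb <- (Vs + Vt) * d
  att <- 4 * (d * d + d)          # q,k,v,o projections with bias
  ln <- 2 * d
  ffn <- d * ff + ff + ff * d + d
  enc <- att + ffn + 2 * ln
  dec <- 2 * att + ffn + 3 * ln
  out <- d * Vt + Vt
  expect_equal(n_params(m), emb + enc + dec + out)
})

test_that("warmup schedule has the documented shape and closed-form values", {
  cfg <- model_config(d_model = 512, warmup_steps = 4000, seed = 1)
  expect_equal(lr_at_step(4000, cfg), 512^(-0.5) * 4000^(-0.5))
  # continuity at the knee: both branches agree
  expect_equal(512^(-0.5) * 4000 * 4000^(-1.5), 512^(-0.5) * 4000^(-0.5))
  steps <- c(1, 10, 100, 1000, 3999)
  expect_true(all(diff(lr_at_step(steps, cfg)) > 0))
  steps2 <- c(4000, 5000, 10000, 80000)
  expect_true(all(diff(lr_at_step(steps2, cfg)) < 0))
  expect_error(lr_at_step(0, cfg))
})

test_that("cross-entropy excludes padding and matches closed forms", {
  V <- 7
  logits <- matrix(0, 4, V)                      # uniform scores
  tgt <- c(3L, 4L, 5L, 6L)
  lo <- token_xent_loss(logits, tgt)
  expect_equal(lo$loss, log(V), tolerance = 1e-12)
  # appending pad positions leaves the loss unchanged
  lo2 <- token_xent_loss(rbind(logits, matrix(rnorm(2 * V), 2, V)),
                         c(tgt, 0L, 0L))
  expect_equal(lo2$loss, lo$loss, tolerance = 1e-12)
  # random logits equal an independently computed softmax cross-entropy
  set.seed(2)
  L <- matrix(rnorm(5 * V), 5, V)
  t5 <- c(1L, 2L, 3L, 4L, 5L)
  by_hand <- mean(vapply(1:5, function(i) {
    p <- exp(L[i, ]) / sum(exp(L[i, ]))
    -log(p[t5[i] + 1])
  }, numeric(1)))
  expect_equal(token_xent_loss(L, t5)$loss, by_hand, tolerance = 1e-12)
  expect_error(token_xent_loss(logits, rep(0L, 4)), "padding")
})

test_that("analytic gradients match numerical differentiation", {
  for (norm in c("post_ln", "pre_ln")) {
    m <- build_model(tiny_cfg(norm_placement = norm), 9, 9)
    batch <- tiny_batch()
    lg <- model_loss_grads(m, batch, train = FALSE)
    eps <- 1e-6
    set.seed(31)
    for (nm in sample(names(m$params), 8)) {
      k <- sample(length(m$params[[nm]]), 1)
      m2 <- m
      m2$params[[nm]][k] <- m$params[[nm]][k] + eps
      up <- model_loss_grads(m2, batch, train = FALSE)$loss
      m2$params[[nm]][k] <- m$params[[nm]][k] - eps
      dn <- model_loss_grads(m2, batch, train = FALSE)$loss
      num <- (up - dn) / (2 * eps)
      expect_equal(lg$grads[[nm]][k], num, tolerance = 1e-4,
                   label = paste("grad", nm))
    }
  }
})

test_that("teacher-forced predictions are causal", {
  m <- build_model(tiny_cfg(), 9, 9)
  src <- c(1L, 4L, 5L, 2L)
  tgt <- c(1L, 5L, 6L, 7L, 8L, 2L)
  base <- teacher_forced_predict(m, src, tgt)[[1]]
  for (cut in 2:5) {
    tgt2 <- tgt
    tgt2[(cut + 1):6] <- sample(4:8, 6 - cut, replace = TRUE)
    pert <- teacher_forced_predict(m, src, tgt2)[[1]]
    # predictions at positions <= cut depend only on tokens < position
    expect_identical(base[seq_len(cut)], pert[seq_len(cut)])
  }
  expect_length(base, length(tgt) - 1L)
})

test_that("loss is invariant to extra padding columns", {
  m <- build_model(tiny_cfg(), 9, 9)
  b <- tiny_batch()
  l1 <- model_loss_grads(m, b, train = FALSE)$loss
  b2 <- list(source = cbind(b$source, 0L, 0L),
             target = cbind(b$target, 0L))
  l2 <- model_loss_grads(m, b2, train = FALSE)$loss
  expect_equal(l1, l2, tolerance = 1e-10)
})

test_that("training is deterministic and decodes its overfitted batch", {
  x <- fixture_tiny_model()
  pairs <- make_translation_pairs(x$corpus, x$vocab, source_mode = "stored")
  batch <- make_batches(pairs, 400, bucketing = FALSE)[[1]]
  run <- function() {
    set.seed(1)
    m <- x$model; st <- NULL
    for (i in 1:150) {
      r <- train_step(m, batch, st)
      m <- r$model; st <- r$state
    }
    list(m = m, st = st)
  }
  r1 <- run(); r2 <- run()
  expect_identical(r1$st$loss_history, r2$st$loss_history)
  expect_true(all(r1$st$loss_history$loss >= 0))
  final_loss <- tail(r1$st$loss_history$loss, 1)
  expect_lt(final_loss, 0.05)
  # greedy decoding reproduces every training target exactly
  dec <- greedy_decode(r1$m, batch$source, max_len = 40)
  tgt <- x$corpus$canonical_smiles[batch$molecule_index]
  got <- vapply(dec, detokenize, character(1), vocab = x$vocab)
  expect_identical(got, tgt)
  # decoding twice gives identical output
  dec2 <- greedy_decode(r1$m, batch$source, max_len = 40)
  expect_identical(dec, dec2)
  # teacher-forced predictions equal the targets on the overfitted batch
  tf <- teacher_forced_predict(r1$m, batch$source, batch$target)
  for (i in seq_along(tf)) {
    want <- batch$target[i, -1]
    keep <- want != 0L
    expect_identical(tf[[i]][keep], want[keep])
  }
})

test_that("greedy decoding respects max_len and flags truncation", {
  m <- build_model(tiny_cfg(), 9, 9)
  out <- greedy_decode(m, c(1L, 4L, 2L), max_len = 2)
  expect_lte(length(out[[1]]), 2)
  long <- greedy_decode(m, c(1L, 4L, 2L), max_len = 5)[[1]]
  if (!identical(long[length(long)], 2L))
    expect_true(isTRUE(attr(long, "truncated")))
})

test_that("non-finite loss aborts with a diagnostic", {
  m <- build_model(tiny_cfg(), 9, 9)
  m$params$out_W[] <- NaN
  expect_error(train_step(m, tiny_batch()), "non-finite loss")
})

test_that("compiled and reference engines agree to near machine precision", {
  for (norm in c("post_ln", "pre_ln")) {
    m <- build_model(tiny_cfg(norm_placement = norm), 9, 11)
    batch <- tiny_batch()
    a <- model_loss_grads(m, batch, train = FALSE, engine = "r")
    b <- model_loss_grads(m, batch, train = FALSE, engine = "cpp")
    expect_equal(a$loss, b$loss, tolerance = 1e-12)
    for (nm in names(a$grads))
      expect_lt(max(abs(a$grads[[nm]] - b$grads[[nm]])), 1e-10)
  }
})
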