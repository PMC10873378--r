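test_that("Welch/Bonferroni comparisons match closed forms", {
  ctrl <- c(60000, 58000, 62000, 61000)
  # identical group: t = 0, raw p = 1, corrected p = 1
  res <- compare_conditions(list(none = ctrl, same = ctrl), control = "none")
  expect_equal(res$t_statistic, 0)
  expect_equal(res$raw_p, 1)
  expect_equal(res$corrected_p, 1)
  # strongly separated groups: small corrected p
  fast <- c(10000, 10400, 9800, 10100)
  res2 <- compare_conditions(list(none = ctrl, pre_ln = fast),
                             control = "none")
  expect_lt(res2$corrected_p, 0.01)
  # closed-form Welch t for one pair
  tt <- (mean(fast) - mean(ctrl)) /
    sqrt(var(fast) / length(fast) + var(ctrl) / length(ctrl))
  expect_equal(res2$t_statistic, tt, tolerance = 1e-12)
  # Bonferroni multiplies by the number of non-control groups, capped at 1
  g4 <- list(none = ctrl, a = ctrl + rnorm(4, 0, 500),
             b = ctrl + rnorm(4, 0, 500), c = ctrl + rnorm(4, 0, 500),
             d = ctrl + rnorm(4, 0, 500))
  res4 <- compare_conditions(g4, control = "none")
  expect_equal(res4$n_comparisons, rep(4, 4))
  expect_equal(res4$corrected_p, pmin(1, res4$raw_p * 4))
  expect_true(all(res4$corrected_p >= res4$raw_p))
  # both groups identical constants: t undefined
  expect_error(compare_conditions(list(none = c(5, 5), x = c(5, 5))),
               "undefined")
})

test_that("init seed and iteration seed factorize the randomness", {
  cfg <- model_config(d_model = 16, d_ff = 24, n_layers_enc = 1,
                      n_layers_dec = 1, n_heads = 2, dropout = 0,
                      max_len = 32, seed = 1)
  cfg$seed <- 42L
  m1 <- build_model(cfg, 12, 12)
  set.seed(999)  # unrelated draws in between must not matter
  runif(10)
  cfg$seed <- 42L
  m2 <- build_model(cfg, 12, 12)
  expect_identical(m1$params, m2$params)
})

make_micro_corpus <- function() {
  gcfg <- generator_config(40, heavy_atom_range = c(4, 7),
                           chiral_fraction = 0.5,
                           element_set = c("C", "N", "O"), seed = 55)
  generate_corpus(gcfg)
}

micro_spec <- function(max_steps = 20L, ...) {
  mcfg <- model_config(d_model = 16, d_ff = 24, n_layers_enc = 1,
                       n_layers_dec = 1, n_heads = 2, dropout = 0,
                       warmup_steps = 10, token_budget_per_step = 300,
                       accum_batches = 2, max_steps = max_steps,
                       max_len = 32, seed = 1)
  run_spec(mcfg, init_seed = 3, iteration_order_seed = 4, eval_every = 10,
           abort_at_perfect = NA, test_fraction = 0.2, ...)
}

test_that("an experiment run produces coherent snapshots and is repeatable", {
  corp <- make_micro_corpus()
  res <- run_experiment(micro_spec(), corp, similarity_cfgs = NULL)
  expect_equal(res$snapshots$step, c(10, 20))
  expect_true(all(res$snapshots$perfect_accuracy >= 0 &
                  res$snapshots$perfect_accuracy <= 1))
  expect_true(all(res$snapshots$partial_accuracy >=
                  res$snapshots$perfect_accuracy))
  # stagnation summary invariants
  expect_lte(res$stagnation$step_07, res$stagnation$step_095)
  expect_lte(res$stagnation$step_095, res$stagnation$end_step)
  # per-token tables and chirality breakdowns per evaluation
  expect_length(res$per_token, 2)
  expect_length(res$chirality, 2)
  b <- res$chirality[[1]]
  expect_equal(b$frac_correct + b$frac_chirality_only + b$frac_other, 1,
               tolerance = 1e-9)
  expect_equal(b$frac_correct, res$snapshots$perfect_accuracy[1],
               tolerance = 1e-12)
  # end-to-end determinism
  res2 <- run_experiment(micro_spec(), corp, similarity_cfgs = NULL)
  expect_identical(res$snapshots, res2$snapshots)
})

test_that("interventions change the intended configuration knob", {
  corp <- make_micro_corpus()
  sp <- micro_spec(max_steps = 2L)
  r_pre <- run_experiment(sp_with <- {
    s <- sp; s$intervention <- "pre_ln"; s
  }, corp, similarity_cfgs = NULL)
  expect_equal(r_pre$model$cfg$norm_placement, "pre_ln")
  r_adamw <- run_experiment({
    s <- sp; s$intervention <- "adamw"; s
  }, corp, similarity_cfgs = NULL)
  expect_equal(r_adamw$model$cfg$optimizer, "adamw")
  r_he <- run_experiment({
    s <- sp; s$intervention <- "he_normal"; s
  }, corp, similarity_cfgs = NULL)
  expect_equal(r_he$model$cfg$init_scheme, "he_normal")
  # chirality enrichment trains on fewer molecules but same test set
  r_chir <- run_experiment({
    s <- sp; s$intervention <- "chirality_enriched"; s
  }, corp, similarity_cfgs = NULL)
  expect_identical(r_chir$test, run_experiment(sp, corp,
                                               similarity_cfgs = NULL)$test)
})

test_that("training aborts once perfect accuracy crosses the abort threshold", {
  # overfit a tiny corpus so the threshold is reached, then check no
  # evaluations exist after the crossing step
  gcfg <- generator_config(12, heavy_atom_range = c(3, 5),
                           chiral_fraction = 0,
                           element_set = c("C", "O"), seed = 77)
  corp <- generate_corpus(gcfg)
  mcfg <- model_config(d_model = 24, d_ff = 48, n_layers_enc = 1,
                       n_layers_dec = 1, n_heads = 2, dropout = 0,
                       warmup_steps = 40, token_budget_per_step = 200,
                       accum_batches = 1, max_steps = 400, max_len = 32,
                       seed = 2)
  sp <- run_spec(mcfg, init_seed = 2, iteration_order_seed = 2,
                 eval_every = 20, abort_at_perfect = 0.9,
                 test_fraction = 0.25)
  res <- run_experiment(sp, corp, similarity_cfgs = NULL)
  crossed <- which(res$snapshots$perfect_accuracy >= 0.9)
  if (length(crossed) > 0) {
    expect_equal(crossed[1], nrow(res$snapshots))
    expect_lt(res$snapshots$step[crossed[1]], mcfg$max_steps)
  } else {
    expect_equal(tail(res$snapshots$step, 1), mcfg$max_steps)
  }
})
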