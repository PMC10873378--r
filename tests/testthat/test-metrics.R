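test_that("metrics match independent brute-force recounts on corrupted pairs", {
  px <- make_synthetic_pairs(400, seed = 11)
  p <- px$predictions; t <- px$targets
  expect_equal(perfect_accuracy(p, t), oracle_perfect(p, t), tolerance = 1e-12)
  expect_equal(partial_accuracy(p, t), oracle_partial(p, t), tolerance = 1e-12)
  for (tok in c("@", "@@", "C", "Cl")) {
    id <- px$vocab$token_to_id[[tok]]
    expect_equal(masked_perfect_accuracy(p, t, id),
                 oracle_masked(p, t, id), tolerance = 1e-12)
  }
  brk <- classify_chirality_errors(p, t, px$at, px$atat)
  orc <- oracle_chirality(p, t, px$at, px$atat)
  expect_equal(brk$frac_correct, unname(orc["correct"]), tolerance = 1e-12)
  expect_equal(brk$frac_chirality_only, unname(orc["chir"]), tolerance = 1e-12)
  expect_equal(brk$frac_other, unname(orc["other"]), tolerance = 1e-12)
})

test_that("per-token accuracy matches a recount and omits absent tokens", {
  px <- make_synthetic_pairs(150, seed = 5)
  vocab <- px$vocab
  # teacher-forced predictions aligned to target positions after <s>
  tf <- lapply(seq_along(px$targets), function(i) px$predictions[[i]][-1])
  # pad/truncate tf to target length minus one, as the model would emit
  tf <- lapply(seq_along(tf), function(i) {
    need <- length(px$targets[[i]]) - 1L
    out <- tf[[i]]
    length(out) <- need
    out[is.na(out)] <- vocab$pad_id
    out
  })
  got <- per_token_accuracy(tf, px$targets, vocab)
  want <- oracle_per_token(tf, px$targets, vocab)
  expect_equal(got[sort(names(got))], want[sort(names(want))],
               tolerance = 1e-12)
  # tokens absent from targets are not reported
  expect_false("<pad>" %in% names(got))
})

test_that("metric inequalities hold across random batches", {
  for (s in 1:30) {
    px <- make_synthetic_pairs(40, seed = 100 + s,
                               p_sub = runif(1, 0, 0.3),
                               p_swap = runif(1, 0, 0.5),
                               p_trunc = runif(1, 0, 0.2))
    p <- px$predictions; t <- px$targets
    pa <- perfect_accuracy(p, t)
    expect_lte(pa, partial_accuracy(p, t))
    for (tok in c("@", "@@", "C")) {
      id <- px$vocab$token_to_id[[tok]]
      expect_gte(masked_perfect_accuracy(p, t, id), pa)
    }
    brk <- classify_chirality_errors(p, t, px$at, px$atat)
    expect_equal(brk$frac_correct + brk$frac_chirality_only + brk$frac_other,
                 1, tolerance = 1e-9)
    expect_equal(brk$frac_correct, pa, tolerance = 1e-12)
  }
})

test_that("masking a token absent from all targets reproduces perfect accuracy", {
  px <- make_synthetic_pairs(100, seed = 3)
  vocab <- px$vocab
  absent <- vocab$token_to_id[["P"]]
  # P never sampled into these targets? enforce by filtering pairs containing it
  keep <- vapply(seq_along(px$targets), function(i)
    !(absent %in% px$targets[[i]]) && !(absent %in% px$predictions[[i]]),
    logical(1))
  p <- px$predictions[keep]; t <- px$targets[keep]
  expect_equal(masked_perfect_accuracy(p, t, absent),
               perfect_accuracy(p, t), tolerance = 1e-12)
})

test_that("chirality classification distinguishes swap-only from mixed errors", {
  v <- fixture_vocab()
  id <- function(tok) v$token_to_id[[tok]]
  tgt <- c(v$bos_id, id("C"), id("@"), id("N"), v$eos_id)
  swap_only <- c(v$bos_id, id("C"), id("@@"), id("N"), v$eos_id)
  mixed <- c(v$bos_id, id("O"), id("@@"), id("N"), v$eos_id)
  exact <- tgt
  brk <- classify_chirality_errors(list(exact, swap_only, mixed),
                                   list(tgt, tgt, tgt), id("@"), id("@@"))
  expect_equal(brk$frac_correct, 1 / 3)
  expect_equal(brk$frac_chirality_only, 1 / 3)
  expect_equal(brk$frac_other, 1 / 3)
})

test_that("threshold-step extraction picks the first crossing or the end step", {
  ser <- data.frame(step = c(2000, 4000, 6000),
                    perfect_accuracy = c(0.3, 0.75, 0.8))
  expect_equal(extract_threshold_step(ser, 0.7, 80000), 4000)
  expect_equal(extract_threshold_step(ser, 0.95, 80000), 80000)
  expect_equal(extract_threshold_step(ser, 0.2, 80000), 2000)
  expect_error(extract_threshold_step(ser[0, ], 0.7, 80000), "empty")
})

test_that("empty inputs and special-token masking are rejected", {
  px <- make_synthetic_pairs(5, seed = 2)
  expect_error(perfect_accuracy(list(), list()), "empty")
  expect_error(partial_accuracy(list(), list()), "empty")
  expect_error(masked_perfect_accuracy(px$predictions, px$targets,
                                       px$vocab$pad_id), "special")
})
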