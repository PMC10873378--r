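test_that("tanimoto obeys its definition and edge conventions", {
  a <- integer(8); b <- integer(8)
  a[c(1, 2, 3)] <- 1L; b[c(2, 3, 4)] <- 1L
  expect_equal(tanimoto(a, b), 0.5)            # 2 common / 4 in union
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(a, integer(8) + c(0L,0L,0L,0L,1L,1L,0L,0L)), 0)
  expect_equal(tanimoto(integer(8), integer(8)), 0)  # both empty
  expect_error(tanimoto(a, integer(4)), "width")
  # symmetry on random bit sets
  set.seed(3)
  for (k in 1:20) {
    x <- sample(0:1, 32, TRUE); y <- sample(0:1, 32, TRUE)
    expect_equal(tanimoto(x, y), tanimoto(y, x))
    expect_gte(tanimoto(x, y), 0); expect_lte(tanimoto(x, y), 1)
    if (sum(x | y) > 0)
      expect_equal(tanimoto(x, y) == 1, all(x == y))
  }
})

test_that("fingerprints have documented widths and detect identity", {
  fp <- fingerprint_smiles(c("CCO", "C[C@@H](N)O"), "maccs")
  expect_equal(dim(fp), c(2, 166))
  fe <- fingerprint_smiles("CCO", "ecfp", radius = 2, n_bits = 2048)
  expect_equal(ncol(fe), 2048)
  expect_true(all(fe %in% 0:1))
  # same molecule, different SMILES: identical fingerprints
  f1 <- fingerprint_smiles("OCC", "ecfp")
  f2 <- fingerprint_smiles("CCO", "ecfp")
  expect_equal(tanimoto(f1[1, ], f2[1, ]), 1)
  # invalid SMILES yields NA rows
  fi <- fingerprint_smiles(c("CCO", "C1CC"), "maccs")
  expect_false(anyNA(fi[1, ])); expect_true(all(is.na(fi[2, ])))
})

test_that("similarity report filters invalid predictions and scores survivors", {
  tgt <- c("CCO", "CCN", "CCC", "CCOC", "CCCC",
           "OCCO", "NCCN", "CC(C)C", "CCCCC", "COC")
  pred <- tgt
  cfgs <- list(fingerprint_config("maccs"),
               fingerprint_config("ecfp", radius = 1),
               fingerprint_config("ecfp", radius = 2),
               fingerprint_config("ecfp", radius = 3))
  rep0 <- similarity_report(pred, tgt, cfgs)
  expect_true(all(rep0$mean_tanimoto == 1))
  expect_equal(rep0$n_invalid, 0)
  expect_equal(rep0$n_evaluated, 10)
  pred[4] <- "C1CC"    # unclosed ring
  rep1 <- similarity_report(pred, tgt, cfgs)
  expect_equal(rep1$n_evaluated, 9)
  expect_equal(rep1$n_invalid, 1)
  expect_error(similarity_report(rep("C1CC", 3), tgt[1:3], cfgs),
               "no prediction survived")
})

test_that("predictions equivalent up to SMILES order give MACCS similarity 1", {
  tgt <- c("CC(CCO)CC1CCC1CN", "O=C(O)CC", "CC1CC(O)CC1N")
  set.seed(5)
  pred <- vapply(tgt, randomize_smiles, character(1), USE.NAMES = FALSE)
  expect_false(all(pred == tgt))   # different strings...
  rep <- similarity_report(pred, tgt, list(fingerprint_config("maccs")))
  expect_equal(unname(rep$mean_tanimoto), 1)  # ...same molecules
})

test_that("per-bit MACCS agreement tables match a direct recount", {
  tgt <- c("CCO", "CCN", "OCCO", "CCS", "CCCl")
  pred <- c("CCO", "CCO", "OCCO", "C1CC", "CCCl")  # one wrong, one invalid
  tab <- maccs_bitwise_agreement(pred, tgt)
  expect_true(all(tab$fraction >= 0 & tab$fraction <= 1))
  expect_setequal(unique(tab$bit_value), c(0L, 1L))
  # recount independently from raw fingerprints
  fp_t <- fingerprint_smiles(tgt, "maccs")
  valid <- smiles_is_valid(pred)
  fp_p <- matrix(0L, 5, 166)
  fp_p[valid, ] <- fingerprint_smiles(pred[valid], "maccs")
  for (row in sample(nrow(tab), 25)) {
    b <- tab$bit_index[row]; v <- tab$bit_value[row]
    among <- which(fp_t[, b] == v)
    want <- mean(valid[among] & fp_p[among, b] == v)
    expect_equal(tab$fraction[row], want, tolerance = 1e-12)
    expect_equal(tab$n_targets[row], length(among))
  }
  # a bit value absent from every target is not reported
  absent <- setdiff(seq_len(166), tab$bit_index[tab$bit_value == 1])
  if (length(absent) > 0)
    expect_true(all(colSums(fp_t[, absent, drop = FALSE]) == 0))
})

test_that("perfect predictions give all-one agreement; invalid give all-zero", {
  tgt <- c("CCO", "CCN", "OCCO")
  tab1 <- maccs_bitwise_agreement(tgt, tgt)
  expect_true(all(tab1$fraction == 1))
  tab0 <- maccs_bitwise_agreement(rep("C1CC", 3), tgt)
  expect_true(all(tab0$fraction == 0))
})
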