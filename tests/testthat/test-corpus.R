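test_that("filtering removes small, alien-element and invalid molecules", {
  out <- suppressMessages(filter_molecules(c("CC", "CCO")))
  expect_identical(as.character(out), "CCO")
  out <- suppressMessages(filter_molecules("CCO.[Na+]"))
  expect_identical(as.character(out), "CCO")   # largest fragment kept
  expect_length(suppressMessages(filter_molecules("[Si](C)(C)C")), 0)
  expect_length(suppressMessages(filter_molecules("C1CC")), 0)  # invalid
  big <- paste(rep("C", 51), collapse = "")
  expect_length(suppressMessages(filter_molecules(big)), 0)
  expect_length(filter_molecules(character(0)), 0)
})

test_that("stratified sampling caps every length group", {
  set.seed(2)
  cfg <- generator_config(300, heavy_atom_range = c(3, 14),
                          chiral_fraction = 0.2, seed = 12)
  pool <- generate_corpus(cfg)$canonical_smiles
  out <- stratified_sample(pool, per_length_cap = 10)
  got <- table(nchar(out))
  want <- table(nchar(pool))
  # oracle: per-length histogram capped at 10
  for (len in names(want))
    expect_equal(unname(got[len]),
                 min(unname(want[len]), 10),
                 ignore_attr = TRUE)
  # cap >= pool size returns the whole pool
  expect_setequal(stratified_sample(pool, length(pool)), pool)
})

test_that("small worked example of stratified sampling", {
  pool <- c(sprintf("C%d", 1:10), "CCCCCCC", "OCCCCCC", "NCCCCCC")
  pool[1:10] <- replicate(10, paste(sample(c("C","N","O"), 5, TRUE),
                                    collapse = ""))
  set.seed(1)
  out <- stratified_sample(pool, 5)
  expect_equal(sum(nchar(out) == 5), 5)
  expect_equal(sum(nchar(out) == 7), 3)
})

test_that("chirality-enriched resampling keeps all chiral molecules", {
  set.seed(6)
  chir <- c("C[C@@H](N)O", "C[C@H](O)CC")
  achir <- sprintf("%s", replicate(10000, "CCO"))
  expect_identical(chirality_enriched_resample(chir, 0.5), chir)
  only <- chirality_enriched_resample(c(chir, achir), 0)
  expect_identical(only, chir)
  kept <- length(chirality_enriched_resample(achir, 0.5))
  # binomial 99% CI around 5000 at n=10000
  expect_gt(kept, 5000 - 2.576 * sqrt(10000 * 0.25))
  expect_lt(kept, 5000 + 2.576 * sqrt(10000 * 0.25))
})

test_that("vocabulary round-trips token ids and treats multi-char tokens atomically", {
  v <- fixture_vocab()
  ids <- tokenize("C[C@@H](N)O", v)
  toks <- decode_ids(ids, v)
  expect_identical(toks, c("<s>", "C", "[", "C", "@@", "H", "]", "(", "N",
                           ")", "O", "</s>"))
  expect_identical(decode_ids(tokenize("CCl", v), v),
                   c("<s>", "C", "Cl", "</s>"))
  expect_identical(detokenize(ids, v), "C[C@@H](N)O")
  # encode/decode closure over corpus strings
  set.seed(44)
  cfg <- generator_config(60, heavy_atom_range = c(3, 15),
                          chiral_fraction = 0.5, seed = 13)
  corp <- generate_corpus(cfg)
  vc <- build_vocabulary(c(corp$canonical_smiles, corp$randomized_smiles))
  for (s in c(corp$canonical_smiles, corp$randomized_smiles))
    expect_identical(detokenize(tokenize(s, vc), vc), s)
})

test_that("unknown characters raise or map to <unk> per configuration", {
  v <- build_vocabulary("CCO")
  expect_error(tokenize("CCN", v), "no vocabulary token")
  ids <- tokenize("CCN", v, on_unknown = "unk")
  expect_true(v$unk_id %in% ids)
})

test_that("vocabulary JSON serialization restores identical behavior", {
  v <- fixture_vocab()
  f <- tempfile(fileext = ".json")
  write_vocabulary(v, f)
  v2 <- read_vocabulary(f)
  expect_identical(v$tokens, v2$tokens)
  expect_identical(tokenize("C[C@@H](N)O", v), tokenize("C[C@@H](N)O", v2))
})

test_that("batches respect the token budget and partition the pairs", {
  set.seed(9)
  cfg <- generator_config(80, heavy_atom_range = c(3, 16),
                          chiral_fraction = 0.3, seed = 21)
  corp <- generate_corpus(cfg)
  v <- build_vocabulary(c(corp$canonical_smiles, corp$randomized_smiles))
  pairs <- make_translation_pairs(corp, v, source_mode = "stored")
  budget <- 120
  batches <- make_batches(pairs, budget, bucketing = TRUE, pad_id = v$pad_id)
  seen <- unlist(lapply(batches, `[[`, "molecule_index"))
  expect_setequal(seen, seq_len(nrow(corp)))
  expect_equal(length(seen), nrow(corp))
  for (b in batches)
    expect_lte(length(b$source), budget)
  # a pair longer than the budget is rejected
  expect_error(make_batches(pairs, 3), "exceeds the token budget")
})

test_that("bucketing reduces padding waste versus unbucketed batching", {
  set.seed(10)
  cfg <- generator_config(150, heavy_atom_range = c(3, 18),
                          chiral_fraction = 0.3, seed = 22)
  corp <- generate_corpus(cfg)
  v <- build_vocabulary(c(corp$canonical_smiles, corp$randomized_smiles))
  pairs <- make_translation_pairs(corp, v, source_mode = "stored")
  set.seed(1)
  with_b <- padding_stats(make_batches(pairs, 200, bucketing = TRUE))
  set.seed(1)
  without <- padding_stats(make_batches(pairs, 200, bucketing = FALSE))
  expect_lte(with_b["pad_fraction"], without["pad_fraction"])
})

test_that("batch order is reproducible from the RNG seed", {
  cfg <- generator_config(40, heavy_atom_range = c(3, 10), seed = 31)
  corp <- generate_corpus(cfg)
  v <- build_vocabulary(c(corp$canonical_smiles, corp$randomized_smiles))
  pairs <- make_translation_pairs(corp, v, source_mode = "stored")
  set.seed(77); b1 <- make_batches(pairs, 150)
  set.seed(77); b2 <- make_batches(pairs, 150)
  expect_identical(b1, b2)
})

test_that("train/test splitting is disjoint and covers the corpus", {
  cfg <- generator_config(100, heavy_atom_range = c(3, 8), seed = 41)
  corp <- generate_corpus(cfg)
  set.seed(5)
  sp <- split_corpus(corp, 0.03)
  expect_equal(nrow(sp$test), 3)
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(corp))
  expect_length(intersect(sp$train$canonical_smiles,
                          sp$test$canonical_smiles), 0)
})

test_that("InChI source mode builds translation pairs from InChI strings", {
  cfg <- generator_config(12, heavy_atom_range = c(3, 7),
                          chiral_fraction = 0, seed = 61)
  corp <- generate_corpus(cfg, include_inchi = TRUE)
  expect_true(all(startsWith(corp$inchi, "InChI=")))
  src_vocab <- build_vocabulary(corp$inchi)
  tgt_vocab <- build_vocabulary(corp$canonical_smiles)
  pairs <- make_translation_pairs(corp, src_vocab, tgt_vocab, "inchi")
  expect_identical(detokenize(pairs[[3]]$source, src_vocab), corp$inchi[3])
  expect_identical(detokenize(pairs[[3]]$target, tgt_vocab),
                   corp$canonical_smiles[3])
  # a corpus without InChI refuses the mode
  corp2 <- generate_corpus(cfg)
  expect_error(make_translation_pairs(corp2, src_vocab, tgt_vocab, "inchi"),
               "no InChI")
})

test_that("the bundled example SMILES file flows through the filter pipeline", {
  f <- system.file("extdata", "example_molecules.smi",
                   package = "smiletran")
  skip_if(f == "", "extdata not installed")
  raw <- read_smiles_file(f)
  kept <- suppressMessages(filter_molecules(raw))
  expect_gt(length(kept), 5)
  expect_lt(length(kept), length(raw))      # salts, Si, C2, invalids dropped
  expect_true(all(smiles_is_valid(kept)))
  expect_true(all(count_heavy_atoms(kept) >= 3 & count_heavy_atoms(kept) <= 50))
})
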