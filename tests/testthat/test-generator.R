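test_that("generator config enforces its invariants", {
  expect_error(generator_config(10, heavy_atom_range = c(10, 5)))
  expect_error(generator_config(10, chiral_fraction = 1.2))
  expect_error(generator_config(10, at_at_balance = -0.1))
  expect_error(generator_config(10, heavy_atom_range = c(0, 5)))
  expect_s3_class(generator_config(10), "generator_config")
})

test_that("forced-chiral and forced-achiral draws behave as constructed", {
  set.seed(8)
  cfg <- generator_config(1, heavy_atom_range = c(5, 12),
                          chiral_fraction = 1.0)
  for (k in 1:10) {
    rec <- generate_molecule(cfg)
    expect_true(grepl("@", rec$canonical_smiles))
    expect_true(rec$has_stereocenter)
  }
  cfg0 <- generator_config(1, heavy_atom_range = c(3, 10),
                           chiral_fraction = 0)
  for (k in 1:10)
    expect_false(grepl("@", generate_molecule(cfg0)$canonical_smiles))
})

test_that("a stereocenter cannot be demanded of molecules that cannot host one", {
  cfg <- generator_config(1, heavy_atom_range = c(3, 4), chiral_fraction = 1)
  set.seed(1)
  expect_error(generate_molecule(cfg), "stereocenter")
})

test_that("exact heavy-atom bounds are honored, verified by toolkit reparse", {
  set.seed(30)
  # the space of 3-heavy-atom C/O molecules is tiny; ask for a handful
  cfg <- generator_config(6, heavy_atom_range = c(3, 3),
                          chiral_fraction = 0, element_set = c("C", "O"))
  corp <- generate_corpus(cfg)
  expect_equal(nrow(corp), 6)
  # oracle: element-count from an independent lexical pass on the
  # toolkit-canonicalized string
  recount <- vapply(corp$canonical_smiles, function(s) {
    toks <- strsplit(canonicalize_smiles(s), "")[[1]]
    sum(toks %in% c("C", "O"))
  }, numeric(1), USE.NAMES = FALSE)
  expect_true(all(recount == 3))
})

test_that("corpora are reproducible, unique and fully round-trippable", {
  cfg <- generator_config(120, heavy_atom_range = c(4, 12),
                          chiral_fraction = 0.5, seed = 5)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_identical(a, b)
  expect_equal(anyDuplicated(a$canonical_smiles), 0L)
  expect_true(all(smiles_is_valid(a$canonical_smiles)))
  expect_identical(canonicalize_smiles(a$randomized_smiles),
                   a$canonical_smiles)
  expect_true(all(a$n_heavy_atoms >= 4 & a$n_heavy_atoms <= 12))
})

test_that("empty corpora are permitted", {
  cfg <- generator_config(0, seed = 2)
  expect_equal(nrow(generate_corpus(cfg)), 0)
})

test_that("chiral fraction and parity balance track their targets", {
  cfg <- generator_config(400, heavy_atom_range = c(5, 10),
                          chiral_fraction = 0.5, at_at_balance = 0.5,
                          seed = 17)
  corp <- generate_corpus(cfg)
  # binomial 99% interval around 0.5 at n=400: +-2.576*sqrt(.25/400)=0.0644
  expect_gt(mean(corp$has_stereocenter), 0.5 - 0.0644)
  expect_lt(mean(corp$has_stereocenter), 0.5 + 0.0644)
  par <- corp$chiral_parity[corp$chiral_parity != ""]
  ci <- 2.576 * sqrt(0.25 / length(par))
  expect_gt(mean(par == "@@"), 0.5 - ci)
  expect_lt(mean(par == "@@"), 0.5 + ci)
})

test_that("synthetic labels are structure-derived", {
  cfg <- generator_config(50, heavy_atom_range = c(4, 10),
                          chiral_fraction = 0.4, seed = 3)
  corp <- generate_corpus(cfg)
  cls <- synthetic_labels(corp, "classification")
  expect_identical(cls, as.integer(corp$has_stereocenter))
  set.seed(1)
  reg <- synthetic_labels(corp, "regression", noise_sd = 0)
  n_ox <- vapply(strsplit(corp$canonical_smiles, ""), function(x)
    sum(x == "O"), numeric(1))
  expect_equal(reg, corp$n_heavy_atoms + 2 * n_ox)
})

test_that("corpus files round-trip through disk", {
  cfg <- generator_config(10, heavy_atom_range = c(3, 6), seed = 9)
  corp <- generate_corpus(cfg)
  smi <- tempfile(fileext = ".smi"); csv <- tempfile(fileext = ".csv")
  write_corpus(corp, smi, "smiles")
  write_corpus(corp, csv, "csv")
  expect_identical(read_smiles_file(smi), corp$canonical_smiles)
  back <- utils::read.csv(csv)
  expect_identical(back$canonical_smiles, corp$canonical_smiles)
})
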