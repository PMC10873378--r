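Package: smiletran
Title: Learning Dynamics of SMILES-Translation Transformers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying how sequence-to-sequence Transformer models learn
    chemical structure from SMILES strings. Provides a synthetic molecule generator
    with controllable tetrahedral stereochemistry, SMILES randomization and
    tokenization, a compact encoder-decoder Transformer (post-LN and pre-LN
    variants, Adam/AdamW, warmup schedule) implemented natively as a base R
    reference with a compiled RcppArmadillo engine, a translation
    accuracy metric suite (perfect, partial, masked and per-token accuracy,
    chirality-error classification), fingerprint-based structure similarity
    (MACCS keys, ECFP Tanimoto), encoder-memory descriptor pooling with a
    gradient-boosting downstream-prediction harness, and a multi-seed experiment
    harness with Welch/Bonferroni comparisons of training interventions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    jsonlite,
    Rcpp,
    stats,
    utils,
    xgboost
LinkingTo:
    Rcpp,
    RcppArmadillo
SystemRequirements: OpenBabel (the obabel executable, for fingerprints)
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
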