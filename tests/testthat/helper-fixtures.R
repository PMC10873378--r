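# Shared fixtures, built once per test session.

# a small vocabulary over plausible SMILES symbols, with "@"/"@@" present
fixture_vocab <- local({
  v <- NULL
  function() {
    if (is.null(v))
      v <<- build_vocabulary(c("C[C@@H](N)O", "CCCl", "c%12",
                               "O=C(O)CC#N", "FC(Br)I", "[C@H]1CCS1",
                               "PB"))
    v
  }
})

# random prediction/target token pairs with errors injected at known rates:
# substitutions, chirality swaps, truncations
make_synthetic_pairs <- function(n, seed = 1,
                                 p_sub = 0.05, p_swap = 0.1, p_trunc = 0.05) {
  set.seed(seed)
  vocab <- fixture_vocab()
  at <- vocab$token_to_id[["@"]]
  atat <- vocab$token_to_id[["@@"]]
  content_ids <- unname(vocab$token_to_id[-(1:4)])
  tgts <- list(); preds <- list()
  for (i in seq_len(n)) {
    L <- sample(5:20, 1)
    t <- sample(content_ids, L, replace = TRUE)
    if (runif(1) < 0.5) t[sample(L, 1)] <- sample(c(at, atat), 1)
    p <- t
    for (j in seq_len(L)) {
      if (p[j] %in% c(at, atat) && runif(1) < p_swap)
        p[j] <- if (p[j] == at) atat else at
      else if (runif(1) < p_sub)
        p[j] <- sample(content_ids, 1)
    }
    if (runif(1) < p_trunc && L > 3) p <- p[1:(L - 2)]
    tgts[[i]] <- c(vocab$bos_id, t, vocab$eos_id)
    preds[[i]] <- c(vocab$bos_id, p, vocab$eos_id)
  }
  list(predictions = preds, targets = tgts, vocab = vocab,
       at = at, atat = atat)
}

# tiny corpus + trained-for-a-few-steps model, reused by slow tests
fixture_tiny_model <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    gcfg <- generator_config(24, heavy_atom_range = c(4, 8),
                             chiral_fraction = 0.5, seed = 99)
    corp <- generate_corpus(gcfg)
    vocab <- build_vocabulary(c(corp$canonical_smiles,
                                corp$randomized_smiles))
    mcfg <- model_config(d_model = 16, d_ff = 32, n_layers_enc = 1,
                         n_layers_dec = 1, n_heads = 2, dropout = 0,
                         warmup_steps = 50, max_len = 48, seed = 7)
    model <- build_model(mcfg, length(vocab$tokens), length(vocab$tokens))
    cache <<- list(corpus = corp, vocab = vocab, model = model, cfg = mcfg)
    cache
  }
})
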