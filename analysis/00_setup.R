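#!/usr/bin/env Rscript
# Shared settings for the analysis scripts. The scaled study conditions
# (corpus + model + run settings) live in the package itself as
# scaled_defaults(), so the tests, the acceptance script and these drivers
# all exercise the same experiment. Run each numbered script from the
# repository root:
#   Rscript analysis/01_corpus.R
# Results are written under results/.

library(smiletran)

RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE)

scaled_generator_config <- function(seed = 11L) {
  scaled_defaults(corpus_seed = seed)$generator_config
}

scaled_run_spec <- function(init_seed = 1L, iteration_order_seed = 1L, ...) {
  scaled_defaults(init_seed = init_seed,
                  iteration_order_seed = iteration_order_seed, ...)$run_spec
}
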