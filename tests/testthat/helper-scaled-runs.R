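# The five-seed scaled study runs used by the learning-dynamics and
# chirality-lag acceptance checks. Built once per test session and shared:
# both checks look at the same experiment, as in the underlying analysis.

scaled_study_runs <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    sd0 <- scaled_defaults()
    corpus <- generate_corpus(sd0$generator_config)
    runs <- lapply(1:5, function(s) {
      sd <- scaled_defaults(init_seed = s, iteration_order_seed = 1L)
      run_experiment(sd$run_spec, corpus)
    })
    cache <<- runs
    runs
  }
})
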