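# Orchestration: full training runs with periodic evaluation snapshots,
# stagnation summaries, intervention handling, multi-seed sweeps and the
# Welch/Bonferroni comparison of intervention groups against control.

#' Specification of one training run
#'
#' Bundles the model configuration, data settings and the intervention
#' applied relative to the control condition. Weight initialization and
#' data-iteration order are controlled by two independent seeds.
#'
#' @param model_cfg a [model_config()]; its `seed` is overridden by
#'   `init_seed`.
#' @param init_seed seed for the initial weights.
#' @param iteration_order_seed seed for SMILES randomization, batch
#'   composition, batch order and dropout.
#' @param intervention one of `"none"`, `"pre_ln"`, `"adamw"`,
#'   `"he_normal"`, `"chirality_enriched"`.
#' @param abort_at_perfect stop training once perfect accuracy reaches this
#'   value (`NA` = never).
#' @param eval_every evaluation cadence in optimizer steps.
#' @param test_fraction held-out fraction of the corpus.
#' @param evaluation what the evaluation set measures: `"held_out"` scores
#'   the held-out molecules (generalization to unseen structures);
#'   `"train_resampled"` scores a fixed sample of training molecules under
#'   freshly drawn randomized source spellings (canonicalization competence
#'   on the training distribution — the appropriate reading at desk scale,
#'   where a corpus of hundreds cannot cover chemical space the way a
#'   30-million-molecule corpus does).
#' @param n_eval evaluation-set size for `"train_resampled"`.
#' @param keep_prob_achiral achiral retention probability for the
#'   chirality-enriched intervention.
#' @return a `run_spec` list.
#' @export
run_spec <- function(model_cfg, init_seed = 1L, iteration_order_seed = 1L,
                     intervention = c("none", "pre_ln", "adamw", "he_normal",
                                      "chirality_enriched"),
                     abort_at_perfect = 0.95, eval_every = 2000L,
                     test_fraction = 0.03,
                     evaluation = c("held_out", "train_resampled"),
                     n_eval = 100L, keep_prob_achiral = 0.5) {
  intervention <- match.arg(intervention)
  evaluation <- match.arg(evaluation)
  stopifnot(inherits(model_cfg, "model_config"))
  structure(list(model_cfg = model_cfg, init_seed = as.integer(init_seed),
                 iteration_order_seed = as.integer(iteration_order_seed),
                 intervention = intervention,
                 abort_at_perfect = abort_at_perfect,
                 eval_every = as.integer(eval_every),
                 test_fraction = test_fraction,
                 evaluation = evaluation, n_eval = as.integer(n_eval),
                 keep_prob_achiral = keep_prob_achiral),
            class = "run_spec")
}

apply_intervention <- function(cfg, intervention) {
  switch(intervention,
         none = cfg,
         pre_ln = { cfg$norm_placement <- "pre_ln"; cfg },
         adamw = { cfg$optimizer <- "adamw"; cfg },
         he_normal = { cfg$init_scheme <- "he_normal"; cfg },
         chirality_enriched = cfg)
}

evaluate_model <- function(model, test_src, test_tgt, vocab, max_decode_len,
                           step) {
  preds <- greedy_decode(model, test_src, max_len = max_decode_len)
  tgt_list <- lapply(seq_len(nrow(test_tgt)), function(i) test_tgt[i, ])
  tf <- teacher_forced_predict(model, test_src, test_tgt)
  pta <- per_token_accuracy(tf, tgt_list, vocab)
  has_chiral <- all(c("@", "@@") %in% names(vocab$token_to_id))
  brk <- if (has_chiral)
    classify_chirality_errors(preds, tgt_list, vocab$token_to_id[["@"]],
                              vocab$token_to_id[["@@"]]) else NULL
  pred_smiles <- vapply(preds, detokenize, character(1), vocab = vocab)
  list(step = step,
       perfect_accuracy = perfect_accuracy(preds, tgt_list),
       partial_accuracy = partial_accuracy(preds, tgt_list),
       per_token_accuracy = pta,
       chirality_breakdown = brk,
       pred_smiles = pred_smiles)
}

#' Run one training experiment with periodic evaluation
#'
#' Trains per the spec on the given corpus, re-randomizing every molecule's
#' source SMILES at each epoch, evaluating the held-out test set every
#' `eval_every` optimizer steps (greedy decoding for perfect/partial
#' accuracy and chirality classification; teacher forcing for per-token
#' accuracy), and recording mean fingerprint similarity over molecules whose
#' predictions were valid at every evaluated step.
#'
#' @param spec a [run_spec()].
#' @param corpus corpus data.frame from [generate_corpus()].
#' @param vocab optional shared vocabulary (built from the corpus when
#'   `NULL`).
#' @param similarity_cfgs fingerprint configs for the similarity series
#'   (`NULL` disables fingerprints).
#' @param verbose print progress lines.
#' @return list: `snapshots` (one row per evaluation), `per_token` (list of
#'   named vectors), `chirality` (list of breakdowns), `similarity`
#'   (data.frame, fixed always-valid subset), `stagnation`
#'   (step-0.7/step-0.95 summary), `model`, `state`, `vocab`, `test`.
#' @export
run_experiment <- function(spec, corpus, vocab = NULL,
                           similarity_cfgs = list(fingerprint_config("maccs")),
                           verbose = FALSE) {
  stopifnot(inherits(spec, "run_spec"))
  cfg <- apply_intervention(spec$model_cfg, spec$intervention)
  cfg$seed <- spec$init_seed
  if (is.null(vocab))
    vocab <- build_vocabulary(c(corpus$canonical_smiles,
                                corpus$randomized_smiles))

  set.seed(spec$iteration_order_seed)
  sp <- split_corpus(corpus, spec$test_fraction)
  train_set <- sp$train; test_set <- sp$test
  if (spec$intervention == "chirality_enriched") {
    keep <- grepl("@", train_set$canonical_smiles, fixed = TRUE) |
      (stats::runif(nrow(train_set)) < spec$keep_prob_achiral)
    train_set <- train_set[keep, , drop = FALSE]
  }
  if (identical(spec$evaluation, "train_resampled")) {
    take <- sample(nrow(train_set), min(spec$n_eval, nrow(train_set)))
    test_set <- train_set[take, , drop = FALSE]
  }
  stopifnot(nrow(test_set) >= 1, nrow(train_set) >= 1)
  max_decode_len <- max(nchar(corpus$canonical_smiles)) + 7L

  # fixed test inputs for comparable snapshots across steps
  test_pairs <- make_translation_pairs(test_set, vocab,
                                       source_mode = "randomized")
  test_src <- pad_to_matrix(lapply(test_pairs, `[[`, "source"), vocab$pad_id)
  test_tgt <- pad_to_matrix(lapply(test_pairs, `[[`, "target"), vocab$pad_id)

  model <- build_model(cfg, length(vocab$tokens), length(vocab$tokens))
  # parse training molecules once; epochs only re-serialize + tokenize
  train_graphs <- lapply(train_set$canonical_smiles, parse_smiles)
  train_tgt_ids <- lapply(train_set$canonical_smiles, tokenize_fast,
                          vocab = vocab)
  fresh_epoch_pairs <- function() {
    lapply(seq_along(train_graphs), function(i) {
      g <- train_graphs[[i]]
      src <- if (g$n_atoms == 1L) write_smiles(g)
             else write_smiles(g, sample.int(g$n_atoms))
      list(source = tokenize_fast(src, vocab),
           target = train_tgt_ids[[i]],
           molecule_index = i)
    })
  }
  # weight init used its own seed; the iteration stream resumes here
  set.seed(spec$iteration_order_seed + 1L)
  state <- NULL
  batch_queue <- list()
  per_batch_budget <- cfg$token_budget_per_step %/% cfg$accum_batches
  snapshots <- list(); per_token <- list(); chirality <- list()
  preds_by_step <- list()

  while (is.null(state) || state$step < cfg$max_steps) {
    while (length(batch_queue) < cfg$accum_batches) {
      pairs <- fresh_epoch_pairs()
      batch_queue <- c(batch_queue,
                       make_batches(pairs, per_batch_budget,
                                    bucketing = TRUE, pad_id = vocab$pad_id))
    }
    take <- seq_len(cfg$accum_batches)
    res <- train_step(model, batch_queue[take], state, vocab$pad_id)
    batch_queue <- batch_queue[-take]
    model <- res$model; state <- res$state

    if (state$step %% spec$eval_every == 0L || state$step >= cfg$max_steps) {
      ev <- evaluate_model(model, test_src, test_tgt, vocab, max_decode_len,
                           state$step)
      snapshots[[length(snapshots) + 1L]] <- data.frame(
        step = ev$step,
        perfect_accuracy = ev$perfect_accuracy,
        partial_accuracy = ev$partial_accuracy,
        mean_loss = res$loss)
      per_token[[length(per_token) + 1L]] <- ev$per_token_accuracy
      chirality[[length(chirality) + 1L]] <- ev$chirality_breakdown
      preds_by_step[[length(preds_by_step) + 1L]] <- ev$pred_smiles
      if (verbose)
        message(sprintf("step %d  loss %.4f  perfect %.3f  partial %.3f",
                        state$step, res$loss, ev$perfect_accuracy,
                        ev$partial_accuracy))
      if (!is.na(spec$abort_at_perfect) &&
          ev$perfect_accuracy >= spec$abort_at_perfect) break
    }
  }
  snap_df <- do.call(rbind, snapshots)

  similarity <- NULL
  if (!is.null(similarity_cfgs) && length(preds_by_step) > 0) {
    valid_mat <- vapply(preds_by_step, smiles_is_valid,
                        logical(nrow(test_set)))
    always_valid <- if (is.matrix(valid_mat)) rowMeans(valid_mat) == 1
                    else valid_mat
    # preferred subset: molecules valid at every evaluated step, so the
    # averaged set is fixed across the series; early-training invalidity can
    # shrink it below anything statistically meaningful, in which case each
    # step scores its own valid subset instead
    per_step <- sum(always_valid) < min(10L, nrow(test_set))
    similarity <- do.call(rbind, lapply(seq_along(preds_by_step),
                                        function(k) {
      keep <- if (per_step) smiles_is_valid(preds_by_step[[k]])
              else always_valid
      if (!any(keep)) return(NULL)
      rep_k <- similarity_report(preds_by_step[[k]],
                                 test_set$canonical_smiles,
                                 similarity_cfgs, keep_mask = keep)
      data.frame(step = snap_df$step[k],
                 fingerprint = names(rep_k$mean_tanimoto),
                 mean_tanimoto = as.numeric(rep_k$mean_tanimoto),
                 n_evaluated = rep_k$n_evaluated,
                 subset = if (per_step) "per_step" else "fixed")
    }))
  }

  end_step <- cfg$max_steps
  stagnation <- list(
    step_07 = extract_threshold_step(snap_df, 0.7, end_step),
    step_095 = extract_threshold_step(snap_df, 0.95, end_step),
    end_step = end_step)
  stagnation$stagnated <- stagnation$step_07 > 0.5 * end_step

  list(snapshots = snap_df, per_token = per_token, chirality = chirality,
       similarity = similarity, stagnation = stagnation,
       model = model, state = state, vocab = vocab, test = test_set,
       spec = spec)
}

#' Run a seed grid of experiments
#'
#' @param base_spec template [run_spec()].
#' @param corpus corpus data.frame.
#' @param init_seeds vector of weight-initialization seeds.
#' @param interventions character vector of interventions to sweep.
#' @param ... passed to [run_experiment()].
#' @return nested list: `results[[intervention]][[seed index]]`.
#' @export
run_sweep <- function(base_spec, corpus, init_seeds,
                      interventions = "none", ...) {
  out <- list()
  for (iv in interventions) {
    out[[iv]] <- lapply(init_seeds, function(s) {
      sp <- base_spec
      sp$init_seed <- as.integer(s)
      sp$intervention <- iv
      run_experiment(sp, corpus, ...)
    })
  }
  out
}

#' Compare intervention groups to a control by Welch's t-test
#'
#' Two-sided Welch's t-test of each non-control group's threshold steps
#' against the control group, Bonferroni-corrected over the number of
#' comparisons.
#'
#' @param groups named list: condition -> numeric vector of threshold steps
#'   (each of length >= 2).
#' @param control name of the control condition.
#' @return data.frame: condition, group mean, control mean, `t_statistic`,
#'   `raw_p`, `corrected_p`, `n_comparisons`.
#' @export
compare_conditions <- function(groups, control = "none") {
  stopifnot(control %in% names(groups))
  others <- setdiff(names(groups), control)
  k <- length(others)
  stopifnot(k >= 1)
  ctrl <- groups[[control]]
  stopifnot(length(ctrl) >= 2)
  rows <- lapply(others, function(cond) {
    x <- groups[[cond]]
    stopifnot(length(x) >= 2)
    if (stats::var(x) == 0 && stats::var(ctrl) == 0) {
      if (isTRUE(all.equal(mean(x), mean(ctrl))))
        stop("t statistic undefined: both groups are identical constants")
      tt <- list(statistic = c(t = sign(mean(x) - mean(ctrl)) * Inf),
                 p.value = 0)
    } else {
      tt <- stats::t.test(x, ctrl, var.equal = FALSE)
    }
    data.frame(condition = cond,
               mean_group = mean(x), mean_control = mean(ctrl),
               t_statistic = unname(tt$statistic),
               raw_p = tt$p.value,
               corrected_p = min(1, tt$p.value * k),
               n_comparisons = k)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Scaled default study conditions
#'
#' The corpus, model and run settings of the desk-scale experiment the
#' analysis scripts and acceptance checks exercise: 300 unique molecules of
#' 4-8 heavy atoms over {C, N, O} with chiral fraction 0.8 (parity balance
#' 0.5); a 64-wide 1+1-layer 2-head Transformer without dropout; 1,400
#' source tokens per optimizer step in 2 accumulated batches; up to 1,600
#' steps with evaluation of 80 resampled training molecules every 100 steps
#' and early abort at perfect accuracy 0.95. A control run takes about
#' three minutes on one CPU core. See the methods vignette for the
#' rationale behind each choice and what does and does not reproduce at
#' this scale.
#'
#' @param corpus_seed seed for corpus generation.
#' @param init_seed,iteration_order_seed run seeds, see [run_spec()].
#' @param ... overrides forwarded to [run_spec()].
#' @return list: `generator_config`, `model_config`, `run_spec`.
#' @export
scaled_defaults <- function(corpus_seed = 11L, init_seed = 1L,
                            iteration_order_seed = 1L, ...) {
  gcfg <- generator_config(300, heavy_atom_range = c(4, 8),
                           chiral_fraction = 0.8, at_at_balance = 0.5,
                           element_set = c("C", "N", "O"),
                           seed = corpus_seed)
  mcfg <- model_config(d_model = 64, d_ff = 128, n_layers_enc = 1,
                       n_layers_dec = 1, n_heads = 2, dropout = 0,
                       warmup_steps = 150, token_budget_per_step = 1400,
                       accum_batches = 2, max_steps = 1600, max_len = 48,
                       seed = init_seed)
  spec <- run_spec(mcfg, init_seed = init_seed,
                   iteration_order_seed = iteration_order_seed,
                   eval_every = 100, abort_at_perfect = 0.95,
                   test_fraction = 0.1, evaluation = "train_resampled",
                   n_eval = 80, ...)
  list(generator_config = gcfg, model_config = mcfg, run_spec = spec)
}
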