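# Training loop (Adam/AdamW with warmup, gradient accumulation), greedy
# decoding and teacher-forced prediction.

ADAM_BETA1 <- 0.9
ADAM_BETA2 <- 0.98
ADAM_EPS <- 1e-9

new_train_state <- function(model) {
  list(step = 0L,
       m = lapply(model$params, function(x) x * 0),
       v = lapply(model$params, function(x) x * 0),
       loss_history = data.frame(step = integer(0), batch = integer(0),
                                 loss = numeric(0)))
}

adam_update <- function(model, state, grads) {
  cfg <- model$cfg
  state$step <- state$step + 1L
  lr <- lr_at_step(state$step, cfg)
  t <- state$step
  bc1 <- 1 - ADAM_BETA1^t
  bc2 <- 1 - ADAM_BETA2^t
  for (nm in names(model$params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- ADAM_BETA1 * state$m[[nm]] + (1 - ADAM_BETA1) * g
    state$v[[nm]] <- ADAM_BETA2 * state$v[[nm]] + (1 - ADAM_BETA2) * g * g
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + ADAM_EPS)
    if (cfg$optimizer == "adamw")
      upd <- upd + cfg$weight_decay * model$params[[nm]]
    model$params[[nm]] <- model$params[[nm]] - lr * upd
  }
  list(model = model, state = state)
}

#' One optimizer step over accumulated batches
#'
#' Runs teacher-forced forward/backward on `accum_batches` consecutive
#' batches, averages their gradients, and applies one Adam/AdamW update with
#' the warmup learning-rate schedule.
#'
#' @param model a [build_model()] result.
#' @param batches list of batches (length `cfg$accum_batches`) from
#'   [make_batches()].
#' @param state train state from a previous call, or `NULL` to start.
#' @param pad_id padding token id.
#' @return list: updated `model`, `state` (with per-batch loss history),
#'   `loss` (mean over the accumulated batches).
#' @export
train_step <- function(model, batches, state = NULL, pad_id = 0L) {
  if (is.null(state)) state <- new_train_state(model)
  if (!is.null(batches$source)) batches <- list(batches)   # single batch
  grads <- NULL
  losses <- numeric(length(batches))
  for (k in seq_along(batches)) {
    lg <- model_loss_grads(model, batches[[k]], pad_id, train = TRUE)
    if (!is.finite(lg$loss))
      stop("non-finite loss at step ", state$step + 1L,
           " (batch ", k, "): training aborted")
    losses[k] <- lg$loss
    if (is.null(grads)) {
      grads <- lg$grads
    } else {
      for (nm in names(lg$grads))
        grads[[nm]] <- grads[[nm]] + lg$grads[[nm]]
    }
  }
  nb <- length(batches)
  if (nb > 1) for (nm in names(grads)) grads[[nm]] <- grads[[nm]] / nb
  up <- adam_update(model, state, grads)
  state <- up$state
  state$loss_history <- rbind(state$loss_history,
                              data.frame(step = state$step,
                                         batch = seq_len(nb),
                                         loss = losses))
  list(model = up$model, state = state, loss = mean(losses))
}

# forward-only helpers honoring the engine option
model_encode <- function(model, src_mat, pad_id = 0L) {
  if (engine_choice() == "cpp") {
    cpp_encode(model$params, model$cfg, model$pe, storage_int(src_mat),
               as.integer(pad_id))
  } else {
    encoder_fwd(model, src_mat, pad_id, train = FALSE)$memory
  }
}

model_logits <- function(model, tgt_in, memory, src_mat, pad_id = 0L) {
  if (engine_choice() == "cpp") {
    cpp_decode_logits(model$params, model$cfg, model$pe,
                      storage_int(tgt_in), memory, storage_int(src_mat),
                      as.integer(pad_id))
  } else {
    decoder_fwd(model, tgt_in, memory, src_mat != pad_id, pad_id,
                train = FALSE)$logits
  }
}

#' Greedy decoding
#'
#' Decodes a batch of source sequences token-by-token from the start token,
#' emitting the argmax at each position, stopping at the end token or
#' `max_len`. Deterministic given the weights.
#'
#' @param model trained model.
#' @param src_mat `B x Ls` matrix of 0-based source ids (or a single id
#'   vector).
#' @param max_len decode length cap (content + specials).
#' @param pad_id,bos_id,eos_id special token ids.
#' @return list of integer id vectors (each starts with the start token;
#'   ends with the end token unless truncated, in which case the result
#'   carries attribute `truncated = TRUE`).
#' @export
greedy_decode <- function(model, src_mat, max_len = 64L,
                          pad_id = 0L, bos_id = 1L, eos_id = 2L) {
  stopifnot(max_len >= 2)
  if (is.vector(src_mat)) src_mat <- matrix(src_mat, nrow = 1)
  max_len <- min(max_len, model$cfg$max_len)
  B <- nrow(src_mat)
  memory <- model_encode(model, src_mat, pad_id)
  out <- matrix(bos_id, B, 1)
  done <- rep(FALSE, B)
  while (ncol(out) < max_len && !all(done)) {
    logits <- model_logits(model, out, memory, src_mat, pad_id)
    # logits of the last position of each sequence
    Lt <- ncol(out)
    last_rows <- (seq_len(B) - 1L) * Lt + Lt
    nxt <- as.integer(max.col(logits[last_rows, , drop = FALSE],
                              "first")) - 1L
    nxt[done] <- pad_id
    out <- cbind(out, nxt)
    done <- done | nxt == eos_id
  }
  lapply(seq_len(B), function(b) {
    ids <- out[b, ]
    eos <- which(ids == eos_id)
    if (length(eos) > 0) {
      ids[seq_len(eos[1])]
    } else {
      structure(ids[ids != pad_id], truncated = TRUE)
    }
  })
}

#' Teacher-forced per-position predictions
#'
#' Feeds the correct target prefix at every position and returns the
#' argmax prediction for each target position (positions 2..Lt, i.e. all
#' tokens after the start token).
#'
#' @param model trained model.
#' @param src_mat `B x Ls` source id matrix (or single id vector).
#' @param tgt_mat `B x Lt` target id matrix (or single id vector),
#'   beginning with the start token.
#' @param pad_id padding id.
#' @return list of integer vectors of length `Lt - 1`: the predicted token
#'   at every position given the correct preceding tokens.
#' @export
teacher_forced_predict <- function(model, src_mat, tgt_mat, pad_id = 0L) {
  if (is.vector(src_mat)) src_mat <- matrix(src_mat, nrow = 1)
  if (is.vector(tgt_mat)) tgt_mat <- matrix(tgt_mat, nrow = 1)
  stopifnot(nrow(src_mat) == nrow(tgt_mat), ncol(tgt_mat) >= 2)
  B <- nrow(src_mat); Lt <- ncol(tgt_mat)
  memory <- model_encode(model, src_mat, pad_id)
  tgt_in <- tgt_mat[, -Lt, drop = FALSE]
  logits <- model_logits(model, tgt_in, memory, src_mat, pad_id)
  pred <- as.integer(max.col(logits, "first")) - 1L
  lapply(seq_len(B), function(b)
    pred[((b - 1) * (Lt - 1) + 1):(b * (Lt - 1))])
}

#' Encoder memory for descriptor pooling
#'
#' Runs the encoder on one tokenized source sequence and returns the hidden
#' vectors of its non-padding positions.
#'
#' @param model trained model.
#' @param src_ids integer vector of 0-based source token ids.
#' @param pad_id padding id.
#' @return `L x d_model` numeric matrix.
#' @export
encoder_memory <- function(model, src_ids, pad_id = 0L) {
  src_mat <- matrix(as.integer(src_ids), nrow = 1)
  memory <- model_encode(model, src_mat, pad_id)
  memory[src_ids != pad_id, , drop = FALSE]
}

#' Save / load a model checkpoint
#'
#' Stores configuration, weights and train state in one RDS file.
#'
#' @param model model; @param state train state; @param path file path.
#' @export
save_checkpoint <- function(model, state, path) {
  saveRDS(list(cfg = model$cfg, params = model$params,
               src_vocab_size = model$src_vocab_size,
               tgt_vocab_size = model$tgt_vocab_size,
               state = state), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  model <- structure(list(cfg = x$cfg, params = x$params,
                          pe = positional_encoding(x$cfg$max_len,
                                                   x$cfg$d_model),
                          src_vocab_size = x$src_vocab_size,
                          tgt_vocab_size = x$tgt_vocab_size),
                     class = "transformer_model")
  list(model = model, state = x$state)
}
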