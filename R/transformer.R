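# The encoder-decoder Transformer: configuration, parameter initialization,
# forward passes (post-LN and pre-LN variants) and the matching manual
# backward passes. Implemented directly in base R matrix algebra; gradients
# are verified against numerical differentiation in the test suite.

#' Transformer model configuration
#'
#' Defaults follow the original base Transformer (model width 512,
#' feed-forward 2048, 6+6 layers, 8 heads, ReLU, dropout 0.1, 4000 warmup
#' steps); reduced values give desk-scale models with the same anatomy.
#'
#' @param d_model embedding width; must be divisible by `n_heads`.
#' @param d_ff feed-forward inner width.
#' @param n_layers_enc,n_layers_dec encoder / decoder layer counts.
#' @param n_heads attention heads.
#' @param dropout dropout probability in \[0, 1).
#' @param norm_placement `"post_ln"` (original) or `"pre_ln"`.
#' @param init_scheme `"framework_default"` (Xavier-uniform linears) or
#'   `"he_normal"`.
#' @param optimizer `"adam"` or `"adamw"`.
#' @param weight_decay decoupled weight decay for AdamW.
#' @param warmup_steps warmup schedule knee.
#' @param token_budget_per_step source-token budget per optimizer step.
#' @param accum_batches batches accumulated per optimizer step (the step
#'   budget is split evenly across them).
#' @param max_steps training length in optimizer steps.
#' @param max_len longest source/target length the positional table covers.
#' @param seed initialization seed.
#' @return a `model_config` list.
#' @export
model_config <- function(d_model = 512L, d_ff = 2048L,
                         n_layers_enc = 6L, n_layers_dec = 6L,
                         n_heads = 8L, dropout = 0.1,
                         norm_placement = c("post_ln", "pre_ln"),
                         init_scheme = c("framework_default", "he_normal"),
                         optimizer = c("adam", "adamw"),
                         weight_decay = 0.01,
                         warmup_steps = 4000L,
                         token_budget_per_step = 25000L,
                         accum_batches = 2L,
                         max_steps = 80000L,
                         max_len = 256L,
                         seed = 1L) {
  norm_placement <- match.arg(norm_placement)
  init_scheme <- match.arg(init_scheme)
  optimizer <- match.arg(optimizer)
  stopifnot(d_model >= 2, d_ff >= 1, n_layers_enc >= 1, n_layers_dec >= 1,
            n_heads >= 1, d_model %% n_heads == 0,
            dropout >= 0, dropout < 1,
            warmup_steps >= 1, token_budget_per_step >= 1,
            accum_batches >= 1, max_steps >= 1, max_len >= 4)
  structure(list(d_model = as.integer(d_model), d_ff = as.integer(d_ff),
                 n_layers_enc = as.integer(n_layers_enc),
                 n_layers_dec = as.integer(n_layers_dec),
                 n_heads = as.integer(n_heads), dropout = dropout,
                 norm_placement = norm_placement, init_scheme = init_scheme,
                 optimizer = optimizer, weight_decay = weight_decay,
                 warmup_steps = as.integer(warmup_steps),
                 token_budget_per_step = as.integer(token_budget_per_step),
                 accum_batches = as.integer(accum_batches),
                 max_steps = as.integer(max_steps),
                 max_len = as.integer(max_len),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Warmup learning-rate schedule
#'
#' `lr = d_model^(-1/2) * min(step^(-1/2), step * warmup_steps^(-3/2))`:
#' linear warmup to the knee at `warmup_steps`, inverse-square-root decay
#' after.
#'
#' @param step optimizer step, >= 1.
#' @param cfg a [model_config()].
#' @return learning rate.
#' @export
lr_at_step <- function(step, cfg) {
  stopifnot(all(step >= 1))
  cfg$d_model^(-0.5) * pmin(step^(-0.5), step * cfg$warmup_steps^(-1.5))
}

init_matrix <- function(nr, nc, scheme, kind = c("linear", "embedding")) {
  kind <- match.arg(kind)
  if (scheme == "he_normal") {
    fan_in <- if (kind == "embedding") nc else nr
    matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
  } else if (kind == "embedding") {
    matrix(stats::rnorm(nr * nc, 0, nc^(-0.5)), nr, nc)
  } else {
    lim <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
}

att_param_names <- function(prefix)
  paste0(prefix, c("_Wq", "_bq", "_Wk", "_bk", "_Wv", "_bv", "_Wo", "_bo"))

#' Build a Transformer model
#'
#' Allocates and initializes all parameters; weights are reproducible from
#' `cfg$seed`.
#'
#' @param cfg a [model_config()].
#' @param src_vocab_size,tgt_vocab_size vocabulary sizes (token id count).
#' @return a `transformer_model` list: `cfg`, `params`, the positional
#'   table, and vocabulary sizes.
#' @export
build_model <- function(cfg, src_vocab_size, tgt_vocab_size) {
  stopifnot(inherits(cfg, "model_config"),
            src_vocab_size >= 5, tgt_vocab_size >= 5)
  set.seed(cfg$seed)
  d <- cfg$d_model; ff <- cfg$d_ff; sch <- cfg$init_scheme
  p <- list()
  p$src_emb <- init_matrix(src_vocab_size, d, sch, "embedding")
  p$tgt_emb <- init_matrix(tgt_vocab_size, d, sch, "embedding")
  add_att <- function(p, prefix) {
    for (w in c("Wq", "Wk", "Wv", "Wo"))
      p[[paste0(prefix, "_", w)]] <- init_matrix(d, d, sch)
    for (b in c("bq", "bk", "bv", "bo"))
      p[[paste0(prefix, "_", b)]] <- numeric(d)
    p
  }
  add_ln <- function(p, prefix) {
    p[[paste0(prefix, "_g")]] <- rep(1, d)
    p[[paste0(prefix, "_b")]] <- numeric(d)
    p
  }
  add_ff <- function(p, prefix) {
    p[[paste0(prefix, "_W1")]] <- init_matrix(d, ff, sch)
    p[[paste0(prefix, "_b1")]] <- numeric(ff)
    p[[paste0(prefix, "_W2")]] <- init_matrix(ff, d, sch)
    p[[paste0(prefix, "_b2")]] <- numeric(d)
    p
  }
  for (l in seq_len(cfg$n_layers_enc)) {
    pre <- paste0("enc_l", l)
    p <- add_att(p, paste0(pre, "_att"))
    p <- add_ln(p, paste0(pre, "_ln1"))
    p <- add_ff(p, paste0(pre, "_ff"))
    p <- add_ln(p, paste0(pre, "_ln2"))
  }
  for (l in seq_len(cfg$n_layers_dec)) {
    pre <- paste0("dec_l", l)
    p <- add_att(p, paste0(pre, "_self"))
    p <- add_ln(p, paste0(pre, "_ln1"))
    p <- add_att(p, paste0(pre, "_cross"))
    p <- add_ln(p, paste0(pre, "_ln2"))
    p <- add_ff(p, paste0(pre, "_ff"))
    p <- add_ln(p, paste0(pre, "_ln3"))
  }
  if (cfg$norm_placement == "pre_ln") {
    p <- add_ln(p, "enc_final_ln")
    p <- add_ln(p, "dec_final_ln")
  }
  p$out_W <- init_matrix(d, tgt_vocab_size, sch)
  p$out_b <- numeric(tgt_vocab_size)
  structure(list(cfg = cfg, params = p,
                 pe = positional_encoding(cfg$max_len, d),
                 src_vocab_size = as.integer(src_vocab_size),
                 tgt_vocab_size = as.integer(tgt_vocab_size)),
            class = "transformer_model")
}

#' Count model parameters
#'
#' @param model a [build_model()] result.
#' @return total number of scalar parameters.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}

#' @export
print.transformer_model <- function(x, ...) {
  cfg <- x$cfg
  cat("<transformer_model> d_model=", cfg$d_model, " d_ff=", cfg$d_ff,
      " layers=", cfg$n_layers_enc, "+", cfg$n_layers_dec,
      " heads=", cfg$n_heads, " ", cfg$norm_placement,
      " params=", n_params(x), "\n", sep = "")
  invisible(x)
}

embed_fwd <- function(ids_mat, emb, pe, d, dropout, train) {
  B <- nrow(ids_mat); L <- ncol(ids_mat)
  idx <- as.integer(t(ids_mat)) + 1L       # row-blocks per sequence
  X <- emb[idx, , drop = FALSE] * sqrt(d)
  X <- X + pe[rep(seq_len(L), B), , drop = FALSE]
  dp <- dropout_fwd(X, dropout, train)
  list(Y = dp$Y, idx = idx, dp = dp, B = B, L = L)
}

embed_bwd <- function(dY, cache, vocab_size, d) {
  dY <- dropout_bwd(dY, cache$dp)
  dY <- dY * sqrt(d)
  demb <- matrix(0, vocab_size, d)
  # accumulate duplicate ids
  agg <- rowsum(dY, group = cache$idx)
  demb[as.integer(rownames(agg)), ] <- agg
  demb
}

# sublayer wiring for one residual block; fn_fwd must return list(Y, cache)
sublayer_fwd <- function(X, p, ln_prefix, placement, dropout, train, fn_fwd) {
  if (placement == "post_ln") {
    inner <- fn_fwd(X)
    dp <- dropout_fwd(inner$Y, dropout, train)
    ln <- layernorm_fwd(X + dp$Y, p[[paste0(ln_prefix, "_g")]],
                        p[[paste0(ln_prefix, "_b")]])
    list(Y = ln$Y, inner = inner$cache, dp = dp, ln = ln)
  } else {
    ln <- layernorm_fwd(X, p[[paste0(ln_prefix, "_g")]],
                        p[[paste0(ln_prefix, "_b")]])
    inner <- fn_fwd(ln$Y)
    dp <- dropout_fwd(inner$Y, dropout, train)
    list(Y = X + dp$Y, inner = inner$cache, dp = dp, ln = ln)
  }
}

# returns list(dX, grads) given fn_bwd(dInner, cache) -> list(dX, grads)
sublayer_bwd <- function(dY, cache, p, ln_prefix, placement, fn_bwd) {
  g <- p[[paste0(ln_prefix, "_g")]]
  if (placement == "post_ln") {
    lnb <- layernorm_bwd(dY, cache$ln, g)
    dsum <- lnb$dX
    dinner <- dropout_bwd(dsum, cache$dp)
    fb <- fn_bwd(dinner, cache$inner)
    grads <- fb$grads
    grads[[paste0(ln_prefix, "_g")]] <- lnb$dg
    grads[[paste0(ln_prefix, "_b")]] <- lnb$db
    list(dX = dsum + fb$dX, grads = grads)
  } else {
    dinner <- dropout_bwd(dY, cache$dp)
    fb <- fn_bwd(dinner, cache$inner)
    lnb <- layernorm_bwd(fb$dX, cache$ln, g)
    grads <- fb$grads
    grads[[paste0(ln_prefix, "_g")]] <- lnb$dg
    grads[[paste0(ln_prefix, "_b")]] <- lnb$db
    list(dX = dY + lnb$dX, grads = grads)
  }
}

ff_block_fwd <- function(X, p, prefix, dropout, train) {
  l1 <- linear_fwd(X, p[[paste0(prefix, "_W1")]], p[[paste0(prefix, "_b1")]])
  r <- relu_fwd(l1$Y)
  l2 <- linear_fwd(r$Y, p[[paste0(prefix, "_W2")]], p[[paste0(prefix, "_b2")]])
  list(Y = l2$Y, cache = list(l1 = l1, r = r, l2 = l2))
}

ff_block_bwd <- function(dY, cache, p, prefix) {
  b2 <- linear_bwd(dY, cache$l2, p[[paste0(prefix, "_W2")]])
  dr <- relu_bwd(b2$dX, cache$r)
  b1 <- linear_bwd(dr, cache$l1, p[[paste0(prefix, "_W1")]])
  grads <- list()
  grads[[paste0(prefix, "_W1")]] <- b1$dW
  grads[[paste0(prefix, "_b1")]] <- b1$db
  grads[[paste0(prefix, "_W2")]] <- b2$dW
  grads[[paste0(prefix, "_b2")]] <- b2$db
  list(dX = b1$dX, grads = grads)
}

# full encoder forward: src_mat is B x Ls of 0-based ids
encoder_fwd <- function(model, src_mat, pad_id = 0L, train = FALSE) {
  cfg <- model$cfg; p <- model$params
  B <- nrow(src_mat); Ls <- ncol(src_mat)
  stopifnot(Ls <= cfg$max_len)
  key_mask <- src_mat != pad_id
  emb <- embed_fwd(src_mat, p$src_emb, model$pe, cfg$d_model,
                   cfg$dropout, train)
  X <- emb$Y
  layers <- vector("list", cfg$n_layers_enc)
  for (l in seq_len(cfg$n_layers_enc)) {
    pre <- paste0("enc_l", l)
    att <- sublayer_fwd(X, p, paste0(pre, "_ln1"), cfg$norm_placement,
                        cfg$dropout, train, function(Xin) {
      cc <- mha_fwd(Xin, Xin, p, paste0(pre, "_att"), cfg$n_heads,
                    B, Ls, Ls, key_mask = key_mask)
      list(Y = cc$Y, cache = cc)
    })
    X <- att$Y
    ffb <- sublayer_fwd(X, p, paste0(pre, "_ln2"), cfg$norm_placement,
                        cfg$dropout, train, function(Xin) {
      ff_block_fwd(Xin, p, paste0(pre, "_ff"), cfg$dropout, train)
    })
    X <- ffb$Y
    layers[[l]] <- list(att = att, ff = ffb)
  }
  final_ln <- NULL
  if (cfg$norm_placement == "pre_ln") {
    final_ln <- layernorm_fwd(X, p$enc_final_ln_g, p$enc_final_ln_b)
    X <- final_ln$Y
  }
  list(memory = X, key_mask = key_mask, emb = emb, layers = layers,
       final_ln = final_ln, B = B, Ls = Ls)
}

encoder_bwd <- function(dmem, enc, model) {
  cfg <- model$cfg; p <- model$params
  grads <- list()
  add <- function(g) for (nm in names(g))
    grads[[nm]] <<- if (is.null(grads[[nm]])) g[[nm]] else grads[[nm]] + g[[nm]]
  dX <- dmem
  if (cfg$norm_placement == "pre_ln") {
    lnb <- layernorm_bwd(dX, enc$final_ln, p$enc_final_ln_g)
    add(list(enc_final_ln_g = lnb$dg, enc_final_ln_b = lnb$db))
    dX <- lnb$dX
  }
  for (l in rev(seq_len(cfg$n_layers_enc))) {
    pre <- paste0("enc_l", l)
    lay <- enc$layers[[l]]
    sb <- sublayer_bwd(dX, lay$ff, p, paste0(pre, "_ln2"),
                       cfg$norm_placement, function(dY, cache)
      ff_block_bwd(dY, cache, p, paste0(pre, "_ff")))
    add(sb$grads); dX <- sb$dX
    sb <- sublayer_bwd(dX, lay$att, p, paste0(pre, "_ln1"),
                       cfg$norm_placement, function(dY, cache) {
      mb <- mha_bwd(dY, cache, p, paste0(pre, "_att"))
      list(dX = mb$dXq + mb$dXkv, grads = mb$grads)
    })
    add(sb$grads); dX <- sb$dX
  }
  demb <- embed_bwd(dX, enc$emb, model$src_vocab_size, cfg$d_model)
  add(list(src_emb = demb))
  grads
}

# decoder forward on teacher-forced input (B x Lt-1 ids); returns logits for
# each input position
decoder_fwd <- function(model, tgt_in_mat, memory, src_key_mask,
                        pad_id = 0L, train = FALSE) {
  cfg <- model$cfg; p <- model$params
  B <- nrow(tgt_in_mat); Lt <- ncol(tgt_in_mat)
  Ls <- ncol(src_key_mask)
  stopifnot(Lt <= cfg$max_len)
  emb <- embed_fwd(tgt_in_mat, p$tgt_emb, model$pe, cfg$d_model,
                   cfg$dropout, train)
  X <- emb$Y
  layers <- vector("list", cfg$n_layers_dec)
  for (l in seq_len(cfg$n_layers_dec)) {
    pre <- paste0("dec_l", l)
    self <- sublayer_fwd(X, p, paste0(pre, "_ln1"), cfg$norm_placement,
                         cfg$dropout, train, function(Xin) {
      cc <- mha_fwd(Xin, Xin, p, paste0(pre, "_self"), cfg$n_heads,
                    B, Lt, Lt, causal = TRUE)
      list(Y = cc$Y, cache = cc)
    })
    X <- self$Y
    cross <- sublayer_fwd(X, p, paste0(pre, "_ln2"), cfg$norm_placement,
                          cfg$dropout, train, function(Xin) {
      cc <- mha_fwd(Xin, memory, p, paste0(pre, "_cross"), cfg$n_heads,
                    B, Lt, Ls, key_mask = src_key_mask)
      list(Y = cc$Y, cache = cc)
    })
    X <- cross$Y
    ffb <- sublayer_fwd(X, p, paste0(pre, "_ln3"), cfg$norm_placement,
                        cfg$dropout, train, function(Xin) {
      ff_block_fwd(Xin, p, paste0(pre, "_ff"), cfg$dropout, train)
    })
    X <- ffb$Y
    layers[[l]] <- list(self = self, cross = cross, ff = ffb)
  }
  final_ln <- NULL
  if (cfg$norm_placement == "pre_ln") {
    final_ln <- layernorm_fwd(X, p$dec_final_ln_g, p$dec_final_ln_b)
    X <- final_ln$Y
  }
  out <- linear_fwd(X, p$out_W, p$out_b)
  list(logits = out$Y, out = out, emb = emb, layers = layers,
       final_ln = final_ln, B = B, Lt = Lt)
}

decoder_bwd <- function(dlogits, dec, model) {
  cfg <- model$cfg; p <- model$params
  grads <- list()
  add <- function(g) for (nm in names(g))
    grads[[nm]] <<- if (is.null(grads[[nm]])) g[[nm]] else grads[[nm]] + g[[nm]]
  ob <- linear_bwd(dlogits, dec$out, p$out_W)
  add(list(out_W = ob$dW, out_b = ob$db))
  dX <- ob$dX
  if (cfg$norm_placement == "pre_ln") {
    lnb <- layernorm_bwd(dX, dec$final_ln, p$dec_final_ln_g)
    add(list(dec_final_ln_g = lnb$dg, dec_final_ln_b = lnb$db))
    dX <- lnb$dX
  }
  dmem <- NULL
  for (l in rev(seq_len(cfg$n_layers_dec))) {
    pre <- paste0("dec_l", l)
    lay <- dec$layers[[l]]
    sb <- sublayer_bwd(dX, lay$ff, p, paste0(pre, "_ln3"),
                       cfg$norm_placement, function(dY, cache)
      ff_block_bwd(dY, cache, p, paste0(pre, "_ff")))
    add(sb$grads); dX <- sb$dX
    cross_dmem <- NULL
    sb <- sublayer_bwd(dX, lay$cross, p, paste0(pre, "_ln2"),
                       cfg$norm_placement, function(dY, cache) {
      mb <- mha_bwd(dY, cache, p, paste0(pre, "_cross"))
      cross_dmem <<- mb$dXkv
      list(dX = mb$dXq, grads = mb$grads)
    })
    add(sb$grads); dX <- sb$dX
    dmem <- if (is.null(dmem)) cross_dmem else dmem + cross_dmem
    sb <- sublayer_bwd(dX, lay$self, p, paste0(pre, "_ln1"),
                       cfg$norm_placement, function(dY, cache) {
      mb <- mha_bwd(dY, cache, p, paste0(pre, "_self"))
      list(dX = mb$dXq + mb$dXkv, grads = mb$grads)
    })
    add(sb$grads); dX <- sb$dX
  }
  demb <- embed_bwd(dX, dec$emb, model$tgt_vocab_size, cfg$d_model)
  add(list(tgt_emb = demb))
  list(grads = grads, dmem = dmem)
}

#' Cross-entropy loss over non-padding tokens
#'
#' Mean softmax cross-entropy across all positions whose target is not the
#' padding token.
#'
#' @param logits `N x V` score matrix (rows = target positions).
#' @param targets integer vector of `N` 0-based target ids.
#' @param pad_id padding token id excluded from the mean.
#' @return list: `loss`, `dlogits` (gradient w.r.t. logits), `n_tokens`.
#' @export
token_xent_loss <- function(logits, targets, pad_id = 0L) {
  stopifnot(nrow(logits) == length(targets))
  keep <- targets != pad_id
  n <- sum(keep)
  if (n == 0L) stop("all target positions are padding")
  if (!all(is.finite(logits)))
    return(list(loss = NaN, dlogits = logits * NaN, n_tokens = n))
  P <- softmax_rows(logits)
  rows <- which(keep)
  picked <- P[cbind(rows, targets[rows] + 1L)]
  loss <- -mean(log(pmax(picked, 1e-300)))
  dlogits <- P
  dlogits[cbind(rows, targets[rows] + 1L)] <-
    dlogits[cbind(rows, targets[rows] + 1L)] - 1
  dlogits[!keep, ] <- 0
  dlogits <- dlogits / n
  list(loss = loss, dlogits = dlogits, n_tokens = n)
}

# engine selection: "cpp" (compiled, default) or "r" (reference); both
# implement the same mathematics and are cross-checked in the test suite
engine_choice <- function() {
  match.arg(getOption("smiletran.engine", "cpp"), c("cpp", "r"))
}

# one full forward+backward over a batch; returns loss and parameter grads
model_loss_grads <- function(model, batch, pad_id = 0L, train = TRUE,
                             engine = engine_choice()) {
  if (engine == "cpp") {
    out <- cpp_loss_grads(model$params, model$cfg, model$pe,
                          storage_int(batch$source), storage_int(batch$target),
                          as.integer(pad_id), isTRUE(train),
                          model$src_vocab_size, model$tgt_vocab_size)
    return(list(loss = as.numeric(out$loss), grads = out$grads,
                n_tokens = out$n_tokens))
  }
  model_loss_grads_r(model, batch, pad_id, train)
}

storage_int <- function(m) {
  if (is.integer(m)) m else matrix(as.integer(m), nrow(m), ncol(m))
}

model_loss_grads_r <- function(model, batch, pad_id = 0L, train = TRUE) {
  tgt <- batch$target
  Lt <- ncol(tgt)
  tgt_in <- tgt[, -Lt, drop = FALSE]
  tgt_out <- as.integer(t(tgt[, -1, drop = FALSE]))
  enc <- encoder_fwd(model, batch$source, pad_id, train)
  dec <- decoder_fwd(model, tgt_in, enc$memory, enc$key_mask, pad_id, train)
  lo <- token_xent_loss(dec$logits, tgt_out, pad_id)
  db <- decoder_bwd(lo$dlogits, dec, model)
  ge <- encoder_bwd(db$dmem, enc, model)
  grads <- db$grads
  for (nm in names(ge))
    grads[[nm]] <- if (is.null(grads[[nm]])) ge[[nm]] else grads[[nm]] + ge[[nm]]
  list(loss = lo$loss, grads = grads, n_tokens = lo$n_tokens)
}
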