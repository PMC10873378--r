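# Independent brute-force re-implementations of the accuracy metrics,
# written as explicit loops over trimmed token vectors. These never share
# code with the package implementations; they are the reference the metric
# suite is checked against.

oracle_trim <- function(ids, bos = 1L, eos = 2L, pad = 0L) {
  ids <- ids[ids != pad]
  if (length(ids) && ids[1] == bos) ids <- ids[-1]
  out <- integer(0)
  for (x in ids) {
    if (x == eos) break
    out <- c(out, x)
  }
  out
}

oracle_perfect <- function(preds, tgts) {
  hit <- 0
  for (i in seq_along(tgts)) {
    p <- oracle_trim(preds[[i]]); t <- oracle_trim(tgts[[i]])
    if (length(p) == length(t) && all(p == t)) hit <- hit + 1
  }
  hit / length(tgts)
}

oracle_partial <- function(preds, tgts) {
  hit <- 0; tot <- 0
  for (i in seq_along(tgts)) {
    t <- c(oracle_trim(tgts[[i]]), 2L)   # eos position is scored too
    p <- c(oracle_trim(preds[[i]]), 2L)
    for (j in seq_along(t)) {
      tot <- tot + 1
      if (j <= length(p) && p[j] == t[j]) hit <- hit + 1
    }
  }
  hit / tot
}

oracle_masked <- function(preds, tgts, masked) {
  hit <- 0
  for (i in seq_along(tgts)) {
    p <- oracle_trim(preds[[i]]); t <- oracle_trim(tgts[[i]])
    if (length(p) != length(t)) next
    ok <- TRUE
    for (j in seq_along(t))
      if (t[j] != masked && p[j] != t[j]) ok <- FALSE
    if (ok) hit <- hit + 1
  }
  hit / length(tgts)
}

oracle_chirality <- function(preds, tgts, at, atat) {
  counts <- c(correct = 0, chir = 0, other = 0)
  for (i in seq_along(tgts)) {
    p <- oracle_trim(preds[[i]]); t <- oracle_trim(tgts[[i]])
    if (length(p) == length(t) && all(p == t)) {
      counts["correct"] <- counts["correct"] + 1
    } else if (length(p) != length(t)) {
      counts["other"] <- counts["other"] + 1
    } else {
      bad <- which(p != t)
      is_swap <- all((t[bad] == at & p[bad] == atat) |
                     (t[bad] == atat & p[bad] == at))
      if (is_swap) counts["chir"] <- counts["chir"] + 1
      else counts["other"] <- counts["other"] + 1
    }
  }
  counts / length(tgts)
}

oracle_per_token <- function(tf_preds, tgts, vocab) {
  num <- list(); den <- list()
  for (i in seq_along(tgts)) {
    t <- tgts[[i]][-1]          # positions after the start token
    p <- tf_preds[[i]]
    for (j in seq_along(t)) {
      if (t[j] == 0L) next
      tok <- vocab$tokens[t[j] + 1L]
      den[[tok]] <- (if (is.null(den[[tok]])) 0 else den[[tok]]) + 1
      num[[tok]] <- (if (is.null(num[[tok]])) 0 else num[[tok]]) +
        as.numeric(p[j] == t[j])
    }
  }
  out <- vapply(names(den), function(k) num[[k]] / den[[k]], numeric(1))
  out[sort(names(out))]
}
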