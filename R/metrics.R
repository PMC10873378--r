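# Translation accuracy metrics. All metrics operate at the token level of
# the training vocabulary (so "@@" and "Cl" are single units) on 0-based id
# sequences as produced by tokenize()/greedy_decode(). The comparison region
# of a pair runs from the first content token through the end token; padding
# after the end token is ignored, and prediction positions that are absent
# (shorter prediction) count as mismatches.

# strip bos, keep content..eos, drop pads; returns content tokens only
content_tokens <- function(ids, bos_id = 1L, eos_id = 2L, pad_id = 0L) {
  ids <- as.integer(ids)
  ids <- ids[ids != pad_id]
  if (length(ids) > 0 && ids[1] == bos_id) ids <- ids[-1]
  eos <- which(ids == eos_id)
  if (length(eos) > 0) ids <- ids[seq_len(eos[1] - 1L)]
  ids
}

check_pair_input <- function(predictions, targets) {
  if (length(predictions) == 0L || length(targets) == 0L)
    stop("empty prediction/target input")
  if (length(predictions) != length(targets))
    stop("predictions and targets differ in length")
}

#' Perfect accuracy
#'
#' Fraction of pairs whose predicted token sequence matches the target
#' exactly from the first content token through the end token (padding
#' ignored).
#'
#' @param predictions,targets lists of 0-based token id vectors.
#' @param bos_id,eos_id,pad_id special token ids.
#' @return fraction in \[0, 1\].
#' @export
perfect_accuracy <- function(predictions, targets,
                             bos_id = 1L, eos_id = 2L, pad_id = 0L) {
  check_pair_input(predictions, targets)
  ok <- mapply(function(p, t) {
    identical(content_tokens(p, bos_id, eos_id, pad_id),
              content_tokens(t, bos_id, eos_id, pad_id))
  }, predictions, targets)
  mean(ok)
}

#' Partial accuracy
#'
#' Position-wise (micro-averaged) agreement between prediction and target
#' over all target content positions plus the end-token position; positions
#' beyond the end of the prediction count as mismatches.
#'
#' @inheritParams perfect_accuracy
#' @return fraction in \[0, 1\].
#' @export
partial_accuracy <- function(predictions, targets,
                             bos_id = 1L, eos_id = 2L, pad_id = 0L) {
  check_pair_input(predictions, targets)
  hits <- 0; total <- 0
  for (i in seq_along(targets)) {
    tt <- c(content_tokens(targets[[i]], bos_id, eos_id, pad_id), eos_id)
    pp <- c(content_tokens(predictions[[i]], bos_id, eos_id, pad_id), eos_id)
    n <- length(tt)
    total <- total + n
    cmp <- seq_len(min(n, length(pp)))
    hits <- hits + sum(tt[cmp] == pp[cmp])
  }
  hits / total
}

#' Masked perfect accuracy
#'
#' Perfect accuracy computed while exempting target positions bearing one
#' designated token: those positions are not required to match (but they
#' still occupy a position, so length must agree elsewhere). Mirrors the
#' per-character masking analysis used to localize chirality errors.
#'
#' @inheritParams perfect_accuracy
#' @param masked_id 0-based id of the masked token (not a special token).
#' @return fraction in \[0, 1\].
#' @export
masked_perfect_accuracy <- function(predictions, targets, masked_id,
                                    bos_id = 1L, eos_id = 2L, pad_id = 0L) {
  check_pair_input(predictions, targets)
  if (masked_id %in% c(bos_id, eos_id, pad_id))
    stop("masked token must not be a special token")
  ok <- mapply(function(p, t) {
    tt <- content_tokens(t, bos_id, eos_id, pad_id)
    pp <- content_tokens(p, bos_id, eos_id, pad_id)
    if (length(tt) != length(pp)) return(FALSE)
    keep <- tt != masked_id
    all(tt[keep] == pp[keep])
  }, predictions, targets)
  mean(ok)
}

#' Per-token teacher-forced accuracy
#'
#' For each vocabulary token with at least one occurrence among target
#' content positions: the fraction of those positions where the
#' teacher-forced prediction equals the target. Tokens with zero
#' occurrences are omitted.
#'
#' @param tf_predictions list of per-position predicted id vectors from
#'   [teacher_forced_predict()] (aligned to target positions 2..Lt).
#' @param targets list of target id vectors (with start token).
#' @param vocab vocabulary used to name the result.
#' @param include_eos also score the end-token position.
#' @return named numeric vector: token -> accuracy.
#' @export
per_token_accuracy <- function(tf_predictions, targets, vocab,
                               include_eos = TRUE) {
  check_pair_input(tf_predictions, targets)
  tally <- new.env(hash = TRUE)
  for (i in seq_along(targets)) {
    tt <- targets[[i]]
    stopifnot(tt[1] == vocab$bos_id)
    aligned <- tt[-1]                       # positions predicted by the model
    keep <- aligned != vocab$pad_id
    if (!include_eos) keep <- keep & aligned != vocab$eos_id
    pp <- tf_predictions[[i]]
    stopifnot(length(pp) >= sum(keep))
    for (j in which(keep)) {
      tok <- vocab$tokens[aligned[j] + 1L]
      cur <- tally[[tok]]
      if (is.null(cur)) cur <- c(0, 0)
      tally[[tok]] <- cur + c(pp[j] == aligned[j], 1)
    }
  }
  toks <- ls(tally)
  out <- vapply(toks, function(tk) {
    x <- tally[[tk]]; x[1] / x[2]
  }, numeric(1))
  names(out) <- toks
  out
}

#' Classify prediction errors by chirality
#'
#' Splits pairs into: `correct` (exact match), `chirality_only` (same token
#' count and every mismatching position is a swap of the two tetrahedral
#' parity tokens), and `other` (all remaining mistakes, including length
#' mismatches).
#'
#' @inheritParams perfect_accuracy
#' @param at_id,atat_id 0-based ids of the `"@"` and `"@@"` tokens.
#' @return list of class `chirality_breakdown`: `frac_correct`,
#'   `frac_chirality_only`, `frac_other`, and counts.
#' @export
classify_chirality_errors <- function(predictions, targets, at_id, atat_id,
                                      bos_id = 1L, eos_id = 2L, pad_id = 0L) {
  check_pair_input(predictions, targets)
  n <- length(targets)
  kinds <- vapply(seq_len(n), function(i) {
    tt <- content_tokens(targets[[i]], bos_id, eos_id, pad_id)
    pp <- content_tokens(predictions[[i]], bos_id, eos_id, pad_id)
    if (identical(tt, pp)) return("correct")
    if (length(tt) != length(pp)) return("other")
    bad <- which(tt != pp)
    swap <- (tt[bad] == at_id & pp[bad] == atat_id) |
            (tt[bad] == atat_id & pp[bad] == at_id)
    if (all(swap)) "chirality_only" else "other"
  }, character(1))
  structure(list(frac_correct = mean(kinds == "correct"),
                 frac_chirality_only = mean(kinds == "chirality_only"),
                 frac_other = mean(kinds == "other"),
                 n = n),
            class = "chirality_breakdown")
}

#' @export
print.chirality_breakdown <- function(x, ...) {
  cat(sprintf(
    "<chirality_breakdown> correct %.3f | chirality-only %.3f | other %.3f (n=%d)\n",
    x$frac_correct, x$frac_chirality_only, x$frac_other, x$n))
  invisible(x)
}

#' First step at which an accuracy series reaches a threshold
#'
#' Returns the smallest evaluated step whose accuracy is at least
#' `threshold`; if the series never reaches it, the end-of-training step is
#' returned.
#'
#' @param series data.frame with columns `step` and `perfect_accuracy`
#'   (sorted by step), or a numeric vector named by step.
#' @param threshold accuracy threshold in (0, 1].
#' @param end_step step assigned when the threshold is never reached.
#' @return a step number.
#' @export
extract_threshold_step <- function(series, threshold, end_step) {
  stopifnot(threshold > 0, threshold <= 1)
  if (is.data.frame(series)) {
    steps <- series$step; acc <- series$perfect_accuracy
  } else {
    steps <- as.numeric(names(series)); acc <- as.numeric(series)
  }
  if (length(steps) == 0L) stop("empty accuracy series")
  stopifnot(!is.unsorted(steps))
  hit <- which(acc >= threshold)
  if (length(hit) == 0L) end_step else steps[hit[1]]
}
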