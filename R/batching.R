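# Token-budget batching with optional length bucketing. A batch is capped by
# its padded source token count (rows x padded length <= token_budget);
# bucketing groups similar source lengths to cut padding waste.

pad_to_matrix <- function(seqs, pad_id) {
  L <- max(lengths(seqs))
  m <- matrix(pad_id, nrow = length(seqs), ncol = L)
  for (i in seq_along(seqs)) m[i, seq_along(seqs[[i]])] <- seqs[[i]]
  m
}

#' Assemble translation pairs into token-budget batches
#'
#' Every pair appears in exactly one batch. Each batch satisfies
#' `nrow * padded_source_length <= token_budget`. With `bucketing`, pairs
#' are grouped into source-length deciles before batching so batches draw
#' from similar lengths; batch iteration order is shuffled either way, and
#' reproducible from the RNG state.
#'
#' @param pairs list of pairs from [make_translation_pairs()].
#' @param token_budget maximum padded source tokens per batch.
#' @param bucketing group by length deciles before batching (default TRUE).
#' @param pad_id pad token id (default 0).
#' @return list of batches: each has `source` and `target` 0-based id
#'   matrices (right-padded), and `molecule_index`.
#' @export
make_batches <- function(pairs, token_budget, bucketing = TRUE, pad_id = 0L) {
  stopifnot(length(pairs) > 0)
  src_len <- vapply(pairs, function(p) length(p$source), integer(1))
  if (max(src_len) > token_budget)
    stop("a single sequence (", max(src_len),
         " tokens) exceeds the token budget ", token_budget)
  if (bucketing && length(pairs) > 1) {
    qs <- unique(stats::quantile(src_len, probs = seq(0, 1, by = 0.1),
                                 type = 1))
    bucket <- cut(src_len, breaks = qs, include.lowest = TRUE, labels = FALSE)
  } else {
    bucket <- rep(1L, length(pairs))
  }
  batches <- list()
  for (b in sample(unique(bucket))) {
    idx <- sample(which(bucket == b))
    while (length(idx) > 0) {
      take <- 0L; maxlen <- 0L
      while (take < length(idx)) {
        cand_max <- max(maxlen, src_len[idx[take + 1L]])
        if ((take + 1L) * cand_max > token_budget) break
        take <- take + 1L; maxlen <- cand_max
      }
      sel <- idx[seq_len(take)]
      idx <- idx[-seq_len(take)]
      batches[[length(batches) + 1L]] <- list(
        source = pad_to_matrix(lapply(pairs[sel], `[[`, "source"), pad_id),
        target = pad_to_matrix(lapply(pairs[sel], `[[`, "target"), pad_id),
        molecule_index = vapply(pairs[sel], `[[`, integer(1),
                                "molecule_index"))
    }
  }
  batches[sample.int(length(batches))]
}

#' Count pad tokens across a batch list
#'
#' @param batches output of [make_batches()].
#' @param pad_id pad token id.
#' @return named vector: total source cells, pad cells, pad fraction.
#' @export
padding_stats <- function(batches, pad_id = 0L) {
  cells <- sum(vapply(batches, function(b) length(b$source), numeric(1)))
  pads <- sum(vapply(batches, function(b) sum(b$source == pad_id),
                     numeric(1)))
  c(cells = cells, pads = pads, pad_fraction = pads / cells)
}
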