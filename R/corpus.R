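# Data pathway from raw SMILES lines to model-ready translation pairs:
# element/heavy-atom filtering with fragment stripping, stratified-by-length
# sampling, chirality-enriched resampling and train/test splitting.

ALLOWED_ELEMENTS <- c("H", "B", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I")

largest_fragment <- function(smiles) {
  parts <- strsplit(smiles, ".", fixed = TRUE)[[1]]
  if (length(parts) == 1L) return(smiles)
  parts[which.max(count_heavy_atoms(parts))]
}

#' Filter raw SMILES for the training corpus
#'
#' Keeps the largest fragment of each input, drops invalid SMILES, molecules
#' with elements outside H,B,C,N,O,F,P,S,Cl,Br,I, and molecules with fewer
#' than `min_heavy` or more than `max_heavy` heavy atoms.
#'
#' @param smiles_stream character vector of candidate SMILES.
#' @param min_heavy,max_heavy inclusive heavy-atom bounds (defaults 3 and 50).
#' @return character vector of surviving (largest-fragment) SMILES, with
#'   attribute `n_dropped` giving the number of removed entries.
#' @export
filter_molecules <- function(smiles_stream, min_heavy = 3L, max_heavy = 50L) {
  if (length(smiles_stream) == 0L) {
    return(structure(character(0), n_dropped = 0L))
  }
  frag <- vapply(smiles_stream, largest_fragment, character(1),
                 USE.NAMES = FALSE)
  valid <- smiles_is_valid(frag)
  keep <- valid
  if (any(valid)) {
    elems_ok <- vapply(frag[valid], function(s)
      all(smiles_elements(s) %in% ALLOWED_ELEMENTS), logical(1))
    nh <- count_heavy_atoms(frag[valid])
    keep[valid] <- elems_ok & nh >= min_heavy & nh <= max_heavy
  }
  out <- frag[keep]
  dropped <- sum(!keep)
  if (dropped > 0)
    message(dropped, " of ", length(smiles_stream),
            " molecules removed by filtering")
  structure(out, n_dropped = dropped)
}

#' Stratified sampling by SMILES length
#'
#' Groups molecules by character length of their SMILES and samples at most
#' `per_length_cap` uniformly without replacement from each group; groups at
#' or below the cap are taken whole.
#'
#' @param pool character vector of SMILES.
#' @param per_length_cap maximum molecules contributed per length group.
#' @return character vector (grouped by increasing length).
#' @export
stratified_sample <- function(pool, per_length_cap) {
  stopifnot(per_length_cap >= 1)
  if (length(pool) == 0L) return(character(0))
  groups <- split(pool, nchar(pool))
  out <- lapply(groups, function(g) {
    if (length(g) <= per_length_cap) g
    else sample(g, per_length_cap)
  })
  unlist(out, use.names = FALSE)
}

#' Chirality-enriched resampling
#'
#' Retains every molecule whose SMILES carries a chiral token (`@` or `@@`)
#' and each remaining molecule independently with probability
#' `keep_prob_achiral`.
#'
#' @param smiles character vector of SMILES.
#' @param keep_prob_achiral retention probability for achiral molecules
#'   (default 0.5).
#' @return character vector of retained SMILES.
#' @export
chirality_enriched_resample <- function(smiles, keep_prob_achiral = 0.5) {
  stopifnot(keep_prob_achiral >= 0, keep_prob_achiral <= 1)
  chiral <- grepl("@", smiles, fixed = TRUE)
  keep <- chiral | (runif(length(smiles)) < keep_prob_achiral)
  smiles[keep]
}

#' Split a corpus into training and test sets
#'
#' @param corpus corpus `data.frame` from [generate_corpus()] (or any
#'   data.frame with one row per molecule).
#' @param test_fraction fraction held out for testing (default 0.03).
#' @return list with `train` and `test` data.frames.
#' @export
split_corpus <- function(corpus, test_fraction = 0.03) {
  stopifnot(test_fraction >= 0, test_fraction < 1)
  n <- nrow(corpus)
  n_test <- round(n * test_fraction)
  test_idx <- if (n_test > 0) sample.int(n, n_test) else integer(0)
  list(train = corpus[setdiff(seq_len(n), test_idx), , drop = FALSE],
       test = corpus[test_idx, , drop = FALSE])
}
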