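# Tokenization. The vocabulary is the symbol inventory observed in a corpus
# plus four special tokens; multi-character tokens (two-letter elements,
# "@@", "%NN" ring indices) are matched longest-first so that e.g. "Cl" is
# one token and "@@" is never read as two "@".

PAD_TOKEN <- "<pad>"
BOS_TOKEN <- "<s>"
EOS_TOKEN <- "</s>"
UNK_TOKEN <- "<unk>"

scan_tokens <- function(s) {
  pattern <- "%[0-9]{2}|Cl|Br|@@|."
  regmatches(s, gregexpr(pattern, s, perl = TRUE))[[1]]
}

#' Build a vocabulary from corpus strings
#'
#' @param strings character vector (SMILES or InChI).
#' @return a `vocabulary` object: `tokens` (id order, specials first),
#'   `token_to_id` (0-based ids), and ids of the special tokens.
#' @export
build_vocabulary <- function(strings) {
  stopifnot(length(strings) > 0)
  observed <- sort(unique(unlist(lapply(strings, scan_tokens))))
  tokens <- c(PAD_TOKEN, BOS_TOKEN, EOS_TOKEN, UNK_TOKEN, observed)
  ids <- seq_along(tokens) - 1L
  names(ids) <- tokens
  structure(list(tokens = tokens, token_to_id = ids,
                 pad_id = 0L, bos_id = 1L, eos_id = 2L, unk_id = 3L),
            class = "vocabulary")
}

#' @export
print.vocabulary <- function(x, ...) {
  cat("<vocabulary>", length(x$tokens), "tokens:",
      paste(utils::head(x$tokens, 20), collapse = " "),
      if (length(x$tokens) > 20) "..." else "", "\n")
  invisible(x)
}

#' Tokenize a string into vocabulary token ids
#'
#' Greedy longest-match over the vocabulary; start and end tokens are
#' attached. Characters with no matching token either raise an error or map
#' to the unknown token.
#'
#' @param s a single non-empty string.
#' @param vocab a [build_vocabulary()] object.
#' @param on_unknown `"error"` or `"unk"`.
#' @return integer vector of 0-based token ids.
#' @export
tokenize <- function(s, vocab, on_unknown = c("error", "unk")) {
  on_unknown <- match.arg(on_unknown)
  stopifnot(is.character(s), length(s) == 1L, nzchar(s))
  content <- vocab$tokens[-(1:4)]
  by_len <- split(content, nchar(content))
  lens <- sort(as.integer(names(by_len)), decreasing = TRUE)
  ids <- integer(0)
  i <- 1L; nc <- nchar(s)
  while (i <= nc) {
    matched <- FALSE
    for (L in lens) {
      if (i + L - 1L > nc) next
      piece <- substr(s, i, i + L - 1L)
      if (piece %in% by_len[[as.character(L)]]) {
        ids <- c(ids, vocab$token_to_id[[piece]])
        i <- i + L
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      if (on_unknown == "error")
        stop("no vocabulary token matches '", substr(s, i, i), "' in ", s)
      ids <- c(ids, vocab$unk_id)
      i <- i + 1L
    }
  }
  c(vocab$bos_id, ids, vocab$eos_id)
}

# fast tokenization path: regex scan + id lookup; falls back to the greedy
# longest-match tokenizer when a scanned piece is not a vocabulary token
tokenize_fast <- function(s, vocab, on_unknown = "unk") {
  toks <- scan_tokens(s)
  ids <- unname(vocab$token_to_id[toks])
  if (anyNA(ids)) return(tokenize(s, vocab, on_unknown))
  c(vocab$bos_id, ids, vocab$eos_id)
}

#' Convert token ids back to tokens or text
#'
#' @param ids integer vector of 0-based token ids.
#' @param vocab vocabulary.
#' @return `decode_ids`: character vector of tokens; `detokenize`: the
#'   concatenated string with special tokens removed (content up to the
#'   first end token).
#' @export
decode_ids <- function(ids, vocab) {
  stopifnot(all(ids >= 0), all(ids < length(vocab$tokens)))
  vocab$tokens[ids + 1L]
}

#' @rdname decode_ids
#' @export
detokenize <- function(ids, vocab) {
  toks <- decode_ids(ids, vocab)
  eos <- which(toks == EOS_TOKEN)
  if (length(eos) > 0) toks <- toks[seq_len(eos[1] - 1L)]
  toks <- toks[!(toks %in% c(PAD_TOKEN, BOS_TOKEN, EOS_TOKEN))]
  paste(toks, collapse = "")
}

#' Serialize / restore a vocabulary as JSON
#'
#' The JSON file holds the token list in id order.
#'
#' @param vocab vocabulary.
#' @param path file path.
#' @export
write_vocabulary <- function(vocab, path) {
  jsonlite::write_json(vocab$tokens, path)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  tokens <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(identical(tokens[1:4],
                      c(PAD_TOKEN, BOS_TOKEN, EOS_TOKEN, UNK_TOKEN)))
  ids <- seq_along(tokens) - 1L
  names(ids) <- tokens
  structure(list(tokens = tokens, token_to_id = ids,
                 pad_id = 0L, bos_id = 1L, eos_id = 2L, unk_id = 3L),
            class = "vocabulary")
}

#' Build source/target translation pairs from a corpus
#'
#' Source is a randomized SMILES (fresh renumbering by default, or the
#' stored variant), target the canonical SMILES; InChI source mode uses the
#' molecule's InChI string instead.
#'
#' @param corpus corpus data.frame.
#' @param src_vocab,tgt_vocab vocabularies for source and target strings.
#' @param source_mode `"randomized"`, `"stored"`, or `"inchi"`.
#' @return list of pairs, each `list(source, target, molecule_index)` with
#'   0-based id vectors.
#' @export
make_translation_pairs <- function(corpus, src_vocab, tgt_vocab = src_vocab,
                                   source_mode = c("randomized", "stored",
                                                   "inchi")) {
  source_mode <- match.arg(source_mode)
  src_str <- switch(source_mode,
    randomized = vapply(corpus$canonical_smiles, randomize_smiles,
                        character(1), USE.NAMES = FALSE),
    stored = corpus$randomized_smiles,
    inchi = {
      if (all(is.na(corpus$inchi)))
        stop("corpus has no InChI column values; regenerate with ",
             "include_inchi = TRUE")
      corpus$inchi
    })
  lapply(seq_len(nrow(corpus)), function(i) {
    list(source = tokenize(src_str[i], src_vocab, on_unknown = "unk"),
         target = tokenize(corpus$canonical_smiles[i], tgt_vocab),
         molecule_index = i)
  })
}
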