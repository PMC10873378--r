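# All interaction with the OpenBabel toolkit is funnelled through this file
# so the rest of the package sees a plain character/logical interface:
# canonical SMILES in, canonical SMILES / validity flags / bit vectors out.
# Canonicalization, validity and InChI use the ChemmineOB bindings;
# fingerprints use the obabel command-line tool in batched calls (the
# binding-level fingerprint decoder allocates per-bit argument vectors on
# the C++ side that are never reclaimed, which rules it out for series of
# thousands of molecules).

#' Canonicalize SMILES strings
#'
#' Converts each SMILES to the toolkit's canonical form. Invalid strings
#' (grammar errors or valence/octet violations) map to `NA`.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, `NA` where the input does
#'   not parse.
#' @export
canonicalize_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    out <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", s),
                    error = function(e) "")
    out <- trimws(out)
    if (!nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

#' Test SMILES validity
#'
#' A SMILES is valid when it is grammatically correct and encodes a molecule
#' the toolkit can sanitize (octet rule satisfied).
#'
#' @param smiles character vector.
#' @return logical vector.
#' @export
smiles_is_valid <- function(smiles) {
  !is.na(canonicalize_smiles(smiles))
}

#' Convert SMILES to InChI
#'
#' @param smiles character vector of valid SMILES.
#' @return character vector of InChI strings (`NA` on failure). Tetrahedral
#'   parity is not propagated by the 0D converter, so the /t layer is absent.
#' @export
smiles_to_inchi <- function(smiles) {
  vapply(smiles, function(s) {
    out <- tryCatch(ChemmineOB::convertFormat("SMI", "INCHI", s),
                    error = function(e) "")
    out <- trimws(out)
    if (!nzchar(out) || !startsWith(out, "InChI=")) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

# number of meaningful MACCS keys; the toolkit pads its bit string to 256
MACCS_NBITS <- 166L

#' Compute molecular fingerprints
#'
#' Computes MACCS key (166-bit) or ECFP (extended-connectivity, radius
#' `radius`, folded to `n_bits`) fingerprints for a vector of SMILES.
#'
#' @param smiles character vector of valid SMILES.
#' @param kind `"maccs"` or `"ecfp"`.
#' @param radius ECFP radius (1, 2 or 3); ignored for MACCS.
#' @param n_bits folded ECFP width, a power of two; ignored for MACCS.
#' @return integer 0/1 matrix, one row per molecule. Rows for invalid SMILES
#'   are all `NA`.
#' @export
fingerprint_smiles <- function(smiles, kind = c("maccs", "ecfp"),
                               radius = 2L, n_bits = 2048L) {
  kind <- match.arg(kind)
  if (kind == "ecfp") {
    stopifnot(radius %in% 1:5, n_bits >= 2, bitwAnd(n_bits, n_bits - 1L) == 0L)
    fp_name <- paste0("ECFP", 2L * as.integer(radius))
    width <- as.integer(n_bits)
  } else {
    fp_name <- "MACCS"
    width <- MACCS_NBITS
  }
  out <- matrix(NA_integer_, nrow = length(smiles), ncol = width)
  ok <- smiles_is_valid(smiles)
  if (any(ok)) {
    raw_width <- if (kind == "maccs") 256L else as.integer(n_bits)
    rows <- ob_fingerprints_cli(smiles[ok], fp_name, raw_width)
    if (kind == "maccs")
      rows <- rows[, seq_len(MACCS_NBITS), drop = FALSE]
    out[ok, ] <- rows
  }
  out
}

# Batched fingerprints through the obabel command-line tool (one process per
# call). The fpt hex output prints each fingerprint's 32-bit words from the
# highest word down; bits are LSB-first within a word.
ob_fingerprints_cli <- function(valid_smiles, fp_name, width) {
  stopifnot(width %% 32 == 0)
  smi <- tempfile(fileext = ".smi")
  on.exit(unlink(smi), add = TRUE)
  writeLines(valid_smiles, smi)
  args <- c(smi, "-ofpt", paste0("-xf", fp_name), "-xh")
  if (!startsWith(fp_name, "MACCS")) args <- c(args, paste0("-xN", width))
  txt <- suppressWarnings(system2("obabel", args, stdout = TRUE,
                                  stderr = FALSE))
  toks <- unlist(strsplit(txt[!startsWith(txt, ">")], "[[:space:]]+"))
  toks <- toks[grepl("^[0-9a-fA-F]{8}$", toks)]
  words_per_fp <- width %/% 32L
  n <- length(toks) %/% words_per_fp
  if (n != length(valid_smiles) || length(toks) %% words_per_fp != 0)
    stop("fingerprint computation lost molecules (", n, " of ",
         length(valid_smiles), ")")
  # expand one 8-digit hex word into 32 bits, LSB first
  word_bits <- function(hex) {
    v <- as.numeric(paste0("0x", hex))
    as.integer(v %/% 2^(0:31) %% 2)
  }
  rows <- matrix(0L, n, width)
  for (i in seq_len(n)) {
    words <- rev(toks[((i - 1L) * words_per_fp + 1L):(i * words_per_fp)])
    rows[i, ] <- unlist(lapply(words, word_bits))
  }
  rows
}

#' Tanimoto similarity of two bit vectors
#'
#' `|A intersect B| / |A union B|`; defined as 0 when both vectors are empty.
#'
#' @param fp_a,fp_b 0/1 integer vectors of equal length.
#' @return similarity in \[0, 1\].
#' @export
tanimoto <- function(fp_a, fp_b) {
  if (length(fp_a) != length(fp_b))
    stop("fingerprint widths differ: ", length(fp_a), " vs ", length(fp_b))
  a <- as.logical(fp_a); b <- as.logical(fp_b)
  un <- sum(a | b)
  if (un == 0L) return(0)
  sum(a & b) / un
}
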