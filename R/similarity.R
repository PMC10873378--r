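# Fingerprint-based comparison of predicted and target molecules: validity
# filtering, mean Tanimoto per fingerprint configuration, and per-bit MACCS
# agreement tables.

#' Fingerprint configuration
#'
#' @param kind `"maccs"` or `"ecfp"`.
#' @param radius ECFP radius (1-3 in routine use).
#' @param n_bits ECFP folded width (power of two; 2048 matches the baseline
#'   descriptor).
#' @return a `fingerprint_config` list with a display label.
#' @export
fingerprint_config <- function(kind = c("maccs", "ecfp"), radius = 2L,
                               n_bits = 2048L) {
  kind <- match.arg(kind)
  label <- if (kind == "maccs") "MACCS" else paste0("ECFP(R=", radius, ")")
  structure(list(kind = kind, radius = as.integer(radius),
                 n_bits = as.integer(n_bits), label = label),
            class = "fingerprint_config")
}

#' Mean fingerprint similarity between predictions and targets
#'
#' Pairs whose prediction is not a valid SMILES are excluded; the mean
#' Tanimoto over the surviving pairs is reported for every fingerprint
#' configuration. Callers tracking a multi-step analysis can pass
#' `keep_mask` to restrict scoring to the molecules that were valid at all
#' evaluated steps.
#'
#' @param pred_smiles,target_smiles aligned character vectors.
#' @param cfgs list of [fingerprint_config()]s.
#' @param keep_mask optional logical vector; pairs set to `FALSE` are
#'   excluded before validity filtering.
#' @return list of class `similarity_report`: `mean_tanimoto` (named by
#'   config label), `n_evaluated`, `n_invalid`, `valid` (logical per input
#'   pair).
#' @export
similarity_report <- function(pred_smiles, target_smiles,
                              cfgs = list(fingerprint_config("maccs")),
                              keep_mask = NULL) {
  stopifnot(length(pred_smiles) == length(target_smiles))
  n <- length(pred_smiles)
  if (is.null(keep_mask)) keep_mask <- rep(TRUE, n)
  valid <- rep(FALSE, n)
  valid[keep_mask] <- smiles_is_valid(pred_smiles[keep_mask])
  idx <- which(valid)
  if (length(idx) == 0L) stop("no prediction survived validity filtering")
  means <- vapply(cfgs, function(cfg) {
    fp_p <- fingerprint_smiles(pred_smiles[idx], cfg$kind, cfg$radius,
                               cfg$n_bits)
    fp_t <- fingerprint_smiles(target_smiles[idx], cfg$kind, cfg$radius,
                               cfg$n_bits)
    mean(vapply(seq_along(idx), function(k)
      tanimoto(fp_p[k, ], fp_t[k, ]), numeric(1)))
  }, numeric(1))
  names(means) <- vapply(cfgs, `[[`, character(1), "label")
  structure(list(mean_tanimoto = means,
                 n_evaluated = length(idx),
                 n_invalid = sum(keep_mask) - length(idx),
                 valid = valid),
            class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat("<similarity_report> n_evaluated=", x$n_evaluated,
      " n_invalid=", x$n_invalid, "\n", sep = "")
  print(round(x$mean_tanimoto, 4))
  invisible(x)
}

#' Per-bit MACCS agreement between predictions and targets
#'
#' For each MACCS key and each bit value v (1 and 0): among target molecules
#' whose key equals v, the fraction whose prediction is a valid SMILES and
#' whose predicted key also equals v. Keys never taking value v in any
#' target are absent from the table.
#'
#' @param pred_smiles,target_smiles aligned character vectors of SMILES.
#' @return data.frame: `bit_index` (1-based MACCS key), `bit_value` (1 or
#'   0), `fraction`, `n_targets`.
#' @export
maccs_bitwise_agreement <- function(pred_smiles, target_smiles) {
  stopifnot(length(pred_smiles) == length(target_smiles))
  fp_t <- fingerprint_smiles(target_smiles, "maccs")
  valid <- smiles_is_valid(pred_smiles)
  fp_p <- matrix(0L, length(pred_smiles), ncol(fp_t))
  if (any(valid))
    fp_p[valid, ] <- fingerprint_smiles(pred_smiles[valid], "maccs")
  rows <- list()
  for (v in c(1L, 0L)) {
    n_tgt <- colSums(fp_t == v)
    agree <- colSums(fp_t == v & valid & fp_p == v)
    defined <- which(n_tgt > 0)
    rows[[length(rows) + 1L]] <- data.frame(
      bit_index = defined, bit_value = v,
      fraction = agree[defined] / n_tgt[defined],
      n_targets = n_tgt[defined])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
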