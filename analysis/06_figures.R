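#!/usr/bin/env Rscript
# Figures from the tables the earlier scripts wrote: learning curves
# (perfect/partial/similarity vs step), per-token accuracy with chirality
# tokens highlighted, chirality error breakdown over training, and the
# intervention comparison.

source("analysis/00_setup.R")

snap <- utils::read.csv(file.path(RESULTS_DIR, "control_snapshots.csv"))
sim <- utils::read.csv(file.path(RESULTS_DIR, "control_similarity.csv"))
per_tok <- utils::read.csv(file.path(RESULTS_DIR, "control_per_token.csv"))
chir <- utils::read.csv(file.path(RESULTS_DIR, "control_chirality.csv"))

pdf(file.path(RESULTS_DIR, "figures.pdf"), width = 8, height = 6)

# learning curves
plot(snap$step, snap$perfect_accuracy, type = "l", col = "firebrick",
     lwd = 2, ylim = c(0, 1), xlab = "optimizer step", ylab = "accuracy",
     main = "Partial structure is learned before overall structure")
lines(snap$step, snap$partial_accuracy, col = "steelblue", lwd = 2)
maccs <- subset(sim, fingerprint == "MACCS")
lines(maccs$step, maccs$mean_tanimoto, col = "darkgreen", lwd = 2, lty = 2)
legend("bottomright", c("perfect accuracy", "partial accuracy",
                        "MACCS Tanimoto"),
       col = c("firebrick", "steelblue", "darkgreen"),
       lty = c(1, 1, 2), lwd = 2, bty = "n")

# per-token teacher-forced accuracy, chirality tokens highlighted
toks <- unique(per_tok$token)
plot(NULL, xlim = range(per_tok$step), ylim = c(0, 1),
     xlab = "optimizer step", ylab = "teacher-forced accuracy",
     main = "Chirality tokens trail every other token")
for (tk in setdiff(toks, c("@", "@@"))) {
  d <- subset(per_tok, token == tk)
  lines(d$step, d$accuracy, col = "grey70")
}
for (tk in intersect(c("@", "@@"), toks)) {
  d <- subset(per_tok, token == tk)
  lines(d$step, d$accuracy, col = if (tk == "@") "firebrick" else "purple",
        lwd = 2)
}
legend("bottomright", c("other tokens", "@", "@@"),
       col = c("grey70", "firebrick", "purple"), lwd = c(1, 2, 2), bty = "n")

# chirality error breakdown
plot(chir$step, chir$frac_correct, type = "l", lwd = 2, ylim = c(0, 1),
     xlab = "optimizer step", ylab = "fraction of test molecules",
     main = "Most near-miss translations are chirality-only errors")
lines(chir$step, chir$frac_chirality_only, col = "firebrick", lwd = 2)
lines(chir$step, chir$frac_other, col = "grey50", lwd = 2)
legend("right", c("correct", "chirality-only error", "other error"),
       col = c("black", "firebrick", "grey50"), lwd = 2, bty = "n")

# intervention comparison, if computed
f <- file.path(RESULTS_DIR, "intervention_steps.rds")
if (file.exists(f)) {
  iv <- readRDS(f)
  s05 <- lapply(iv, `[[`, "s05")
  boxplot(s05, ylab = "step-0.5",
          main = "Steps to perfect accuracy 0.5 by condition")
}
dev.off()
cat("written: results/figures.pdf\n")
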