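#!/usr/bin/env Rscript

# Kinase-substrate prediction by position weight matrices. For each kinase
# with enough known substrates, the 15-residue contexts of its sites are
# compared against all S/T/Y-centered windows of the proteome (log2-odds,
# pseudocount 0.5); the median training score is the prediction cutoff.

library(phosphoco)

seqs <- read_protein_fasta("results/synthetic/proteome.fasta")
ks <- read.delim("results/synthetic/kinase_substrates.tsv")
bg <- proteome_sty_windows(seqs)
message(nrow(bg), " background S/T/Y windows")

models <- list()
rows <- list()
for (k in unique(ks$kinase)) {
  sub <- ks[ks$kinase == k, ]
  fg <- extract_windows(seqs, sub)
  model <- calibrate_cutoff(build_pwm(k, fg, bg), fg)
  models[[k]] <- model
  set.seed(23L)
  bgs <- score_window(model, bg[sample(nrow(bg), 500L), ])
  rows[[k]] <- data.frame(
    kinase = k, n_substrates = model$n_substrates,
    cutoff = model$cutoff,
    train_sensitivity = mean(score_window(model, fg) > model$cutoff),
    background_fpr = mean(bgs > model$cutoff))
  # export the fitted 20 x 15 log2-odds matrix
  write.table(round(model$M, 4),
              file.path("results", paste0("pwm_", k, ".tsv")),
              sep = "\t", quote = FALSE)
}
tab <- do.call(rbind, rows)
write.table(tab, "results/kinase_models.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(tab, row.names = FALSE)

## multi-kinase predictions for the first 200 background windows
set.seed(29L)
idx <- sample(nrow(bg), 200L)
pred <- vapply(idx, function(i)
  paste(predict_kinases(bg[i, ], models), collapse = ";"), character(1))
write.table(data.frame(window = rownames(bg)[idx], predicted = pred),
            "results/kinase_predictions.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("%.1f%% of background windows draw at least one prediction",
                100 * mean(nzchar(pred))))
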