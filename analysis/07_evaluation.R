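#!/usr/bin/env Rscript

# Benchmarking. Using the planted pairs as the positive set and all other
# scanned pairs as negatives, the -log10 co-occurrence p-value is scored by
# ROC/AUC; the positive/negative proportions are compared across thresholds
# (fold enrichment with exact-test p-values); co-occurring pairs are compared
# with controls on sequence distance, with and without distance matching.

library(phosphoco)

res <- read.delim("results/cooccurrence_pairs.tsv")
planted <- read.delim("results/synthetic/planted_pairs.tsv")
key <- function(d) paste(d$site1, d$site2)
res$positive <- key(res) %in% key(planted)

auc <- roc_auc(res$positive, -log10(res$p_co))
message(sprintf("AUC separating planted from null pairs: %.3f", auc))

## fold enrichment of co-occurrence calls across thresholds
enrich <- do.call(rbind, lapply(10^seq(-6, -2), function(tau) {
  k1 <- sum(res$p_co[res$positive] < tau)
  k2 <- sum(res$p_co[!res$positive] < tau)
  cbind(threshold = tau,
        proportion_enrichment(k1, sum(res$positive),
                              k2, sum(!res$positive)))
}))
write.table(enrich, "results/positive_negative_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(enrich, row.names = FALSE)

## sequence distances: co-occurring vs control pairs, then distance-matched
pos_of <- function(id) as.integer(sub("^.*:", "", id))
res$seq_dist <- sequence_distance(pos_of(res$site1), pos_of(res$site2))
co <- res[res$label == "co-occurring", ]
ctrl <- res[res$label == "control", ]
p_dist <- permutation_median_test(co$seq_dist, ctrl$seq_dist, n_perm = 2e4,
                                  seed = 37L)
message(sprintf(
  "median sequence distance: co-occurring %.0f vs control %.0f (permutation p = %.2g)",
  median(co$seq_dist), median(ctrl$seq_dist), p_dist))

picked <- match_controls_by_distance(co$seq_dist, ctrl$seq_dist, seed = 41L)
matched <- ctrl[picked, ]
message(sprintf(
  "distance-matched controls: %d selected (shortfall %d); matched median %.0f",
  length(picked), attr(picked, "shortfall"), median(matched$seq_dist)))
write.table(matched[, c("site1", "site2", "p_co", "seq_dist")],
            "results/matched_controls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

summary <- data.frame(auc = auc,
                      co_median_dist = median(co$seq_dist),
                      ctrl_median_dist = median(ctrl$seq_dist),
                      matched_median_dist = median(matched$seq_dist))
write.table(summary, "results/evaluation_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
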