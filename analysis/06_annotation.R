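#!/usr/bin/env Rscript

# Functional annotation sharing. Pairs are classified homo-functional (same
# curated class, >= 1 shared term) or hetero-functional (different classes,
# no shared term); the information-content weighted sharing score upweights
# rare terms. Planted homo pairs should classify and score as designed.

library(phosphoco)

ann <- read_site_annotations("results/synthetic/annotations.tsv")
cls <- read_site_classes("results/synthetic/site_classes.tsv")
truth <- read.delim("results/synthetic/annotation_truth.tsv")

freqs <- term_frequency_table(ann)
terms_of <- split(ann$term, ann$site_id)
class_of <- setNames(cls$class, cls$site_id)

rows <- lapply(seq_len(nrow(truth)), function(i) {
  s1 <- truth$site1[i]; s2 <- truth$site2[i]
  data.frame(
    site1 = s1, site2 = s2, planted = truth$pair_class[i],
    classified = classify_functional_pair(class_of[[s1]], class_of[[s2]],
                                          terms_of[[s1]], terms_of[[s2]]),
    sharing = sharing_score(terms_of[[s1]], terms_of[[s2]], freqs))
})
tab <- do.call(rbind, rows)
write.table(tab, "results/annotation_pairs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

print(table(planted = tab$planted, classified = tab$classified))
homo <- tab$sharing[tab$planted == "homo"]
hetero <- tab$sharing[tab$planted == "hetero"]
p <- permutation_median_test(homo, hetero, n_perm = 2e4, seed = 31L)
message(sprintf(
  "median sharing score: homo %.2f vs hetero %.2f (permutation p = %.2g); %.1f%% vs %.1f%% share a term",
  median(homo), median(hetero), p, 100 * mean(homo > 0),
  100 * mean(hetero > 0)))
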