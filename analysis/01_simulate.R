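#!/usr/bin/env Rscript

# Generate the synthetic study inputs with known ground truth: a
# phosphosite-by-condition matrix with 500 planted co-occurring pairs
# (coupling 0.8, baseline rate 0.1, 88 conditions), a vertebrate-like
# species tree with coupled alignment columns, kinase-substrate data with
# planted motifs, and curated-style annotations with planted homo- and
# hetero-functional pairs. All downstream drivers read these files.

library(phosphoco)

out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20170501L

## phosphosite-by-condition matrix with planted modules
cfg <- synth_config(n_proteins = 1000L, mean_sites = 3, n_conditions = 88L,
                    base_rate = 0.1, n_modules = 500L, module_size = 2L,
                    rho = 0.8, seed = seed)
sim <- simulate_phospho_matrix(cfg)
write_phospho_matrix(sim$matrix, file.path(out, "phospho_matrix.tsv"))
write.table(sim$truth$planted_pairs, file.path(out, "planted_pairs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("matrix: ", nrow(sim$matrix$status), " sites x ",
        ncol(sim$matrix$status), " conditions; ",
        nrow(sim$truth$planted_pairs), " planted pairs")

## confounded variant (segment abundance gating, no planted signal)
cfg_conf <- synth_config(n_proteins = 300L, mean_sites = 6, base_rate = 0.35,
                         rho = 0, confounder = TRUE, detect_prob = 0.5,
                         segment_length = 60L, protein_length = 120L,
                         seed = seed + 1L)
sim_conf <- simulate_phospho_matrix(cfg_conf)
write_phospho_matrix(sim_conf$matrix, file.path(out, "phospho_confounded.tsv"))

## species tree and alignment columns (40 coupled pairs, 80 independent)
tree <- simulate_tree(16L, seed = seed + 2L)
ape::write.tree(tree, file.path(out, "species_tree.nwk"))
msa <- simulate_msa(tree, n_independent = 80L, n_coupled = 40L,
                    coupling = 0.9, rate = 2, seed = seed + 3L)
aln <- Biostrings::AAStringSet(apply(msa$alignment, 1, paste, collapse = ""))
Biostrings::writeXStringSet(aln, file.path(out, "alignment.fasta"))
write.table(data.frame(column = colnames(msa$alignment)),
            file.path(out, "alignment_columns.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(msa$coupled_pairs, file.path(out, "coupled_columns.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

## kinase-substrate data with planted motifs
kd <- simulate_kinase_data(n_kinases = 3L, substrates_per_kinase = 200L,
                           motif_positions = 5L, motif_strength = 0.9,
                           n_proteins = 100L, seed = seed + 4L)
Biostrings::writeXStringSet(Biostrings::AAStringSet(kd$sequences),
                            file.path(out, "proteome.fasta"))
write.table(kd$kinase_substrates, file.path(out, "kinase_substrates.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

## curated-style annotations with planted pair classes
sa <- simulate_annotations(rownames(sim$matrix$status), n_homo_pairs = 100L,
                           n_hetero_pairs = 100L, seed = seed + 5L)
write.table(sa$annotations, file.path(out, "annotations.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sa$classes, file.path(out, "site_classes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sa$truth, file.path(out, "annotation_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message("synthetic study written under ", out)
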