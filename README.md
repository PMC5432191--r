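# phosphoco

Co-occurrence analysis of protein phosphorylation across biological
conditions.

## The problem

Proteome-wide "bottom-up" mass-spectrometry surveys report, for each
phosphosite (a serine, threonine or tyrosine residue of a protein), only a
binary modification status per condition — phosphorylated or not detected.
Functional interplay between phosphosites (PTM cross-talk, shared pathways,
catalysis by the same kinase) leaves a statistical trace in these profiles:
functionally associated sites tend to be modified **under the same
conditions**. `phosphoco` implements that idea as a tested pipeline for
anyone working with condition-stratified phosphoproteomics data: it finds
site pairs whose binary profiles coincide more often than chance allows,
quantifies how much of that signal margin-preserving randomization can
explain, and characterizes the significant pairs by proximity, annotation
and kinase sharing, residue co-evolution, and conservation.

## The statistic

For sites X and Y observed over N conditions, the joint status is
cross-tabulated into a 2×2 contingency table n<sub>ij</sub> (i, j ∈ {0,1}),
and co-occurrence is tested with the one-sided Fisher's exact test: with the
table margins fixed, the p-value is the hypergeometric tail probability
P(X ≥ n<sub>11</sub>), computed exactly in log space. Pairs with p < 1E-5
are called co-occurring; pairs with p ≥ 0.5 serve as controls. Sites
modified in fewer than 3 conditions are removed first (they cannot reach
significance). The null expectation is calibrated by permutation:
modification states are reshuffled among each protein's (or each short
peptide segment's) potential sites, preserving every per-protein
per-condition count, and the co-occurring proportion of the observed data is
reported as a fold increase over the pooled randomized replicates.

Characterization statistics include:

- **Annotation/kinase sharing** (information-content weighted): for term
  sets A, B, the score is
  (1/N<sub>A</sub>N<sub>B</sub>) Σ 1{A<sub>i</sub>=B<sub>j</sub>}/F(A<sub>i</sub>),
  with F the corpus frequency of the term, so sharing a rare term counts
  more.
- **Residue co-evolution**: normalized mutual information
  nMI = MI(X;Y)/√(H(X)·H(Y)) between the orthologous alignment columns of
  two sites (gap treated as a 21st symbol).
- **Residue conservation score** RCS = MBL × RCR on a species tree: the
  patristic spread of species conserving the reference residue (relative to
  the tree diameter) times the conserved fraction within their MRCA clade.
- **Kinase prediction**: per-kinase 20×15 position weight matrices
  M<sub>k,j</sub> = log2(q<sub>k,j</sub>/b<sub>k,j</sub>) over the
  15-residue site context, scored additively, with the median training-set
  score as prediction cutoff.

A synthetic-data module generates every input the pipeline reads — binary
matrices with planted co-occurring pairs and a peptide-segment abundance
confounder, alignments with coupled columns evolved down a tree, planted
kinase motifs, and annotation tables with planted homo-/hetero-functional
pairs — so every stage is testable with known ground truth and no downloads.

## Worked example

```r
library(phosphoco)

cfg <- synth_config(n_proteins = 1000, mean_sites = 3, n_conditions = 88,
                    base_rate = 0.1, n_modules = 500, rho = 0.8,
                    seed = 20170501)
sim <- simulate_phospho_matrix(cfg)
hf  <- filter_high_frequency(sim$matrix, 3)      # sites modified >= 3 times
pairs <- enumerate_within_protein_pairs(hf)
res <- scan_pairs(hf, pairs, tau_co = 1e-5, tau_ctrl = 0.5)
table(res$label)
#> co-occurring      control      neither
#>          236         2630         1459
attr(res, "sweep")
#>   threshold count proportion
#> 1     1e-07    89 0.02057803
#> 2     1e-06   153 0.03537572
#> 3     1e-05   236 0.05456647
#> 4     1e-04   330 0.07630058
#> 5     1e-03   408 0.09433526
#> 6     1e-02   475 0.10982659
```

Of the 4,325 within-protein pairs, 236 are called co-occurring at p < 1E-5;
all 236 are planted pairs (precision 100%), recovering 47.2% of the 500
planted pairs — the remainder are planted pairs whose noisy profiles do not
reach the stringent threshold. The same run driven from the command line,
with the permutation, co-evolution, kinase and annotation stages and their
output tables under `results/`:

```sh
Rscript analysis/01_simulate.R      # synthetic study inputs + ground truth
Rscript analysis/02_cooccurrence.R  # exact-test scan, labels, threshold sweep
Rscript analysis/03_randomization.R # protein/segment-level fold increases
Rscript analysis/04_coevolution.R   # nMI and RCS per column (pair)
Rscript analysis/05_kinase.R        # PWM training, cutoffs, predictions
Rscript analysis/06_annotation.R    # homo/hetero classification, sharing
Rscript analysis/07_evaluation.R    # ROC/AUC, enrichment, distance matching
```

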