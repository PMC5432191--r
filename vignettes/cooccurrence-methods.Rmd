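---
title: "Co-occurrence analysis of phosphorylation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-occurrence analysis of phosphorylation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphoco)
```

## The observable and its model

The pipeline's central object is a binary phosphosite-by-condition matrix: a
row per S/T/Y residue of a protein, a column per biological condition (a
tissue, cell line or disease context surveyed by mass spectrometry), and an
entry of 1 where the site was detected phosphorylated. The key modeling
commitment, inherited from how bottom-up MS data are published, is that **0
means "not detected" and is treated as unmodified**. No imputation is
attempted; the cost of this choice is that anything that co-modulates
detectability of nearby sites — peptide abundance above all — masquerades as
biological co-occurrence. The permutation machinery and the confounder mode
of the generator exist to measure exactly that failure mode.

Sites modified in fewer than 3 conditions are removed before pair testing
(`filter_high_frequency()`, threshold inclusive): with a margin of 1 or 2
the hypergeometric tail cannot reach the significance levels of interest,
so low-frequency sites only dilute the scan.

## The exact test

For a site pair observed over `N` conditions, the joint profile reduces to a
2×2 table `(n11, n10, n01, n00)`. Co-occurrence is the upper tail of the
hypergeometric law with all margins fixed:

\[ p_{\mathrm{co}} = P(X \ge n_{11}), \qquad
   p_{\mathrm{neg}} = P(X \le n_{11}), \]

both including the observed point, computed in log space with `lgamma` and
accumulated from the small end of the support (`fisher_one_sided()`). There
is no continuity correction, and thresholds are applied to **raw** p-values
— the scan deliberately mirrors a raw-threshold design, with randomized
data providing the error context instead of an FDR: the pair hypotheses are
heavily dependent (they share sites), and the discrete test is conservative,
so a nominal FDR would be misleading on both ends. Tables with a degenerate
margin (a site on or off everywhere) return p = 1 with a flag rather than an
error, because permutation replicates legitimately produce them.

Numerical choices worth knowing:

* tables sharing margins are computed once and looked up, which is what
  makes scans of 10^5 pairs take seconds;
* the two margins are canonicalized (min, max) before computation, so
  transposing a table gives a bit-identical p-value;
* p-values remain exact down to the smallest normal doubles (~1E-300), far
  below anything an 88-condition table can produce (~1E-26).

Pairs are labeled by two thresholds: co-occurring iff `p_co < 1e-5`
(strict), control iff `p_co >= 0.5` (inclusive). The defaults are the
pipeline's calibrated operating point — stringent enough that, in the
randomization experiments, the randomized proportion at the threshold is an
order of magnitude below the observed one, while still recovering roughly
half of planted (or curated-positive) pairs.

## Permutation nulls

`shuffle_protein_level()` redraws, independently for every protein and
condition, which of the protein's potential sites carry the observed number
of modifications (a seeded partial Fisher–Yates shuffle). This preserves
exactly: matrix dimensions, the identity of potential sites, and every
per-protein per-condition count. `shuffle_segment_level()` does the same
within short peptide windows (`segment_windows()`: non-overlapping
`L`-residue tiles anchored at residue 1, terminal remainder dropped, kept
only with ≥ 5 potential sites — anchoring and remainder handling are our
choice, as is including the observed point in both tails; neither affects
any conclusion at more than the margin level). `fold_increase_report()`
pools randomized p-values across replicates (denominator `n_reps × n_pairs`)
rather than averaging per replicate; pooling matches how the randomized
proportions are meant to be read — as one long null scan.

Two properties of the shuffle deserve emphasis. First, it conditions on
per-protein counts, so any confounder that operates at the **whole-protein**
level is reproduced, not removed, by the shuffle — gated sites are
exchangeable given the counts. This is why the generator's confounder mode
gates **peptide segments** (below): segment-level gating is a confounder the
protein-level shuffle provably cannot absorb, which is the scenario the
segment-level permutation is designed to probe. Second, for proteins with
very few sites the shuffle is heavily constrained (a 2-site protein's
condition with one modification can only swap it between the two sites), so
fold increases at small `mean_sites` are conservative.

## The synthetic study

`synth_config()` defaults define the benchmark conditions, shaped like a
proteome-wide human survey at ~1/20 scale: 500 proteins, ~3 potential sites per protein
(1 + Poisson), 88 conditions, baseline per-site per-condition rate 0.1
(which puts the median site at ~9 modified conditions, comfortably above the
high-frequency cut), S/T/Y drawn at 58.7/23.6/17.8%. Planted co-occurrence:
a module's sites copy a shared per-condition latent Bernoulli state with
probability `rho` and draw independent noise otherwise, so `rho = 0` is the
exact null and `rho = 1` (noise-free) gives identical vectors. The planted
benchmark (1000 proteins, 500 modules of size 2, `rho = 0.8`) yields recall
0.472 and precision 1.0 at p < 1E-5 under seed 20170501, frozen in
`inst/extdata/planted_recovery_expected.tsv` and regenerated bit-exactly by
the test suite.

Confounder mode multiplies all sites of a peptide segment (60-residue tiles
by default) by a per-segment per-condition detectability gate drawn from a
two-point distribution (`detect_prob`) — the simplest mechanism matching the
verbal model of abundance-gated detection. With gating on and `rho = 0`, the
observed co-occurring proportion exceeds the protein-level shuffle
expectation several-fold; with gating off the two agree within Monte-Carlo
error. That contrast — an artifact the shuffle cannot explain away — is the
pipeline's cautionary tale about interpreting co-occurrence causally.

What the generator does **not** emulate: heterogeneous per-condition
coverage (all conditions are exchangeable), correlated conditions (replicate
cell lines), realistic protein length/site-density joint distributions, or
missingness that depends on peptide chemistry. Passing tests therefore
certify the statistical machinery, not robustness to every property of real
MS compendia.

## Co-evolution and conservation

Orthologous alignment columns are compared with normalized mutual
information over the shared species, with the gap as a 21st symbol and
natural logarithms throughout. The normalization is the geometric mean,
`nMI = MI / sqrt(H(X) H(Y))` — the single most consequential interpretation
in this module, since the product of entropies is also defensible
typographically; `normalization = "product"` is available as a switch, and
the geometric mean is the default because it is the form with the \[0, 1\]
range that the downstream comparisons assume. Columns qualify only with at
least 3 species differing from the reference residue ("non-conserved" read
as *different from the reference*, not as a distinct-symbol count), and
zero-entropy columns are flagged ineligible rather than scored.

The residue conservation score multiplies two ratios on a rooted species
tree with branch lengths: MBL, the maximum patristic distance within the set
C of species conserving the reference residue, divided by the tree diameter
(the distance between the two most distant species — we read the denominator
as the diameter of the whole tree, not of C); and RCR, the fraction of
leaves under MRCA(C) that belong to C. Both are in \[0, 1\], as is their
product. A residue conserved only in the reference scores 0; a fully
conserved column scores 1 on any tree, including the degenerate zero-length
tree. RCS is invariant to leaf relabeling and to uniform branch-length
scaling (both are tested).

The alignment simulator evolves independent columns by root-uniform draws
and per-branch substitution with probability `1 − exp(−rate·t)`. Coupled
pairs are generated by slaving the second column's leaf symbols to a fixed
random bijection of the first column's, with probability `coupling` per
leaf, rather than by literal joint substitution events along branches: the
construction is simpler, statistically equivalent for the quantities tested,
and makes the limits exact — coupling 1 is a deterministic relabeling
(nMI = 1 whenever entropy is positive), coupling 0 is independence. Note
that small species samples inflate nMI for *all* column pairs (the familiar
small-sample MI bias); comparisons should always be coupled-vs-independent
at the same species count, never against an absolute scale.

## Annotation sharing and functional pair classes

Term frequencies are site-based: `F(term)` = fraction of annotated sites
carrying the term, within the loaded corpus (the denominator is our choice;
the alternative — annotation-row-based — differs only when sites repeat
terms). Matching is exact string equality after case/whitespace
normalization; there is deliberately no ontology expansion, since the terms
are curated flat vocabularies. The sharing score averages reciprocal
frequencies of matches over all `N_A × N_B` term pairs: symmetric, zero iff
disjoint, strictly decreasing as unmatched terms are added, strictly
increasing as shared terms get rarer.

Homo-functional pairs (same curated class — activate/inhibit/dual — and ≥ 1
shared term) proxy positives; hetero-functional pairs (different classes,
no shared term) proxy negatives. Class equality is strict: a "dual" site
never forms a homo pair with an "activate" site, the conservative reading
where the definition is silent. The union of process and function terms is
used for the sharing test by default.

## Kinase motif models

Per kinase with ≥ 50 site-specific substrates, a 20×15 log2-odds matrix over
the 15-residue context centered on the acceptor. The background is
positional — frequencies of each amino acid at each window position over
*all* S/T/Y-centered windows of the proteome — so the center column's
background mass is concentrated on S/T/Y and the center contributes the
kinase's acceptor preference, not a spurious enrichment. A pseudocount of
0.5 per amino acid per position on both sides keeps every entry finite.
Windows extending past a terminus are padded, and the pad scores 0 (neutral)
so terminal sites remain scorable; unknown residues (X, U) also score 0 and
are logged rather than fatal.

The prediction cutoff is the median score of the kinase's own training
substrates; prediction is strict (`score > cutoff`), so ties are
non-predictions and one site can be claimed by several kinases or none. By
construction in-sample sensitivity is 0.5. Out of sample it is
noticeably lower: the fitted log-odds
absorb training-set sampling noise, which shifts the training score
distribution — and hence the median cutoff — upward relative to fresh
substrates. This bias is inherent to calibrating the cutoff on the training
substrates themselves (which is how the procedure is defined); specificity
against background windows remains high (the acceptance report computes it
at the benchmark scale), and held-out substrates remain strongly enriched
above the cutoff relative to background. Consumers should
read the cutoff as "scores like the top half of known substrates", not as a
50%-sensitivity guarantee on new sites.

## Evaluation utilities

* `roc_auc()`: the rank (Mann–Whitney) estimator with midrank ties,
  equivalent to sweeping the p-value threshold; score = −log10(p).
* `proportion_enrichment()`: fold ratio of two proportions plus the
  one-sided exact-test p from the same hypergeometric core as the scan.
* `permutation_median_test()`: two-sided label permutation of
  |median(A) − median(B)| (the statistic is our choice where a "permutation
  test" is underdetermined). When `choose(nA+nB, nA) ≤ n_perm` all splits
  are enumerated and the p-value is exact; otherwise Monte Carlo with
  add-one smoothing, `(1 + extreme)/(1 + n_perm)`, which cannot return 0.
* `match_controls_by_distance()`: control pairs subsampled without
  replacement inside log2-spaced sequence-distance bins to reproduce the
  co-occurring set's histogram; bins are log2-spaced because sequence
  distances are heavy-tailed and the comparisons of interest (sharing,
  co-evolution) vary roughly with log distance. Shortfalls (bins with too
  few controls) are reported, never silently filled from other bins.
* `interface_colocalization()`: among pairs mappable to an annotated
  interacting protein pair, the fraction with both sites inside interface
  intervals.
* `read_ca_coordinates()`: a thin Cα reader for PDB-format files (first
  model, first chain per residue); any UniProt↔PDB numbering offset is the
  caller's responsibility, by design — the package does not attempt
  structure mapping.

## Problem sizes and determinism

The test suite and the acceptance script run the full pipeline at the scales
the package's own benchmarks use: the planted benchmark at 1000 proteins ×
88 conditions (~4,300 pairs), the null calibration at ~125,000 pairs, 10–20
shuffle replicates, 16-species alignments, 3 kinases × 200 substrates.
These sizes were chosen so that every stage's behavior (type-I control,
recovery, confounder contrast) is measurable with comfortable Monte-Carlo
margins while a complete run stays in the minutes range on one core. Every
stochastic step takes an explicit seed, restores the caller's RNG state on
exit, and is bit-reproducible given the seed; derived seeds stay below 2^31.

## Known limitations

* Binary status conflates "unmodified" with "undetected"; the marginal
  association the test measures is not conditional association (mutually
  exclusive sites on one isoform can still co-occur across a pool of
  isoforms), which is why negative-correlation scans come up nearly empty
  and `conditional_exclusivity()` is provided as a complementary view.
* Raw p-value thresholds are calibrated against randomization, not FDR;
  counts at different thresholds are not independent discoveries.
* The ortholog mapper consumes precomputed pairwise alignments; it does not
  align, and it enforces 1-to-1 maps with confidence > 0.9, dropping
  everything else.
* The co-evolution module assumes the provided rooted tree; MBL is
  root-independent but MRCA (hence RCR) is not.
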