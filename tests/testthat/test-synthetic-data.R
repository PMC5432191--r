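test_that("generation is bit-reproducible under a fixed seed", {
  cfg <- synth_config(n_proteins = 40, n_modules = 10, seed = 99)
  s1 <- simulate_phospho_matrix(cfg)
  s2 <- simulate_phospho_matrix(cfg)
  expect_identical(s1$matrix$status, s2$matrix$status)
  expect_identical(s1$truth$planted_pairs, s2$truth$planted_pairs)

  tree <- simulate_tree(10, seed = 7)
  expect_identical(ape::write.tree(tree),
                   ape::write.tree(simulate_tree(10, seed = 7)))
  m1 <- simulate_msa(tree, 5, 3, seed = 8)
  m2 <- simulate_msa(tree, 5, 3, seed = 8)
  expect_identical(m1$alignment, m2$alignment)
})

test_that("a seed is mandatory and probabilities are validated", {
  expect_error(synth_config(), "seed")
  expect_error(synth_config(rho = 1.5, seed = 1))
  expect_error(synth_config(base_rate = 0, seed = 1))
})

test_that("every emitted site is observed at least once", {
  cfg <- synth_config(n_proteins = 100, base_rate = 0.02, n_conditions = 30,
                      seed = 12)
  sim <- simulate_phospho_matrix(cfg)
  expect_true(all(rowSums(sim$matrix$status) >= 1))
})

test_that("full coupling with no noise yields identical module vectors", {
  cfg <- synth_config(n_proteins = 30, n_modules = 10, module_size = 3,
                      rho = 1, module_rate = 0.3, seed = 21)
  sim <- simulate_phospho_matrix(cfg)
  for (m in seq_len(10)) {
    pp <- sim$truth$planted_pairs[sim$truth$planted_pairs$module == m, ]
    ids <- unique(c(pp$site1, pp$site2))
    block <- sim$matrix$status[ids, , drop = FALSE]
    expect_true(all(apply(block, 2, function(col) length(unique(col)) == 1)))
  }
})

test_that("null generator respects the exact-test type-I bound at small scale", {
  cfg <- synth_config(n_proteins = 200, mean_sites = 4, n_conditions = 88,
                      base_rate = 0.1, n_modules = 0, seed = 31)
  sim <- simulate_phospho_matrix(cfg)
  hf <- filter_high_frequency(sim$matrix)
  pr <- enumerate_within_protein_pairs(hf)
  res <- scan_pairs(hf, pr, negative_tail = FALSE)
  frac <- mean(res$p_co < 0.01)
  expect_lte(frac, 0.01 + 3 * sqrt(0.01 / nrow(res)))
})

test_that("simulated alignments hit the coupling limits", {
  tree <- simulate_tree(12, seed = 61)
  # coupling 1: every coupled pair has nMI 1 whenever entropy is positive
  msa <- simulate_msa(tree, n_independent = 2, n_coupled = 8, coupling = 1,
                      rate = 2, seed = 62)
  for (i in seq_len(8)) {
    res <- nmi(alignment_column(msa$alignment[, paste0("cpl_", i, "A")]),
               alignment_column(msa$alignment[, paste0("cpl_", i, "B")]))
    if (res$eligible) expect_equal(res$nmi, 1, tolerance = 1e-12)
  }
  # zero-length branches: no substitutions, every column fully conserved,
  # and RCS = 1 everywhere
  flat <- tree
  flat$edge.length <- rep(0, length(tree$edge.length))
  msa0 <- simulate_msa(flat, n_independent = 5, n_coupled = 0, seed = 63)
  expect_true(all(apply(msa0$alignment, 2, function(x)
    length(unique(x)) == 1)))
  col <- alignment_column(msa0$alignment[, 1])
  expect_equal(rcs(col, flat)$rcs, 1)
})

test_that("uncoupled column pairs are indistinguishable from independent ones", {
  tree <- simulate_tree(14, seed = 71)
  msa <- simulate_msa(tree, n_independent = 100, n_coupled = 50,
                      coupling = 0, rate = 2, seed = 72)
  al <- msa$alignment
  get_nmi <- function(a, b) {
    nmi(alignment_column(al[, a]), alignment_column(al[, b]))$nmi
  }
  cpl <- vapply(seq_len(50), function(i)
    get_nmi(paste0("cpl_", i, "A"), paste0("cpl_", i, "B")), numeric(1))
  ind <- vapply(seq_len(50), function(i)
    get_nmi(paste0("ind_", 2 * i - 1), paste0("ind_", 2 * i)), numeric(1))
  cpl <- cpl[!is.na(cpl)]; ind <- ind[!is.na(ind)]
  p <- wilcox.test(cpl, ind, exact = FALSE)$p.value
  expect_gt(p, 0.05)
})

test_that("kinase data respects the substrate minimum and motif limits", {
  kd <- simulate_kinase_data(n_kinases = 2, substrates_per_kinase = 30,
                             seed = 81)
  expect_identical(nrow(kd$kinase_substrates), 60L)
  bg <- proteome_sty_windows(kd$sequences)
  sub <- kd$kinase_substrates[kd$kinase_substrates$kinase == "KIN01", ]
  fg <- extract_windows(kd$sequences, sub)
  # below the training minimum: model refused
  expect_error(build_pwm("KIN01", fg, bg), "50 required")
  # the planted center residue is recovered at every substrate
  centers <- fg[, 8]
  expect_identical(unique(centers), kd$motifs$KIN01$center)

  # motif at background strength carries no information: held-out substrates
  # of an uninformative kinase score like background
  kd0 <- simulate_kinase_data(n_kinases = 1, substrates_per_kinase = 120,
                              motif_strength = 0.05, seed = 82)
  bg0 <- proteome_sty_windows(kd0$sequences)
  sub0 <- kd0$kinase_substrates
  fg0 <- extract_windows(kd0$sequences, sub0[1:60, ])
  m0 <- calibrate_cutoff(build_pwm("KIN01", fg0, bg0), fg0)
  held <- extract_windows(kd0$sequences, sub0[61:120, ])
  sens <- mean(score_window(m0, held) > m0$cutoff)
  withr::local_seed(83)
  fpr <- mean(score_window(m0, bg0[sample(nrow(bg0), 300), ]) > m0$cutoff)
  # substrates of an uninformative kinase behave like background windows
  expect_lt(abs(sens - fpr), 0.15)
})

test_that("planted annotation pairs classify as designed and share more", {
  ids <- sprintf("P%03d:%d", 1:120, 7)
  sa <- simulate_annotations(ids, n_homo_pairs = 15, n_hetero_pairs = 15,
                             seed = 91)
  fr <- term_frequency_table(sa$annotations)
  cls <- setNames(sa$classes$class, sa$classes$site_id)
  terms_of <- function(id) sa$annotations$term[sa$annotations$site_id == id]
  got <- vapply(seq_len(nrow(sa$truth)), function(i) {
    with(sa$truth[i, ],
         classify_functional_pair(cls[site1], cls[site2],
                                  terms_of(site1), terms_of(site2)))
  }, character(1))
  expect_identical(got, ifelse(sa$truth$pair_class == "homo", "homo", "hetero"))

  homo_scores <- vapply(which(sa$truth$pair_class == "homo"), function(i)
    sharing_score(terms_of(sa$truth$site1[i]), terms_of(sa$truth$site2[i]),
                  fr), numeric(1))
  withr::local_seed(92)
  rand_scores <- vapply(1:30, function(i) {
    pick <- sample(ids[61:120], 2)
    sharing_score(terms_of(pick[1]), terms_of(pick[2]), fr)
  }, numeric(1))
  expect_gt(median(homo_scores), median(rand_scores))
  expect_lt(wilcox.test(homo_scores, rand_scores, exact = FALSE,
                        alternative = "greater")$p.value, 0.01)
})

test_that("confounder gating induces co-occurrence among same-segment sites", {
  cfg <- synth_config(n_proteins = 150, mean_sites = 6, base_rate = 0.35,
                      rho = 0, confounder = TRUE, detect_prob = 0.5,
                      segment_length = 60, protein_length = 120, seed = 111)
  sim <- simulate_phospho_matrix(cfg)
  hf <- filter_high_frequency(sim$matrix)
  pr <- enumerate_within_protein_pairs(hf)
  res <- scan_pairs(hf, pr, negative_tail = FALSE)
  # well above the nominal level, unlike the null case
  expect_gt(mean(res$p_co < 1e-3), 0.01)
})
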