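test_that("window extraction pads beyond the termini and centers the site", {
  seq20 <- "MKSTLYRAPSGDKQWERTYV"
  w <- extract_window(seq20, 10L)        # an S with 7 residues on each side
  expect_identical(length(unclass(w)), 15L)
  expect_false(any(w == "-"))
  expect_identical(w[8], "S")
  expect_true(attr(w, "center_ok"))

  w3 <- suppressWarnings(extract_window(seq20, 3L))
  expect_identical(sum(w3 == "-"), 5L)   # 5 leading pads
  expect_identical(w3[1:5], rep("-", 5))

  wend <- suppressWarnings(extract_window(seq20, 20L))
  expect_identical(sum(wend == "-"), 7L) # 7 trailing pads
  expect_identical(wend[9:15], rep("-", 7))

  expect_warning(extract_window(seq20, 1L), "not S/T/Y")  # center M
  expect_error(extract_window(seq20, 21L), "outside")
})

test_that("identical foreground and background give an all-zero matrix", {
  withr::local_seed(23)
  win <- matrix(sample(AA_ALPHABET, 60 * 15, replace = TRUE), 60, 15)
  win[, 8] <- "S"
  m <- build_pwm("K", win, win, min_substrates = 50L)
  expect_true(all(abs(m$M) < 1e-12))
  expect_identical(score_window(m, win[1, ]), 0)
})

test_that("log2-odds equal 1 when a residue doubles its background frequency", {
  # large counts make the 0.5 pseudocount negligible: foreground frequency
  # 0.5 against background 0.05 gives log2-odds log2(10); a residue at twice
  # its background frequency scores log2(2) = 1
  fg <- matrix("A", 4000, 3)
  fg[seq(1, 4000, 2), 1] <- "C"          # position 1: half A, half C
  bg_counts <- matrix(1000, 20, 3, dimnames = list(AA_ALPHABET, NULL))
  m <- build_pwm("K", fg, bg_counts, min_substrates = 50L)
  expect_equal(unname(m$M["C", 1]), log2(0.5 / 0.05), tolerance = 1e-2)
  fg2 <- matrix("A", 4000, 3)
  fg2[1:400, 2] <- "C"                   # position 2: C at 0.10 vs 0.05
  m2 <- build_pwm("K", fg2, bg_counts, min_substrates = 50L)
  expect_equal(unname(m2$M["C", 2]), 1, tolerance = 1e-2)
})

test_that("a 3-window toy foreground matches the hand-computed matrix", {
  # width-3 windows, alphabet counts done by hand, pseudocount 0.5
  fg <- rbind(c("A", "S", "C"),
              c("A", "S", "D"),
              c("C", "S", "D"))
  bg <- rbind(c("A", "S", "A"),
              c("C", "S", "C"),
              c("D", "S", "D"),
              c("A", "T", "C"))
  m <- build_pwm("K", fg, bg, pseudocount = 0.5, min_substrates = 1L)
  denom_fg <- 3 + 20 * 0.5
  denom_bg <- 4 + 20 * 0.5
  expect_equal(unname(m$M["A", 1]),
               log2(((2 + 0.5) / denom_fg) / ((2 + 0.5) / denom_bg)),
               tolerance = 1e-12)
  expect_equal(unname(m$M["D", 3]),
               log2(((2 + 0.5) / denom_fg) / ((1 + 0.5) / denom_bg)),
               tolerance = 1e-12)
  expect_equal(unname(m$M["S", 2]),
               log2(((3 + 0.5) / denom_fg) / ((3 + 0.5) / denom_bg)),
               tolerance = 1e-12)
  expect_true(all(is.finite(m$M)))
  expect_error(build_pwm("K", fg, bg, min_substrates = 50L), "50 required")
})

test_that("window scores equal the elementwise matrix lookup", {
  withr::local_seed(29)
  m <- build_pwm("K",
                 matrix(sample(AA_ALPHABET, 60 * 15, TRUE), 60, 15),
                 matrix(sample(AA_ALPHABET, 200 * 15, TRUE), 200, 15),
                 min_substrates = 50L)
  for (i in 1:100) {
    w <- sample(c(AA_ALPHABET, "-", "X"), 15, replace = TRUE)
    oracle <- 0
    for (j in 1:15) if (w[j] %in% AA_ALPHABET) oracle <- oracle + m$M[w[j], j]
    expect_equal(score_window(m, w), unname(oracle), tolerance = 1e-12)
  }
  # additivity: permuting window positions together with matrix columns
  perm <- sample(15)
  m_perm <- m
  m_perm$M <- m$M[, perm]
  w <- sample(AA_ALPHABET, 15, replace = TRUE)
  expect_equal(score_window(m_perm, w[perm]), score_window(m, w),
               tolerance = 1e-12)
})

test_that("cutoff calibration takes the median with the even-count convention", {
  m <- structure(list(kinase = "K", M = matrix(0, 20, 1,
                                               dimnames = list(AA_ALPHABET,
                                                               NULL)),
                      n_substrates = 3L, cutoff = NA_real_),
                 class = "kinase_pwm")
  # scores of single-column windows equal the matrix entry
  m$M[, 1] <- seq(0.1, 2, length.out = 20)
  odd <- calibrate_cutoff(m, matrix(c("A", "C", "D"), ncol = 1))
  expect_equal(odd$cutoff, unname(m$M["C", 1]))
  even <- calibrate_cutoff(m, matrix(c("A", "C", "D", "E"), ncol = 1))
  expect_equal(even$cutoff, unname(m$M["C", 1] + m$M["D", 1]) / 2)
})

test_that("multi-kinase prediction uses a strict cutoff per kinase", {
  make <- function(name, cutoff) {
    m <- structure(list(kinase = name,
                        M = matrix(0, 20, 15,
                                   dimnames = list(AA_ALPHABET, NULL)),
                        n_substrates = 50L, cutoff = cutoff),
                   class = "kinase_pwm")
    m$M["S", 8] <- 2
    m
  }
  w <- rep("A", 15); w[8] <- "S"         # scores 2 against every model
  models <- list(make("K1", 1), make("K2", 1.5), make("K3", 2))
  expect_setequal(predict_kinases(w, models), c("K1", "K2"))  # tie at 2 excluded
  expect_identical(predict_kinases(w, list()), character(0))
})

test_that("planted motifs separate substrates from background windows", {
  kd <- simulate_kinase_data(n_kinases = 2, substrates_per_kinase = 400,
                             motif_positions = 5, motif_strength = 0.9,
                             n_proteins = 150, seed = 314)
  bg <- proteome_sty_windows(kd$sequences)
  ks <- kd$kinase_substrates
  withr::local_seed(315)
  bg_sample <- bg[sample(nrow(bg), 300), ]
  for (k in unique(ks$kinase)) {
    sub <- ks[ks$kinase == k, ]
    train <- sub[1:200, ]; held <- sub[201:400, ]
    fg <- extract_windows(kd$sequences, train)
    m <- calibrate_cutoff(build_pwm(k, fg, bg), fg)
    # in-sample sensitivity is ~0.5 exactly, by the median construction
    expect_equal(mean(score_window(m, fg) > m$cutoff), 0.5, tolerance = 0.02)
    # out of sample the cutoff is biased upward (the log-odds fit the
    # training windows' sampling noise), so sensitivity drops below 0.5
    # but substrates remain strongly enriched over background windows
    sens <- mean(score_window(m, extract_windows(kd$sequences, held)) >
                   m$cutoff)
    fpr <- mean(score_window(m, bg_sample) > m$cutoff)
    expect_gt(sens, 0.1)
    expect_gt(sens, 5 * fpr)
    expect_gt(1 - fpr, 0.9)              # specificity
  }
})
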