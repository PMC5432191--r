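# Small in-code fixtures shared across test files.

# A tiny deterministic matrix: 2 proteins, 5 sites, 6 conditions.
toy_matrix <- function() {
  sites <- data.frame(
    protein = c("P1", "P1", "P1", "P2", "P2"),
    position = c(10L, 25L, 40L, 5L, 12L),
    residue = c("S", "T", "S", "Y", "S"))
  status <- rbind(
    c(1, 1, 0, 1, 0, 0),
    c(1, 1, 0, 1, 0, 0),
    c(0, 0, 1, 0, 0, 1),
    c(1, 0, 0, 0, 1, 1),
    c(0, 1, 0, 0, 0, 1))
  phospho_matrix(sites, status, conditions = paste0("c", 1:6))
}

# Random binary matrix with independent sites (pure null).
random_matrix <- function(n_proteins, sites_per_protein, n_conditions,
                          rate, seed) {
  withr::local_seed(seed)
  n <- n_proteins * sites_per_protein
  sites <- data.frame(
    protein = rep(sprintf("P%04d", seq_len(n_proteins)),
                  each = sites_per_protein),
    position = rep(seq(10L, by = 10L, length.out = sites_per_protein),
                   n_proteins),
    residue = "S")
  status <- matrix(rbinom(n * n_conditions, 1L, rate), n, n_conditions)
  # ensure every site is observed at least once
  zero <- rowSums(status) == 0L
  status[cbind(which(zero), sample.int(n_conditions, sum(zero),
                                       replace = TRUE))] <- 1L
  phospho_matrix(sites, status)
}

# Exhaustive hypergeometric oracle: enumerate all tables with the observed
# margins and sum the tail probabilities with exact choose() arithmetic.
oracle_fisher <- function(n11, n10, n01, n00, tail = "co-occurrence") {
  N <- n11 + n10 + n01 + n00
  r <- n11 + n10
  cc <- n11 + n01
  k <- max(0L, r + cc - N):min(r, cc)
  prob <- choose(cc, k) * choose(N - cc, r - k) / choose(N, r)
  if (tail == "co-occurrence") sum(prob[k >= n11]) else sum(prob[k <= n11])
}

write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
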