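#' Configuration for the synthetic phosphoproteome generator
#'
#' Defaults mirror the shape of a proteome-wide human survey at roughly 1/20 scale:
#' ~500 proteins with a mean of ~3 potential S/T/Y sites each, observed under
#' 88 conditions, with a per-site per-condition baseline modification rate of
#' 0.1. Planted modules are groups of sites sharing a latent per-condition
#' activation: with probability `rho` a module site copies the latent state,
#' otherwise it draws independent Bernoulli noise at the baseline rate, so
#' `rho = 0` is the pure null and `rho = 1` with no noise gives identical
#' status vectors.
#'
#' Confounder mode emulates peptide-segment abundance gating: each protein is
#' tiled into segments of `segment_length` residues and each segment is
#' detectable in a condition with probability `detect_prob`; when a segment is
#' undetectable all its sites read 0 regardless of their true state. This
#' induces artifactual co-occurrence among same-segment sites even at
#' `rho = 0`, the failure mode the permutation analysis is designed to expose.
#'
#' @param n_proteins number of proteins.
#' @param mean_sites mean potential sites per protein (1 + Poisson).
#' @param n_conditions number of conditions; default 88.
#' @param base_rate per-site per-condition modification probability.
#' @param n_modules number of planted co-occurring site groups.
#' @param module_size sites per module; default 2 (one planted pair each).
#' @param rho module coupling probability in \[0, 1\].
#' @param module_rate latent activation rate of a module per condition;
#'   defaults to `base_rate`.
#' @param confounder enable segment abundance gating?
#' @param detect_prob per-segment per-condition detectability.
#' @param segment_length confounder segment length in residues.
#' @param protein_length residue length of every simulated protein.
#' @param seed mandatory integer seed.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_proteins = 500L, mean_sites = 3, n_conditions = 88L,
                         base_rate = 0.1, n_modules = 0L, module_size = 2L,
                         rho = 0.8, module_rate = base_rate,
                         confounder = FALSE, detect_prob = 0.5,
                         segment_length = 60L, protein_length = 360L,
                         seed = NULL) {
  if (is.null(seed)) stop("a seed is mandatory for synthetic generation")
  stopifnot(rho >= 0, rho <= 1, base_rate > 0, base_rate <= 1,
            detect_prob > 0, detect_prob <= 1, module_size >= 2L,
            n_modules <= n_proteins)
  structure(list(n_proteins = n_proteins, mean_sites = mean_sites,
                 n_conditions = n_conditions, base_rate = base_rate,
                 n_modules = n_modules, module_size = module_size,
                 rho = rho, module_rate = module_rate,
                 confounder = confounder, detect_prob = detect_prob,
                 segment_length = segment_length,
                 protein_length = protein_length, seed = seed),
            class = "synth_config")
}

#' Simulate a phosphosite-by-condition matrix with known ground truth
#'
#' See [synth_config()] for the generating model. Module sites are placed in
#' distinct proteins (one module per protein, sites in the same confounder
#' segment when gating is on, so planted signal and gating act on the same
#' pairs they would in real data). Sites never observed in any condition are
#' redrawn under the same law (up to 100 attempts) so that every emitted site
#' is a potential phosphosite.
#'
#' @param config a [synth_config()].
#' @return list with `matrix` (a [phospho_matrix()]), `truth` (list with
#'   `planted_pairs` data.frame of all within-module site pairs and
#'   `module_sites`), and `config`.
#' @export
simulate_phospho_matrix <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  local_seed(config$seed)
  n_prot <- config$n_proteins
  proteins <- sprintf("P%04d", seq_len(n_prot))
  n_sites <- 1L + rpois(n_prot, max(config$mean_sites - 1, 0))
  if (config$n_modules > 0L) {
    module_protein <- seq_len(config$n_modules)   # first proteins host modules
    n_sites[module_protein] <- pmax(n_sites[module_protein],
                                    config$module_size)
  }
  sites <- do.call(rbind, lapply(seq_len(n_prot), function(i) {
    k <- n_sites[i]
    pos <- sort(sample.int(config$protein_length, k))
    data.frame(protein = proteins[i], position = pos,
               residue = sample(c("S", "T", "Y"), k, replace = TRUE,
                                prob = c(0.587, 0.236, 0.178)),
               stringsAsFactors = FALSE)
  }))
  n_total <- nrow(sites)
  C <- config$n_conditions

  is_module_site <- logical(n_total)
  module_of <- integer(n_total)
  if (config$n_modules > 0L) {
    for (m in seq_len(config$n_modules)) {
      idx <- which(sites$protein == proteins[m])
      if (config$confounder) {
        # keep module sites within one gating segment
        seg <- (sites$position[idx] - 1L) %/% config$segment_length
        seg_counts <- table(seg)
        target <- as.integer(names(seg_counts)[which.max(seg_counts)])
        in_seg <- idx[seg == target]
        if (length(in_seg) < config$module_size) {
          lo <- target * config$segment_length + 1L
          hi <- min((target + 1L) * config$segment_length,
                    config$protein_length)
          free <- setdiff(lo:hi, sites$position[idx])
          need <- config$module_size - length(in_seg)
          newpos <- sample(free, need)
          sites$position[setdiff(idx, in_seg)[seq_len(need)]] <- newpos
          idx <- which(sites$protein == proteins[m])
          seg <- (sites$position[idx] - 1L) %/% config$segment_length
          in_seg <- idx[seg == target]
        }
        chosen <- in_seg[seq_len(config$module_size)]
      } else {
        chosen <- idx[seq_len(config$module_size)]
      }
      is_module_site[chosen] <- TRUE
      module_of[chosen] <- m
    }
  }

  draw_row <- function(i, latent) {
    if (is_module_site[i]) {
      copy <- runif(C) < config$rho
      noise <- rbinom(C, 1L, config$base_rate)
      ifelse(copy, latent[[module_of[i]]], noise)
    } else {
      rbinom(C, 1L, config$base_rate)
    }
  }
  latent <- lapply(seq_len(max(config$n_modules, 1L)),
                   function(m) rbinom(C, 1L, config$module_rate))
  status <- matrix(0L, n_total, C)
  for (i in seq_len(n_total)) status[i, ] <- draw_row(i, latent)

  if (config$confounder) {
    seg_id <- paste0(sites$protein, ":",
                     (sites$position - 1L) %/% config$segment_length)
    for (s in unique(seg_id)) {
      rows <- which(seg_id == s)
      gate <- rbinom(C, 1L, config$detect_prob)
      status[rows, ] <- sweep(status[rows, , drop = FALSE], 2L, gate, "*")
    }
  }

  # every emitted site must be observed at least once
  for (i in which(rowSums(status) == 0L)) {
    for (attempt in seq_len(100L)) {
      row <- draw_row(i, latent)
      if (config$confounder) {
        gate <- rbinom(C, 1L, config$detect_prob)
        row <- row * gate
      }
      if (sum(row) > 0L) { status[i, ] <- row; break }
      if (attempt == 100L) stop("could not draw an observed site in 100 attempts")
    }
  }

  mat <- phospho_matrix(sites, status,
                        conditions = sprintf("cond_%02d", seq_len(C)))
  planted <- if (config$n_modules > 0L) {
    do.call(rbind, lapply(seq_len(config$n_modules), function(m) {
      pos <- sites$position[module_of == m]
      ids <- site_id(sites$protein[module_of == m], pos)[order(pos)]
      idx <- combn(length(ids), 2L)
      data.frame(site1 = ids[idx[1, ]], site2 = ids[idx[2, ]], module = m,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(site1 = character(), site2 = character(), module = integer(),
               stringsAsFactors = FALSE)
  }
  list(matrix = mat,
       truth = list(planted_pairs = planted,
                    module_sites = site_id(sites$protein[is_module_site],
                                           sites$position[is_module_site])),
       config = config)
}

#' Simulate an ultrametric-ish species tree
#'
#' A random coalescent-style tree with the first tip renamed to the reference
#' species, for use with [simulate_msa()] and [rcs()].
#'
#' @param n_species number of tips.
#' @param ref_name name given to the reference tip; default `"human"`.
#' @param seed integer seed.
#' @return an `ape::phylo` tree with branch lengths.
#' @export
simulate_tree <- function(n_species, ref_name = "human", seed = NULL) {
  local_seed(seed)
  tree <- ape::rcoal(n_species, tip.label = c(ref_name,
    sprintf("sp%02d", seq_len(n_species - 1L))))
  tree
}

#' Simulate alignment columns with planted coupled pairs down a species tree
#'
#' Independent columns evolve by a simple substitution process: the root draws
#' a uniform amino acid, and along each branch of length t a substitution to a
#' uniformly chosen different residue occurs with probability
#' `1 - exp(-rate * t)`. For a coupled column pair (X, Y), a fixed random
#' bijection f over the alphabet is drawn; each species' Y symbol is set to
#' f(X) with probability `coupling` and taken from an independently evolved
#' column otherwise. Coupling 1 therefore makes Y a deterministic relabeling
#' of X (nMI = 1 whenever the column entropy is positive); coupling 0 leaves
#' the pair independent.
#'
#' @param tree `phylo` species tree with branch lengths.
#' @param n_independent number of unpaired columns.
#' @param n_coupled number of coupled column pairs.
#' @param coupling coupling probability in \[0, 1\].
#' @param rate substitution rate per unit branch length.
#' @param seed integer seed.
#' @return list with `alignment` (species x column character matrix; columns
#'   named `ind_*`, `cpl_*A`, `cpl_*B`) and `coupled_pairs` (data.frame with
#'   columns `col_a`, `col_b`).
#' @export
simulate_msa <- function(tree, n_independent = 50L, n_coupled = 20L,
                         coupling = 0.9, rate = 1, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  local_seed(seed)

  evolve_column <- function() {
    n_nodes <- ape::Ntip(tree) + tree$Nnode
    state <- character(n_nodes)
    root <- ape::Ntip(tree) + 1L
    state[root] <- sample(AA_ALPHABET, 1L)
    ord <- reorder(tree, "cladewise")
    for (e in seq_len(nrow(ord$edge))) {
      from <- ord$edge[e, 1L]; to <- ord$edge[e, 2L]
      len <- ord$edge.length[e]
      if (runif(1) < 1 - exp(-rate * len)) {
        state[to] <- sample(setdiff(AA_ALPHABET, state[from]), 1L)
      } else {
        state[to] <- state[from]
      }
    }
    setNames(state[seq_len(ape::Ntip(tree))], tree$tip.label)
  }

  cols <- list()
  for (i in seq_len(n_independent))
    cols[[paste0("ind_", i)]] <- evolve_column()
  coupled <- data.frame(col_a = character(), col_b = character(),
                        stringsAsFactors = FALSE)
  for (i in seq_len(n_coupled)) {
    x <- evolve_column()
    indep <- evolve_column()
    f <- setNames(sample(AA_ALPHABET), AA_ALPHABET)   # random bijection
    slave <- runif(length(x)) < coupling
    y <- ifelse(slave, unname(f[x]), unname(indep))
    names(y) <- names(x)
    a <- paste0("cpl_", i, "A"); b <- paste0("cpl_", i, "B")
    cols[[a]] <- x
    cols[[b]] <- y
    coupled <- rbind(coupled, data.frame(col_a = a, col_b = b,
                                         stringsAsFactors = FALSE))
  }
  alignment <- do.call(cbind, cols)
  rownames(alignment) <- tree$tip.label
  list(alignment = alignment, coupled_pairs = coupled)
}

#' Simulate kinase-substrate data with planted motifs
#'
#' Generates a background proteome of random sequences, then for each kinase
#' plants a positional motif: at `motif_positions` randomly chosen non-center
#' window positions, a kinase-specific consensus residue appears with
#' probability `motif_strength` (background residue usage otherwise). The
#' substrate windows are written into the protein sequences so that
#' [extract_window()] recovers them. `motif_strength` at the background
#' frequency level makes the motif uninformative.
#'
#' @param n_kinases number of kinases.
#' @param substrates_per_kinase substrate sites per kinase (at least the
#'   training minimum, default 50).
#' @param motif_positions number of informative window positions per kinase.
#' @param motif_strength consensus residue probability at informative
#'   positions.
#' @param n_proteins,protein_length background proteome shape.
#' @param seed integer seed.
#' @return list with `sequences` (named character vector),
#'   `kinase_substrates` (data.frame `kinase`, `protein`, `position`),
#'   `truth` (per-site generating kinase; `site_id` keyed) and `motifs`
#'   (per kinase: informative positions, consensus residues, center residue).
#' @export
simulate_kinase_data <- function(n_kinases = 3L, substrates_per_kinase = 100L,
                                 motif_positions = 4L, motif_strength = 0.8,
                                 n_proteins = 60L, protein_length = 400L,
                                 seed = NULL) {
  local_seed(seed)
  flank <- 7L
  width <- 2L * flank + 1L
  proteins <- sprintf("BG%03d", seq_len(n_proteins))
  sequences <- setNames(vapply(proteins, function(p)
    paste(sample(AA_ALPHABET, protein_length, replace = TRUE),
          collapse = ""), character(1)), proteins)

  motifs <- list()
  subs <- list()
  used <- list()                          # occupied windows per protein
  for (k in seq_len(n_kinases)) {
    kname <- sprintf("KIN%02d", k)
    center <- sample(c("S", "T", "Y"), 1L)
    info_pos <- sample(setdiff(seq_len(width), flank + 1L), motif_positions)
    consensus <- sample(AA_ALPHABET, motif_positions, replace = TRUE)
    motifs[[kname]] <- list(center = center, positions = info_pos,
                            consensus = consensus)
    placed <- 0L
    while (placed < substrates_per_kinase) {
      p <- sample(proteins, 1L)
      pos <- sample(seq(flank + 1L, protein_length - flank), 1L)
      span <- (pos - flank):(pos + flank)
      if (any(span %in% used[[p]])) next
      used[[p]] <- c(used[[p]], span)
      window <- sample(AA_ALPHABET, width, replace = TRUE)
      window[flank + 1L] <- center
      hit <- runif(motif_positions) < motif_strength
      window[info_pos[hit]] <- consensus[hit]
      chars <- strsplit(sequences[[p]], "")[[1]]
      chars[span] <- window
      sequences[[p]] <- paste(chars, collapse = "")
      subs[[length(subs) + 1L]] <- data.frame(kinase = kname, protein = p,
                                              position = pos,
                                              stringsAsFactors = FALSE)
      placed <- placed + 1L
    }
  }
  kinase_substrates <- do.call(rbind, subs)
  truth <- setNames(kinase_substrates$kinase,
                    site_id(kinase_substrates$protein,
                            kinase_substrates$position))
  list(sequences = sequences, kinase_substrates = kinase_substrates,
       truth = truth, motifs = motifs)
}

#' Simulate curated site annotations with planted pair classes
#'
#' Terms are drawn from a Zipf-distributed vocabulary (frequency of term t
#' proportional to 1/t^s). Planted homo-functional pairs share a functional
#' class and at least one term; planted hetero-functional pairs get different
#' classes and disjoint term sets.
#'
#' @param site_ids character vector of site ids to annotate.
#' @param n_homo_pairs,n_hetero_pairs numbers of planted pairs (drawn from the
#'   head of `site_ids`, consuming two sites per pair).
#' @param vocab_size term vocabulary size.
#' @param zipf_s Zipf exponent.
#' @param terms_per_site mean number of terms per site (at least 1).
#' @param seed integer seed.
#' @return list with `annotations` (long data.frame `site_id`, `category`,
#'   `term`), `classes` (data.frame `site_id`, `class`), and `truth`
#'   (data.frame `site1`, `site2`, `pair_class` in homo/hetero).
#' @export
simulate_annotations <- function(site_ids, n_homo_pairs = 20L,
                                 n_hetero_pairs = 20L, vocab_size = 200L,
                                 zipf_s = 1, terms_per_site = 3,
                                 seed = NULL) {
  local_seed(seed)
  needed <- 2L * (n_homo_pairs + n_hetero_pairs)
  stopifnot(length(site_ids) >= needed)
  vocab <- sprintf("term%03d", seq_len(vocab_size))
  zipf_p <- (1 / seq_len(vocab_size)^zipf_s)
  zipf_p <- zipf_p / sum(zipf_p)
  draw_terms <- function(n, exclude = character(0)) {
    pool <- setdiff(vocab, exclude)
    p <- zipf_p[match(pool, vocab)]
    sample(pool, n, prob = p / sum(p))
  }
  classes_vec <- c("activate", "inhibit", "dual")
  ann <- list(); cls <- list(); truth <- list()
  cursor <- 1L
  add_site <- function(id, class, terms) {
    ann[[length(ann) + 1L]] <<- data.frame(site_id = id, category = "process",
                                           term = terms,
                                           stringsAsFactors = FALSE)
    cls[[length(cls) + 1L]] <<- data.frame(site_id = id, class = class,
                                           stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_homo_pairs)) {
    s1 <- site_ids[cursor]; s2 <- site_ids[cursor + 1L]; cursor <- cursor + 2L
    class <- sample(classes_vec, 1L)
    shared <- draw_terms(1L)
    k1 <- 1L + rpois(1L, terms_per_site - 1)
    k2 <- 1L + rpois(1L, terms_per_site - 1)
    add_site(s1, class, unique(c(shared, draw_terms(k1 - 1L))))
    add_site(s2, class, unique(c(shared, draw_terms(k2 - 1L))))
    truth[[length(truth) + 1L]] <- data.frame(site1 = s1, site2 = s2,
                                              pair_class = "homo",
                                              stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_hetero_pairs)) {
    s1 <- site_ids[cursor]; s2 <- site_ids[cursor + 1L]; cursor <- cursor + 2L
    two_classes <- sample(classes_vec, 2L)
    t1 <- draw_terms(1L + rpois(1L, terms_per_site - 1))
    t2 <- draw_terms(1L + rpois(1L, terms_per_site - 1), exclude = t1)
    add_site(s1, two_classes[1], t1)
    add_site(s2, two_classes[2], t2)
    truth[[length(truth) + 1L]] <- data.frame(site1 = s1, site2 = s2,
                                              pair_class = "hetero",
                                              stringsAsFactors = FALSE)
  }
  # remaining sites: random class and terms, no planted structure
  rest <- site_ids[cursor:length(site_ids)]
  for (id in rest)
    add_site(id, sample(classes_vec, 1L),
             unique(draw_terms(1L + rpois(1L, terms_per_site - 1))))
  list(annotations = do.call(rbind, ann),
       classes = do.call(rbind, cls),
       truth = do.call(rbind, truth))
}
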