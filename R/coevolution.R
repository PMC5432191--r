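#' Read a multiple sequence alignment from aligned FASTA
#'
#' @param path aligned FASTA of one orthologous group; all records must have
#'   equal aligned length. Record names are species identifiers.
#' @return character matrix, rows = species, columns = alignment positions;
#'   symbols are upper-case amino acids or `"-"` for gaps.
#' @export
read_msa <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (length(unique(Biostrings::width(seqs))) != 1L)
    stop("alignment records have unequal lengths")
  m <- do.call(rbind, strsplit(toupper(as.character(seqs)), ""))
  rownames(m) <- names(seqs)
  m
}

#' Extract the alignment column holding a reference-species residue
#'
#' Maps an ungapped (sequence) position of the reference species to its
#' aligned column index, skipping gaps in the reference row, and returns the
#' per-species symbols of that column.
#'
#' @param msa character matrix from [read_msa()] (or equivalent).
#' @param ref_id row name of the reference (e.g. human) sequence.
#' @param position 1-based ungapped position in the reference sequence.
#' @return an `alignment_column`: named character vector of symbols per
#'   species, with attributes `ref` (reference species), `ref_symbol` and
#'   `aligned_index`.
#' @export
column_for_site <- function(msa, ref_id, position) {
  if (!ref_id %in% rownames(msa))
    stop("reference sequence '", ref_id, "' not in the alignment")
  ref <- msa[ref_id, ]
  ungapped <- cumsum(ref != "-")
  if (position < 1L || position > max(ungapped))
    stop("position ", position, " beyond the ungapped length of ", ref_id,
         " (", max(ungapped), ")")
  col_idx <- which(ungapped == position & ref != "-")[1]
  alignment_column(msa[, col_idx], ref = ref_id, aligned_index = col_idx)
}

#' Construct an alignment column
#'
#' @param symbols named character vector, species -> symbol (20 amino acids or
#'   `"-"`); must include the reference species.
#' @param ref reference species name (default `"human"`).
#' @param aligned_index optional aligned column index, kept as metadata.
#' @return an `alignment_column` object.
#' @export
alignment_column <- function(symbols, ref = "human", aligned_index = NA_integer_) {
  stopifnot(!is.null(names(symbols)), ref %in% names(symbols),
            length(symbols) >= 2L)
  structure(symbols, class = "alignment_column", ref = ref,
            ref_symbol = unname(symbols[ref]), aligned_index = aligned_index)
}

#' Is a column eligible for co-evolution scoring?
#'
#' Eligible iff at least `min_divergent` species carry a symbol (amino acid or
#' gap) different from the reference species' residue. Fully or nearly
#' conserved columns carry no co-variation signal and are excluded.
#'
#' @param column an [alignment_column()].
#' @param min_divergent minimum divergent species; default 3.
#' @return logical flag.
#' @export
eligible_for_nmi <- function(column, min_divergent = 3L) {
  ref <- attr(column, "ref")
  sum(column[setdiff(names(column), ref)] != attr(column, "ref_symbol")) >=
    min_divergent
}

.entropy <- function(freq) -sum(freq * log(freq))

#' Residue co-evolution of two sites by normalized mutual information
#'
#' Mutual information between the symbol distributions (20 amino acids plus
#' the gap as a 21st symbol) of the two orthologous columns over their shared
#' species, normalized to \[0, 1\]. The default normalization divides MI by
#' the geometric mean of the two column entropies; `"product"` divides by
#' their product. Natural logarithms are used (the base cancels in the
#' geometric-mean ratio).
#'
#' @param col_x,col_y [alignment_column()]s; species sets are intersected.
#' @param normalization `"geometric"` (default) or `"product"`.
#' @param min_divergent eligibility bound per column over the shared species,
#'   see [eligible_for_nmi()].
#' @return one-row data.frame: `mi`, `nmi`, `h_x`, `h_y`, `n_species`,
#'   `eligible`. `nmi` is `NA` with `eligible = FALSE` when either column is
#'   insufficiently divergent or has zero entropy over the shared species.
#' @export
nmi <- function(col_x, col_y, normalization = c("geometric", "product"),
                min_divergent = 3L) {
  normalization <- match.arg(normalization)
  shared <- intersect(names(col_x), names(col_y))
  ref <- attr(col_x, "ref")
  stopifnot(identical(ref, attr(col_y, "ref")), ref %in% shared)
  x <- col_x[shared]; y <- col_y[shared]
  sub_x <- alignment_column(x, ref = ref)
  sub_y <- alignment_column(y, ref = ref)
  n <- length(shared)

  px <- table(x) / n
  py <- table(y) / n
  h_x <- .entropy(px); h_y <- .entropy(py)
  eligible <- eligible_for_nmi(sub_x, min_divergent) &&
    eligible_for_nmi(sub_y, min_divergent) && h_x > 0 && h_y > 0
  pxy <- table(x, y) / n
  mi <- 0
  for (i in rownames(pxy)) for (j in colnames(pxy)) {
    pj <- pxy[i, j]
    if (pj > 0) mi <- mi + pj * log(pj / (px[[i]] * py[[j]]))
  }
  mi <- max(mi, 0)
  nmi_val <- if (!eligible) NA_real_ else switch(
    normalization,
    geometric = mi / sqrt(h_x * h_y),
    product = mi / (h_x * h_y))
  data.frame(mi = mi, nmi = nmi_val, h_x = h_x, h_y = h_y,
             n_species = n, eligible = eligible)
}

#' Residue conservation score of a site on a species tree
#'
#' Let C be the species carrying the same residue as the reference. The
#' maximum branch length (MBL) is the largest patristic distance between any
#' two members of C, as a ratio of the largest patristic distance between any
#' two species in the tree (the tree diameter). The ratio of conserved
#' residues (RCR) is the fraction of species under the most recent common
#' ancestor of C that belong to C. RCS = MBL x RCR, in \[0, 1\]; a residue
#' conserved nowhere outside the reference scores 0.
#'
#' @param column an [alignment_column()] whose species resolve to tree tips.
#' @param tree a rooted `phylo` tree with branch lengths (see [ape::read.tree]).
#' @return one-row data.frame: `mbl`, `rcr`, `rcs`, `n_conserved`.
#' @export
rcs <- function(column, tree) {
  stopifnot(inherits(tree, "phylo"))
  missing <- setdiff(names(column), tree$tip.label)
  if (length(missing))
    stop("species not in the tree: ", paste(head(missing, 3), collapse = ", "))
  conserved <- names(column)[column == attr(column, "ref_symbol")]
  if (length(conserved) < 2L)
    return(data.frame(mbl = 0, rcr = 0, rcs = 0,
                      n_conserved = length(conserved)))
  dists <- ape::cophenetic.phylo(tree)
  diameter <- max(dists)
  if (diameter == 0) {
    mbl <- 1                              # zero-length tree: no divergence
  } else {
    mbl <- max(dists[conserved, conserved]) / diameter
  }
  if (length(conserved) == ape::Ntip(tree)) {
    subtree_tips <- tree$tip.label
  } else {
    mrca <- ape::getMRCA(tree, conserved)
    subtree_tips <- ape::extract.clade(tree, mrca)$tip.label
  }
  rcr <- length(intersect(conserved, subtree_tips)) / length(subtree_tips)
  data.frame(mbl = mbl, rcr = rcr, rcs = mbl * rcr,
             n_conserved = length(conserved))
}
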