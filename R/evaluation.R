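#' Area under the ROC curve by the rank (Mann-Whitney) estimator
#'
#' AUC = P(score of a random positive > score of a random negative), with
#' ties counted 1/2 via midranks. For co-occurrence p-values pass
#' `-log10(p)` as the score so that smaller p means more positive.
#'
#' @param labels logical (or 0/1) vector; `TRUE` = positive.
#' @param scores numeric scores, larger = more positive.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.logical(labels)
  stopifnot(length(labels) == length(scores), !anyNA(labels), !anyNA(scores))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("ROC needs at least one positive and one negative")
  r <- rank(scores)                       # midranks for ties
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Fold enrichment of a proportion, with an exact-test p-value
#'
#' Compares k1/n1 against k2/n2 (e.g. the co-occurring proportion in a
#' positive set against a negative set): fold = (k1/n1) / (k2/n2), p from the
#' one-sided exact test for over-representation of group 1 successes.
#'
#' @param k1,n1 successes and total in group 1.
#' @param k2,n2 successes and total in group 2.
#' @return one-row data.frame: `prop1`, `prop2`, `fold`, `p`. `fold` is `NA`
#'   when `k2` is zero (undefined ratio).
#' @export
proportion_enrichment <- function(k1, n1, k2, n2) {
  stopifnot(k1 <= n1, k2 <= n2, k1 >= 0, k2 >= 0)
  prop1 <- k1 / n1; prop2 <- k2 / n2
  fold <- if (k2 == 0L) NA_real_ else prop1 / prop2
  p <- as.numeric(fisher_one_sided(k1, n1 - k1, k2, n2 - k2,
                                   tail = "co-occurrence"))
  data.frame(prop1 = prop1, prop2 = prop2, fold = fold, p = p)
}

#' Permutation test for a difference in group medians
#'
#' Two-sided label-permutation test of `|median(A) - median(B)|`. When the
#' number of distinct label splits `choose(nA + nB, nA)` does not exceed
#' `n_perm`, all splits are enumerated and the p-value is exact; otherwise
#' `n_perm` random splits are drawn and the add-one smoothed estimate
#' `(1 + #extreme) / (1 + n_perm)` is returned (never exactly 0).
#'
#' @param group_a,group_b numeric value vectors.
#' @param n_perm permutation budget; default 1e5.
#' @param seed optional integer seed (Monte-Carlo route only).
#' @return p-value.
#' @export
permutation_median_test <- function(group_a, group_b, n_perm = 1e5,
                                    seed = NULL) {
  stopifnot(length(group_a) >= 1L, length(group_b) >= 1L)
  pooled <- c(group_a, group_b)
  n_a <- length(group_a)
  observed <- abs(median(group_a) - median(group_b))
  n_splits <- choose(length(pooled), n_a)
  if (n_splits <= n_perm) {
    splits <- combn(length(pooled), n_a)
    stats <- apply(splits, 2L, function(idx)
      abs(median(pooled[idx]) - median(pooled[-idx])))
    return(sum(stats >= observed - 1e-12) / n_splits)
  }
  local_seed(seed)
  extreme <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(pooled), n_a)
    if (abs(median(pooled[idx]) - median(pooled[-idx])) >= observed - 1e-12)
      extreme <- extreme + 1L
  }
  (1 + extreme) / (1 + n_perm)
}

#' Sequence distance between two sites of the same protein
#'
#' @param pos1,pos2 1-based residue positions (vectorized).
#' @return `abs(pos1 - pos2)` in residues.
#' @export
sequence_distance <- function(pos1, pos2) abs(pos1 - pos2)

#' Euclidean distance between two C-alpha coordinates
#'
#' @param xyz1,xyz2 numeric length-3 vectors, or n x 3 matrices, of C-alpha
#'   coordinates in Angstroms.
#' @return distance(s) in Angstroms.
#' @export
structural_distance <- function(xyz1, xyz2) {
  if (!is.matrix(xyz1)) xyz1 <- matrix(xyz1, ncol = 3L)
  if (!is.matrix(xyz2)) xyz2 <- matrix(xyz2, ncol = 3L)
  sqrt(rowSums((xyz1 - xyz2)^2))
}

#' Thin C-alpha coordinate reader for PDB-format files
#'
#' Extracts per-residue C-alpha coordinates from the first model, taking the
#' first chain that maps each residue number. Any mapping between UniProt and
#' PDB numbering must be applied by the caller via `offset`.
#'
#' @param path PDB-format file.
#' @param chain optional chain identifier; default: first chain per residue.
#' @param offset added to PDB residue numbers to obtain sequence positions.
#' @return data.frame with columns `position`, `x`, `y`, `z`.
#' @export
read_ca_coordinates <- function(path, chain = NULL, offset = 0L) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("read_ca_coordinates() needs the bio3d package")
  pdb <- bio3d::read.pdb(path, multi = FALSE)
  sel <- pdb$atom[pdb$atom$elety == "CA" & pdb$atom$type == "ATOM", ,
                  drop = FALSE]
  if (!is.null(chain)) sel <- sel[sel$chain == chain, , drop = FALSE]
  sel <- sel[!duplicated(sel$resno), , drop = FALSE]
  data.frame(position = sel$resno + offset,
             x = sel$x, y = sel$y, z = sel$z)
}

#' Select control pairs matching the distance distribution of co-occurring pairs
#'
#' Samples control pairs without replacement within log2-spaced sequence
#' distance bins so that the matched set reproduces the co-occurring set's
#' bin histogram (capped by control availability per bin). Removes sequence
#' distance as a confounder when comparing annotation sharing or co-evolution
#' between the two sets.
#'
#' @param cooccurring_dist,control_dist sequence distances (residues, >= 1)
#'   of the co-occurring and control pairs.
#' @param seed optional integer seed for the within-bin sampling.
#' @return integer indices into the control set; attribute `shortfall` counts
#'   co-occurring pairs that could not be matched for lack of controls in
#'   their bin, and `bins` records the bin breaks.
#' @export
match_controls_by_distance <- function(cooccurring_dist, control_dist,
                                       seed = NULL) {
  stopifnot(all(cooccurring_dist >= 1), all(control_dist >= 1))
  local_seed(seed)
  top <- max(cooccurring_dist, control_dist)
  breaks <- 2^(0:ceiling(log2(top + 1)))    # bins [2^i, 2^(i+1))
  bin_co <- findInterval(cooccurring_dist, breaks)
  bin_ct <- findInterval(control_dist, breaks)
  picked <- integer(0)
  shortfall <- 0L
  for (b in sort(unique(bin_co))) {
    need <- sum(bin_co == b)
    avail <- which(bin_ct == b)
    take <- min(need, length(avail))
    shortfall <- shortfall + (need - take)
    if (take > 0L)
      picked <- c(picked, avail[sample.int(length(avail), take)])
  }
  structure(picked, shortfall = shortfall, bins = breaks)
}

#' Co-localization of site pairs at protein-protein interaction interfaces
#'
#' Given residue intervals annotating the interaction interface of each
#' protein pair, computes the proportion of site pairs (among those mappable
#' to an annotated protein pair) with both sites inside interface regions.
#'
#' @param pairs data.frame with columns `protein1`, `pos1`, `protein2`,
#'   `pos2`.
#' @param interfaces data.frame with columns `protein1`, `protein2` (the
#'   annotated interacting pair, in the same orientation convention as
#'   `pairs`), `protein` (which member the interval belongs to), `start`,
#'   `end` (closed residue interval).
#' @return one-row data.frame: `n_mappable`, `n_colocalized`, `proportion`.
#' @export
interface_colocalization <- function(pairs, interfaces) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  pk <- key(pairs$protein1, pairs$protein2)
  ik <- key(interfaces$protein1, interfaces$protein2)
  mappable <- pk %in% ik
  in_interface <- function(pair_key, protein, pos) {
    rows <- interfaces[ik == pair_key & interfaces$protein == protein, ,
                       drop = FALSE]
    nrow(rows) > 0L && any(pos >= rows$start & pos <= rows$end)
  }
  n_co <- 0L
  for (i in which(mappable)) {
    if (in_interface(pk[i], pairs$protein1[i], pairs$pos1[i]) &&
        in_interface(pk[i], pairs$protein2[i], pairs$pos2[i]))
      n_co <- n_co + 1L
  }
  data.frame(n_mappable = sum(mappable), n_colocalized = n_co,
             proportion = if (any(mappable)) n_co / sum(mappable) else NA_real_)
}
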