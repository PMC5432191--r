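#' Permute modification status within proteins, preserving per-condition counts
#'
#' For every protein and every condition independently, reassigns the observed
#' number of modifications uniformly at random among that protein's potential
#' phosphosites (a seeded Fisher-Yates partial shuffle). Matrix dimensions,
#' the identity of potential sites, and per-protein per-condition on-counts
#' are preserved exactly.
#'
#' @param x a [phospho_matrix()].
#' @param seed optional integer seed; the shuffle is bit-reproducible given
#'   the seed and leaves the caller's RNG state untouched.
#' @return a shuffled [phospho_matrix()] (individual sites may end up with
#'   all-zero rows; the potential-site set is defined by the original data).
#' @export
shuffle_protein_level <- function(x, seed = NULL) {
  stopifnot(inherits(x, "phospho_matrix"))
  .shuffle_by_group(x, x$sites$protein, seed)
}

.shuffle_by_group <- function(x, group, seed = NULL) {
  local_seed(seed)
  status <- x$status
  idx_by_group <- split(seq_len(nrow(status)), group)
  for (idx in idx_by_group) {
    k <- length(idx)
    if (k < 2L) next                      # a single site: only one subset
    block <- status[idx, , drop = FALSE]
    m <- colSums(block)
    for (j in which(m > 0L & m < k)) {
      col <- integer(k)
      col[sample.int(k, m[j])] <- 1L
      block[, j] <- col
    }
    status[idx, ] <- block
  }
  structure(list(sites = x$sites, status = status), class = "phospho_matrix")
}

#' Tile proteins into fixed-length peptide-segment windows
#'
#' Non-overlapping windows of `L` residues anchored at the N-terminus
#' (positions `[1, L+1)`, `[L+1, 2L+1)`, ...; the terminal remainder shorter
#' than `L` is dropped). Only windows holding at least `min_sites` potential
#' phosphosites are kept; these short segments are then treated as individual
#' proteins in segment-level permutation.
#'
#' @param protein_lengths named integer vector of protein lengths, or named
#'   character vector of sequences (lengths are taken with `nchar`).
#' @param sites data.frame with columns `protein`, `position`, `site_id`
#'   (e.g. `x$sites` of a [phospho_matrix()]).
#' @param L window length in residues; typical choices are 10, 20, 50, 70 or 100.
#' @param min_sites minimum potential sites per retained window; default 5.
#' @return data.frame with columns `window_id`, `protein`, `start`, `end`
#'   (half-open `[start, end)`), `n_sites`; attribute `site_window` is a named
#'   character vector mapping retained site ids to window ids.
#' @export
segment_windows <- function(protein_lengths, sites, L, min_sites = 5L) {
  stopifnot(L >= 1L, min_sites >= 1L)
  if (is.character(protein_lengths))
    protein_lengths <- setNames(nchar(protein_lengths),
                                names(protein_lengths))
  rows <- list()
  site_window <- character(0)
  for (p in intersect(names(protein_lengths), unique(sites$protein))) {
    n_win <- protein_lengths[[p]] %/% L
    if (n_win == 0L) next
    s <- sites[sites$protein == p, , drop = FALSE]
    win <- (s$position - 1L) %/% L + 1L       # window index, 1-based
    win[win > n_win] <- NA                    # positions in dropped remainder
    counts <- table(factor(win, levels = seq_len(n_win)))
    keep <- which(counts >= min_sites)
    for (w in keep) {
      wid <- paste0(p, ":w", w)
      rows[[length(rows) + 1L]] <- data.frame(
        window_id = wid, protein = p,
        start = (w - 1L) * L + 1L, end = w * L + 1L,
        n_sites = as.integer(counts[w]), stringsAsFactors = FALSE)
      in_w <- !is.na(win) & win == w
      site_window[s$site_id[in_w]] <- wid
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(window_id = character(), protein = character(),
               start = integer(), end = integer(), n_sites = integer(),
               stringsAsFactors = FALSE)
  attr(out, "site_window") <- site_window
  out
}

#' Permute modification status within peptide-segment windows
#'
#' Same margin-preserving shuffle as [shuffle_protein_level()], but the
#' exchangeable groups are the retained windows of a [segment_windows()] set.
#' Sites outside any retained window are left untouched (they do not take part
#' in the segment-level analysis).
#'
#' @param x a [phospho_matrix()].
#' @param segments a [segment_windows()] result.
#' @inheritParams shuffle_protein_level
#' @return a shuffled [phospho_matrix()].
#' @export
shuffle_segment_level <- function(x, segments, seed = NULL) {
  stopifnot(inherits(x, "phospho_matrix"))
  site_window <- attr(segments, "site_window")
  group <- site_window[x$sites$site_id]
  group[is.na(group)] <- paste0(".unsegmented:", which(is.na(group)))
  .shuffle_by_group(x, group, seed)
}

#' Fold increase of co-occurring pairs over margin-preserving randomized data
#'
#' Repeats the shuffle `n_reps` times, rescans the same pairs in each
#' replicate, pools the randomized p-values across replicates (denominator =
#' `n_reps * nrow(pairs)`), and reports, per threshold, observed and
#' randomized counts/proportions and their ratio (the fold increase).
#'
#' @param x the observed [phospho_matrix()].
#' @param pairs pair table scanned (see [scan_pairs()]).
#' @param n_reps number of shuffle replicates; default 100.
#' @param thresholds p-value grid.
#' @param level `"protein"` or `"segment"` shuffling.
#' @param segments required [segment_windows()] set when `level = "segment"`.
#' @param seed integer seed for the replicate shuffles.
#' @param observed_p optionally, precomputed observed p-values for `pairs`
#'   (skips one scan).
#' @return data.frame with columns `threshold`, `observed_count`,
#'   `observed_prop`, `random_count`, `random_prop`, `fold`,
#'   `fold_is_finite`. A zero randomized proportion gives `fold = Inf` with
#'   `fold_is_finite = FALSE`.
#' @export
fold_increase_report <- function(x, pairs, n_reps = 100L,
                                 thresholds = 10^seq(-7, -2),
                                 level = c("protein", "segment"),
                                 segments = NULL, seed = NULL,
                                 observed_p = NULL) {
  level <- match.arg(level)
  if (level == "segment" && is.null(segments))
    stop("segment-level randomization needs a segment_windows() set")
  if (is.null(observed_p))
    observed_p <- scan_pairs(x, pairs, negative_tail = FALSE)$p_co
  local_seed(seed)
  rand_counts <- numeric(length(thresholds))
  for (rep in seq_len(n_reps)) {
    shuf <- if (level == "protein") .shuffle_by_group(x, x$sites$protein)
            else shuffle_segment_level(x, segments)
    p <- scan_pairs(shuf, pairs, negative_tail = FALSE)$p_co
    rand_counts <- rand_counts +
      vapply(thresholds, function(t) sum(p < t), numeric(1))
  }
  obs_counts <- vapply(thresholds, function(t) sum(observed_p < t), numeric(1))
  obs_prop <- obs_counts / length(observed_p)
  rand_prop <- rand_counts / (n_reps * length(observed_p))
  fold <- obs_prop / rand_prop
  data.frame(threshold = thresholds,
             observed_count = obs_counts, observed_prop = obs_prop,
             random_count = rand_counts, random_prop = rand_prop,
             fold = fold, fold_is_finite = is.finite(fold))
}
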