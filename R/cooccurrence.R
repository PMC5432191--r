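#' Cross-tabulate the joint modification status of two sites
#'
#' Counts conditions by joint on/off state of a site pair: `n11` = both
#' modified, `n10` = only the first, `n01` = only the second, `n00` = neither.
#'
#' @param status_a,status_b equal-length 0/1 vectors over the same conditions.
#' @return named integer vector `c(n11, n10, n01, n00)`.
#' @export
build_contingency <- function(status_a, status_b) {
  if (length(status_a) != length(status_b))
    stop("status vectors must have equal length")
  if (!length(status_a)) stop("status vectors must be non-empty")
  stopifnot(all(status_a %in% 0:1), all(status_b %in% 0:1))
  a <- as.integer(status_a); b <- as.integer(status_b)
  c(n11 = sum(a & b), n10 = sum(a & !b),
    n01 = sum(!a & b), n00 = sum(!a & !b))
}

# Hypergeometric right/left tail (including the observed point) for 2x2
# tables with fixed margins, computed in log space via lgamma so p-values
# remain exact down to the smallest representable doubles. The tail sum is
# accumulated from the extreme of the support so small terms are added first.
# Tables sharing margins (N, r, c) are computed once and looked up.
.hyper_tails <- function(n11, r, c, N) {
  stopifnot(length(r) == length(n11), length(c) == length(n11),
            length(N) == length(n11))
  p_co <- p_neg <- numeric(length(n11))
  # p is symmetric in the two margins; compute with the canonical (min, max)
  # ordering so transposed tables give bit-identical results
  rlo <- pmin(r, c); rhi <- pmax(r, c)
  key <- paste(N, rlo, rhi, sep = ":")
  for (grp in split(seq_along(n11), key)) {
    i <- grp[1]
    kmin <- max(0L, rlo[i] + rhi[i] - N[i])
    kmax <- rlo[i]
    k <- kmin:kmax
    logp <- lgamma(rlo[i] + 1) - lgamma(k + 1) - lgamma(rlo[i] - k + 1) +
      lgamma(N[i] - rlo[i] + 1) - lgamma(rhi[i] - k + 1) -
      lgamma(N[i] - rlo[i] - rhi[i] + k + 1) -
      (lgamma(N[i] + 1) - lgamma(rhi[i] + 1) - lgamma(N[i] - rhi[i] + 1))
    p <- exp(logp)
    upper <- rev(cumsum(rev(p)))            # P(X >= k)
    lower <- cumsum(p)                      # P(X <= k)
    idx <- n11[grp] - kmin + 1L
    p_co[grp] <- pmin(upper[idx], 1)
    p_neg[grp] <- pmin(lower[idx], 1)
  }
  list(p_co = p_co, p_neg = p_neg)
}

#' One-sided Fisher's exact test for a 2x2 contingency table
#'
#' Evaluates the tendency of two phosphosites to be modified together
#' (`tail = "co-occurrence"`: P(X >= n11) under the hypergeometric law with
#' margins fixed) or apart (`tail = "negative"`: P(X <= n11)). Exact, computed
#' in log space via log-gamma; no continuity correction. All arguments are
#' vectorized.
#'
#' Tables with a degenerate margin (a site on or off in every condition) carry
#' no information about association: p = 1 is returned and flagged in the
#' `"degenerate"` attribute.
#'
#' @param n11,n10,n01,n00 nonnegative integer cell counts (see
#'   [build_contingency()]); a 4-element vector/table may be passed as `n11`.
#' @param tail `"co-occurrence"` (right tail, the default) or `"negative"`
#'   (left tail).
#' @return numeric vector of p-values in (0, 1], with a logical attribute
#'   `degenerate`.
#' @export
fisher_one_sided <- function(n11, n10 = NULL, n01 = NULL, n00 = NULL,
                             tail = c("co-occurrence", "negative")) {
  tail <- match.arg(tail)
  if (is.null(n10) && length(n11) == 4L) {
    n10 <- n11[[2]]; n01 <- n11[[3]]; n00 <- n11[[4]]; n11 <- n11[[1]]
  }
  stopifnot(all(n11 >= 0), all(n10 >= 0), all(n01 >= 0), all(n00 >= 0))
  n11 <- as.integer(n11); n10 <- as.integer(n10)
  n01 <- as.integer(n01); n00 <- as.integer(n00)
  N <- n11 + n10 + n01 + n00
  r <- n11 + n10
  cc <- n11 + n01
  degenerate <- r == 0L | r == N | cc == 0L | cc == N
  tails <- .hyper_tails(n11, r, cc, N)
  p <- if (tail == "co-occurrence") tails$p_co else tails$p_neg
  p[degenerate] <- 1
  attr(p, "degenerate") <- degenerate
  p
}

#' Label a pair from its co-occurrence p-value
#'
#' Co-occurring if p is below `tau_co` (default 1E-5), control if p is
#' no less than `tau_ctrl` (default 0.5), otherwise neither.
#'
#' @param p_co p-value(s) from [fisher_one_sided()].
#' @param tau_co strict upper threshold for co-occurring pairs.
#' @param tau_ctrl inclusive lower threshold for control pairs.
#' @return character vector over `{"co-occurring", "neither", "control"}`.
#' @export
classify_pair <- function(p_co, tau_co = 1e-5, tau_ctrl = 0.5) {
  if (tau_co >= tau_ctrl)
    stop("configuration error: tau_co must be < tau_ctrl")
  stopifnot(all(p_co > 0), all(p_co <= 1))
  ifelse(p_co < tau_co, "co-occurring",
         ifelse(p_co >= tau_ctrl, "control", "neither"))
}

#' Test all site pairs for co-occurring modification status
#'
#' Builds the 2x2 contingency table and one-sided exact-test p-values for each
#' pair, labels pairs by the thresholds, and attaches a threshold-sweep
#' summary.
#'
#' @param x a [phospho_matrix()] containing every site referenced by `pairs`.
#' @param pairs data.frame with columns `site1`, `site2` (site ids), e.g. from
#'   [enumerate_within_protein_pairs()].
#' @param tau_co,tau_ctrl thresholds, see [classify_pair()].
#' @param negative_tail also compute the left-tail p-value `p_neg` (for the
#'   negative-correlation scan)? Default `TRUE`.
#' @param sweep_thresholds p-value grid for the attached sweep summary.
#' @return data.frame with one row per pair: `site1`, `site2`, `n11`, `n10`,
#'   `n01`, `n00`, `p_co`, (`p_neg`,) `degenerate`, `label`; attribute
#'   `sweep` holds the [threshold_sweep()] table.
#' @export
scan_pairs <- function(x, pairs, tau_co = 1e-5, tau_ctrl = 0.5,
                       negative_tail = TRUE,
                       sweep_thresholds = 10^seq(-7, -2)) {
  stopifnot(inherits(x, "phospho_matrix"))
  missing <- setdiff(unique(c(pairs$site1, pairs$site2)), rownames(x$status))
  if (length(missing))
    stop("pairs reference sites absent from the matrix: ",
         paste(head(missing, 3), collapse = ", "))
  s1 <- x$status[pairs$site1, , drop = FALSE]
  s2 <- x$status[pairs$site2, , drop = FALSE]
  n11 <- as.integer(rowSums(s1 * s2))
  r <- as.integer(rowSums(s1))
  cc <- as.integer(rowSums(s2))
  N <- ncol(x$status)
  n10 <- r - n11; n01 <- cc - n11; n00 <- N - r - cc + n11
  p_co <- fisher_one_sided(n11, n10, n01, n00, tail = "co-occurrence")
  out <- data.frame(site1 = pairs$site1, site2 = pairs$site2,
                    n11 = n11, n10 = n10, n01 = n01, n00 = n00,
                    p_co = as.numeric(p_co), stringsAsFactors = FALSE)
  if (negative_tail)
    out$p_neg <- as.numeric(fisher_one_sided(n11, n10, n01, n00,
                                             tail = "negative"))
  out$degenerate <- attr(p_co, "degenerate")
  out$label <- classify_pair(out$p_co, tau_co, tau_ctrl)
  attr(out, "sweep") <- threshold_sweep(out$p_co, sweep_thresholds)
  out
}

#' Count pairs below a grid of p-value thresholds
#'
#' @param p numeric vector of p-values.
#' @param thresholds p-value cutoffs (strict `<`).
#' @return data.frame with columns `threshold`, `count`, `proportion`.
#' @export
threshold_sweep <- function(p, thresholds = 10^seq(-7, -2)) {
  counts <- vapply(thresholds, function(t) sum(p < t), integer(1))
  data.frame(threshold = thresholds, count = counts,
             proportion = counts / length(p))
}

#' Conditional exclusivity of a site pair
#'
#' Among conditions where at least one of the two sites is modified, the
#' fraction where exactly one is. Used to probe presumed mutually exclusive
#' (hetero-functional) pairs: marginally such pairs rarely show negative
#' correlation because in most conditions neither site is modified.
#'
#' @param status_a,status_b equal-length 0/1 vectors.
#' @return `(n10 + n01) / (n11 + n10 + n01)`, or `NA` (with a warning) when no
#'   condition has either site modified.
#' @export
conditional_exclusivity <- function(status_a, status_b) {
  tab <- build_contingency(status_a, status_b)
  denom <- tab[["n11"]] + tab[["n10"]] + tab[["n01"]]
  if (denom == 0L) {
    warning("conditional exclusivity undefined: neither site is ever modified")
    return(NA_real_)
  }
  (tab[["n10"]] + tab[["n01"]]) / denom
}

#' Write a pair-level co-occurrence result table as TSV
#'
#' @param results data.frame from [scan_pairs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cooccurrence <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
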