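#' Read long-format site annotations
#'
#' @param path TSV with header and columns `site_id`, `category`
#'   (e.g. `process`, `function`, `kinase`), `term`.
#' @return data.frame with those columns, whitespace-trimmed, case preserved
#'   for display but matched case-insensitively by the scoring functions.
#' @export
read_site_annotations <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("site_id", "category", "term") %in% names(df)))
  df$term <- trimws(df$term)
  if (any(!nzchar(df$term))) stop("annotation terms must be non-empty")
  df
}

#' Read site functional-class assignments
#'
#' @param path TSV with header and columns `site_id`, `class` (one of
#'   `activate`, `inhibit`, `dual`).
#' @return data.frame.
#' @export
read_site_classes <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("site_id", "class") %in% names(df)))
  bad <- setdiff(unique(df$class), c("activate", "inhibit", "dual"))
  if (length(bad)) stop("unknown functional class: ", paste(bad, collapse = ", "))
  df
}

.normalize_term <- function(term) tolower(trimws(term))

#' Term frequencies over an annotation corpus
#'
#' The frequency F(term) of a term is the fraction of annotated sites carrying
#' it, computed over the loaded corpus (optionally within one category). Rare
#' terms are the most informative, and the sharing score weights a match by
#' 1/F.
#'
#' @param annotations long-format data.frame (see [read_site_annotations()]).
#' @param category optionally restrict to one category before counting.
#' @return named numeric vector of frequencies in (0, 1], keyed by normalized
#'   term.
#' @export
term_frequency_table <- function(annotations, category = NULL) {
  if (!is.null(category))
    annotations <- annotations[annotations$category == category, , drop = FALSE]
  if (!nrow(annotations)) stop("no annotations to count")
  ann <- unique(data.frame(site_id = annotations$site_id,
                           term = .normalize_term(annotations$term)))
  n_sites <- length(unique(ann$site_id))
  counts <- table(ann$term)
  setNames(as.numeric(counts) / n_sites, names(counts))
}

#' Information-content weighted annotation sharing score
#'
#' For term sets A and B of two sites, the score is
#' `1/(N_A N_B) * sum over (i, j) of [A_i == B_j] / F(A_i)`: every matching
#' term pair contributes the reciprocal of the term's corpus frequency, and
#' the double sum is averaged over all term pairs. Zero iff the sets are
#' disjoint; rarer shared terms contribute more; unmatched terms dilute.
#'
#' @param terms_a,terms_b character vectors of terms (duplicates removed after
#'   normalization).
#' @param freqs [term_frequency_table()] covering every term in the sets.
#' @return nonnegative score, or `NA` when either set is empty (such pairs
#'   are excluded from comparisons, mirroring "both sites annotated").
#' @export
sharing_score <- function(terms_a, terms_b, freqs) {
  a <- unique(.normalize_term(terms_a))
  b <- unique(.normalize_term(terms_b))
  a <- a[nzchar(a)]; b <- b[nzchar(b)]
  if (!length(a) || !length(b)) return(NA_real_)
  miss <- setdiff(c(a, b), names(freqs))
  if (length(miss))
    stop("terms missing from the frequency table: ",
         paste(head(miss, 3), collapse = ", "))
  shared <- intersect(a, b)
  sum(1 / freqs[shared]) / (length(a) * length(b))
}

#' Kinase sharing between two sites
#'
#' Reuses the annotation sharing score with kinases as terms, plus a plain
#' boolean intersection test.
#'
#' @param kinases_a,kinases_b character vectors of kinase names per site.
#' @param freqs kinase [term_frequency_table()].
#' @return list with `shares_any` (logical, `NA` if either set empty) and
#'   `score` (see [sharing_score()]).
#' @export
kinase_sharing <- function(kinases_a, kinases_b, freqs) {
  a <- unique(.normalize_term(kinases_a))
  b <- unique(.normalize_term(kinases_b))
  if (!length(a) || !length(b))
    return(list(shares_any = NA, score = NA_real_))
  list(shares_any = length(intersect(a, b)) > 0L,
       score = sharing_score(a, b, freqs))
}

#' Classify a same-protein site pair as homo- or hetero-functional
#'
#' A homo-functional pair has the same curated functional class and shares at
#' least one annotation term; a hetero-functional pair has different classes
#' and no shared term. Everything else (including pairs with a missing class)
#' is `"neither"`. Homo-functional pairs are enriched for true functional
#' association; hetero-functional pairs serve as the negative set.
#'
#' @param class_a,class_b functional classes (`activate`/`inhibit`/`dual`, or
#'   `NA` when uncurated).
#' @param terms_a,terms_b annotation term vectors (the union of process and
#'   function terms by default usage).
#' @return `"homo"`, `"hetero"` or `"neither"`.
#' @export
classify_functional_pair <- function(class_a, class_b, terms_a, terms_b) {
  if (is.na(class_a) || is.na(class_b)) return("neither")
  shared <- length(intersect(unique(.normalize_term(terms_a)),
                             unique(.normalize_term(terms_b)))) > 0L
  if (class_a == class_b && shared) return("homo")
  if (class_a != class_b && !shared) return("hetero")
  "neither"
}
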