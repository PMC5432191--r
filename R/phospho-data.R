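#' @importFrom stats median rbinom rpois runif setNames
#' @importFrom utils combn read.delim write.table head
NULL

#' Site identifier strings
#'
#' A phosphosite is identified by its protein accession and 1-based residue
#' position, joined as `"<protein>:<position>"`. Positions follow UniProt
#' residue numbering.
#'
#' @param protein character vector of protein accessions.
#' @param position integer vector of 1-based residue positions.
#' @return character vector of site ids.
#' @export
site_id <- function(protein, position) {
  paste0(protein, ":", position)
}

#' Construct a phosphosite-by-condition binary matrix
#'
#' The central observable of the co-occurrence analysis: for each phosphosite
#' (an S/T/Y residue of a protein) a 0/1 modification status under each of a
#' set of laboratory or physiological conditions. Status 0 means "not detected
#' under that condition" and is treated as unmodified; no imputation is
#' performed.
#'
#' @param sites data.frame with columns `protein`, `position`, `residue`
#'   (one of S, T, Y).
#' @param status numeric/integer matrix of 0/1 entries, one row per site in
#'   `sites` order, one column per condition.
#' @param conditions character vector of unique condition labels; defaults to
#'   `colnames(status)`.
#' @param require_observed if `TRUE` (the default for data read from disk),
#'   every site must be modified under at least one condition ("potential
#'   phosphosite"). Permutation replicates may legitimately contain all-zero
#'   rows and are built with `require_observed = FALSE`.
#' @return object of class `phospho_matrix`: a list with elements `sites`
#'   (data.frame with an added `site_id` column) and `status` (integer matrix
#'   with site ids as rownames and conditions as colnames). Sites are
#'   canonicalized to protein-lexicographic, then position-ascending order.
#' @export
phospho_matrix <- function(sites, status, conditions = colnames(status),
                           require_observed = TRUE) {
  stopifnot(is.data.frame(sites),
            all(c("protein", "position", "residue") %in% names(sites)))
  status <- as.matrix(status)
  if (nrow(status) != nrow(sites))
    stop("status has ", nrow(status), " rows but sites has ", nrow(sites))
  if (is.null(conditions)) conditions <- paste0("cond_", seq_len(ncol(status)))
  if (length(conditions) != ncol(status))
    stop("length(conditions) != ncol(status)")
  if (anyDuplicated(conditions))
    stop("condition labels must be unique")
  if (!all(status %in% c(0L, 1L)))
    stop("status entries must all be 0 or 1")
  if (!all(sites$residue %in% c("S", "T", "Y")))
    stop("residues must be one of S, T, Y")
  if (any(sites$position < 1L))
    stop("positions are 1-based and must be >= 1")
  ids <- site_id(sites$protein, sites$position)
  if (anyDuplicated(ids))
    stop("duplicate site key(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (require_observed && any(rowSums(status) == 0))
    stop("every site must be observed (status 1) in at least one condition")

  ord <- order(sites$protein, sites$position)
  sites <- sites[ord, , drop = FALSE]
  status <- status[ord, , drop = FALSE]
  ids <- ids[ord]
  sites$site_id <- ids
  rownames(sites) <- NULL
  storage.mode(status) <- "integer"
  dimnames(status) <- list(ids, conditions)
  structure(list(sites = sites, status = status), class = "phospho_matrix")
}

#' @export
print.phospho_matrix <- function(x, ...) {
  cat("phospho_matrix: ", nrow(x$status), " sites in ",
      length(unique(x$sites$protein)), " proteins x ",
      ncol(x$status), " conditions\n", sep = "")
  cat("  modified entries: ", sum(x$status), " (",
      sprintf("%.1f%%", 100 * mean(x$status)), ")\n", sep = "")
  invisible(x)
}

#' @export
dim.phospho_matrix <- function(x) dim(x$status)

#' Read a phosphosite-by-condition matrix from TSV
#'
#' Expected layout: a header row `protein  position  residue  <cond_1> ...`,
#' then one row per site with 0/1 status values.
#'
#' @param path file path.
#' @return a [phospho_matrix()].
#' @export
read_phospho_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 4L ||
      !identical(header[1:3], c("protein", "position", "residue")))
    stop("malformed header: expected 'protein\\tposition\\tresidue\\t<conditions...>'")
  conditions <- header[-(1:3)]
  lines <- readLines(path)[-1L]
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != length(header))
  if (length(bad))
    stop("malformed row length at line ", bad[1] + 1L, ": expected ",
         length(header), " fields, got ", nf[bad[1]])
  m <- matrix(unlist(fields), ncol = length(header), byrow = TRUE)
  vals <- m[, -(1:3), drop = FALSE]
  if (!all(vals %in% c("0", "1"))) {
    off <- which(!(vals %in% c("0", "1")))[1]
    stop("non-binary status entry '", vals[off], "' (line ",
         ((off - 1L) %% nrow(vals)) + 2L, ")")
  }
  status <- matrix(as.integer(vals), nrow = nrow(m))
  colnames(status) <- conditions
  sites <- data.frame(protein = m[, 1],
                      position = as.integer(m[, 2]),
                      residue = m[, 3],
                      stringsAsFactors = FALSE)
  phospho_matrix(sites, status, conditions)
}

#' Write a phosphosite-by-condition matrix as TSV
#'
#' @param x a [phospho_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_phospho_matrix <- function(x, path) {
  df <- cbind(x$sites[, c("protein", "position", "residue")],
              as.data.frame(x$status, check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Keep high-frequency phosphosites
#'
#' Sites phosphorylated in fewer than `min_conditions` conditions cannot reach
#' the significance levels used to call co-occurrence and are removed before
#' pair testing. The default keeps sites modified in at least 3
#' conditions.
#'
#' @param x a [phospho_matrix()].
#' @param min_conditions minimum number of conditions (inclusive) in which a
#'   site must be modified; default 3.
#' @return the filtered [phospho_matrix()] (condition set unchanged).
#' @export
filter_high_frequency <- function(x, min_conditions = 3L) {
  stopifnot(inherits(x, "phospho_matrix"), min_conditions >= 1L)
  keep <- rowSums(x$status) >= min_conditions
  if (!any(keep))
    warning("no sites pass the high-frequency filter (min_conditions = ",
            min_conditions, ")")
  structure(list(sites = x$sites[keep, , drop = FALSE],
                 status = x$status[keep, , drop = FALSE]),
            class = "phospho_matrix")
}

#' Enumerate all within-protein site pairs
#'
#' For each protein with k sites emits the k(k-1)/2 unordered pairs, ordered
#' deterministically by protein accession and then ascending positions.
#'
#' @param x a (typically frequency-filtered) [phospho_matrix()].
#' @return data.frame with columns `site1`, `site2`, `protein`.
#' @export
enumerate_within_protein_pairs <- function(x) {
  stopifnot(inherits(x, "phospho_matrix"))
  by_prot <- split(x$sites$site_id, x$sites$protein)
  by_prot <- by_prot[lengths(by_prot) >= 2L]
  if (!length(by_prot))
    return(data.frame(site1 = character(), site2 = character(),
                      protein = character(), stringsAsFactors = FALSE))
  out <- lapply(names(by_prot), function(p) {
    ids <- by_prot[[p]]          # already position-ascending (canonical order)
    idx <- combn(length(ids), 2L)
    data.frame(site1 = ids[idx[1, ]], site2 = ids[idx[2, ]], protein = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Read a two-column protein-pair list
#'
#' @param path TSV with two columns of protein accessions (no header by
#'   default).
#' @param source tag describing the pair provenance, e.g. `"PPI"`,
#'   `"kinase-substrate"` or `"complex"`.
#' @param header does the file carry a header row?
#' @param allow_self keep self-pairs? Default drops them.
#' @return data.frame with columns `protein1`, `protein2` (lexicographically
#'   ordered within pair), deduplicated, with a `source` attribute.
#' @export
read_protein_pairs <- function(path, source = "PPI", header = FALSE,
                               allow_self = FALSE) {
  df <- read.delim(path, header = header, stringsAsFactors = FALSE)
  protein_pair_list(df[[1]], df[[2]], source = source, allow_self = allow_self)
}

#' Build a deduplicated protein-pair list
#'
#' @param protein1,protein2 character vectors of accessions.
#' @inheritParams read_protein_pairs
#' @return see [read_protein_pairs()].
#' @export
protein_pair_list <- function(protein1, protein2, source = "PPI",
                              allow_self = FALSE) {
  a <- pmin(protein1, protein2)
  b <- pmax(protein1, protein2)
  keep <- if (allow_self) rep(TRUE, length(a)) else a != b
  df <- unique(data.frame(protein1 = a[keep], protein2 = b[keep],
                          stringsAsFactors = FALSE))
  rownames(df) <- NULL
  attr(df, "source") <- source
  df
}

#' Enumerate site pairs between interacting proteins
#'
#' For each protein pair (A, B) in `pairs`, emits every cross pair (site in A,
#' site in B). Within-protein combinations are never emitted. Protein pairs
#' with a member absent from the matrix are skipped and counted.
#'
#' @param x a (frequency-filtered) [phospho_matrix()].
#' @param pairs a [protein_pair_list()] data.frame.
#' @return data.frame with columns `site1`, `site2`, `protein1`, `protein2`;
#'   attribute `n_skipped` counts protein pairs dropped for missing proteins.
#' @export
enumerate_between_protein_pairs <- function(x, pairs) {
  stopifnot(inherits(x, "phospho_matrix"))
  by_prot <- split(x$sites$site_id, x$sites$protein)
  present <- pairs$protein1 %in% names(by_prot) &
    pairs$protein2 %in% names(by_prot) & pairs$protein1 != pairs$protein2
  n_skipped <- sum(!present)
  use <- pairs[present, , drop = FALSE]
  out <- if (nrow(use)) {
    do.call(rbind, lapply(seq_len(nrow(use)), function(i) {
      s1 <- by_prot[[use$protein1[i]]]
      s2 <- by_prot[[use$protein2[i]]]
      expand.grid(site1 = s1, site2 = s2, KEEP.OUT.ATTRS = FALSE,
                  stringsAsFactors = FALSE)[, c("site1", "site2")] |>
        cbind(protein1 = use$protein1[i], protein2 = use$protein2[i])
    }))
  } else {
    data.frame(site1 = character(), site2 = character(),
               protein1 = character(), protein2 = character(),
               stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Read a precomputed ortholog site map
#'
#' Five-column TSV `protein1  position1  protein2  position2  confidence`
#' derived from pairwise alignments of 1-to-1 orthologs. Rows with ortholog
#' confidence not exceeding `min_confidence` are dropped (the default keeps only
#' 1-to-1 orthologs with confidence > 0.9).
#'
#' @param path file path (header row expected).
#' @param min_confidence strict lower bound on the per-protein-pair ortholog
#'   confidence; default 0.9.
#' @return data.frame with columns `site1` (source species site id), `site2`
#'   (target species site id), `confidence`.
#' @export
read_ortholog_map <- function(path, min_confidence = 0.9) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(ncol(df) >= 5L)
  names(df)[1:5] <- c("protein1", "position1", "protein2", "position2",
                      "confidence")
  ortholog_site_map(df, min_confidence = min_confidence)
}

#' Validate an ortholog site map
#'
#' @param map data.frame with columns `protein1`, `position1`, `protein2`,
#'   `position2`, `confidence`.
#' @inheritParams read_ortholog_map
#' @return data.frame with `site1`, `site2`, `confidence`; mapping is enforced
#'   1-to-1 per site.
#' @export
ortholog_site_map <- function(map, min_confidence = 0.9) {
  map <- map[map$confidence > min_confidence, , drop = FALSE]
  out <- data.frame(site1 = site_id(map$protein1, map$position1),
                    site2 = site_id(map$protein2, map$position2),
                    confidence = map$confidence, stringsAsFactors = FALSE)
  if (anyDuplicated(out$site1) || anyDuplicated(out$site2))
    stop("ortholog site map must be 1-to-1 per site")
  rownames(out) <- NULL
  out
}

#' Map site pairs to orthologous sites in a second species
#'
#' A pair survives only if both sites map through `map` and both mapped sites
#' are present (i.e. high-frequency) in the second-species matrix. Unmapped
#' pairs are dropped and counted.
#'
#' @param pairs data.frame with columns `site1`, `site2` (source species).
#' @param map an [ortholog_site_map()].
#' @param matrix2 the second-species [phospho_matrix()], already
#'   frequency-filtered.
#' @return data.frame of mapped pairs with columns `site1`, `site2` (target
#'   species ids) plus the originating `src_site1`, `src_site2`; attributes
#'   `n_unmapped` and `n_low_frequency` count dropped pairs.
#' @export
map_orthologous_pairs <- function(pairs, map, matrix2) {
  stopifnot(inherits(matrix2, "phospho_matrix"))
  lut <- setNames(map$site2, map$site1)
  t1 <- lut[pairs$site1]
  t2 <- lut[pairs$site2]
  mapped <- !is.na(t1) & !is.na(t2)
  ok <- mapped & t1 %in% rownames(matrix2$status) &
    t2 %in% rownames(matrix2$status)
  out <- data.frame(site1 = unname(t1[ok]), site2 = unname(t2[ok]),
                    src_site1 = pairs$site1[ok], src_site2 = pairs$site2[ok],
                    stringsAsFactors = FALSE)
  attr(out, "n_unmapped") <- sum(!mapped)
  attr(out, "n_low_frequency") <- sum(mapped) - sum(ok)
  out
}

#' Check stated residues against protein sequences
#'
#' @param x a [phospho_matrix()].
#' @param sequences named character vector (or `AAStringSet`) of protein
#'   sequences keyed by accession.
#' @return invisibly `TRUE`; stops naming the first mismatching site.
#' @export
check_sites_against_sequences <- function(x, sequences) {
  sequences <- as_sequence_vector(sequences)
  have <- x$sites$protein %in% names(sequences)
  s <- x$sites[have, , drop = FALSE]
  actual <- substring(sequences[s$protein], s$position, s$position)
  bad <- which(actual != s$residue)
  if (length(bad))
    stop("residue mismatch at ", s$site_id[bad[1]], ": annotated ",
         s$residue[bad[1]], ", sequence has ", actual[bad[1]])
  invisible(TRUE)
}

# Accept either a named character vector or a Biostrings AAStringSet.
as_sequence_vector <- function(sequences) {
  if (methods::is(sequences, "XStringSet"))
    sequences <- setNames(as.character(sequences), names(sequences))
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  sequences
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file keyed by accession.
#' @return named character vector of amino-acid sequences.
#' @export
read_protein_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  setNames(as.character(seqs), names(seqs))
}
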