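#' The 20-letter amino-acid alphabet of the motif models
#'
#' Windows running past a protein terminus are padded with `"-"`, which is
#' score-neutral.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
PAD_SYMBOL <- "-"

#' Extract the 15-residue sequence context of a phosphosite
#'
#' Positions `position - 7 .. position + 7` of the protein sequence; the
#' phospho-acceptor sits at window position 8. Positions beyond either
#' terminus are filled with the padding symbol `"-"`, which scores 0, so
#' terminal sites remain scorable.
#'
#' @param sequence protein sequence (single string).
#' @param position 1-based residue position, the window center.
#' @param flank residues on each side; default 7 (window length 15).
#' @return character vector of `2 * flank + 1` symbols, with attribute
#'   `center_ok` flagging whether the center residue is S/T/Y (a curated site
#'   may disagree with the sequence version in hand; this is a warning, not an
#'   error).
#' @export
extract_window <- function(sequence, position, flank = 7L) {
  n <- nchar(sequence)
  if (position < 1L || position > n)
    stop("position ", position, " outside sequence of length ", n)
  idx <- (position - flank):(position + flank)
  chars <- rep(PAD_SYMBOL, length(idx))
  inside <- idx >= 1L & idx <= n
  chars[inside] <- substring(sequence, idx[inside], idx[inside])
  center_ok <- chars[flank + 1L] %in% c("S", "T", "Y")
  if (!center_ok)
    warning("window center at position ", position, " is '",
            chars[flank + 1L], "', not S/T/Y")
  structure(chars, center_ok = center_ok)
}

#' Extract windows for a table of sites
#'
#' @param sequences named character vector of protein sequences.
#' @param sites data.frame with columns `protein`, `position`.
#' @inheritParams extract_window
#' @return character matrix, one row per site, `2 * flank + 1` columns.
#' @export
extract_windows <- function(sequences, sites, flank = 7L) {
  sequences <- as_sequence_vector(sequences)
  out <- t(vapply(seq_len(nrow(sites)), function(i) {
    suppressWarnings(
      as.character(extract_window(sequences[[sites$protein[i]]],
                                  sites$position[i], flank)))
  }, character(2L * flank + 1L)))
  rownames(out) <- site_id(sites$protein, sites$position)
  out
}

#' All S/T/Y-centered windows of a proteome (background set)
#'
#' @param sequences named character vector of protein sequences.
#' @inheritParams extract_window
#' @return character matrix of windows centered on every S, T or Y residue.
#' @export
proteome_sty_windows <- function(sequences, flank = 7L) {
  sequences <- as_sequence_vector(sequences)
  sites <- do.call(rbind, lapply(names(sequences), function(p) {
    pos <- which(strsplit(sequences[[p]], "")[[1]] %in% c("S", "T", "Y"))
    if (!length(pos)) return(NULL)
    data.frame(protein = p, position = pos, stringsAsFactors = FALSE)
  }))
  extract_windows(sequences, sites, flank)
}

# Positional amino-acid counts of a window set: 20 x width integer matrix.
# Padding and non-standard symbols are not counted; each position's
# frequencies are later normalized over the symbols actually counted.
position_counts <- function(windows) {
  stopifnot(is.matrix(windows))
  counts <- vapply(seq_len(ncol(windows)), function(j)
    table(factor(windows[, j], levels = AA_ALPHABET)),
    integer(length(AA_ALPHABET)))
  dimnames(counts) <- list(AA_ALPHABET, NULL)
  counts
}

#' Train a kinase position-weight-matrix motif model
#'
#' Log2-odds of positional amino-acid frequencies in the kinase's substrate
#' windows (foreground) against all S/T/Y-centered windows of the proteome
#' (background): `M[k, j] = log2(q[k, j] / b[k, j])`. A pseudocount is added
#' per amino acid per position to both sets so every entry is finite. The
#' background is positional, so the center column's background mass sits on
#' S/T/Y.
#'
#' @param kinase kinase name.
#' @param foreground_windows character matrix of substrate windows (rows).
#' @param background_windows character matrix of proteome background windows,
#'   or a precomputed 20 x width count matrix from `position_counts`.
#' @param pseudocount added to every count cell; default 0.5.
#' @param min_substrates minimum foreground windows; models are trained only
#'   for kinases with enough known substrates (default 50).
#' @return object of class `kinase_pwm`: list with `kinase`, `M` (20 x width
#'   log2-odds matrix), `n_substrates`, `cutoff` (`NA` until
#'   [calibrate_cutoff()]).
#' @export
build_pwm <- function(kinase, foreground_windows, background_windows,
                      pseudocount = 0.5, min_substrates = 50L) {
  if (nrow(foreground_windows) < min_substrates)
    stop("kinase ", kinase, " has ", nrow(foreground_windows),
         " substrate windows; ", min_substrates, " required")
  fg <- position_counts(foreground_windows) + pseudocount
  bg <- if (is.numeric(background_windows)) background_windows + pseudocount
        else position_counts(background_windows) + pseudocount
  stopifnot(identical(dim(fg), dim(bg)))
  q <- sweep(fg, 2L, colSums(fg), "/")
  b <- sweep(bg, 2L, colSums(bg), "/")
  M <- log2(q / b)
  stopifnot(all(is.finite(M)))
  structure(list(kinase = kinase, M = M,
                 n_substrates = nrow(foreground_windows), cutoff = NA_real_),
            class = "kinase_pwm")
}

#' @export
print.kinase_pwm <- function(x, ...) {
  cat("kinase_pwm '", x$kinase, "': ", nrow(x$M), " x ", ncol(x$M),
      " log2-odds, ", x$n_substrates, " training substrates, cutoff = ",
      format(x$cutoff, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Score a sequence window against a kinase motif model
#'
#' `Score = sum over j of M[s_j, j]`, the sum of the 15 positional log2-odds
#' entries for the window's residues. Padding and unknown symbols (X, U, ...)
#' contribute 0.
#'
#' @param model a [build_pwm()] model.
#' @param window character vector (one window) or matrix (one row per window)
#'   of the model's width.
#' @return numeric score(s).
#' @export
score_window <- function(model, window) {
  stopifnot(inherits(model, "kinase_pwm"))
  if (!is.matrix(window)) window <- matrix(window, nrow = 1L)
  stopifnot(ncol(window) == ncol(model$M))
  scores <- numeric(nrow(window))
  for (j in seq_len(ncol(window))) {
    row <- match(window[, j], AA_ALPHABET)
    known <- !is.na(row)
    scores[known] <- scores[known] + model$M[cbind(row[known], j)]
  }
  scores
}

#' Calibrate a kinase model's prediction cutoff
#'
#' Scores the kinase's own training substrates and takes the median as the
#' cutoff (for an even count, the mean of the central pair). By construction
#' about half the training substrates score at or above the cutoff.
#'
#' @param model a [build_pwm()] model.
#' @param training_windows the kinase's substrate window matrix.
#' @return the model with `cutoff` set.
#' @export
calibrate_cutoff <- function(model, training_windows) {
  model$cutoff <- median(score_window(model, training_windows))
  model
}

#' Predict the catalytic kinases of a phosphosite
#'
#' A site is predicted as a substrate of every kinase whose PWM score for the
#' site's window strictly exceeds that kinase's median-score cutoff; one site
#' can therefore be assigned multiple kinases (or none).
#'
#' @param window a single sequence window (character vector).
#' @param models list of calibrated [kinase_pwm] models.
#' @return character vector of predicted kinase names (possibly empty).
#' @export
predict_kinases <- function(window, models) {
  if (!length(models)) return(character(0))
  hits <- vapply(models, function(m) {
    stopifnot(!is.na(m$cutoff))
    score_window(m, window) > m$cutoff
  }, logical(1))
  vapply(models[hits], `[[`, character(1), "kinase")
}
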