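# Per-column conservation statistics for clade alignments: residue
# frequencies, Shannon information content in bits (sequence-logo stack
# height), gap tracking, consensus calls.

# Character matrix view of an MSA (rows = sequences, columns = positions).
msa_matrix <- function(msa) {
  m <- do.call(rbind, strsplit(msa$sequence, "", fixed = TRUE))
  rownames(m) <- msa$id
  m
}

column_profile_from_letters <- function(letters) {
  n_rows <- length(letters)
  gaps <- sum(letters == "-")
  counted <- letters[letters %in% AA20]
  n_eff <- length(counted)
  freqs <- stats::setNames(numeric(20), AA20)
  consensus <- NA_character_
  if (n_eff > 0) {
    tab <- table(factor(counted, levels = AA20))
    freqs[] <- as.numeric(tab) / n_eff
    # max-frequency residue; ties broken alphabetically (AA20 is sorted)
    consensus <- AA20[which.max(freqs)]
  }
  structure(list(frequencies = freqs,
                 gap_fraction = gaps / n_rows,
                 n_effective = n_eff,
                 consensus = consensus),
            class = "column_profile")
}

#' Residue frequencies for one alignment column
#'
#' Frequencies are computed over the 20 canonical residues only: gaps are
#' tracked separately as `gap_fraction`, and the ambiguity letters X/B/Z/U are
#' treated as missing (they contribute to neither frequencies nor gaps). The
#' consensus is the max-frequency residue with alphabetical tie-break, or `NA`
#' when no canonical residue is observed.
#'
#' @param msa A `protein_msa` (see [read_fasta()] with `aligned = TRUE`).
#' @param col 1-based column index.
#' @return A `column_profile`: list with `frequencies` (named over the 20
#'   canonical residues, summing to 1 when any residue is observed),
#'   `gap_fraction`, `n_effective`, `consensus`.
#' @export
column_frequencies <- function(msa, col) {
  n_cols <- attr(msa, "n_columns")
  if (is.null(n_cols)) msa <- as_protein_msa(msa)
  n_cols <- attr(msa, "n_columns")
  if (length(col) != 1 || col < 1 || col > n_cols)
    stop("column index out of range: ", col, " (alignment has ", n_cols,
         " columns)")
  column_profile_from_letters(substring(msa$sequence, col, col))
}

#' Information content of a column, in bits
#'
#' The sequence-logo statistic `R = log2(20) - H`, with `H` the Shannon
#' entropy of the observed residue frequencies. Returns 0 for columns with no
#' observed canonical residue. With `correction = TRUE` the small-sample
#' correction `e(n) = 19 / (2 ln(2) n)` is subtracted (floored at 0).
#'
#' @param profile A `column_profile` or a numeric frequency vector.
#' @param correction Apply the small-sample correction (default `FALSE`).
#' @return Information content in bits, in `[0, log2(20)]`.
#' @export
information_content <- function(profile, correction = FALSE) {
  if (inherits(profile, "column_profile")) {
    freqs <- profile$frequencies
    n <- profile$n_effective
  } else {
    freqs <- profile
    n <- attr(profile, "n_effective")
  }
  if (!is.null(n) && n == 0) return(0)
  p <- freqs[freqs > 0]
  if (length(p) == 0) return(0)
  h <- -sum(p * log2(p))
  r <- log2(20) - h
  if (correction) {
    if (is.null(n)) stop("n_effective required for the small-sample correction")
    r <- max(0, r - 19 / (2 * log(2) * n))
  }
  r
}

#' Conservation profile of a clade alignment
#'
#' One [column_frequencies()] profile per column plus per-column information
#' content. Columns with `gap_fraction > 0.5` are retained but flagged
#' low-confidence (mirroring removal of unreliably aligned columns without
#' re-scoring the alignment).
#'
#' @param msa A `protein_msa` with at least 2 rows.
#' @param clade Clade label carried into the profile.
#' @param correction Small-sample correction for information content.
#' @return An object of class `conservation_profile`: list with `clade`,
#'   `frequencies` (20 x n_columns matrix), `gap_fraction`, `n_effective`,
#'   `consensus`, `information` (bits), `low_confidence` (logical).
#' @export
profile_msa <- function(msa, clade = "clade", correction = FALSE) {
  if (!inherits(msa, "protein_msa")) msa <- as_protein_msa(msa)
  if (nrow(msa) < 2) stop("profile requires >=2 sequences")
  m <- msa_matrix(msa)
  n_cols <- ncol(m)
  n_rows <- nrow(m)
  freqs <- matrix(0, nrow = 20, ncol = n_cols, dimnames = list(AA20, NULL))
  gap_fraction <- colMeans(m == "-")
  canonical <- matrix(m %in% AA20, nrow = n_rows)
  n_effective <- colSums(canonical)
  for (j in seq_len(n_cols)) {
    counted <- m[canonical[, j], j]
    if (length(counted) > 0)
      freqs[, j] <- as.numeric(table(factor(counted, levels = AA20))) /
        length(counted)
  }
  consensus <- ifelse(n_effective > 0, AA20[apply(freqs, 2, which.max)],
                      NA_character_)
  information <- vapply(seq_len(n_cols), function(j) {
    f <- freqs[, j]
    attr(f, "n_effective") <- n_effective[j]
    information_content(f, correction = correction)
  }, numeric(1))
  structure(list(clade = clade, frequencies = freqs,
                 gap_fraction = gap_fraction, n_effective = n_effective,
                 consensus = consensus, information = information,
                 low_confidence = gap_fraction > 0.5,
                 n_sequences = n_rows),
            class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat("Conservation profile for clade '", x$clade, "': ",
      length(x$information), " columns from ", x$n_sequences,
      " sequences\n", sep = "")
  cat(sprintf("  mean IC %.3f bits; %d low-confidence columns (gap fraction > 0.5)\n",
              mean(x$information), sum(x$low_confidence)))
  invisible(x)
}

#' @export
summary.conservation_profile <- function(object, ...) {
  top <- order(object$information, decreasing = TRUE)[
    seq_len(min(10, length(object$information)))]
  data.frame(column = top,
             consensus = object$consensus[top],
             information = object$information[top],
             gap_fraction = object$gap_fraction[top])
}

#' Plot per-column information content
#'
#' @param x A `conservation_profile`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.conservation_profile <- function(x, ...) {
  graphics::plot(seq_along(x$information), x$information, type = "h",
                 xlab = "alignment column", ylab = "information (bits)",
                 main = paste("Conservation:", x$clade),
                 ylim = c(0, log2(20)), ...)
  graphics::abline(h = log2(20), lty = 3)
  invisible(x)
}

#' Export logo data for external plotting
#'
#' Writes one row per alignment column: column index, per-residue frequency,
#' number of counted residues, gap fraction, information content, and the
#' low-confidence flag.
#'
#' @param profile A `conservation_profile`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
export_logo_data <- function(profile, path) {
  if (!inherits(profile, "conservation_profile"))
    stop("profile must be a conservation_profile")
  n <- length(profile$information)
  if (n == 0) stop("empty profile")
  df <- data.frame(column = seq_len(n), t(profile$frequencies),
                   n_effective = profile$n_effective,
                   gap_fraction = profile$gap_fraction,
                   information = profile$information,
                   low_confidence = profile$low_confidence)
  utils::write.table(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read logo data written by [export_logo_data()]
#'
#' @param path TSV path.
#' @return Data frame with the exported columns.
#' @export
read_logo_data <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
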