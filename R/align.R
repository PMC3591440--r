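# Pairwise global alignment against the NOX2 reference and derived
# position maps, so signature positions (NOX2 numbering) can be read from
# any homolog. A Kyte-Doolittle hydropathy scan provides transmembrane
# context for reporting (never used for classification).

#' Affine-gap scoring scheme
#'
#' Substitution scores come from the named matrix (BLOSUM62 by default, taken
#' from Biostrings) restricted to the 20 canonical residues; the ambiguity
#' letters X/B/Z/U score 0 against everything. A gap of length L costs
#' `gap_open + L * gap_extend`.
#'
#' @param matrix Name of a substitution matrix shipped with Biostrings.
#' @param gap_open,gap_extend Positive gap costs, `gap_extend <= gap_open`.
#' @return A `scoring_scheme`: list with the extended `matrix`, `gap_open`,
#'   `gap_extend`.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 11,
                           gap_extend = 1) {
  if (gap_open <= 0 || gap_extend <= 0) stop("gap costs must be positive")
  if (gap_extend > gap_open) stop("gap_extend must be <= gap_open")
  base <- get(utils::data(list = matrix, package = "Biostrings",
                          envir = environment()))
  letters <- c(AA20, AA_AMBIGUOUS)
  mat <- matrix(0L, nrow = length(letters), ncol = length(letters),
                dimnames = list(letters, letters))
  mat[AA20, AA20] <- base[AA20, AA20]
  structure(list(matrix = mat, gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

check_alignable <- function(seq, what) {
  if (length(seq) != 1 || is.na(seq) || nchar(seq) == 0)
    stop(what, " sequence must be non-empty")
  seq <- toupper(seq)
  letters <- unique(strsplit(seq, "", fixed = TRUE)[[1]])
  bad <- setdiff(letters, c(AA20, AA_AMBIGUOUS))
  if (length(bad) > 0)
    stop(what, " sequence contains unalignable letters: ",
         paste(bad, collapse = ", "), " (degap first)")
  seq
}

#' Needleman-Wunsch global alignment with affine gaps
#'
#' Optimal global alignment under the given [scoring_scheme()]; the alignment
#' engine is `Biostrings::pairwiseAlignment` with a deterministic traceback.
#'
#' @param query,ref Ungapped amino-acid strings.
#' @param scheme A [scoring_scheme()].
#' @return A `pairwise_alignment`: list with `aligned_query`, `aligned_ref`
#'   (equal-length gapped strings) and `score`.
#' @export
global_align <- function(query, ref, scheme = scoring_scheme()) {
  query <- check_alignable(query, "query")
  ref <- check_alignable(ref, "reference")
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(query),
    subject = Biostrings::AAString(ref),
    type = "global", substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
  out <- list(aligned_query = as.character(Biostrings::alignedPattern(aln)),
              aligned_ref = as.character(Biostrings::alignedSubject(aln)),
              score = Biostrings::score(aln))
  stopifnot(nchar(out$aligned_query) == nchar(out$aligned_ref))
  class(out) <- "pairwise_alignment"
  out
}

# One vectorized pairwiseAlignment call for many queries vs one reference.
global_align_many <- function(queries, ref, scheme = scoring_scheme()) {
  queries <- vapply(queries, check_alignable, character(1), what = "query")
  ref <- check_alignable(ref, "reference")
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(unname(queries)),
    subject = Biostrings::AAString(ref),
    type = "global", substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
  ap <- as.character(Biostrings::alignedPattern(aln))
  as_ <- as.character(Biostrings::alignedSubject(aln))
  sc <- Biostrings::score(aln)
  lapply(seq_along(queries), function(i)
    structure(list(aligned_query = ap[i], aligned_ref = as_[i],
                   score = sc[i]), class = "pairwise_alignment"))
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("Global alignment, score ", x$score, "\n", sep = "")
  cat("  query: ", substr(x$aligned_query, 1, 60),
      if (nchar(x$aligned_query) > 60) "..." else "", "\n", sep = "")
  cat("  ref:   ", substr(x$aligned_ref, 1, 60),
      if (nchar(x$aligned_ref) > 60) "..." else "", "\n", sep = "")
  invisible(x)
}

#' Position map from a pairwise alignment
#'
#' One `(query_pos, ref_pos)` pair per alignment column where both rows hold
#' residues; strictly increasing in both coordinates.
#'
#' @param aln A `pairwise_alignment` from [global_align()].
#' @return A data frame of class `position_map` with columns `query_pos`,
#'   `ref_pos` and attributes `query_length`, `ref_length`.
#' @export
build_position_map <- function(aln) {
  q <- strsplit(aln$aligned_query, "", fixed = TRUE)[[1]]
  r <- strsplit(aln$aligned_ref, "", fixed = TRUE)[[1]]
  stopifnot(length(q) == length(r))
  qpos <- cumsum(q != "-")
  rpos <- cumsum(r != "-")
  both <- q != "-" & r != "-"
  map <- data.frame(query_pos = qpos[both], ref_pos = rpos[both])
  attr(map, "query_length") <- sum(q != "-")
  attr(map, "ref_length") <- sum(r != "-")
  class(map) <- c("position_map", "data.frame")
  map
}

#' Map a reference position to the query
#'
#' @param map A `position_map`.
#' @param ref_pos 1-based reference position(s).
#' @return Integer query position(s); `NA` where the reference position is
#'   aligned to a gap in the query (absent).
#' @export
ref_to_query <- function(map, ref_pos) {
  if (any(ref_pos < 1)) stop("ref_pos must be >= 1")
  map$query_pos[match(ref_pos, map$ref_pos)]
}

#' Kyte-Doolittle hydropathy values
#'
#' @return Named numeric vector over the 20 canonical residues.
#' @export
kyte_doolittle <- function() {
  c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
    I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
    R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)
}

#' Sliding-window hydropathy scan for transmembrane segments
#'
#' Window-centered Kyte-Doolittle means above `threshold` are collected into
#' maximal runs of consecutive center positions; each run is reported as a
#' 1-based interval over the centers. Ambiguity letters and gaps contribute a
#' hydropathy of 0. This is a coarse stand-in for dedicated transmembrane
#' predictors, used only for reporting context.
#'
#' @param seq Amino-acid string.
#' @param window Odd window size (default 19).
#' @param threshold Mean-hydropathy threshold (default 1.6).
#' @return Data frame with columns `start`, `end` (center positions); empty
#'   (with a warning) when the sequence is shorter than the window.
#' @export
hydropathy_tm_scan <- function(seq, window = 19, threshold = 1.6) {
  if (window %% 2 != 1) stop("window must be odd")
  letters <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(letters)
  if (n < window) {
    warning("sequence shorter than window; no scan performed")
    return(data.frame(start = integer(0), end = integer(0)))
  }
  kd <- kyte_doolittle()
  h <- kd[letters]
  h[is.na(h)] <- 0
  means <- as.numeric(stats::filter(h, rep(1 / window, window), sides = 2))
  centers <- which(!is.na(means) & means > threshold)
  if (length(centers) == 0)
    return(data.frame(start = integer(0), end = integer(0)))
  breaks <- c(0, which(diff(centers) > 1), length(centers))
  data.frame(
    start = centers[breaks[-length(breaks)] + 1],
    end = centers[breaks[-1]])
}
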