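# EF-hand loop detection and domain-architecture categorization. Accessory
# domains in this superfamily are generally fused N-terminal to the
# FRD / FAD-binding / NADPH-binding core, which the rule cascade exploits.

# Positional classes of the canonical 12-residue Ca2+-binding loop.
EF_LOOP_CLASSES <- list(
  `1` = "D",
  `3` = c("D", "N", "S"),
  `5` = c("D", "E", "N", "S", "T", "G"),
  `6` = c("D", "N", "Q", "G", "H", "R", "K"),
  `9` = c("D", "E", "N", "Q", "S", "T", "A", "G", "C"),
  `12` = c("D", "E"))

EF_CONSTRAINED_OFFSETS <- c(1L, 3L, 5L, 6L, 9L, 12L)

ef_window_matches <- function(window) {
  # window: character vector of length 12; returns number of matched classes,
  # or -1 when the hard constraint (no proline at loop position 7) fails
  if (window[7] == "P") return(-1L)
  sum(vapply(EF_CONSTRAINED_OFFSETS, function(off)
    window[off] %in% EF_LOOP_CLASSES[[as.character(off)]], logical(1)))
}

#' Detect EF-hand Ca2+-binding loops
#'
#' Scans with the canonical 12-residue loop pattern (1 = D; 3 in D/N/S; 5 in
#' D/E/N/S/T/G; 6 in D/N/Q/G/H/R/K; 9 in D/E/N/Q/S/T/A/G/C; 12 in D/E; no P
#' at 7; other positions unconstrained). A window matching all six
#' constrained classes is a canonical hit; a window matching at least five is
#' a relaxed hit (`canonical = FALSE`). Hits are collected greedily left to
#' right without overlap.
#'
#' @param seq Amino-acid string.
#' @return Data frame of class `ef_hits` with columns `start`, `end`
#'   (`end - start + 1 == 12`), `canonical`.
#' @export
detect_ef_hands <- function(seq) {
  letters <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(letters)
  if (n == 0) stop("sequence must be non-empty")
  starts <- integer(0)
  canon <- logical(0)
  i <- 1L
  while (i <= n - 11L) {
    m <- ef_window_matches(letters[i:(i + 11L)])
    if (m >= 5L) {
      starts <- c(starts, i)
      canon <- c(canon, m == 6L)
      i <- i + 12L
    } else i <- i + 1L
  }
  out <- data.frame(start = starts, end = starts + 11L, canonical = canon)
  class(out) <- c("ef_hits", "data.frame")
  out
}

ARCHITECTURE_CATEGORIES <- c("FRD-only", "bacterial-long/core-triad",
                             "STEAP2-4-like", "NOX-EF", "DUOX-like",
                             "RBOH-like", "FRE+DOMON", "fuFRE-like",
                             "unclassified-novel")

# TRUE when the ordered name vector contains `pattern` as a subsequence.
in_order <- function(names, pattern) {
  idx <- 0L
  for (p in pattern) {
    hit <- which(names == p)
    hit <- hit[hit > idx]
    if (length(hit) == 0) return(FALSE)
    idx <- hit[1]
  }
  TRUE
}

#' Categorize a domain architecture
#'
#' Applies an ordered rule cascade to the N-to-C domain sequence of one
#' protein. Detected EF-hand loops (from [detect_ef_hands()]) are merged with
#' any `EF_hand` rows in the hit table. `TM_extra` hits lying inside an
#' `NADPH_binding` hit are ignored (such transmembrane predictions inside the
#' dehydrogenase module are artifacts). Overlapping core domains in
#' contradictory order yield `unclassified-novel` with a warning.
#'
#' @param hits Data frame of domain hits for one sequence (columns
#'   `domain_name`, `start`, `end`), e.g. one `seq_id` group from
#'   [read_domain_hits()].
#' @param ef Optional data frame of EF-hand loops (`start`, `end`).
#' @param seq_length Optional sequence length to validate coordinates.
#' @return List of class `architecture_call`: `seq_id`, `category`,
#'   `evidence` (ordered domain names), `ef_hand_count`.
#' @export
classify_architecture <- function(hits, ef = NULL, seq_length = NULL) {
  seq_id <- if (nrow(hits) > 0 && "seq_id" %in% names(hits))
    hits$seq_id[1] else NA_character_
  hits <- as.data.frame(hits)
  if (!is.null(seq_length) && nrow(hits) > 0 && any(hits$end > seq_length))
    stop("domain hit exceeds sequence length for ", seq_id)
  hits <- hits[, c("domain_name", "start", "end"), drop = FALSE]
  if (!is.null(ef) && nrow(ef) > 0) {
    extra <- data.frame(domain_name = "EF_hand",
                        start = ef$start, end = ef$end)
    # keep table-declared EF_hand rows authoritative where they overlap scans
    declared <- hits[hits$domain_name == "EF_hand", , drop = FALSE]
    if (nrow(declared) > 0) {
      overlap <- vapply(seq_len(nrow(extra)), function(i)
        any(extra$start[i] <= declared$end & extra$end[i] >= declared$start),
        logical(1))
      extra <- extra[!overlap, , drop = FALSE]
    }
    hits <- rbind(hits, extra)
  }
  hits <- hits[order(hits$start), , drop = FALSE]

  # drop predicted TMs inside the NADPH-binding domain (prediction artifacts)
  nadph <- hits[hits$domain_name == "NADPH_binding", , drop = FALSE]
  if (nrow(nadph) > 0 && any(hits$domain_name == "TM_extra")) {
    inside <- hits$domain_name == "TM_extra" &
      vapply(seq_len(nrow(hits)), function(i)
        any(hits$start[i] >= nadph$start & hits$end[i] <= nadph$end),
        logical(1))
    hits <- hits[!inside, , drop = FALSE]
  }

  names_ord <- hits$domain_name
  core <- hits[hits$domain_name %in%
                 c("FRD", "FAD_binding", "NADPH_binding"), , drop = FALSE]
  contradictory <- FALSE
  if (nrow(core) > 1) {
    for (i in seq_len(nrow(core) - 1)) {
      if (core$start[i + 1] <= core$end[i]) contradictory <- TRUE
    }
  }
  category <- if (nrow(hits) == 0) {
    "unclassified-novel"
  } else if (contradictory) {
    warning("overlapping core domains in contradictory order for ",
            seq_id, "; unclassified-novel")
    "unclassified-novel"
  } else if (all(names_ord == "FRD")) {
    "FRD-only"
  } else if (identical(names_ord, c("FRD", "FAD_binding", "NADPH_binding"))) {
    "bacterial-long/core-triad"
  } else if (in_order(names_ord, c("NADP_F420", "FRD"))) {
    "STEAP2-4-like"
  } else if (in_order(names_ord, c("peroxidase_like", "TM_extra", "EF_hand",
                                   "FRD"))) {
    "DUOX-like"
  } else if (in_order(names_ord, c("SH3", "EF_hand", "FRD"))) {
    "RBOH-like"
  } else if (in_order(names_ord, c("DOMON", "FRD"))) {
    "FRE+DOMON"
  } else if (in_order(names_ord, c("EF_hand", "FRD", "FAD_binding",
                                   "NADPH_binding"))) {
    "NOX-EF"
  } else if (tm_immediately_before_core(names_ord) &&
             !("EF_hand" %in% names_ord)) {
    "fuFRE-like"
  } else {
    "unclassified-novel"
  }
  structure(list(seq_id = seq_id, category = category,
                 evidence = names_ord,
                 ef_hand_count = sum(names_ord == "EF_hand")),
            class = "architecture_call")
}

tm_immediately_before_core <- function(names_ord) {
  frd <- which(names_ord == "FRD")
  if (length(frd) == 0 || frd[1] == 1L) return(FALSE)
  names_ord[frd[1] - 1L] == "TM_extra"
}

#' @export
print.architecture_call <- function(x, ...) {
  cat(x$seq_id, ": ", x$category, " [",
      paste(x$evidence, collapse = " > "), "]",
      if (x$ef_hand_count > 0) paste0(" (", x$ef_hand_count, " EF-hand)"),
      "\n", sep = "")
  invisible(x)
}

#' Categorize architectures for a whole hit table
#'
#' @param hits A `domain_hits` table ([read_domain_hits()]).
#' @param records Optional `protein_set`; when given, EF-hand loops are
#'   detected from the sequences and sequence lengths validated.
#' @return Data frame with `seq_id`, `category`, `ef_hand_count`, `evidence`.
#' @export
classify_architectures <- function(hits, records = NULL) {
  ids <- unique(hits$seq_id)
  if (!is.null(records)) ids <- unique(c(ids, records$id))
  rows <- lapply(ids, function(sid) {
    h <- hits[hits$seq_id == sid, , drop = FALSE]
    ef <- NULL
    len <- NULL
    if (!is.null(records) && sid %in% records$id) {
      seq <- gsub("-", "", records$sequence[records$id == sid], fixed = TRUE)
      ef <- detect_ef_hands(seq)
      len <- nchar(seq)
    }
    call <- classify_architecture(h, ef = ef, seq_length = len)
    data.frame(seq_id = sid, category = call$category,
               ef_hand_count = call$ef_hand_count,
               evidence = paste(call$evidence, collapse = ";"))
  })
  do.call(rbind, rows)
}
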