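# The human NOX2 reference frame. The seven signature positions of the
# superfamily are expressed in NOX2 numbering: the four canonical
# heme-coordinating histidines (101, 115 in TM3; 209, 222 in TM5), the
# oxidase-indicative His-119 (TM3) and the Thr-178/Gly-179 dipeptide (TM4).
#
# The bundled reference sequences are SYNTHETIC stand-ins built here in code:
# NOX2-like and NOX5-like scaffolds of the documented lengths carrying the
# documented residues at the documented positions, hydrophobic transmembrane
# windows, and (for NOX5) four canonical EF-hand loops. They are not the
# UniProtKB entries.

#' Signature positions in NOX2 numbering
#'
#' @return Integer vector of the seven reference positions.
#' @export
CANONICAL_POSITIONS <- c(101L, 115L, 119L, 178L, 179L, 209L, 222L)

#' The four canonical heme-coordinating histidine positions
#'
#' @export
HEME_POSITIONS <- c(101L, 115L, 209L, 222L)

# NOX2-like transmembrane windows used for the synthetic scaffold (1-based
# inclusive). Only TM3-TM5 carry signature positions.
REFERENCE_TM_WINDOWS <- list(TM1 = c(25L, 47L), TM2 = c(60L, 82L),
                             TM3 = c(98L, 122L), TM4 = c(158L, 182L),
                             TM5 = c(201L, 227L), TM6 = c(238L, 260L))

NOX_PLANTED <- c(`101` = "H", `115` = "H", `119` = "H", `178` = "T",
                 `179` = "G", `209` = "H", `222` = "H")

# Calmodulin-style canonical Ca2+-binding loop used to plant EF-hands.
EF_CANONICAL_LOOP <- "DKDGDGTITTKE"

# Deterministically remove accidental EF-hand-pattern windows from a residue
# vector: mutate the first matched constrained position to L (in no loop
# class) until no hit survives outside the protected positions.
scrub_ef_artifacts <- function(residues, protect = integer(0)) {
  repeat {
    hits <- detect_ef_hands(paste(residues, collapse = ""))
    keep <- vapply(seq_len(nrow(hits)), function(i)
      any(seq(hits$start[i], hits$end[i]) %in% protect), logical(1))
    hits <- hits[!keep, , drop = FALSE]
    if (nrow(hits) == 0) return(residues)
    s <- hits$start[1]
    mutated <- FALSE
    for (off in EF_CONSTRAINED_OFFSETS) {
      pos <- s + off - 1L
      if (pos %in% protect) next
      if (residues[pos] %in% EF_LOOP_CLASSES[[as.character(off)]]) {
        residues[pos] <- "L"
        mutated <- TRUE
        break
      }
    }
    if (!mutated) return(residues)  # fully protected window; leave as-is
  }
}

#' Build the synthetic NOX2-like reference scaffold
#'
#' Deterministic 570-residue scaffold: uniform-random canonical background,
#' hydrophobic residues inside six transmembrane windows, the seven signature
#' residues planted at their NOX2 positions, and accidental EF-hand-pattern
#' windows scrubbed so EF-hand truth is well-defined on synthetic data.
#'
#' @return Amino-acid string of length 570.
#' @export
build_reference_scaffold <- function() {
  with_seed(1042L, {
    residues <- sample(AA20, 570, replace = TRUE)
    for (w in REFERENCE_TM_WINDOWS) {
      idx <- seq(w[1], w[2])
      residues[idx] <- sample(AA_HYDROPHOBIC, length(idx), replace = TRUE)
    }
    residues[as.integer(names(NOX_PLANTED))] <- NOX_PLANTED
    residues <- scrub_ef_artifacts(residues)
    residues[as.integer(names(NOX_PLANTED))] <- NOX_PLANTED
    paste(residues, collapse = "")
  })
}

# Kill EF-pattern windows that would start just before a planted loop and
# shift the greedy scan off it: the 11 residues upstream of each loop become
# leucine (in no loop class).
guard_ef_loops <- function(residues, starts, protect = integer(0)) {
  for (s in starts) {
    idx <- setdiff(max(1L, s - 11L):(s - 1L), protect)
    residues[idx] <- "L"
  }
  residues
}

#' Build the synthetic NOX5-like sequence
#'
#' 765 residues: an N-terminal EF-hand region (four canonical 12-residue
#' Ca2+-binding loops) followed by the NOX2-like scaffold, so the catalytic
#' signature positions sit at reference position + 195.
#'
#' @return Amino-acid string of length 765.
#' @export
build_synthetic_nox5 <- function() {
  loop_starts <- c(40L, 76L, 112L, 148L)
  loop_pos <- unlist(lapply(loop_starts, function(s) s:(s + 11L)))
  nterm <- with_seed(2042L, {
    res <- sample(AA20, 195, replace = TRUE)
    for (s in loop_starts)
      res[s:(s + 11L)] <- strsplit(EF_CANONICAL_LOOP, "")[[1]]
    res <- guard_ef_loops(res, loop_starts, protect = loop_pos)
    scrub_ef_artifacts(res, protect = loop_pos)
  })
  paste0(paste(nterm, collapse = ""), build_reference_scaffold())
}

#' Load the bundled synthetic NOX2 reference
#'
#' @return A one-row `protein_set` with the reference sequence.
#' @export
frd_reference <- function() {
  path <- system.file("extdata", "nox2_synthetic.fasta", package = "frdsig")
  if (nzchar(path) && file.exists(path)) return(read_fasta(path))
  protein_set(id = "NOX2_synthetic",
              description = "synthetic NOX2-like reference scaffold",
              sequence = build_reference_scaffold())
}

#' Load the bundled synthetic NOX5 sequence
#'
#' @return A one-row `protein_set`.
#' @export
frd_nox5 <- function() {
  path <- system.file("extdata", "nox5_synthetic.fasta", package = "frdsig")
  if (nzchar(path) && file.exists(path)) return(read_fasta(path))
  protein_set(id = "NOX5_synthetic",
              description = "synthetic NOX5-like sequence with 4 EF-hand loops",
              sequence = build_synthetic_nox5())
}

#' Reference annotation: sequence, signature positions, TM windows
#'
#' TM windows for TM3-TM5 are located by [hydropathy_tm_scan()] on the
#' reference (the interval containing each signature position); they are
#' reporting context only and never used for classification.
#'
#' @return List with `reference` (one-row `protein_set`),
#'   `canonical_positions`, `heme_positions`, `tm_windows`.
#' @export
reference_annotation <- function() {
  ref <- frd_reference()
  seq <- ref$sequence[1]
  res <- strsplit(seq, "", fixed = TRUE)[[1]]
  expect <- NOX_PLANTED
  got <- res[as.integer(names(expect))]
  if (!all(got == expect))
    stop("reference fixture violates the documented signature residues")
  scan <- hydropathy_tm_scan(seq)
  locate <- function(pos) {
    hit <- which(scan$start <= pos & scan$end >= pos)
    if (length(hit) == 0) return(c(NA_integer_, NA_integer_))
    c(scan$start[hit[1]], scan$end[hit[1]])
  }
  tm <- list(TM3 = locate(115L), TM4 = locate(178L), TM5 = locate(209L))
  list(reference = ref,
       canonical_positions = CANONICAL_POSITIONS,
       heme_positions = HEME_POSITIONS,
       tm_windows = tm)
}
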