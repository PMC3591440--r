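# The signature-motif system: per-clade expected residues at the seven NOX2
# reference positions, residue-vector extraction through a position map, the
# rule-based clade classifier, and discovery of discriminating positions
# between two clade profiles.
#
# Pattern language of the table: a residue letter requires that residue; "*"
# matches anything; "!H" requires anything but histidine.

#' The clade signature table
#'
#' Expected residues at the seven reference positions (NOX2 numbering
#' 101, 115, 119, 178, 179, 209, 222) for each clade, plus the exemplar
#' residue each synthetic clade template plants (one shared source for
#' classifier rules and generator truth).
#'
#' Profiles: NOX group `H,H,H,T,G,H,H`; FRE group `H,H,*,*,*,H,H` (with the
#' 119/178/179 exemplars chosen off the NOX triplet); preNOX `H,H,!H,T,G,H,H`
#' whose green-algal variant additionally lacks H at 115; YedZ/STEAP1
#' `R,H,*,*,*,H,H`; STEAP2-4 `R,H,*,*,*,Q,H`.
#'
#' @return List of class `signature_table` with `positions`, `patterns`
#'   (clade -> pattern vector), `exemplars` (clade -> concrete residues used
#'   by the generator), `heme_positions`, and the reference length.
#' @export
signature_table <- function() {
  pos <- CANONICAL_POSITIONS
  pat <- function(...) stats::setNames(c(...), pos)
  patterns <- list(
    "NOX"         = pat("H", "H", "H", "T", "G", "H", "H"),
    "preNOX"      = pat("H", "H", "!H", "T", "G", "H", "H"),
    "preNOX-green" = pat("H", "!H", "!H", "T", "G", "H", "H"),
    "FRE"         = pat("H", "H", "*", "*", "*", "H", "H"),
    "YedZ-STEAP1" = pat("R", "H", "*", "*", "*", "H", "H"),
    "STEAP2-4"    = pat("R", "H", "*", "*", "*", "Q", "H"))
  exemplars <- list(
    "NOX"         = pat("H", "H", "H", "T", "G", "H", "H"),
    "preNOX"      = pat("H", "L", "Y", "T", "G", "H", "H"),
    "FRE"         = pat("H", "H", "F", "S", "A", "H", "H"),
    "YedZ-STEAP1" = pat("R", "H", "L", "S", "A", "H", "H"),
    "STEAP2-4"    = pat("R", "H", "L", "S", "A", "Q", "H"))
  structure(list(positions = pos, patterns = patterns, exemplars = exemplars,
                 heme_positions = HEME_POSITIONS, ref_length = 570L),
            class = "signature_table")
}

#' Positions of the NOX-indicative signature motif
#'
#' Derived from the signature table: reference positions within the TM3-TM4
#' span where the NOX profile requires a specific residue and at least one
#' other clade profile deviates (wildcard, negation, or a different residue).
#' This reproduces the four-residue oxidase motif His-101 / His-119 /
#' Thr-178 / Gly-179.
#'
#' @param table A [signature_table()].
#' @return Integer vector of reference positions.
#' @export
nox_motif_positions <- function(table = signature_table()) {
  pos <- table$positions
  nox <- table$patterns[["NOX"]]
  span <- pos <= 179L  # TM3 through TM4
  main <- setdiff(names(table$patterns), c("NOX", "preNOX-green"))
  deviates <- vapply(seq_along(pos), function(i) {
    any(vapply(table$patterns[main], function(p) p[i] != nox[i], logical(1)))
  }, logical(1))
  pos[span & deviates & nox != "*"]
}

#' Extract the residue vector at reference positions
#'
#' Reads the query residue at each signature position through a position map
#' built against the NOX2 reference.
#'
#' @param query A one-row `protein_set` or an amino-acid string.
#' @param map A `position_map` from [build_position_map()] against the
#'   reference.
#' @param table A [signature_table()].
#' @return List of class `residue_vector`: `query_id`, `residues` (named by
#'   reference position, `NA` where the position is gapped out).
#' @export
extract_residue_vector <- function(query, map, table = signature_table()) {
  if (inherits(query, "data.frame")) {
    qid <- query$id[1]
    seq <- query$sequence[1]
  } else {
    qid <- "query"
    seq <- query
  }
  seq <- gsub("-", "", toupper(seq), fixed = TRUE)
  if (attr(map, "ref_length") != table$ref_length)
    stop("position map was built against a reference of length ",
         attr(map, "ref_length"), ", expected ", table$ref_length)
  qpos <- ref_to_query(map, table$positions)
  residues <- rep(NA_character_, length(table$positions))
  ok <- !is.na(qpos)
  residues[ok] <- substring(seq, qpos[ok], qpos[ok])
  names(residues) <- table$positions
  structure(list(query_id = qid, residues = residues),
            class = "residue_vector")
}

pattern_matches <- function(observed, pattern) {
  if (is.na(observed)) return(FALSE)
  if (pattern == "*") return(TRUE)
  if (startsWith(pattern, "!")) return(observed != substring(pattern, 2))
  observed == pattern
}

#' Classify a residue vector into a superfamily clade
#'
#' Decision cascade over the signature residues (total and deterministic):
#' \enumerate{
#'   \item Arg at 101 (the YedZ/STEAP replacement of the first canonical
#'     heme histidine) -> `YedZ/STEAP`; subtype `YedZ/STEAP1-like` when 209
#'     is His, else `STEAP2-4-like`.
#'   \item His at 101 with the Thr-178/Gly-179 dipeptide intact and at least
#'     3 of \{His-119, Thr-178, Gly-179, His-115\} matching -> `NOX-group`
#'     (the one-site tolerance covers species with multiple NOX inparalogs).
#'   \item Dipeptide intact but 119 not His -> `preNOX-like`.
#'   \item At least 3 canonical heme histidines -> `FRE-group`.
#'   \item Otherwise `ambiguous`.
#' }
#' `heme_histidine_count` counts His at \{101, 115, 209, 222\} only.
#'
#' @param vector A `residue_vector`.
#' @param table A [signature_table()].
#' @return List of class `clade_call`: `query_id`, `label`, `subtype`,
#'   `heme_histidine_count`, `evidence` (per-position data frame).
#' @export
classify_residue_vector <- function(vector, table = signature_table()) {
  obs <- vector$residues
  p <- function(pos) obs[[as.character(pos)]]
  is_res <- function(pos, res) !is.na(p(pos)) && p(pos) == res
  heme <- sum(vapply(table$heme_positions, is_res, logical(1), res = "H"))
  dipeptide <- is_res(178, "T") && is_res(179, "G")
  nox_sites <- c(is_res(119, "H"), is_res(178, "T"), is_res(179, "G"),
                 is_res(115, "H"))
  subtype <- NA_character_
  if (is_res(101, "R")) {
    label <- "YedZ/STEAP"
    subtype <- if (is_res(209, "H")) "YedZ/STEAP1-like" else "STEAP2-4-like"
  } else if (is_res(101, "H") && dipeptide && sum(nox_sites) >= 3) {
    label <- "NOX-group"
  } else if (dipeptide && !is_res(119, "H")) {
    label <- "preNOX-like"
  } else if (heme >= 3) {
    label <- "FRE-group"
  } else {
    label <- "ambiguous"
  }
  evidence <- data.frame(
    ref_pos = table$positions,
    observed = unname(obs),
    nox_expected = unname(table$patterns[["NOX"]]),
    matches_nox = vapply(seq_along(table$positions), function(i)
      pattern_matches(obs[[i]], table$patterns[["NOX"]][[i]]), logical(1)))
  structure(list(query_id = vector$query_id, label = label,
                 subtype = subtype, heme_histidine_count = heme,
                 evidence = evidence),
            class = "clade_call")
}

#' @export
print.clade_call <- function(x, ...) {
  cat(x$query_id, ": ", x$label,
      if (!is.na(x$subtype)) paste0(" (", x$subtype, ")"),
      "; heme histidines ", x$heme_histidine_count, "/4\n", sep = "")
  invisible(x)
}

#' Classify sequences against the NOX2 reference
#'
#' Full pipeline per record: global alignment to the reference, position map,
#' residue vector, clade call.
#'
#' @param records A `protein_set` (gaps are removed before alignment).
#' @param reference One-row `protein_set`; defaults to the bundled synthetic
#'   NOX2 reference.
#' @param scheme A [scoring_scheme()].
#' @param table A [signature_table()].
#' @return Data frame with one row per record: `query_id`, `label`,
#'   `subtype`, `heme_histidine_count`, `residues` (compact evidence,
#'   `pos=observed` separated by `;`).
#' @export
classify_sequences <- function(records, reference = frd_reference(),
                               scheme = scoring_scheme(),
                               table = signature_table()) {
  if (nrow(records) == 0) stop("no sequences to classify")
  queries <- gsub("-", "", toupper(records$sequence), fixed = TRUE)
  alns <- global_align_many(queries, reference$sequence[1], scheme)
  rows <- lapply(seq_len(nrow(records)), function(i) {
    map <- build_position_map(alns[[i]])
    vec <- extract_residue_vector(queries[i], map, table)
    vec$query_id <- records$id[i]
    call <- classify_residue_vector(vec, table)
    data.frame(query_id = call$query_id, label = call$label,
               subtype = call$subtype,
               heme_histidine_count = call$heme_histidine_count,
               residues = paste(table$positions,
                                ifelse(is.na(vec$residues), "-",
                                       vec$residues),
                                sep = "=", collapse = ";"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Map MSA columns to reference coordinates
#'
#' Builds the column-to-reference position map by aligning the profile
#' consensus (columns with an observed consensus, degapped) to the reference.
#'
#' @param profile A `conservation_profile` (or a `protein_msa`, which is
#'   profiled first).
#' @param reference One-row `protein_set`.
#' @param scheme A [scoring_scheme()].
#' @return A `position_map` whose `query_pos` are MSA column indices.
#' @export
msa_reference_map <- function(profile, reference = frd_reference(),
                              scheme = scoring_scheme()) {
  if (inherits(profile, "protein_msa")) profile <- profile_msa(profile)
  cols <- which(!is.na(profile$consensus))
  if (length(cols) == 0) stop("profile has no consensus columns")
  cons <- paste(profile$consensus[cols], collapse = "")
  aln <- global_align(cons, reference$sequence[1], scheme)
  map <- build_position_map(aln)
  map$query_pos <- cols[map$query_pos]
  attr(map, "query_length") <- length(profile$consensus)
  map
}

#' Discover positions that discriminate two clade profiles
#'
#' Reports every reference position where clade A's consensus residue reaches
#' frequency at least `f_cons` in A while that same residue's frequency in
#' clade B is at most `f_bg`.
#'
#' @param profile_a,profile_b `conservation_profile`s.
#' @param map_a,map_b `position_map`s from [msa_reference_map()] (MSA column
#'   to reference position).
#' @param f_cons Minimum consensus frequency in clade A (default 0.8).
#' @param f_bg Maximum frequency of that residue in clade B (default 0.3).
#' @return Data frame sorted by `ref_pos` with columns `ref_pos`,
#'   `residue_a`, `freq_a`, `freq_b_of_residue_a`, `delta`.
#' @export
discover_signatures <- function(profile_a, profile_b, map_a, map_b,
                                f_cons = 0.8, f_bg = 0.3) {
  if (f_cons <= f_bg) stop("thresholds not separating: f_cons must exceed f_bg")
  shared <- intersect(map_a$ref_pos, map_b$ref_pos)
  rows <- lapply(sort(shared), function(rp) {
    ca <- map_a$query_pos[match(rp, map_a$ref_pos)]
    cb <- map_b$query_pos[match(rp, map_b$ref_pos)]
    res <- profile_a$consensus[ca]
    if (is.na(res)) return(NULL)
    fa <- profile_a$frequencies[res, ca]
    fb <- profile_b$frequencies[res, cb]
    if (fa >= f_cons && fb <= f_bg)
      data.frame(ref_pos = rp, residue_a = res, freq_a = fa,
                 freq_b_of_residue_a = fb, delta = fa - fb)
    else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(ref_pos = integer(0), residue_a = character(0),
                      freq_a = numeric(0), freq_b_of_residue_a = numeric(0),
                      delta = numeric(0))
  rownames(out) <- NULL
  out
}
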