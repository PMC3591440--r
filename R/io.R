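# FASTA / TSV / JSON plumbing shared by all analysis steps.
# Coordinates are 1-based inclusive throughout the package.

#' Amino-acid alphabets used by the package
#'
#' `AA20` is the canonical 20-letter alphabet; `AA_AMBIGUOUS` the ambiguity
#' letters retained in sequences but excluded from frequency counts;
#' `AA_HYDROPHOBIC` the residues used to fill synthetic transmembrane windows.
#'
#' @keywords internal
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @rdname AA20
#' @keywords internal
AA_AMBIGUOUS <- c("X", "B", "Z", "U")

#' @rdname AA20
#' @keywords internal
AA_HYDROPHOBIC <- c("I", "L", "V", "F", "A", "M")

AA_VALID <- c(AA20, AA_AMBIGUOUS, "-")

#' Controlled vocabulary of domain names
#'
#' Domain names accepted in domain-hit tables. Pfam accessions commonly seen
#' in scan exports are translated via [domain_alias_table()].
#'
#' @export
DOMAIN_VOCABULARY <- c("FRD", "FAD_binding", "NADPH_binding", "EF_hand",
                       "peroxidase_like", "DOMON", "NADP_F420", "TM_extra",
                       "SH3", "other")

#' Pfam accession aliases for the domain vocabulary
#'
#' @return Named character vector mapping Pfam accessions to the controlled
#'   vocabulary of [DOMAIN_VOCABULARY].
#' @export
domain_alias_table <- function() {
  c(PF01794 = "FRD",
    PF08022 = "FAD_binding",
    PF08030 = "NADPH_binding",
    PF03807 = "NADP_F420",
    PF03098 = "peroxidase_like",
    PF03351 = "DOMON",
    PF00018 = "SH3")
}

validate_sequences <- function(seqs, ids) {
  for (i in seq_along(seqs)) {
    letters <- unique(strsplit(seqs[[i]], "", fixed = TRUE)[[1]])
    bad <- setdiff(letters, AA_VALID)
    if (length(bad) > 0)
      stop("record '", ids[[i]], "' contains invalid letters: ",
           paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' Read protein sequences from a FASTA file
#'
#' Records are returned in file order, upper-cased, with terminal stop
#' characters (`*`) stripped. Duplicated ids are an error (truth-label joins
#' require uniqueness). With `aligned = TRUE` all sequences must have equal
#' length and the result is a `protein_msa`.
#'
#' @param path Path to a FASTA file (plain or aligned).
#' @param aligned Logical; if `TRUE` validate equal lengths and return an MSA.
#' @return A data frame of class `protein_set` with columns `id`,
#'   `description`, `sequence` (and `truth_label`, initially `NA`); for
#'   `aligned = TRUE` additionally of class `protein_msa` with attribute
#'   `n_columns`.
#' @export
read_fasta <- function(path, aligned = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- tryCatch(
    seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                       set.attributes = FALSE, whole.header = TRUE),
    error = function(e) stop("no records in ", path))
  if (length(recs) == 0) stop("no records in ", path)
  headers <- names(recs)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids))
    stop("duplicate ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(unlist(recs, use.names = FALSE))
  seqs <- sub("\\*+$", "", sub("^\\*+", "", seqs))
  if (any(nchar(seqs) == 0)) stop("empty sequence for id ",
                                  ids[which(nchar(seqs) == 0)[1]])
  validate_sequences(seqs, ids)
  out <- data.frame(id = ids, description = desc, sequence = seqs,
                    truth_label = NA_character_, stringsAsFactors = FALSE)
  class(out) <- c("protein_set", "data.frame")
  if (aligned) out <- as_protein_msa(out)
  out
}

#' Assemble a protein set from ids and sequences
#'
#' @param id,sequence Character vectors of equal length.
#' @param description,truth_label Optional character vectors.
#' @return A `protein_set` data frame.
#' @export
protein_set <- function(id, sequence, description = "",
                        truth_label = NA_character_) {
  stopifnot(length(id) == length(sequence))
  if (anyDuplicated(id))
    stop("duplicate ids: ", paste(unique(id[duplicated(id)]), collapse = ", "))
  if (any(grepl("\\s", id))) stop("ids must not contain whitespace")
  sequence <- toupper(sequence)
  if (any(nchar(sequence) == 0)) stop("sequences must be non-empty")
  validate_sequences(sequence, id)
  out <- data.frame(id = id, description = description, sequence = sequence,
                    truth_label = truth_label, stringsAsFactors = FALSE)
  class(out) <- c("protein_set", "data.frame")
  out
}

#' Validate a protein set as a multiple sequence alignment
#'
#' @param records A `protein_set` (or plain data frame with the same columns).
#' @return The input with class `protein_msa` and attribute `n_columns`.
#' @export
as_protein_msa <- function(records) {
  lens <- nchar(records$sequence)
  if (length(unique(lens)) > 1) {
    ref <- lens[1]
    bad <- records$id[lens != ref][1]
    stop("ragged alignment: sequence '", bad, "' has length ",
         lens[records$id == bad][1], ", expected ", ref)
  }
  attr(records, "n_columns") <- lens[1]
  class(records) <- unique(c("protein_msa", "protein_set", "data.frame"))
  records
}

#' @export
print.protein_set <- function(x, ...) {
  if (inherits(x, "protein_msa"))
    cat("Protein MSA: ", nrow(x), " sequences x ", attr(x, "n_columns"),
        " columns\n", sep = "")
  else
    cat("Protein set: ", nrow(x), " sequences (lengths ",
        min(nchar(x$sequence)), "-", max(nchar(x$sequence)), ")\n", sep = "")
  print(utils::head(as.data.frame(x)[, c("id", "description")], 6))
  invisible(x)
}

#' Write a protein set to FASTA
#'
#' @param records A `protein_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (nrow(records) == 0) stop("nothing to write")
  header <- ifelse(nchar(records$description) > 0,
                   paste(records$id, records$description), records$id)
  lines <- character(2L * nrow(records))
  lines[c(TRUE, FALSE)] <- paste0(">", header)
  lines[c(FALSE, TRUE)] <- records$sequence
  writeLines(lines, path)
  invisible(path)
}

#' Read a domain-hit table (Pfam/InterPro-scan-shaped TSV)
#'
#' Expects a header `seq_id, domain_name, start, end, source`. Pfam
#' accessions are translated via [domain_alias_table()]; unknown names are
#' mapped to `"other"` with a warning. Hits are returned sorted by
#' `(seq_id, start)`.
#'
#' @param path TSV path.
#' @return Data frame of class `domain_hits`.
#' @export
read_domain_hits <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("seq_id", "domain_name", "start", "end", "source")
  if (!all(need %in% names(df)))
    stop("domain-hit TSV must have columns: ", paste(need, collapse = ", "))
  for (col in c("start", "end")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v) || any(v != as.integer(v)))
      stop("non-integer coordinates in column '", col, "'")
    df[[col]] <- as.integer(v)
  }
  if (any(df$start < 1)) stop("coordinates are 1-based; start must be >= 1")
  if (any(df$start > df$end))
    stop("start > end for seq_id ", df$seq_id[which(df$start > df$end)[1]])
  alias <- domain_alias_table()
  aliased <- df$domain_name %in% names(alias)
  df$domain_name[aliased] <- alias[df$domain_name[aliased]]
  unknown <- !(df$domain_name %in% DOMAIN_VOCABULARY)
  if (any(unknown)) {
    warning("unknown domain names mapped to 'other': ",
            paste(unique(df$domain_name[unknown]), collapse = ", "))
    df$domain_name[unknown] <- "other"
  }
  df <- df[order(df$seq_id, df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("domain_hits", "data.frame")
  df
}

#' Write classification or architecture results
#'
#' @param results A non-empty data frame (e.g. from [classify_sequences()] or
#'   [classify_architectures()]).
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  results <- as.data.frame(results)
  if (nrow(results) == 0) stop("nothing to write")
  if (format == "tsv") {
    utils::write.table(results, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(results, path, dataframe = "rows", digits = NA,
                         na = "null", auto_unbox = FALSE, pretty = TRUE)
  }
  invisible(path)
}

#' Read results written by [write_results()]
#'
#' @param path File path.
#' @param format `"tsv"` or `"json"`.
#' @return A data frame.
#' @export
read_results <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv")
    utils::read.delim(path, stringsAsFactors = FALSE)
  else
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
}

# Run `code` under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
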