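# Small in-code fixtures shared across test files.

write_tmp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}

# A tiny MSA from explicit row strings.
msa_from_rows <- function(rows, ids = sprintf("s%d", seq_along(rows))) {
  as_protein_msa(protein_set(id = ids, sequence = rows))
}

random_protein <- function(n, alphabet = frdsig:::AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Expected (label, subtype) per default clade template.
expected_call <- function(templates) {
  data.frame(clade = vapply(templates, function(t) t$name, character(1)),
             label = vapply(templates, function(t) t$expected_label,
                            character(1)),
             subtype = vapply(templates, function(t) t$expected_subtype,
                              character(1)))
}

# Accuracy of classification results against benchmark truth.
benchmark_accuracy <- function(results, truth, templates) {
  exp <- expected_call(templates)
  merged <- merge(merge(results, truth, by.x = "query_id", by.y = "seq_id"),
                  exp, by = "clade", suffixes = c("", "_expected"))
  ok <- merged$label == merged$label_expected &
    (is.na(merged$subtype_expected) |
       (!is.na(merged$subtype) & merged$subtype == merged$subtype_expected))
  mean(ok)
}
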