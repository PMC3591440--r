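# Independent oracles: plain recursive enumeration of all affine-gap global
# alignments (no dynamic programming), and a literal entropy loop for
# information content.

# Best global alignment score of a vs b by exhaustive enumeration.
# Gap of length L costs open + L * ext, matching scoring_scheme().
bf_align_score <- function(a, b, scheme = scoring_scheme()) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  mat <- scheme$matrix
  open <- scheme$gap_open
  ext <- scheme$gap_extend
  rec <- function(i, j, state) {
    if (i > length(A) && j > length(B)) return(0)
    best <- -Inf
    if (i <= length(A) && j <= length(B))
      best <- max(best, mat[A[i], B[j]] + rec(i + 1L, j + 1L, "M"))
    if (i <= length(A))
      best <- max(best,
                  -(ext + if (state == "I") 0 else open) + rec(i + 1L, j, "I"))
    if (j <= length(B))
      best <- max(best,
                  -(ext + if (state == "D") 0 else open) + rec(i, j + 1L, "D"))
    best
  }
  rec(1L, 1L, "S")
}

# Information content recomputed by a literal loop over frequencies.
bf_information <- function(freqs) {
  h <- 0
  for (p in freqs) if (p > 0) h <- h - p * log2(p)
  log2(20) - h
}

# All sequences over `alphabet` with lengths 1..max_len.
all_sequences <- function(alphabet, max_len) {
  out <- character(0)
  for (len in seq_len(max_len)) {
    grid <- do.call(expand.grid, rep(list(alphabet), len))
    out <- c(out, apply(grid, 1, paste, collapse = ""))
  }
  unname(out)
}
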