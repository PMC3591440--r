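make_vector <- function(residues) {
  structure(list(query_id = "q",
                 residues = stats::setNames(residues, CANONICAL_POSITIONS)),
            class = "residue_vector")
}

test_that("the signature table covers all clades at all seven positions", {
  tab <- signature_table()
  expect_equal(tab$positions, c(101, 115, 119, 178, 179, 209, 222))
  expect_equal(tab$heme_positions, c(101, 115, 209, 222))
  for (p in tab$patterns) expect_length(p, 7)
  for (e in tab$exemplars) expect_length(e, 7)
  # the NOX-indicative motif has the four TM3-TM4 positions
  expect_equal(nox_motif_positions(tab), c(101, 119, 178, 179))
})

test_that("residue vectors read reference positions through the map", {
  ref <- frd_reference()
  aln <- global_align(ref$sequence[1], ref$sequence[1])
  map <- build_position_map(aln)
  vec <- extract_residue_vector(ref, map)
  expect_equal(unname(vec$residues),
               c("H", "H", "H", "T", "G", "H", "H"))

  # an FRE-template sequence at epsilon = 0 keeps heme H pairs, non-NOX triplet
  fre <- default_clade_templates()[["FRE"]]$sequence
  map <- build_position_map(global_align(fre, ref$sequence[1]))
  vec <- extract_residue_vector(fre, map)
  expect_equal(unname(vec$residues[c("101", "115", "209", "222")]),
               rep("H", 4))
  expect_false(any(vec$residues[c("119", "178", "179")] == c("H", "T", "G")))

  # a gapped-out position is absent
  aln <- list(aligned_query = paste0(substr(ref$sequence[1], 1, 118),
                                     "-",
                                     substr(ref$sequence[1], 120, 570)),
              aligned_ref = ref$sequence[1])
  class(aln) <- "pairwise_alignment"
  map <- build_position_map(aln)
  vec <- extract_residue_vector(gsub("-", "", aln$aligned_query), map)
  expect_true(is.na(vec$residues[["119"]]))
  expect_equal(vec$residues[["101"]], "H")

  # maps against a different reference length are rejected
  short_map <- build_position_map(global_align("MKHLW", "MKHLW"))
  expect_error(extract_residue_vector("MKHLW", short_map), "length")
})

test_that("the decision cascade reproduces the clade rules", {
  calls <- list(
    nox = classify_residue_vector(make_vector(c("H", "H", "H", "T", "G", "H", "H"))),
    steap24 = classify_residue_vector(make_vector(c("R", "H", "L", "S", "A", "Q", "H"))),
    yedz = classify_residue_vector(make_vector(c("R", "H", "L", "S", "A", "H", "H"))),
    fre = classify_residue_vector(make_vector(c("H", "H", "F", "S", "A", "H", "H"))),
    prenox = classify_residue_vector(make_vector(c("H", "L", "Y", "T", "G", "H", "H"))),
    absent = classify_residue_vector(make_vector(rep(NA_character_, 7))))
  expect_equal(calls$nox$label, "NOX-group")
  expect_equal(calls$nox$heme_histidine_count, 4)
  expect_equal(calls$steap24$label, "YedZ/STEAP")
  expect_equal(calls$steap24$subtype, "STEAP2-4-like")
  expect_equal(calls$steap24$heme_histidine_count, 2)
  expect_equal(calls$yedz$subtype, "YedZ/STEAP1-like")
  expect_equal(calls$yedz$heme_histidine_count, 3)
  expect_equal(calls$fre$label, "FRE-group")
  expect_equal(calls$fre$heme_histidine_count, 4)
  expect_equal(calls$prenox$label, "preNOX-like")
  expect_equal(calls$absent$label, "ambiguous")
  expect_equal(calls$absent$heme_histidine_count, 0)

  # one mutated NOX site is tolerated when the T-G dipeptide is intact
  tolerant <- classify_residue_vector(make_vector(c("H", "Q", "H", "T", "G", "H", "H")))
  expect_equal(tolerant$label, "NOX-group")
  # but a broken dipeptide is not a NOX call
  broken <- classify_residue_vector(make_vector(c("H", "H", "H", "T", "A", "H", "H")))
  expect_equal(broken$label, "FRE-group")
})

test_that("classification is total over random residue vectors", {
  set.seed(4)
  labels <- c("NOX-group", "preNOX-like", "FRE-group", "YedZ/STEAP",
              "ambiguous")
  for (i in 1:200) {
    res <- sample(c(frdsig:::AA20, NA), 7, replace = TRUE)
    call <- classify_residue_vector(make_vector(res))
    expect_true(call$label %in% labels)
    expect_true(call$heme_histidine_count %in% 0:4)
    again <- classify_residue_vector(make_vector(res))
    expect_identical(call$label, again$label)
  }
})

test_that("template sequences classify to their clade at epsilon = 0", {
  tpls <- default_clade_templates()
  recs <- protein_set(id = names(tpls),
                      sequence = vapply(tpls, function(t) t$sequence, ""))
  res <- classify_sequences(recs)
  exp <- expected_call(tpls)
  expect_equal(res$label, exp$label)
  expect_equal(res$subtype[!is.na(exp$subtype)],
               exp$subtype[!is.na(exp$subtype)])
  # retained-histidine counts as printed for the short forms
  expect_equal(res$heme_histidine_count[res$query_id == "YedZ-STEAP1"], 3)
  expect_equal(res$heme_histidine_count[res$query_id == "STEAP2-4"], 2)
})

test_that("discovery finds planted differences and nothing in identical clades", {
  expect_error(discover_signatures(NULL, NULL, NULL, NULL,
                                   f_cons = 0.3, f_bg = 0.3),
               "not separating")

  ref <- frd_reference()
  base <- build_reference_scaffold()
  swap119 <- paste0(substr(base, 1, 118), "Y", substr(base, 120, 570))
  msa_a <- msa_from_rows(rep(base, 6))
  msa_b <- msa_from_rows(rep(swap119, 6))
  pa <- profile_msa(msa_a, "A")
  pb <- profile_msa(msa_b, "B")
  ma <- msa_reference_map(pa, ref)
  mb <- msa_reference_map(pb, ref)
  found <- discover_signatures(pa, pb, ma, mb)
  expect_equal(found$ref_pos, 119)
  expect_equal(found$residue_a, "H")
  expect_equal(found$freq_a, 1)
  expect_equal(found$freq_b_of_residue_a, 0)

  # swapping the clades reports the same position with roles exchanged
  rev <- discover_signatures(pb, pa, mb, ma)
  expect_equal(rev$ref_pos, 119)
  expect_equal(rev$residue_a, "Y")

  none <- discover_signatures(pa, pa, ma, ma)
  expect_equal(nrow(none), 0)
})
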