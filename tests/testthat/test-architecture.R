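hits_df <- function(names, starts, ends, seq_id = "s1") {
  data.frame(seq_id = seq_id, domain_name = names, start = starts,
             end = ends, source = "test")
}

test_that("the canonical Ca-binding loop is found in context", {
  seq <- paste0(strrep("A", 50), "DKDGDGTITTKE", strrep("A", 50))
  hits <- detect_ef_hands(seq)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 51)
  expect_equal(hits$end, 62)
  expect_true(hits$canonical)
  expect_equal(hits$end - hits$start + 1, 12)
})

test_that("featureless and proline-blocked sequences yield no EF-hands", {
  expect_equal(nrow(detect_ef_hands(strrep("A", 200))), 0)
  # proline at loop position 7 vetoes an otherwise canonical window
  blocked <- paste0(strrep("A", 20), "DKDGDGPITTKE", strrep("A", 20))
  expect_equal(nrow(detect_ef_hands(blocked)), 0)
  # a single mismatched class still passes as a relaxed (non-canonical) hit
  relaxed <- paste0(strrep("A", 20), "DKDGDGTITTKK", strrep("A", 20))
  h <- detect_ef_hands(relaxed)
  expect_equal(nrow(h), 1)
  expect_false(h$canonical)
})

test_that("planted loops in synthetic templates are recovered exactly", {
  tpl <- clade_template("NOX-EF", signature_table()$exemplars[["NOX"]],
                        ef_loop_starts = c(300L, 330L))
  hits <- detect_ef_hands(tpl$sequence)
  expect_equal(hits$start, c(300, 330))
  expect_true(all(hits$canonical))
})

test_that("EF-hand hits are non-overlapping and sorted on random sequences", {
  set.seed(19)
  for (i in 1:20) {
    hits <- detect_ef_hands(random_protein(300))
    if (nrow(hits) > 1) {
      expect_true(all(diff(hits$start) >= 12))
      expect_true(!is.unsorted(hits$start))
    }
  }
})

test_that("the architecture cascade reproduces the model categories", {
  expect_equal(classify_architecture(hits_df("FRD", 10, 180))$category,
               "FRD-only")
  expect_equal(classify_architecture(
    hits_df(c("FRD", "FAD_binding", "NADPH_binding"),
            c(10, 200, 320), c(180, 310, 440)))$category,
    "bacterial-long/core-triad")
  expect_equal(classify_architecture(
    hits_df(c("NADP_F420", "FRD"), c(1, 40), c(38, 200)))$category,
    "STEAP2-4-like")
  expect_equal(classify_architecture(
    hits_df(c("peroxidase_like", "TM_extra", "EF_hand", "FRD",
              "FAD_binding", "NADPH_binding"),
            c(1, 600, 650, 700, 900, 1020),
            c(570, 625, 661, 880, 1010, 1140)))$category,
    "DUOX-like")
  expect_equal(classify_architecture(
    hits_df(c("SH3", "EF_hand", "FRD", "FAD_binding", "NADPH_binding"),
            c(1, 80, 130, 330, 450),
            c(60, 91, 320, 440, 560)))$category,
    "RBOH-like")
  expect_equal(classify_architecture(
    hits_df(c("DOMON", "FRD", "FAD_binding", "NADPH_binding"),
            c(1, 120, 330, 450), c(110, 320, 440, 560)))$category,
    "FRE+DOMON")
  expect_equal(classify_architecture(
    hits_df(c("EF_hand", "EF_hand", "FRD", "FAD_binding", "NADPH_binding"),
            c(10, 40, 130, 330, 450),
            c(21, 51, 320, 440, 560)))$category,
    "NOX-EF")
  expect_equal(classify_architecture(
    hits_df(c("TM_extra", "FRD", "FAD_binding", "NADPH_binding"),
            c(5, 40, 330, 450), c(30, 320, 440, 560)))$category,
    "fuFRE-like")
  # inverted core order falls through every rule
  expect_equal(classify_architecture(
    hits_df(c("FAD_binding", "FRD"), c(10, 200), c(180, 400)))$category,
    "unclassified-novel")
})

test_that("artifactual TMs inside the NADPH-binding domain are ignored", {
  call <- classify_architecture(
    hits_df(c("FRD", "FAD_binding", "NADPH_binding", "TM_extra"),
            c(10, 200, 320, 360), c(180, 310, 440, 380)))
  expect_equal(call$category, "bacterial-long/core-triad")
})

test_that("contradictory overlapping core domains warn and fall back", {
  expect_warning(
    call <- classify_architecture(
      hits_df(c("FRD", "FAD_binding"), c(10, 100), c(180, 240))),
    "contradictory")
  expect_equal(call$category, "unclassified-novel")
})

test_that("every default template layout round-trips to its category", {
  for (tpl in default_clade_templates()) {
    hits <- data.frame(seq_id = tpl$name,
                       domain_name = tpl$domain_layout$domain_name,
                       start = tpl$domain_layout$start,
                       end = tpl$domain_layout$end, source = "template")
    ef <- detect_ef_hands(tpl$sequence)
    call <- classify_architecture(hits, ef = ef,
                                  seq_length = nchar(tpl$sequence))
    expect_equal(call$category, tpl$expected_architecture, info = tpl$name)
  }
})

test_that("classify_architectures processes a whole hit table", {
  hits <- rbind(hits_df("FRD", 10, 180, seq_id = "a"),
                hits_df(c("NADP_F420", "FRD"), c(1, 40), c(38, 200),
                        seq_id = "b"))
  class(hits) <- c("domain_hits", "data.frame")
  res <- classify_architectures(hits)
  expect_equal(sort(res$seq_id), c("a", "b"))
  expect_equal(res$category[res$seq_id == "a"], "FRD-only")
  expect_equal(res$category[res$seq_id == "b"], "STEAP2-4-like")
})
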