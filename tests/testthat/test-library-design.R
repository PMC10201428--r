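# Variant manifest generation: category generators and barcode assignment.

test_that("truncation series replaces innermost bases, preserving length", {
  end <- transposon_end("right", paste0("TG", strrep("GTCA", 5)),
                        data.frame(label = "R1", start = 9L, end = 22L))
  tr <- design_truncations(end, step = 5L)
  expect_equal(nrow(tr), 4L)
  expect_true(all(nchar(tr$end_sequence) == 22L))
  # variant 1 alters only the innermost 5 bases
  expect_equal(substr(tr$end_sequence[1], 1, 17), substr(end$sequence, 1, 17))
  expect_false(substr(tr$end_sequence[1], 18, 22) ==
                 substr(end$sequence, 18, 22))
  full <- design_truncations(wt_fixture$left_end, step = 1L)
  expect_equal(nrow(full), 147L)
  expect_error(design_truncations(end, step = 23L), "exceeds")
})

test_that("substitution windows tile every offset with the complement rule", {
  expect_error(design_substitutions(wt_fixture$right_end, widths = 3L),
               "subset")
  sub1 <- design_substitutions(wt_fixture$right_end, widths = 1L)
  expect_equal(nrow(sub1), 75L)
  # single-base complement at each position
  expect_equal(substr(sub1$end_sequence[1], 1, 1),
               dna_complement(substr(wt_fixture$right_end$sequence, 1, 1)))
  sub4 <- design_substitutions(wt_fixture$right_end, widths = 4L)
  # an interior base is covered by exactly 4 windows
  pos <- 30L
  covering <- vapply(seq_len(nrow(sub4)), function(i) {
    substr(sub4$end_sequence[i], pos, pos) !=
      substr(wt_fixture$right_end$sequence, pos, pos)
  }, logical(1))
  expect_equal(sum(covering), 4L)
  # a window starting on TGAC becomes ACTG
  w <- design_substitutions(
    transposon_end("right", paste0("TGACTGAC", strrep("GTCA", 4)),
                   data.frame(label = "R1", start = 9L, end = 22L)),
    widths = 4L)
  expect_equal(substr(w$end_sequence[1], 1, 4), "ACTG")
})

test_that("binding-site variant generators enumerate the design space", {
  end <- wt_fixture$right_end
  ident <- design_tbs_variants(end, mode = "identity")
  expect_equal(nrow(ident), 27L)
  expect_equal(anyDuplicated(ident$variant_id), 0L)
  sp <- design_tbs_variants(end, mode = "spacing",
                            params = list(deltas = c(-1L, 1L)))
  expect_equal(nchar(sp$end_sequence) - nchar(end$sequence), c(-1L, 1L))
  expect_error(design_tbs_variants(end, mode = "spacing",
                                   params = list(deltas = -100L)),
               "exceeds")
  inv <- design_tbs_variants(end, mode = "inversion",
                             params = list(sites = "R2"))
  expect_equal(substr(inv$end_sequence, end$tbs$start[2], end$tbs$end[2]),
               dna_revcomp(tbs_sequence(end, "R2")))
  addl <- design_tbs_variants(wt_fixture$left_end, mode = "addition")
  expect_equal(nchar(addl$end_sequence), 147L + 14L)
  # inserted between the last two left-end binding sites
  expect_equal(substr(addl$end_sequence, 1, wt_fixture$left_end$tbs$end[2]),
               substr(wt_fixture$left_end$sequence, 1,
                      wt_fixture$left_end$tbs$end[2]))
})

test_that("barcode assignment yields valid, deterministic manifests", {
  vars <- design_substitutions(wt_fixture$right_end, widths = 1L)
  m1 <- assign_barcodes(vars, wt_fixture$right_end$sequence, seed = 3L)
  expect_equal(nrow(m1), nrow(vars) + 4L)
  expect_equal(sum(m1$category == "wildtype"), 4L)
  expect_true(validate_manifest(m1))
  m2 <- assign_barcodes(vars, wt_fixture$right_end$sequence, seed = 3L)
  expect_identical(as.data.frame(m1), as.data.frame(m2))
  m3 <- assign_barcodes(vars, wt_fixture$right_end$sequence, seed = 4L)
  expect_false(identical(m1$barcode, m3$barcode))
})

test_that("barcode space exhaustion is reported", {
  vars <- design_substitutions(wt_fixture$right_end, widths = 1L)
  expect_error(assign_barcodes(vars, wt_fixture$right_end$sequence,
                               seed = 1L, barcode_length = 3L),
               "barcode space exhausted")
})

test_that("manifests round-trip through TSV and malformed files are named", {
  m <- make_test_manifest()
  tf <- tempfile(fileext = ".tsv")
  write_manifest(m, tf, provenance = "unit test")
  m2 <- read_manifest(tf)
  expect_identical(as.data.frame(m)$barcode, m2$barcode)
  expect_identical(wt_ids(m), wt_ids(m2))
  bad <- as.data.frame(m)
  bad$barcode[3] <- "NOTDNA!!!!"
  tf2 <- tempfile(fileext = ".tsv")
  write_manifest(bad, tf2)
  expect_error(read_manifest(tf2), "row 3")
})
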