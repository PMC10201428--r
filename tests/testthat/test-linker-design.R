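# ORF analysis, constrained recoding and fusion construction.

test_that("stop codons are located per frame", {
  expect_equal(find_stops("TAATAG")$frame1, c(1L, 2L))
  expect_equal(find_stops("GGTGGC")$frame1, integer(0))
  # the minimal right end carries stops in all three frames
  st <- find_stops(wt_minimal$right_end$sequence)
  expect_true(all(lengths(st) >= 1L))
})

test_that("single-codon fixes match the exhaustive neighbor enumeration", {
  variants <- design_linkers("TAA", frame = 1L)
  expect_gt(length(variants), 0L)
  got <- sort(vapply(variants, function(v) v$dna, character(1)))
  # oracle: enumerate the 9 single-base neighbors of TAA
  disallowed <- c("W", "F", "Y", "R", "K", "D", "E", "H", "P")
  code <- genetic_code_table()$code
  nb <- character(0)
  for (i in 1:3) for (b in c("A", "C", "G", "T")) {
    cand <- "TAA"
    substr(cand, i, i) <- b
    if (cand != "TAA" && !(code[cand] %in% c("*", disallowed))) {
      nb <- c(nb, cand)
    }
  }
  expect_identical(got, sort(unique(nb)))
  expect_true(all(vapply(variants, function(v) nrow(v$edits) == 1L,
                         logical(1))))
})

test_that("masked bases are never edited and full masks are unresolvable", {
  expect_error(design_linkers("TAA", frame = 1L, immutable_mask = 1:3),
               "unresolvable codon")
  end <- wt_minimal$right_end
  mask <- conserved_tbs_mask(end)
  for (f in 1:3) {
    variants <- design_linkers(end$sequence, frame = f,
                               immutable_mask = mask, max_variants = 5L)
    expect_gt(length(variants), 0L)
    for (v in variants) {
      expect_length(v$violations, 0L)
      expect_length(find_stops(v$dna)[[f]], 0L)
      expect_equal(nchar(v$dna), nchar(end$sequence))
      changed <- which(strsplit(v$dna, "")[[1]] !=
                         strsplit(end$sequence, "")[[1]])
      expect_length(intersect(changed, mask), 0L)
    }
  }
})

test_that("recoding is minimal: no smaller edit set reaches zero
           violations", {
  dna <- "TGGTAACCA" # Trp, stop, Pro in frame 1
  variants <- design_linkers(dna, frame = 1L, max_variants = 200L)
  n_edit <- vapply(variants, function(v) sum(nchar(v$edits$from) > 0),
                   integer(1))
  min_edits <- vapply(variants, function(v) {
    sum(mapply(function(a, b) {
      sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    }, v$edits$from, v$edits$to))
  }, integer(1))
  # exhaustive search over all 3-codon recodings for the true minimum
  disallowed <- c("W", "F", "Y", "R", "K", "D", "E", "H", "P")
  code <- genetic_code_table()$code
  ok_codons <- names(code)[!(code %in% c("*", disallowed))]
  best <- Inf
  hd <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  for (c1 in ok_codons) for (c2 in ok_codons) for (c3 in ok_codons) {
    d <- hd(c1, "TGG") + hd(c2, "TAA") + hd(c3, "CCA")
    if (d < best) best <- d
  }
  expect_equal(min(min_edits), best)
  expect_true(all(min_edits == best)) # only co-optimal solutions emitted
})

test_that("fusion construction enforces frame and stop-free joints", {
  code <- genetic_code_table()$code
  gene <- strrep("GGC", 30L) # 30 glycine codons
  cargo <- strrep("GCT", 10L) # 10 alanine codons
  linker <- design_linkers(wt_minimal$right_end$sequence, frame = 1L,
                           max_variants = 1L)[[1L]]
  fus <- build_fusion(gene, 90L, linker$dna, cargo)
  expect_true(fus$in_frame)
  expect_equal(fus$n_codons, 30L + 19L + 10L)
  # the stop-carrying wild-type end breaks the fusion
  wt_fus <- build_fusion(gene, 90L, wt_minimal$right_end$sequence, cargo)
  expect_false(wt_fus$in_frame)
  expect_gt(length(wt_fus$internal_stops), 0L)
  # an offset causing a frame shift is reported as such
  shift <- build_fusion(gene, 89L, linker$dna, cargo)
  expect_true(shift$frame_shift)
})

test_that("protein masses use average residue masses plus water", {
  expect_equal(protein_mw("G"), 0.0750671, tolerance = 1e-5)
  expect_warning(mw0 <- protein_mw(""), "empty")
  expect_equal(mw0, 0.01801524, tolerance = 1e-8)
  # cross-check a longer chain against an independent accumulation
  p <- "MSKGEELFT"
  masses <- genetic_code_table()$residue_masses
  manual <- (sum(masses[strsplit(p, "")[[1]]]) +
               genetic_code_table()$water_mass) / 1000
  expect_equal(protein_mw(p), manual)
})

test_that("the packaged sfGFP translates to its expected mass", {
  g <- sfgfp()
  expect_equal(nchar(g$protein), 239L)
  expect_equal(substr(g$protein, 1, 4), "MVSK")
  expect_equal(round(g$mass_kda, 1), 26.8)
  # translation agrees with Biostrings on the packaged CDS
  bs <- as.character(Biostrings::translate(Biostrings::DNAString(g$cds)))
  expect_equal(paste0(g$protein, "*"), bs)
})
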