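# Target-library analysis: filtering, junction calling, enrichment,
# logo pooling and site prediction.

region_a <- target_region("A")

test_that("anchor filtering accepts exact anchors of either length", {
  a34 <- region_a$i5_anchor
  a35 <- region_a$i5_anchor_div
  reads <- c(paste0(a34, "ACGTACGTAC"),
             paste0(a35, "ACGTACGTAC"),
             paste0("T", substr(a34, 2, 34), "ACGTACGT")) # 1 mismatch
  res <- filter_target_read(reads, c(a34, a35))
  expect_equal(res, c(34L, 35L, 0L))
})

test_that("integration calls on error-free reads are exact", {
  s <- simulate_target_reads(default_insertion_model(), 2000, 10000,
                             n_clones = 3000, ends = fixture_ends,
                             seed = 14L)
  calls <- call_integration(s$output$i5, s$output$i7, region_a,
                            ends = fixture_ends)
  expect_true(all(calls$called))
  expect_identical(calls$distance, s$truth$calls$distance)
  expect_identical(calls$orientation, s$truth$calls$orientation)
  expect_identical(calls$degenerate_8mer, s$truth$calls$mer8)
  expect_true(all(calls$end_detected[calls$orientation == "T-RL"] ==
                    "right"))
})

test_that("reads without a junction produce counted no-calls", {
  # unintegrated input reads carry no transposon end
  s <- simulate_target_reads(default_insertion_model(), 500, 500,
                             n_clones = 500, ends = fixture_ends,
                             seed = 15L)
  calls <- call_integration(s$input, NULL, region_a, ends = fixture_ends)
  expect_true(all(!calls$called))
  expect_true(all(calls$reason == "no_end_match"))
})

test_that("degenerate enrichment fold-change arithmetic is exact", {
  withr::with_seed(20L, {
    filler_in <- random_dna(399L, 8L)
    filler_out <- random_dna(396L, 8L)
  })
  mer <- "ACGTACGT"
  input <- c(mer, filler_in) # 1 of 400
  calls <- data.frame(
    degenerate_8mer = c(rep(mer, 4L), filler_out),
    distance = c(rep(49L, 4L), rep(47L, 396L)),
    stringsAsFactors = FALSE)
  e <- degenerate_enrichment(input, calls)
  row <- e[e$mer8 == mer & e$distance == 49L, ]
  expect_equal(row$log2_fc, 2)
  # output combinations with no input counts are undefined
  ghost <- data.frame(degenerate_8mer = "GGGGCCCC", distance = 50L)
  e2 <- degenerate_enrichment(input, rbind(calls, ghost))
  expect_false(e2$defined[e2$mer8 == "GGGGCCCC"])
  # totals conserved against a brute-force recount
  expect_equal(sum(e$output_count), nrow(calls))
  expect_equal(attr(e, "n_input"), length(input))
})

test_that("logo pooling maps bases into TSD-relative columns and
           conserves counts", {
  # a single sequence at distance 49: degenerate positions 43-50 map to
  # window columns -2..+1, each with one observation of the right base
  e <- data.frame(mer8 = "ACGTTGCA", distance = 49L, fold_change = 8)
  logo <- build_logo(list(e), threshold = 4, top_k = 10L)
  expect_equal(unname(colSums(logo)),
               c(0L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 0L, 0L))
  expect_equal(unname(attr(logo, "ic")[colSums(logo) > 0]), rep(2, 8))
  # column counts equal the number of covering sequences
  e2 <- data.frame(mer8 = c("ACGTTGCA", "TTTTTTTT"),
                   distance = c(49L, 46L), fold_change = c(8, 8))
  logo2 <- build_logo(list(e2), threshold = 4, top_k = 10L)
  cover <- function(d) as.integer(43:50 - d + 8L)
  expected <- tabulate(c(cover(49L)[cover(49L) %in% 1:11],
                         cover(46L)[cover(46L) %in% 1:11]), 11L)
  expect_equal(unname(colSums(logo2)), expected)
  # below-threshold sequences are excluded
  e3 <- data.frame(mer8 = "ACGTTGCA", distance = 49L, fold_change = 3.9)
  expect_equal(sum(build_logo(list(e3), threshold = 4, top_k = 10L)), 0L)
})

test_that("motif placement classes shift the modal distance exactly", {
  s <- simulate_target_reads(cwg_insertion_model(), 20000, 60000,
                             n_clones = 20000, ends = fixture_ends,
                             seed = 16L)
  calls <- call_integration(s$output$i5, s$output$i7, region_a,
                            ends = fixture_ends)
  md <- motif_distance_distribution(calls[calls$called, ], "CWG")
  modal <- attr(md, "modal")
  # single-occurrence class at offset j peaks at distance 45 + j
  for (j in as.character(1:6)) {
    expect_equal(unname(modal[j]), 45L + as.integer(j))
  }
  # two non-overlapping copies confer a bimodal distance distribution
  two <- md[md$class == "1+4", ]
  expect_gt(nrow(two), 1L)
  top2 <- two$distance[order(-two$n)][1:2]
  expect_setequal(top2, c(46L, 49L))
  # 8-mers without the motif are excluded from every class
  expect_false(any(md$class == ""))
})

test_that("fitted models recover the planted preference structure", {
  s <- simulate_target_reads(default_insertion_model(), 60000, 30000,
                             n_clones = 10000, ends = fixture_ends,
                             seed = 17L)
  calls <- call_integration(s$output$i5, s$output$i7, region_a,
                            ends = fixture_ends)
  e <- degenerate_enrichment(input_degenerate_mers(s$input, region_a),
                             calls[calls$called, ])
  model <- fit_preference_model(e)
  # the dominant bases of the central triplet are C, A/T, G
  expect_equal(names(which.max(model$weights[, "T2"])), "C")
  expect_true(all(names(sort(model$weights[, "T3"],
                             decreasing = TRUE))[1:2] %in% c("A", "T")))
  expect_equal(names(which.max(model$weights[, "T4"])), "G")
  iupac <- model_iupac_summary(model, mass = 0.85)
  expect_equal(unname(iupac["T3"]), "W")
})

test_that("site prediction ranks a planted optimum first and documents
           tie-breaks", {
  model <- default_insertion_model()
  # two windows with perfect central motifs: distance 49 (its -3 flank at
  # position 42, as on the degenerate targets) and distance 54; in
  # target-A-like flanks the two tie and ascending-distance tie-break
  # ranks 49 first
  ch <- strsplit(strrep("C", 80L), "")[[1]]
  ch[42] <- "G"           # -3 of the 49-bp distance, favored (D)
  ch[46:48] <- c("C", "A", "G")
  ch[51:53] <- c("C", "A", "G")
  ch[57] <- "A"           # +3 of the 54-bp distance, favored (H)
  seq_a <- paste(ch, collapse = "")
  pred <- predict_sites(model, seq_a)
  r <- function(p, d) p$rank[p$distance == d]
  expect_equal(pred$distance[1], 49L)
  expect_equal(pred$score[pred$distance == 49L],
               pred$score[pred$distance == 54L])
  # uniform model: all distances tie, broken by ascending distance
  unif <- insertion_pref_model(matrix(0.25, 4, 11))
  pu <- predict_sites(unif, strrep("ACGT", 20L))
  expect_equal(pu$distance, 43:56)
  # too-short sequences skip incomplete windows and record them
  ps <- predict_sites(model, substr(seq_a, 1, 55))
  expect_equal(attr(ps, "skipped"), 53:56)
  # a disfavored base at -3 of distance 49 only demotes it below its
  # competitor
  ch_b <- ch
  ch_b[42] <- "C"
  pred_b <- predict_sites(model, paste(ch_b, collapse = ""))
  expect_equal(pred_b$distance[1], 54L)
  expect_gt(r(pred_b, 49L), r(pred, 49L))
  expect_gt(pred$score[pred$distance == 49L],
            pred_b$score[pred_b$distance == 49L])
})
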