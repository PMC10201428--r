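# Barcode extraction, counting, enrichment arithmetic and coupling QC.

test_that("barcode extraction requires a perfect primer match", {
  p <- donor_primer19()
  expect_equal(extract_barcode(paste0("CCGGA", p, "ACGTACGTAC", "GGG")),
               "ACGTACGTAC")
  # one mismatch in the primer anchor rejects the read
  p_mut <- paste0("A", substr(p, 2, 19))
  if (p_mut == p) p_mut <- paste0("C", substr(p, 2, 19))
  expect_true(is.na(extract_barcode(paste0("CCGGA", p_mut, "ACGTACGTAC"))))
  # fewer than 10 nt after the anchor rejects the read
  expect_true(is.na(extract_barcode(paste0("CCGGA", p, "ACGTACGTA"))))
  # first occurrence wins when the anchor appears twice
  expect_equal(extract_barcode(paste0(p, "AAAAAAAAAA", p, "CCCCCCCCCC")),
               "AAAAAAAAAA")
})

test_that("barcode counting matches the brute-force oracle", {
  m <- make_test_manifest()
  tr <- sim_truth(m, uncoupling_rate = 0.2, error_rate = 0.005, seed = 5L)
  s <- simulate_donor_reads(m, tr, 1000, 1000, seed = 11L)
  ct <- count_barcodes(s$input, m)
  expect_identical(ct$counts,
                   oracle_count_barcodes(s$input, m, donor_primer19()))
  expect_equal(sum(ct$counts), ct$n_barcode_matched)
  expect_lte(ct$n_barcode_matched, ct$n_pass_filter)
  expect_lte(ct$n_pass_filter, ct$n_total_reads)
})

test_that("counting edge cases: unmatched barcodes and empty read sets", {
  m <- make_test_manifest()
  p <- donor_primer19()
  reads <- c(paste0(p, m$barcode[1]), paste0(p, m$barcode[1]),
             paste0(p, m$barcode[1]), paste0(p, "GGGGGGGGGG"))
  ct <- count_barcodes(reads, m)
  expect_equal(unname(ct$counts[m$variant_id[1]]), 3L)
  expect_equal(ct$n_barcode_matched, 3L)
  expect_equal(ct$n_pass_filter, 4L)
  empty <- count_barcodes(character(0), m)
  expect_true(all(empty$counts == 0L))
  expect_equal(empty$n_total_reads, 0L)
})

test_that("merging count tables sums counts and QC counters", {
  m <- make_test_manifest()
  p <- donor_primer19()
  t1 <- count_barcodes(rep(paste0(p, m$barcode[1]), 2), m, "runA")
  t2 <- count_barcodes(c(rep(paste0(p, m$barcode[1]), 3),
                         paste0(p, m$barcode[2])), m, "runB")
  mg <- merge_counts(t1, t2)
  expect_equal(unname(mg$counts[m$variant_id[1]]), 5L)
  expect_equal(mg$n_total_reads, 6L)
  # identity and commutativity
  e <- count_barcodes(character(0), m)
  expect_equal(merge_counts(t1, e)$counts, t1$counts)
  expect_equal(merge_counts(t1, t2)$counts, merge_counts(t2, t1)$counts)
})

test_that("enrichment arithmetic and wild-type normalization are exact", {
  m <- make_test_manifest()
  wt <- wt_ids(m)
  ids <- m$variant_id
  mk <- function(counts) {
    structure(list(sample_id = "x",
                   counts = stats::setNames(counts, ids),
                   n_total_reads = sum(counts),
                   n_pass_filter = sum(counts),
                   n_barcode_matched = sum(counts)),
              class = "count_table")
  }
  n <- length(ids)
  input <- mk(rep(10L, n))
  out_counts <- rep(10L, n)
  out_counts[1] <- 20L
  output <- mk(out_counts)
  e <- enrichment(input, output, wt)
  # wild-type members have fold-change 1x the WT mean by construction
  expect_equal(mean(e$normalized_score[e$variant_id %in% wt]), 1)
  expect_equal(e$log2_normalized[e$variant_id %in% wt], rep(0, 4))
  # doubled output count doubles fold change relative to WT
  expect_equal(e$normalized_score[1], 2, tolerance = 1e-12)
  # undefined for zero input
  in2 <- rep(10L, n); in2[2] <- 0L
  e2 <- enrichment(mk(in2), output, wt)
  expect_false(e2$defined[2])
  expect_true(is.na(e2$normalized_score[2]))
  # wild-type member missing from input is an error
  in3 <- rep(10L, n); in3[ids == wt[1]] <- 0L
  expect_error(enrichment(mk(in3), output, wt), "zero input")
})

test_that("normalization is idempotent and scale invariant", {
  m <- make_test_manifest()
  tr <- sim_truth(m, uncoupling_rate = 0.1, error_rate = 0.001, seed = 6L)
  s <- simulate_donor_reads(m, tr, 20000, 20000, seed = 12L)
  ic <- count_barcodes(s$input, m)
  oc <- count_barcodes(s$output, m)
  e <- enrichment(ic, oc, wt_ids(m))
  # idempotence: renormalizing by the WT mean changes nothing
  wt_mean <- mean(e$normalized_score[e$variant_id %in% wt_ids(m)])
  expect_equal(e$normalized_score / wt_mean, e$normalized_score)
  # scale invariance: multiplying all output counts by a constant
  oc10 <- oc
  oc10$counts <- oc$counts * 10L
  oc10$n_barcode_matched <- oc$n_barcode_matched * 10L
  e10 <- enrichment(ic, oc10, wt_ids(m))
  expect_equal(e10$normalized_score, e$normalized_score)
})

test_that("coupling QC fractions follow exact pair arithmetic", {
  m <- make_test_manifest()
  p <- donor_primer19()
  v1 <- 5L
  r1 <- rep(paste0(p, m$barcode[v1]), 3)
  r2 <- c(m$end_sequence[v1], m$end_sequence[v1], m$end_sequence[8])
  rep1 <- coupling_qc(r1, r2, m)
  pv <- rep1$per_variant
  expect_equal(pv$fraction_correct[v1], 2 / 3)
  expect_equal(pv$most_abundant_incorrect_fraction[v1], 1 / 3)
  # unmatched barcodes are excluded and counted
  rep2 <- coupling_qc(c(r1, paste0(p, "GGGGGGGGGG")),
                      c(r2, m$end_sequence[1]), m)
  expect_equal(rep2$n_barcode_unmatched, 1L)
  expect_equal(rep2$n_pairs_used, 3L)
})

test_that("planted efficiencies are recovered despite uncoupling noise", {
  m <- make_test_manifest()
  tr <- sim_truth(m, uncoupling_rate = 0.36, error_rate = 0.001, seed = 7L)
  s <- simulate_donor_reads(m, tr, 50000, 50000, seed = 13L)
  e <- enrichment(count_barcodes(s$input, m), count_barcodes(s$output, m),
                  wt_ids(m))
  rho <- stats::cor(tr$efficiency[e$variant_id], e$normalized_score,
                    method = "spearman", use = "complete.obs")
  expect_gte(rho, 0.9)
})
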