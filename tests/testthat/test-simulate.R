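# Read simulators: determinism, conservation, planted-parameter behavior.

test_that("ground truth records validate and round-trip losslessly", {
  m <- make_test_manifest()
  tr <- sim_truth(m, uncoupling_rate = 0.2, error_rate = 0.001, seed = 5L)
  expect_true(all(tr$efficiency[wt_ids(m)] == 1))
  expect_equal(sum(tr$abundance), 1)
  tf <- tempfile(fileext = ".tsv")
  write_truth(tr, tf)
  tr2 <- read_truth(tf)
  expect_equal(tr2$efficiency, tr$efficiency)
  expect_equal(tr2$abundance, tr$abundance)
  expect_equal(tr2$uncoupling_rate, 0.2)
  expect_equal(tr2$error_rate, 0.001)
  expect_error(sim_truth(m, efficiency = stats::setNames(
    rep(-1, nrow(m)), m$variant_id)), "non-negative")
})

test_that("donor simulator is deterministic and conserves read counts", {
  m <- make_test_manifest()
  tr <- sim_truth(m, uncoupling_rate = 0.1, error_rate = 0.001, seed = 5L)
  s1 <- simulate_donor_reads(m, tr, 2000, 2000, seed = 9L)
  s2 <- simulate_donor_reads(m, tr, 2000, 2000, seed = 9L)
  expect_identical(s1$input, s2$input)
  expect_identical(s1$output, s2$output)
  expect_length(s1$input, 2000L)
  expect_length(s1$output, 2000L)
})

test_that("null donor model: output barcode frequencies match input", {
  m <- make_test_manifest()
  tr <- sim_truth(m, efficiency = stats::setNames(rep(1, nrow(m)),
                                                  m$variant_id),
                  uncoupling_rate = 0, error_rate = 0, seed = 2L)
  s <- simulate_donor_reads(m, tr, 20000, 20000, seed = 3L)
  ic <- count_barcodes(s$input, m)$counts
  oc <- count_barcodes(s$output, m)$counts
  keep <- ic + oc > 10
  chi <- suppressWarnings(
    stats::chisq.test(rbind(ic[keep], oc[keep]))$p.value)
  expect_gt(chi, 1e-4)
})

test_that("zero-efficiency variants yield zero output reads", {
  m <- make_test_manifest()
  eff <- stats::setNames(rep(1, nrow(m)), m$variant_id)
  dead <- setdiff(m$variant_id, wt_ids(m))[1:5]
  eff[dead] <- 0
  tr <- sim_truth(m, efficiency = eff, uncoupling_rate = 0, error_rate = 0,
                  seed = 2L)
  s <- simulate_donor_reads(m, tr, 5000, 5000, seed = 3L)
  oc <- count_barcodes(s$output, m)$counts
  expect_true(all(oc[dead] == 0))
})

test_that("coupling pairs reflect the planted uncoupling rate", {
  m <- make_test_manifest()
  tr0 <- sim_truth(m, uncoupling_rate = 0, seed = 2L)
  p0 <- simulate_coupling_pairs(m, tr0, 2000, seed = 4L)
  r0 <- coupling_qc(p0$read1, p0$read2, m)
  expect_equal(r0$overall_fraction_correct, 1)
  expect_true(all(r0$per_variant$fraction_correct[
    r0$per_variant$n_pairs > 0] == 1))
  expect_error(simulate_coupling_pairs(m, tr0, 0), "n must be")
})

test_that("target simulator distances follow the planted model", {
  # uniform model: all attainable distances drawn, none dominant
  unif <- insertion_pref_model(matrix(0.25, 4, 11))
  s <- simulate_target_reads(unif, 1000, 20000, n_clones = 2000, seed = 6L)
  tab <- table(s$truth$calls$distance)
  expect_setequal(as.integer(names(tab)), 43:56)
  expect_lt(max(tab) / sum(tab), 2.5 / 14)
  # strong central motif: distances concentrate on the in-window
  # placements, far above the uniform share
  one <- cwg_insertion_model()
  s1 <- simulate_target_reads(one, 1000, 20000, n_clones = 2000, seed = 7L)
  tab1 <- table(s1$truth$calls$distance)
  expect_gt(max(tab1) / sum(tab1), 1.6 / 14)
  expect_true(as.integer(names(which.max(tab1))) %in% 46:51)
  expect_length(s1$output$i5, 20000L)
  expect_length(s1$output$i7, 20000L)
})

test_that("tn7 simulator validates classes and conserves counts", {
  prefixes <- tn7_class_prefixes(fixture_ends)
  expect_equal(length(prefixes), 1L + 31L * 2L)
  expect_true(all(nchar(prefixes) == 65L))
  expect_error(simulate_tn7_reads(100, c("d31_T-RL" = 1), prefixes),
               "unknown read class")
  expect_error(simulate_tn7_reads(100, c(unintegrated = 0.5), prefixes),
               "sum to 1")
  reads <- simulate_tn7_reads(500, c(unintegrated = 0.6, "d05_T-RL" = 0.4),
                              prefixes, seed = 8L)
  expect_length(reads, 500L)
  expect_setequal(unique(names(reads)), c("unintegrated", "d05_T-RL"))
})

test_that("fastq round-trips preserve simulated reads", {
  m <- make_test_manifest()
  tr <- sim_truth(m, seed = 5L)
  s <- simulate_donor_reads(m, tr, 50, 50, seed = 9L)
  tf <- tempfile(fileext = ".fastq")
  write_fastq(s$input, tf)
  back <- read_fastq(tf)
  expect_identical(unname(back), unname(s$input))
})
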