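# Shared fixtures and independent brute-force oracles used across tests.

wt_fixture <- make_wt_fixture()
wt_minimal <- make_wt_fixture(minimal_right = TRUE)
fixture_ends <- list(left = wt_fixture$left_end$sequence,
                     right = wt_fixture$right_end$sequence)

# brute-force IUPAC scan: explicit per-window character comparison
oracle_iupac_scan <- function(seq, pattern, max_mismatch = 0) {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))
  p <- strsplit(pattern, "")[[1]]
  s <- strsplit(seq, "")[[1]]
  hits <- integer(0)
  mm <- integer(0)
  for (start in seq_len(length(s) - length(p) + 1)) {
    n_mm <- 0L
    for (j in seq_along(p)) {
      if (!(s[start + j - 1] %in% sets[[p[j]]])) n_mm <- n_mm + 1L
    }
    if (n_mm <= max_mismatch) {
      hits <- c(hits, start)
      mm <- c(mm, n_mm)
    }
  }
  data.frame(start = hits, n_mismatch = mm)
}

# brute-force barcode counter: per-read character scan for the primer,
# then exact barcode lookup
oracle_count_barcodes <- function(reads, manifest, primer19) {
  counts <- stats::setNames(integer(nrow(manifest)), manifest$variant_id)
  for (r in reads) {
    pos <- NA
    for (s in seq_len(max(nchar(r) - 18, 0))) {
      if (substr(r, s, s + 18) == primer19) { pos <- s; break }
    }
    if (is.na(pos)) next
    bc <- substr(r, pos + 19, pos + 28)
    if (nchar(bc) < 10) next
    hit <- which(manifest$barcode == bc)
    if (length(hit) == 1) counts[hit] <- counts[hit] + 1L
  }
  counts
}

# small manifest used by several donor-side tests
make_test_manifest <- function(seed = 42L) {
  assign_barcodes(design_substitutions(wt_minimal$right_end, widths = 1L),
                  wt_minimal$right_end$sequence, seed = seed)
}

random_seqs <- function(n, len, seed) {
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = "")
    }, character(1))
  })
}
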