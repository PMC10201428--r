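# IUPAC consensus scanning and position-frequency-matrix (logo) construction.
#
# These primitives back both the transposon-end annotation (TnsB binding
# site consensus, IHF consensus 5'-WATCARNNNNTTR-3') and the target-site
# duplication logos; they are deliberately hand-written so tests can hold
# them against independent oracles (exhaustive per-window scans,
# Biostrings::matchPattern).

#' Scan a DNA sequence for IUPAC consensus matches
#'
#' Slides a degenerate IUPAC pattern over a plain ACGT sequence and reports
#' every window whose mismatch count is at most `max_mismatch`. A pattern
#' symbol matches a base when the base belongs to the symbol's IUPAC set
#' (e.g. `W` matches A or T).
#'
#' @param seq single DNA string (ACGT).
#' @param pattern IUPAC pattern string over `ACGTRYSWKMBDHVN`.
#' @param both_strands also scan the reverse complement. Hits on the minus
#'   strand are reported with `strand = "-"` and `start` giving the position
#'   of the leftmost base of the matching window on the *forward* sequence.
#' @param max_mismatch maximum tolerated mismatches per window (default 0).
#' @return data.frame with columns `start` (1-based), `strand`, `n_mismatch`.
#' @examples
#' iupac_scan("TATCAGACGTTTA", "WATCARNNNNTTR")
#' @export
iupac_scan <- function(seq, pattern, both_strands = FALSE, max_mismatch = 0) {
  stopifnot(length(seq) == 1L, length(pattern) == 1L)
  pat <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  bad <- setdiff(pat, names(IUPAC_SETS))
  if (length(bad) > 0) {
    stop(sprintf("invalid IUPAC symbol(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  seq <- toupper(seq)
  stopifnot_dna(seq, "subject sequence")
  if (nchar(seq) < length(pat)) {
    stop("sequence shorter than pattern", call. = FALSE)
  }
  hits <- scan_one_strand(seq, pat, max_mismatch)
  hits$strand <- rep("+", nrow(hits))
  if (both_strands) {
    rc <- dna_revcomp(seq)
    h2 <- scan_one_strand(rc, pat, max_mismatch)
    if (nrow(h2) > 0) {
      # map start on revcomp back to forward coordinates of the window
      h2$start <- nchar(seq) - (h2$start + length(pat) - 1L) + 1L
      h2$strand <- "-"
      hits <- rbind(hits, h2)
    }
  }
  hits <- hits[order(hits$start, hits$strand), c("start", "strand", "n_mismatch")]
  rownames(hits) <- NULL
  hits
}

# vectorized single-strand scan: one logical vector per pattern position
scan_one_strand <- function(seq, pat, max_mismatch) {
  L <- nchar(seq)
  k <- length(pat)
  n_win <- L - k + 1L
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  mism <- integer(n_win)
  for (j in seq_len(k)) {
    ok <- ch[j:(j + n_win - 1L)] %in% IUPAC_SETS[[pat[j]]]
    mism <- mism + !ok
  }
  keep <- which(mism <= max_mismatch)
  data.frame(start = keep, n_mismatch = mism[keep])
}

#' Build a position frequency matrix from aligned sites
#'
#' Counts nucleotides per column across equal-length sequences and computes
#' the per-column information content IC = 2 - H (bits), where H is the
#' Shannon entropy of the column's base frequencies. No small-sample
#' correction is applied (plain WebLogo-style columns).
#'
#' @param seqs character vector of equal-length ACGT sequences.
#' @param positions optional character vector of column labels.
#' @return object of class `pfm`: a 4 x L count matrix (rows A,C,G,T) with
#'   attributes `ic` (bits per column), `n` (sequences) and `conserved`
#'   (columns with a single observed base).
#' @examples
#' logo_from_sites(c("ACGT", "ACGA"))
#' @export
logo_from_sites <- function(seqs, positions = NULL) {
  if (length(seqs) < 1L) stop("need at least one sequence", call. = FALSE)
  seqs <- toupper(seqs)
  stopifnot_dna(seqs, "site sequences")
  m <- seq_matrix(seqs)
  counts <- vapply(seq_len(ncol(m)),
                   function(j) tabulate(factor(m[, j], levels = DNA_BASES), 4L),
                   integer(4))
  rownames(counts) <- DNA_BASES
  colnames(counts) <- positions %||% as.character(seq_len(ncol(m)))
  new_pfm(counts)
}

new_pfm <- function(counts) {
  stopifnot(nrow(counts) == 4L)
  structure(counts,
            ic = pfm_ic(counts),
            n = max(colSums(counts)),
            conserved = which(apply(counts > 0, 2, sum) == 1L &
                                colSums(counts) > 0),
            class = "pfm")
}

pfm_ic <- function(counts) {
  apply(counts, 2, function(col) {
    tot <- sum(col)
    if (tot == 0) return(NA_real_)
    p <- col[col > 0] / tot
    2 + sum(p * log2(p))
  })
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("Position frequency matrix: %d positions, max column count %d\n",
              ncol(x), attr(x, "n")))
  m <- unclass(x)
  attributes(m)[c("ic", "n", "conserved")] <- NULL
  print(m)
  cat("IC (bits):", paste(sprintf("%.2f", attr(x, "ic")), collapse = " "), "\n")
  invisible(x)
}

#' @method plot pfm
#' @export
plot.pfm <- function(x, main = "Information content", ...) {
  ic <- attr(x, "ic")
  graphics::barplot(ic, names.arg = colnames(x), ylim = c(0, 2),
                    ylab = "bits", main = main, ...)
  invisible(x)
}

#' Column frequencies of a position frequency matrix
#'
#' @param x a `pfm` object.
#' @param pseudocount added to every cell before normalization.
#' @return 4 x L matrix of per-column base frequencies.
#' @export
pfm_frequencies <- function(x, pseudocount = 0) {
  m <- unclass(x) + pseudocount
  attributes(m)[c("ic", "n", "conserved", "class")] <- NULL
  tot <- colSums(m)
  tot[tot == 0] <- NA_real_
  sweep(m, 2, tot, "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
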