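#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC degenerate nucleotide alphabet
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Complement and reverse-complement of DNA strings
#'
#' Vectorized over character vectors of plain ACGT sequences.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
dna_complement <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

#' @rdname dna_complement
#' @export
dna_revcomp <- function(x) {
  vapply(strsplit(dna_complement(x), "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

stopifnot_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop(sprintf("%s contains non-ACGT characters (first offender: '%s')",
                 what, x[which(bad)[1]]), call. = FALSE)
  }
  invisible(x)
}

# deterministic random DNA given the current RNG state
random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  apply(m, 1, paste, collapse = "")
}

# split equal-length sequences into an n x L character matrix
seq_matrix <- function(seqs) {
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("sequences must have equal length", call. = FALSE)
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = length(seqs), ncol = L, byrow = TRUE)
}

#' Read and write FASTA/FASTQ files
#'
#' Thin wrappers around Biostrings that exchange plain named character
#' vectors, the representation used throughout this package.
#'
#' @param path file path.
#' @param seqs named character vector of DNA sequences.
#' @param quality single quality character recycled over every base
#'   (no stage of the pipeline uses base qualities).
#' @return `read_fasta()`/`read_fastq()` return a named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname read_fasta
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @export
write_fastq <- function(seqs, path, quality = "I") {
  if (is.null(names(seqs))) names(seqs) <- sprintf("read%d", seq_along(seqs))
  dss <- Biostrings::DNAStringSet(seqs)
  quals <- Biostrings::BStringSet(strrep(quality, nchar(seqs)))
  Biostrings::writeXStringSet(dss, path, format = "fastq", qualities = quals)
  invisible(path)
}

# inject uniform substitution errors at per-base rate `rate`;
# only reads drawn with >= 1 error are touched, so low rates stay cheap
add_read_errors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0L) return(reads)
  nerr <- stats::rbinom(length(reads), nchar(reads), rate)
  idx <- which(nerr > 0L)
  for (i in idx) {
    pos <- sample.int(nchar(reads[i]), nerr[i])
    ch <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    for (p in pos) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
    reads[i] <- paste(ch, collapse = "")
  }
  reads
}

# write a data.frame as TSV with '#'-prefixed provenance lines
write_tsv_prov <- function(df, path, provenance = character(0)) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (line in provenance) writeLines(paste0("# ", line), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_prov <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
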