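# Auxiliary quantification utilities: qPCR relative efficiency, normalized
# fluorescence intensity, and Tn7 attachment-site amplicon classification.

#' qPCR transposition efficiency (2^dCq)
#'
#' Efficiency per reaction is `2^(Cq_reference - Cq_target)`, so that rarer
#' integration products (later Cq) give efficiencies below 1. Replicates
#' are aggregated as the mean of per-replicate efficiencies (set
#' `average_dcq = TRUE` to average dCq before exponentiation instead).
#'
#' @param records data.frame with columns `cq_target`, `cq_reference` and
#'   optionally `orientation` (grouping variable).
#' @param average_dcq average dCq across replicates before exponentiation.
#' @return data.frame with `orientation`, `n`, `efficiency`.
#' @examples
#' qpcr_efficiency(data.frame(cq_target = 20, cq_reference = 18)) # 0.25
#' @export
qpcr_efficiency <- function(records, average_dcq = FALSE) {
  stopifnot(is.data.frame(records),
            all(c("cq_target", "cq_reference") %in% names(records)))
  if (anyNA(records$cq_reference)) {
    stop("missing reference Cq", call. = FALSE)
  }
  if (anyNA(records$cq_target)) {
    stop("missing target Cq", call. = FALSE)
  }
  orientation <- records$orientation %||% rep("all", nrow(records))
  dcq <- records$cq_reference - records$cq_target
  eff <- 2^dcq
  out <- lapply(split(seq_len(nrow(records)), orientation), function(i) {
    data.frame(orientation = orientation[i[1L]], n = length(i),
               efficiency = if (average_dcq) 2^mean(dcq[i])
                            else mean(eff[i]))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Normalized fluorescence intensity
#'
#' Element-wise fluorescence / OD600 across a time series.
#'
#' @param fluorescence,od600 equal-length numeric vectors; OD must be
#'   positive.
#' @return numeric vector of normalized intensities.
#' @export
nfi <- function(fluorescence, od600) {
  if (length(fluorescence) != length(od600)) {
    stop("fluorescence and od600 series differ in length", call. = FALSE)
  }
  if (any(od600 <= 0)) stop("od600 must be positive", call. = FALSE)
  fluorescence / od600
}

#' Expected 65-nt prefixes of Tn7 attachment-site amplicons
#'
#' Builds the prefix table for classifying glmS-locus amplicon reads: the
#' unintegrated genomic product, and integration at 0-30 bp downstream of
#' the attachment point in either orientation. Each integrated prefix is
#' the genomic sequence up to the junction followed by the proximal
#' transposon end, truncated at 65 nt. The synthetic genomic context is
#' deterministic, and all prefixes are pairwise distinct by construction.
#'
#' @param ends list with `left`/`right` tip-inward end sequences (default:
#'   wild-type fixture).
#' @param genomic_lead bases of genomic sequence before the d = 0 junction
#'   (default 20).
#' @return named character vector of 65-nt prefixes; names are
#'   `"unintegrated"` and `"d<dd>_<T-RL|T-LR>"`.
#' @export
tn7_class_prefixes <- function(ends = NULL, genomic_lead = 20L) {
  if (is.null(ends)) {
    tn <- make_wt_fixture()
    ends <- list(left = tn$left_end$sequence, right = tn$right_end$sequence)
  }
  genome <- withr::with_seed(73107310L, random_dna(1L, 80L))
  prefixes <- c(unintegrated = substr(genome, 1L, 65L))
  for (d in 0:30) {
    for (o in c("T-RL", "T-LR")) {
      end_seq <- if (o == "T-RL") ends$right else ends$left
      p <- paste0(substr(genome, 1L, genomic_lead + d),
                  substr(end_seq, 1L, 65L - genomic_lead - d))
      prefixes[sprintf("d%02d_%s", d, o)] <- p
    }
  }
  if (anyDuplicated(prefixes)) {
    stop("degenerate prefix table: classes are not distinguishable",
         call. = FALSE)
  }
  prefixes
}

#' Classify Tn7 attachment-site amplicon reads
#'
#' Exact-prefix classification: a read whose first 65 nt match an expected
#' class prefix is tallied to that class; everything else is counted as
#' unclassified. Each read contributes to exactly one tally.
#'
#' @param reads character vector of reads (>= 65 nt).
#' @param prefixes prefix table from [tn7_class_prefixes()].
#' @return object of class `tn7_class_table`: list with `counts` (named,
#'   over all classes), `n_unclassified`, `n_reads`,
#'   `integrated_fraction` (of classified reads).
#' @export
classify_tn7 <- function(reads, prefixes = tn7_class_prefixes()) {
  idx <- match(substr(reads, 1L, 65L), prefixes)
  counts <- tabulate(idx, nbins = length(prefixes))
  names(counts) <- names(prefixes)
  n_class <- sum(counts)
  structure(list(counts = counts,
                 n_unclassified = length(reads) - n_class,
                 n_reads = length(reads),
                 integrated_fraction =
                   if (n_class > 0)
                     sum(counts[names(counts) != "unintegrated"]) / n_class
                   else NA_real_),
            class = "tn7_class_table")
}

#' @export
print.tn7_class_table <- function(x, ...) {
  cat(sprintf(paste0("<tn7_class_table> %d reads: %d classified ",
                     "(%.1f%% integrated), %d unclassified\n"),
              x$n_reads, x$n_reads - x$n_unclassified,
              100 * x$integrated_fraction, x$n_unclassified))
  top <- sort(x$counts[x$counts > 0], decreasing = TRUE)
  print(utils::head(top, 5L))
  invisible(x)
}
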