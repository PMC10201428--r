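# Donor-library quantification: primer-anchor filtering, exact barcode
# counting, run merging, wild-type-normalized enrichment and coupling QC.

#' Extract the 10-nt barcode downstream of the primer anchor
#'
#' Returns the 10 nt immediately downstream of the first exact occurrence of
#' the 19-nt primer-binding sequence; reads without a perfect primer match,
#' or with fewer than 10 nt after it, are rejected (`NA`). Rejection is a
#' QC-counted outcome, not an error.
#'
#' @param reads character vector of reads.
#' @param primer19 the 19-nt primer-binding sequence at the cargo-proximal
#'   terminus of the transposon end.
#' @param barcode_length barcode length (default 10).
#' @return character vector of barcodes (`NA` = rejected).
#' @export
extract_barcode <- function(reads, primer19 = donor_primer19(),
                            barcode_length = 10L) {
  if (nchar(primer19) != 19L) stop("primer19 must be 19 nt", call. = FALSE)
  pos <- regexpr(primer19, reads, fixed = TRUE)
  start <- ifelse(pos > 0L, pos + 19L, NA_integer_)
  bc <- substr(reads, start, start + barcode_length - 1L)
  bc[is.na(start) | nchar(bc) < barcode_length] <- NA_character_
  bc
}

#' Count library-member barcodes in a read set
#'
#' Exact-match counting: reads failing primer-anchor extraction are counted
#' as filtered; extracted barcodes not matching any manifest barcode are
#' discarded and counted.
#'
#' @param reads character vector of reads.
#' @param manifest a `variant_manifest`.
#' @param sample_id label carried in the result.
#' @inheritParams extract_barcode
#' @return object of class `count_table`: list with `sample_id`, `counts`
#'   (named integer vector over all manifest variants), `n_total_reads`,
#'   `n_pass_filter`, `n_barcode_matched`.
#' @export
count_barcodes <- function(reads, manifest, sample_id = "sample",
                           primer19 = donor_primer19()) {
  validate_manifest(manifest)
  bc <- extract_barcode(reads, primer19,
                        barcode_length = nchar(manifest$barcode[1L]))
  idx <- match(bc, manifest$barcode)
  counts <- tabulate(idx, nbins = nrow(manifest))
  names(counts) <- manifest$variant_id
  structure(list(sample_id = sample_id,
                 counts = counts,
                 n_total_reads = length(reads),
                 n_pass_filter = sum(!is.na(bc)),
                 n_barcode_matched = sum(!is.na(idx))),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf(paste0("<count_table> %s: %d reads, %d passed filter, ",
                     "%d barcode-matched over %d variants\n"),
              x$sample_id, x$n_total_reads, x$n_pass_filter,
              x$n_barcode_matched, length(x$counts)))
  invisible(x)
}

#' Merge barcode count tables across sequencing runs
#'
#' Element-wise sum of counts and QC counters (the same PCR sample sequenced
#' on multiple runs).
#'
#' @param t1,t2 `count_table` objects over the same variant set.
#' @return a `count_table`.
#' @export
merge_counts <- function(t1, t2) {
  stopifnot(inherits(t1, "count_table"), inherits(t2, "count_table"))
  if (!identical(names(t1$counts), names(t2$counts))) {
    stop("count tables cover different variant sets", call. = FALSE)
  }
  structure(list(sample_id = paste(unique(c(t1$sample_id, t2$sample_id)),
                                   collapse = "+"),
                 counts = t1$counts + t2$counts,
                 n_total_reads = t1$n_total_reads + t2$n_total_reads,
                 n_pass_filter = t1$n_pass_filter + t2$n_pass_filter,
                 n_barcode_matched = t1$n_barcode_matched +
                   t2$n_barcode_matched),
            class = "count_table")
}

#' Wild-type-normalized enrichment scores
#'
#' Relative abundance = count / total matched counts per sample; fold-change
#' = output fraction / input fraction; the normalized score divides each
#' fold-change by the mean fold-change of the four wild-type members, and
#' log2 is applied last. Variants with zero input counts are reported as
#' undefined (`NA`) rather than smoothed; an optional pseudocount (default
#' 0, i.e. no smoothing) is added to every count before fractions are
#' formed.
#'
#' @param input,output `count_table` objects for the input and output
#'   libraries.
#' @param wt `character` ids of the wild-type members (default: taken from
#'   the `wt_ids` column/attribute convention, i.e. pass them explicitly or
#'   via a manifest's [wt_ids()]).
#' @param pseudocount added to every count (default 0).
#' @return object of class `enrichment_table` (a data.frame with columns
#'   variant_id, input_count, output_count, input_fraction, output_fraction,
#'   fold_change, normalized_score, log2_normalized, defined).
#' @export
enrichment <- function(input, output, wt, pseudocount = 0) {
  stopifnot(inherits(input, "count_table"), inherits(output, "count_table"))
  if (!identical(names(input$counts), names(output$counts))) {
    stop("input and output tables cover different variant sets",
         call. = FALSE)
  }
  ids <- names(input$counts)
  missing_wt <- setdiff(wt, ids)
  if (length(missing_wt) > 0) {
    stop("wild-type member(s) absent from the tables: ",
         paste(missing_wt, collapse = ", "), call. = FALSE)
  }
  ic <- input$counts + pseudocount
  oc <- output$counts + pseudocount
  if (any(ic[wt] <= 0)) {
    stop("wild-type member(s) with zero input counts: ",
         paste(wt[ic[wt] <= 0], collapse = ", "), call. = FALSE)
  }
  in_frac <- ic / sum(ic)
  out_frac <- oc / sum(oc)
  fc <- ifelse(ic > 0, out_frac / in_frac, NA_real_)
  wt_mean <- mean(fc[wt])
  if (!is.finite(wt_mean) || wt_mean <= 0) {
    stop("mean wild-type fold-change is not positive", call. = FALSE)
  }
  norm <- fc / wt_mean
  res <- data.frame(variant_id = ids,
                    input_count = unname(input$counts),
                    output_count = unname(output$counts),
                    input_fraction = unname(in_frac),
                    output_fraction = unname(out_frac),
                    fold_change = unname(fc),
                    normalized_score = unname(norm),
                    log2_normalized = unname(log2(norm)),
                    defined = unname(ic > 0),
                    stringsAsFactors = FALSE)
  structure(res, wt = wt, class = c("enrichment_table", "data.frame"))
}

#' Barcode/end coupling QC
#'
#' A pair is "correct" when read 2 carries the manifest end sequence of the
#' variant identified by read 1's barcode (longest matching manifest end at
#' the start of read 2 decides the end identity). Pairs whose barcode
#' matches no library member are excluded and counted.
#'
#' @param read1,read2 character vectors: barcode-carrying reads and
#'   end-carrying mates.
#' @param manifest a `variant_manifest`.
#' @inheritParams extract_barcode
#' @return object of class `coupling_report`: list with `per_variant`
#'   (data.frame: variant_id, n_pairs, n_correct, fraction_correct,
#'   most_abundant_incorrect_fraction), `overall_fraction_correct`,
#'   `mean_most_abundant_incorrect`, `n_pairs_used`, `n_barcode_unmatched`.
#' @export
coupling_qc <- function(read1, read2, manifest,
                        primer19 = donor_primer19()) {
  validate_manifest(manifest)
  stopifnot(length(read1) == length(read2))
  bc <- extract_barcode(read1, primer19,
                        barcode_length = nchar(manifest$barcode[1L]))
  vid <- match(bc, manifest$barcode)
  used <- which(!is.na(vid))
  ends <- unique(manifest$end_sequence)
  ends <- ends[order(-nchar(ends))] # longest match decides identity
  end_id <- rep(NA_integer_, length(read2))
  for (k in seq_along(ends)) {
    hit <- used[is.na(end_id[used]) &
                  startsWith(read2[used], ends[k])]
    end_id[hit] <- k
  }
  expected <- match(manifest$end_sequence[vid], ends)
  correct <- !is.na(end_id) & end_id == expected
  per <- lapply(seq_len(nrow(manifest)), function(v) {
    i <- used[vid[used] == v]
    n <- length(i)
    n_ok <- sum(correct[i])
    worst <- 0
    if (n > n_ok) {
      wrong <- end_id[i][!correct[i]]
      wrong[is.na(wrong)] <- 0L # unrecognized end sequences pool together
      worst <- max(tabulate(wrong + 1L)) / n
    }
    data.frame(variant_id = manifest$variant_id[v], n_pairs = n,
               n_correct = n_ok,
               fraction_correct = if (n > 0) n_ok / n else NA_real_,
               most_abundant_incorrect_fraction = if (n > 0) worst
                                                  else NA_real_)
  })
  per <- do.call(rbind, per)
  structure(list(
    per_variant = per,
    overall_fraction_correct = sum(per$n_correct) / max(sum(per$n_pairs), 1L),
    mean_most_abundant_incorrect =
      mean(per$most_abundant_incorrect_fraction[per$n_pairs > 0]),
    n_pairs_used = length(used),
    n_barcode_unmatched = length(read1) - length(used)),
    class = "coupling_report")
}

#' @export
print.coupling_report <- function(x, ...) {
  cat(sprintf(paste0("<coupling_report> %d pairs used (%d unmatched): ",
                     "%.1f%% coupled; mean most-abundant incorrect %.1f%%\n"),
              x$n_pairs_used, x$n_barcode_unmatched,
              100 * x$overall_fraction_correct,
              100 * x$mean_most_abundant_incorrect))
  invisible(x)
}

#' Write a count or enrichment table as TSV
#'
#' @param x a `count_table` or `enrichment_table`.
#' @param path file path.
#' @param provenance optional `#`-prefixed header lines.
#' @export
write_counts <- function(x, path, provenance = character(0)) {
  if (inherits(x, "count_table")) {
    df <- data.frame(variant_id = names(x$counts), count = unname(x$counts))
    provenance <- c(provenance,
                    sprintf("sample_id=%s", x$sample_id),
                    sprintf("n_total_reads=%d n_pass_filter=%d n_barcode_matched=%d",
                            x$n_total_reads, x$n_pass_filter,
                            x$n_barcode_matched))
    write_tsv_prov(df, path, provenance)
  } else {
    write_tsv_prov(as.data.frame(x), path, provenance)
  }
}
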