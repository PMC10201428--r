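# Synthetic read generation with recorded ground truth.
#
# Every simulator is deterministic given its seed and reproduces the
# statistical structure the quantification stages assume: donor junction
# amplicons with per-variant abundances and planted integration
# efficiencies, PCR-recombination barcode uncoupling, paired barcode/end
# coupling reads, degenerate target amplicons driven by an insertion-site
# preference model, Tn7 attachment-site amplicons, and uniform per-base
# substitution error. Amplification acts multiplicatively on abundance (the
# quantity the fold-change estimator targets); no other amplification bias
# is modelled.

#' Planted simulation ground truth for donor screens
#'
#' @param manifest a `variant_manifest`.
#' @param efficiency named vector of true relative transposition
#'   efficiencies (wild-type members are forced to 1). Default: log-uniform
#'   on `[0.1, 10]`, the dynamic range over which the screen is treated as
#'   quantitative.
#' @param abundance_sdlog sdlog of the log-normal input abundance
#'   distribution (meanlog 0).
#' @param uncoupling_rate probability that a read's barcode is re-drawn
#'   from another library member (PCR recombination).
#' @param error_rate per-base substitution error probability.
#' @param seed integer seed used for the abundance/efficiency draws.
#' @return object of class `sim_truth`.
#' @export
sim_truth <- function(manifest, efficiency = NULL, abundance_sdlog = 0.5,
                      uncoupling_rate = 0, error_rate = 0, seed = 1L) {
  validate_manifest(manifest)
  stopifnot(uncoupling_rate >= 0, uncoupling_rate <= 1,
            error_rate >= 0, error_rate <= 1, abundance_sdlog >= 0)
  ids <- manifest$variant_id
  withr::with_seed(seed, {
    if (is.null(efficiency)) {
      efficiency <- stats::setNames(exp(stats::runif(length(ids), log(0.1),
                                                     log(10))), ids)
    } else {
      stopifnot(!is.null(names(efficiency)),
                all(ids %in% names(efficiency)))
      efficiency <- efficiency[ids]
    }
    efficiency[wt_ids(manifest)] <- 1
    if (any(efficiency < 0)) stop("efficiencies must be non-negative",
                                  call. = FALSE)
    abundance <- stats::setNames(
      stats::rlnorm(length(ids), meanlog = 0, sdlog = abundance_sdlog), ids)
  })
  structure(list(efficiency = efficiency,
                 abundance = abundance / sum(abundance),
                 abundance_sdlog = abundance_sdlog,
                 uncoupling_rate = uncoupling_rate,
                 error_rate = error_rate,
                 seed = seed),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(paste0("<sim_truth> %d variants, uncoupling %.2f, ",
                     "error %.2g, seed %d\n"),
              length(x$efficiency), x$uncoupling_rate, x$error_rate, x$seed))
  invisible(x)
}

#' Write / read a ground-truth record
#'
#' Round-trips the per-variant table (TSV) together with the scalar
#' parameters (echoed as `#`-prefixed key=value header lines).
#'
#' @param truth a `sim_truth`.
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  df <- data.frame(variant_id = names(truth$efficiency),
                   efficiency = unname(truth$efficiency),
                   abundance = unname(truth$abundance))
  hdr <- sprintf("%s=%s",
                 c("abundance_sdlog", "uncoupling_rate", "error_rate", "seed"),
                 c(format(truth$abundance_sdlog, digits = 17),
                   format(truth$uncoupling_rate, digits = 17),
                   format(truth$error_rate, digits = 17),
                   truth$seed))
  write_tsv_prov(df, path, hdr)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  lines <- readLines(path)
  hdr <- sub("^# ", "", lines[startsWith(lines, "#")])
  kv <- strsplit(hdr, "=", fixed = TRUE)
  pars <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  df <- read_tsv_prov(path)
  structure(list(efficiency = stats::setNames(df$efficiency, df$variant_id),
                 abundance = stats::setNames(df$abundance, df$variant_id),
                 abundance_sdlog = as.numeric(pars[["abundance_sdlog"]]),
                 uncoupling_rate = as.numeric(pars[["uncoupling_rate"]]),
                 error_rate = as.numeric(pars[["error_rate"]]),
                 seed = as.integer(pars[["seed"]])),
            class = "sim_truth")
}

# draw one barcode index per read; uncoupled reads re-draw the barcode from
# *another* member, proportional to library abundance
uncouple_barcodes <- function(variant_idx, abundance, rate) {
  n <- length(variant_idx)
  if (rate <= 0 || n == 0L) return(variant_idx)
  swap <- which(stats::runif(n) < rate)
  for (i in swap) {
    p <- abundance
    p[variant_idx[i]] <- 0
    variant_idx[i] <- sample.int(length(p), 1L, prob = p)
  }
  variant_idx
}

#' Simulate donor-junction amplicon reads
#'
#' Input read counts are multinomial over the planted log-normal abundances;
#' output counts are proportional to abundance x efficiency. Each read is
#' `[5-nt flank][end sequence][19-nt primer][10-nt barcode][15-nt cargo
#' stub]`; with probability `uncoupling_rate` the barcode is re-drawn from
#' another library member, and each base is substituted with probability
#' `error_rate`.
#'
#' @param manifest a `variant_manifest`.
#' @param truth a `sim_truth` built from the same manifest.
#' @param n_input,n_output read depths (> 0).
#' @param cargo DNA providing the cargo stub (default: wild-type fixture).
#' @param seed integer seed.
#' @return list with `input` and `output` (character read vectors named by
#'   the *true* variant of each read) and `truth`.
#' @export
simulate_donor_reads <- function(manifest, truth, n_input, n_output,
                                 cargo = NULL, seed = 1L) {
  validate_manifest(manifest)
  stopifnot(inherits(truth, "sim_truth"),
            n_input > 0, n_output > 0)
  if (nrow(manifest) == 0L) stop("empty manifest", call. = FALSE)
  cargo <- cargo %||% make_wt_fixture()$cargo
  stub <- substr(cargo, 1L, 15L)
  a <- truth$abundance[manifest$variant_id]
  e <- truth$efficiency[manifest$variant_id]
  withr::with_seed(seed, {
    build <- function(n, probs) {
      counts <- as.vector(stats::rmultinom(1L, n, probs))
      donor_idx <- rep.int(seq_len(nrow(manifest)), counts)
      bc_idx <- uncouple_barcodes(donor_idx, a, truth$uncoupling_rate)
      reads <- paste0("CCGGA", manifest$end_sequence[donor_idx], PRIMER19,
                      manifest$barcode[bc_idx], stub)
      names(reads) <- manifest$variant_id[donor_idx]
      add_read_errors(reads, truth$error_rate)
    }
    input <- build(n_input, a)
    out_p <- a * e
    if (sum(out_p) <= 0) stop("all planted efficiencies are zero",
                              call. = FALSE)
    output <- build(n_output, out_p / sum(out_p))
  })
  list(input = input, output = output, truth = truth)
}

#' Simulate paired barcode/end coupling reads
#'
#' Read 1 carries `[19-nt primer][barcode]`, read 2 the full transposon end
#' sequence of the same molecule; a fraction `uncoupling_rate` of pairs
#' carries an end re-drawn from another library member. Pairs are error-free
#' unless `error_rate` is set in `truth` (the coupling QC defines "correct"
#' by exact end identity).
#'
#' @inheritParams simulate_donor_reads
#' @param n number of pairs (> 0).
#' @return list with `read1`, `read2` (character vectors, named by the true
#'   variant) and `truth`.
#' @export
simulate_coupling_pairs <- function(manifest, truth, n, seed = 1L) {
  validate_manifest(manifest)
  stopifnot(inherits(truth, "sim_truth"))
  if (n <= 0) stop("n must be > 0", call. = FALSE)
  a <- truth$abundance[manifest$variant_id]
  withr::with_seed(seed, {
    idx <- sample.int(nrow(manifest), n, replace = TRUE, prob = a)
    end_idx <- uncouple_barcodes(idx, a, truth$uncoupling_rate)
    read1 <- paste0(PRIMER19, manifest$barcode[idx])
    read2 <- manifest$end_sequence[end_idx]
    names(read1) <- names(read2) <- manifest$variant_id[idx]
    read1 <- add_read_errors(read1, truth$error_rate)
    read2 <- add_read_errors(read2, truth$error_rate)
  })
  list(read1 = read1, read2 = read2, truth = truth)
}

#' Simulate Tn7 attachment-site amplicon reads
#'
#' Draws read classes (`unintegrated`, or integration at 0-30 bp downstream
#' of the attachment point in either orientation) from `class_probs` and
#' emits reads carrying the 65-nt expected prefix of their class.
#'
#' @param n number of reads.
#' @param class_probs named probability vector over class labels as produced
#'   by [tn7_class_prefixes()] (e.g. `"unintegrated"`, `"d00_T-RL"`).
#'   Must sum to 1; unknown labels are rejected.
#' @param prefixes prefix table from [tn7_class_prefixes()].
#' @param error_rate per-base substitution error probability.
#' @param seed integer seed.
#' @return character vector of reads named by their true class.
#' @export
simulate_tn7_reads <- function(n, class_probs, prefixes = tn7_class_prefixes(),
                               error_rate = 0, seed = 1L) {
  stopifnot(n > 0, !is.null(names(class_probs)))
  unknown <- setdiff(names(class_probs), names(prefixes))
  if (length(unknown) > 0) {
    stop(sprintf("unknown read class(es): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (abs(sum(class_probs) - 1) > 1e-8) {
    stop("class probabilities must sum to 1", call. = FALSE)
  }
  withr::with_seed(seed, {
    cls <- sample(names(class_probs), n, replace = TRUE, prob = class_probs)
    reads <- paste0(prefixes[cls], strrep("A", 15L))
    names(reads) <- cls
    add_read_errors(reads, error_rate)
  })
}
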