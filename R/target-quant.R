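# Degenerate target-library analysis: anchor filtering, integration
# distance/orientation calling, 8-mer enrichment, target-site-duplication
# logo construction, motif-distance analyses, and integration-site
# prediction.
#
# Coordinate system (fixed across simulator and quantification, 1-based):
# position 1 = first bp downstream of the 3' end of the 32-bp target
# sequence. The 8-bp degenerate region occupies positions 43-50 ("42 bp
# downstream"); integration is detected at distances 43-56. A call at
# distance d places the junction at position d; the 5-bp target-site
# duplication (TSD) spans positions d-4..d, so the scored window
# (TSD-relative -3..+3) spans d-7..d+3 and the central TSD triplet is
# d-3..d-1.

TSD_LENGTH <- 5L
DISTANCE_WINDOW <- c(43L, 56L)
DEGENERATE_REGION <- c(43L, 50L)
WINDOW_POSITIONS <- c("-3", "-2", "-1", "T1", "T2", "T3", "T4", "T5",
                      "+1", "+2", "+3")
END_MATCH_LEN <- 20L

#' Synthetic degenerate target region
#'
#' A deterministic plasmid downstream region in the package coordinate
#' system: a 34-nt i5 primer anchor immediately upstream of the degenerate
#' 8-mer (35-nt variant with one extra upstream diversity base), the
#' degenerate region at positions 43-50, and a 45/46-nt region downstream
#' whose reverse complement forms the i7 anchor. Fixed bases are drawn from
#' {C, A} so that neither transposon-end junction sequences nor central
#' insertion motifs can arise from the backbone. Target B differs from
#' target A at position 42 (C instead of A), a disfavored base at the -3
#' window position of the 49-bp integration distance.
#'
#' @param target `"A"` or `"B"`.
#' @return list with `downstream` (120-nt string, degenerate region as
#'   `N`s), anchors (`i5_anchor`, `i5_anchor_div`, `i7_anchor`,
#'   `i7_anchor_div`), `degenerate` interval and `distance_window`.
#' @export
target_region <- function(target = c("A", "B")) {
  target <- match.arg(target)
  ch <- rep("C", 120L)
  ch[8L] <- "A"   # i5 diversity base
  # positions 36-41 are the -3 window positions of distances 43-48; A is
  # favored there (D) without forming a viable central triplet in any
  # window, so no distance is handicapped by its backbone -3 base
  ch[36:41] <- "A"
  # position 42 is the -3 window position of the 49-bp distance; G is
  # likewise favored/dead, C is the disfavored -3 base carried by target B
  ch[42L] <- if (target == "A") "G" else "C"
  ch[96L] <- "A"  # i7 diversity base
  ch[43:50] <- "N"
  down <- paste(ch, collapse = "")
  list(target = target,
       downstream = down,
       i5_anchor = gsub("N", "", substr(down, 9L, 42L)),
       i5_anchor_div = gsub("N", "", substr(down, 8L, 42L)),
       i7_anchor = dna_revcomp(substr(down, 51L, 95L)),
       i7_anchor_div = dna_revcomp(substr(down, 51L, 96L)),
       degenerate = DEGENERATE_REGION,
       distance_window = DISTANCE_WINDOW)
}

# fixed backbone base at downstream position q (degenerate region excluded)
region_base <- function(region, q) {
  substring(region$downstream, q, q)
}

#' Insertion-site nucleotide preference model
#'
#' Per-position nucleotide weights over the TSD-relative window -3..+3
#' around the 5-nt target-site duplication (11 positions). Weights per
#' position sum to 1.
#'
#' @param weights 4 x 11 numeric matrix (rows A,C,G,T; columns
#'   [WINDOW_POSITIONS]). Columns are renormalized.
#' @param covered logical per position: whether the weights were estimated
#'   from data (uncovered positions are uniform).
#' @return object of class `insertion_pref_model`.
#' @export
insertion_pref_model <- function(weights,
                                 covered = rep(TRUE, ncol(weights))) {
  stopifnot(nrow(weights) == 4L, ncol(weights) == length(WINDOW_POSITIONS))
  rownames(weights) <- DNA_BASES
  colnames(weights) <- WINDOW_POSITIONS
  if (any(weights < 0) || any(colSums(weights) <= 0)) {
    stop("weights must be non-negative with positive column sums",
         call. = FALSE)
  }
  weights <- sweep(weights, 2, colSums(weights), "/")
  structure(list(weights = weights, covered = covered,
                 tsd_length = TSD_LENGTH),
            class = "insertion_pref_model")
}

#' @export
print.insertion_pref_model <- function(x, ...) {
  cat("<insertion_pref_model> TSD-relative nucleotide weights\n")
  print(round(x$weights, 3))
  if (!all(x$covered)) {
    cat("uniform (uncovered) positions:",
        paste(WINDOW_POSITIONS[!x$covered], collapse = " "), "\n")
  }
  invisible(x)
}

#' IUPAC summary of a preference model
#'
#' Reports, per window position, the smallest IUPAC symbol whose base set
#' carries at least `mass` of the position's weight.
#'
#' @param model an `insertion_pref_model`.
#' @param mass weight mass the symbol must cover (default 0.9).
#' @return named character vector of IUPAC symbols.
#' @export
model_iupac_summary <- function(model, mass = 0.9) {
  vapply(seq_along(WINDOW_POSITIONS), function(j) {
    w <- model$weights[, j]
    sizes <- vapply(IUPAC_SETS, length, integer(1))
    ok <- vapply(IUPAC_SETS, function(b) sum(w[b]) >= mass, logical(1))
    names(which(ok)[order(sizes[ok])])[1L]
  }, character(1)) |> stats::setNames(WINDOW_POSITIONS)
}

#' Default planted insertion preference model
#'
#' Encodes the documented insertion-site biases: a Y/W/R triplet in the
#' center of the TSD whose preferred realization is 5'-CWG-3' (C strongly
#' dominant within Y at T2, A/T split at T3, G strongly dominant within R
#' at T4), D (not C) at -3 and H (not G) at +3, uniform elsewhere. The
#' strong central concentration reflects the observation that clones
#' offering the preferred motif dominate the integrated pool: because the
#' mean per-position weight over uniform random bases is always 1/4, only
#' a dominant-base weight well above 1/2 lets motif-bearing clones clear a
#' four-fold enrichment over the pool average.
#'
#' @param dominant weight of the dominant central base (C at T2, G at T4;
#'   split between A and T at T3); default 0.82.
#' @param secondary weight of the secondary base completing the Y/R
#'   degeneracy (T at T2, A at T4); default 0.12.
#' @param flank total weight of the three favored bases at -3/+3.
#' @return an `insertion_pref_model`.
#' @export
default_insertion_model <- function(dominant = 0.82, secondary = 0.12,
                                    flank = 0.9) {
  u <- rep(0.25, 4)
  rest <- (1 - dominant - secondary) / 2
  col <- function(major, minor) {
    w <- rep(rest, 4); names(w) <- DNA_BASES
    w[major] <- dominant
    w[minor] <- secondary
    w
  }
  half <- (dominant + secondary) / 2
  w_mid <- rep((1 - dominant - secondary) / 2, 4); names(w_mid) <- DNA_BASES
  w_mid[c("A", "T")] <- half
  three <- function(excl) {
    w <- rep(flank / 3, 4); names(w) <- DNA_BASES
    w[excl] <- 1 - flank
    w
  }
  weights <- cbind("-3" = three("C"), "-2" = u, "-1" = u,
                   T1 = u,
                   T2 = col("C", "T"),   # Y, C preferred
                   T3 = w_mid,           # W
                   T4 = col("G", "A"),   # R, G preferred
                   T5 = u,
                   "+1" = u, "+2" = u, "+3" = three("G"))
  insertion_pref_model(weights)
}

#' A single-motif insertion model
#'
#' Concentrates nearly all central-triplet weight on a 5'-CWG-3' motif
#' (positions T2-T4), uniform elsewhere; used to study how motif placement
#' within the degenerate region steers the integration distance.
#'
#' @param concentration weight of the motif base(s) at each central
#'   position.
#' @return an `insertion_pref_model`.
#' @export
cwg_insertion_model <- function(concentration = 0.94) {
  u <- rep(0.25, 4)
  one <- function(b) {
    w <- rep((1 - concentration) / 3, 4); names(w) <- DNA_BASES
    w[b] <- concentration
    w
  }
  two <- function(b1, b2) {
    w <- rep((1 - concentration) / 2, 4); names(w) <- DNA_BASES
    w[c(b1, b2)] <- concentration / 2
    w
  }
  weights <- cbind("-3" = u, "-2" = u, "-1" = u,
                   T1 = u, T2 = one("C"), T3 = two("A", "T"), T4 = one("G"),
                   T5 = u, "+1" = u, "+2" = u, "+3" = u)
  insertion_pref_model(weights)
}

# log-weight of base `b` at window position index `j` (1..11)
model_logw <- function(model) log(pmax(model$weights, 1e-12))

# per-read distance scores: reads' 8-mers as an n x 8 base-index matrix
distance_scores <- function(mer_idx, model, region) {
  lw <- model_logw(model)
  dists <- DISTANCE_WINDOW[1]:DISTANCE_WINDOW[2]
  n <- nrow(mer_idx)
  scores <- matrix(0, n, length(dists), dimnames = list(NULL, dists))
  for (k in seq_along(dists)) {
    d <- dists[k]
    win <- (d - 7L):(d + 3L)
    s <- numeric(n)
    for (j in seq_along(win)) {
      q <- win[j]
      if (q >= DEGENERATE_REGION[1] && q <= DEGENERATE_REGION[2]) {
        s <- s + lw[cbind(mer_idx[, q - 42L], j)]
      } else {
        b <- match(region_base(region, q), DNA_BASES)
        s <- s + lw[b, j]
      }
    }
    scores[, k] <- s
  }
  scores
}

#' Simulate degenerate target-library amplicon reads
#'
#' The input library is a finite pool of `n_clones` plasmid clones carrying
#' uniform random 8-mers in the degenerate region (the cloning bottleneck
#' of a scraped-plate library). Input reads sample clones uniformly.
#' Output molecules are drawn proportional to each clone's total
#' integration propensity `A(s) = sum_d,o prod(weights)` — clones offering
#' better insertion windows integrate more — and then carry a transposon
#' end joined at a distance drawn from the conditional
#' `P(d | 8-mer, flanks) \propto` the product of per-position weights over
#' the TSD-relative window, with orientation drawn independently. Reads
#' follow the amplicon design: i5 reads begin with the 34-nt (or 35-nt
#' diversity) upstream anchor and run across the junction into 20+ nt of
#' the proximal end; i7 reads begin with the 45/46-nt downstream anchor
#' (reverse strand) and run back across the duplicated TSD into the distal
#' end.
#'
#' @param pref_model an `insertion_pref_model` (the planted truth).
#' @param n_input,n_output read depths.
#' @param n_clones clones in the plasmid pool (default 30000, tens of
#'   thousands of scraped colonies).
#' @param target `"A"` or `"B"` (see [target_region()]).
#' @param orient_probs named probabilities for `T-RL` and `T-LR`.
#' @param ends list with `left`/`right` end sequences (default: wild-type
#'   fixture, tip-inward).
#' @param diversity_frac fraction of reads amplified with the
#'   extra-diversity-base primers (longer anchors).
#' @param error_rate per-base substitution error probability.
#' @param seed integer seed.
#' @return list: `input` (i5 reads), `output` (list `i5`, `i7`), and
#'   `truth` (data.frame mer8/distance/orientation per output read, plus
#'   parameters).
#' @export
simulate_target_reads <- function(pref_model, n_input, n_output,
                                  target = "A", n_clones = 30000L,
                                  orient_probs = c("T-RL" = 0.9,
                                                   "T-LR" = 0.1),
                                  ends = NULL, diversity_frac = 0.5,
                                  error_rate = 0, seed = 1L) {
  stopifnot(inherits(pref_model, "insertion_pref_model"),
            n_input > 0, n_output > 0)
  region <- target_region(target)
  if (is.null(ends)) {
    tn <- make_wt_fixture()
    ends <- list(left = tn$left_end$sequence, right = tn$right_end$sequence)
  }
  orient_probs <- orient_probs / sum(orient_probs)
  withr::with_seed(seed, {
    # --- the clone pool and its integration propensities -----------------
    clone_mers <- random_dna(n_clones, 8L)
    mer_idx <- matrix(match(unlist(strsplit(clone_mers, "", fixed = TRUE)),
                            DNA_BASES), ncol = 8L, byrow = TRUE)
    sc <- exp(distance_scores(mer_idx, pref_model, region)) # clone x d
    propensity <- rowSums(sc)
    cum <- sc / propensity
    for (k in 2:ncol(cum)) cum[, k] <- cum[, k] + cum[, k - 1L]
    # --- input: uniform sampling of the clone pool -----------------------
    in_idx <- sample.int(n_clones, n_input, replace = TRUE)
    in_mers <- clone_mers[in_idx]
    in_div <- stats::runif(n_input) < diversity_frac
    tail_in <- substr(gsub("N", "", region$downstream), 43L, 78L) # pos 51-86
    input <- paste0(ifelse(in_div, region$i5_anchor_div, region$i5_anchor),
                    in_mers, tail_in)
    # --- output: clones drawn by propensity, distances conditionally -----
    out_idx <- sample.int(n_clones, n_output, replace = TRUE,
                          prob = propensity)
    out_mers <- clone_mers[out_idx]
    u <- stats::runif(n_output)
    d <- DISTANCE_WINDOW[1] +
      as.integer(rowSums(cum[out_idx, , drop = FALSE] < u))
    o <- sample(names(orient_probs), n_output, replace = TRUE,
                prob = orient_probs)
    out_div <- stats::runif(n_output) < diversity_frac
    prox <- ifelse(o == "T-RL", ends$right, ends$left)
    dist_end <- ifelse(o == "T-RL", ends$left, ends$right)
    # i5: anchor + positions 43..d (degenerate bases then backbone) + end
    down_fill <- gsub("N", "", region$downstream) # backbone, 43 -> 51 etc.
    mid5 <- ifelse(d <= 50L, substr(out_mers, 1L, d - 42L),
                   paste0(out_mers, substring(down_fill, 43L, d - 8L)))
    i5 <- paste0(ifelse(out_div, region$i5_anchor_div, region$i5_anchor),
                 substr(paste0(mid5, prox), 1L, 40L))
    # i7: anchor + revcomp(positions d-4..50) + distal end tip-inward
    fwd_seg <- ifelse(d - 4L >= 43L,
                      substr(out_mers, d - 46L, 8L),
                      paste0(substring(region$downstream, d - 4L, 42L),
                             out_mers))
    i7 <- paste0(ifelse(out_div, region$i7_anchor_div, region$i7_anchor),
                 substr(paste0(dna_revcomp(fwd_seg), dist_end), 1L, 40L))
    input <- add_read_errors(input, error_rate)
    i5 <- add_read_errors(i5, error_rate)
    i7 <- add_read_errors(i7, error_rate)
  })
  list(input = input,
       output = list(i5 = i5, i7 = i7),
       truth = list(calls = data.frame(mer8 = out_mers, distance = d,
                                       orientation = o),
                    input_mers = in_mers, n_clones = n_clones,
                    target = target, orient_probs = orient_probs,
                    error_rate = error_rate, seed = seed))
}

#' Anchor filtering of target-library reads
#'
#' A read passes when it begins with an exact match to one of the accepted
#' anchors (e.g. the 34-nt upstream sequence or its 35-nt extra-diversity
#' variant for i5 reads; 45/46-nt for i7 reads).
#'
#' @param reads character vector.
#' @param anchors character vector of accepted anchor sequences.
#' @return integer vector: the length of the matched anchor, 0 for rejects.
#' @export
filter_target_read <- function(reads, anchors) {
  stopifnot(length(anchors) >= 1L)
  anchors <- anchors[order(-nchar(anchors))]
  out <- integer(length(reads))
  undecided <- seq_along(reads)
  for (a in anchors) {
    hit <- undecided[startsWith(reads[undecided], a)]
    out[hit] <- nchar(a)
    undecided <- setdiff(undecided, hit)
  }
  out
}

#' Call integration distance and orientation from junction read pairs
#'
#' After anchor filtering, the i5 read is scanned at candidate junction
#' offsets for distances 43-56 in ascending order for an exact 20-nt match
#' to either transposon end; the first match wins and the end identity
#' fixes the orientation (right end at the upstream junction = T-RL, left
#' end = T-LR). The degenerate 8-mer is assembled from the i5 and/or i7
#' read depending on the integration position (upstream of the junction
#' from i5, downstream across the duplicated TSD from i7; on overlap the
#' i5 copy wins). Reads with no end match, an ambiguous double match, or a
#' failed anchor are returned as no-calls with a reason.
#'
#' @param i5,i7 character vectors of paired reads (`i7` may be `NULL` when
#'   every call is expected at distance >= 50).
#' @param region a [target_region()].
#' @param ends list with `left`/`right` tip-inward end sequences (default:
#'   wild-type fixture).
#' @return data.frame with one row per pair: `distance`, `orientation`,
#'   `end_detected`, `degenerate_8mer`, `target`, `called`, `reason`.
#' @export
call_integration <- function(i5, i7 = NULL, region = target_region("A"),
                             ends = NULL) {
  if (is.null(ends)) {
    tn <- make_wt_fixture()
    ends <- list(left = tn$left_end$sequence, right = tn$right_end$sequence)
  }
  left20 <- substr(ends$left, 1L, END_MATCH_LEN)
  right20 <- substr(ends$right, 1L, END_MATCH_LEN)
  n <- length(i5)
  a5 <- filter_target_read(i5, c(region$i5_anchor, region$i5_anchor_div))
  stripped5 <- substr(i5, a5 + 1L, nchar(i5))
  dists <- DISTANCE_WINDOW[1]:DISTANCE_WINDOW[2]
  dist_call <- rep(NA_integer_, n)
  orient <- rep(NA_character_, n)
  endd <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  reason[a5 == 0L] <- "anchor_fail"
  open <- which(a5 > 0L)
  ambiguous <- integer(0)
  for (d in dists) {
    if (length(open) == 0L) break
    # stripped position p corresponds to plasmid position 42 + p, so the
    # end of a distance-d junction starts at stripped position d - 41
    w <- substr(stripped5[open], d - 41L, d - 41L + END_MATCH_LEN - 1L)
    is_r <- w == right20
    is_l <- w == left20
    both <- is_r & is_l
    hit <- is_r | is_l
    idx <- open[hit & !both]
    dist_call[idx] <- d
    orient[idx] <- ifelse(is_r[hit & !both], "T-RL", "T-LR")
    endd[idx] <- ifelse(is_r[hit & !both], "right", "left")
    ambiguous <- c(ambiguous, open[both])
    open <- open[!hit]
  }
  reason[ambiguous] <- "ambiguous_match"
  reason[open] <- "no_end_match"
  # assemble the degenerate 8-mer
  mer <- rep(NA_character_, n)
  called <- which(!is.na(dist_call))
  if (length(called) > 0L) {
    d <- dist_call[called]
    from5 <- substr(stripped5[called], 1L, pmin(d, 50L) - 42L)
    mer[called] <- from5
    need7 <- called[pmin(dist_call[called], 50L) < 50L]
    if (length(need7) > 0L) {
      if (is.null(i7)) {
        reason[need7] <- "mer_incomplete"
        mer[need7] <- NA_character_
        dist_call[need7] <- NA_integer_
        orient[need7] <- NA_character_
        endd[need7] <- NA_character_
      } else {
        a7 <- filter_target_read(i7[need7],
                                 c(region$i7_anchor, region$i7_anchor_div))
        s7 <- substr(i7[need7], a7 + 1L, nchar(i7[need7]))
        d7 <- dist_call[need7]
        seg_len <- 55L - d7 # forward positions d-4..50
        fwd <- dna_revcomp(substr(s7, 1L, seg_len))
        # fwd starts at position d-4, so position d+1 sits at offset 6;
        # the TSD overlap (positions d-4..d) defers to the i5 copy
        add <- substr(fwd, 6L, nchar(fwd))
        bad <- need7[a7 == 0L | nchar(fwd) < seg_len]
        mer[need7] <- paste0(mer[need7], add)
        mer[bad] <- NA_character_
        reason[bad] <- "i7_anchor_fail"
        dist_call[bad] <- NA_integer_
        orient[bad] <- NA_character_
        endd[bad] <- NA_character_
      }
    }
  }
  ok <- !is.na(dist_call) & !is.na(mer) & nchar(mer) == 8L &
    !grepl("[^ACGT]", mer)
  mer[!ok] <- NA_character_
  data.frame(distance = ifelse(ok, dist_call, NA_integer_),
             orientation = ifelse(ok, orient, NA_character_),
             end_detected = ifelse(ok, endd, NA_character_),
             degenerate_8mer = mer,
             target = region$target,
             called = ok,
             reason = ifelse(ok, NA_character_, reason),
             stringsAsFactors = FALSE)
}

#' Extract degenerate 8-mers from filtered input reads
#'
#' @param reads i5 reads of the unintegrated input library.
#' @param region a [target_region()].
#' @return character vector of 8-mers (`NA` for filtered reads).
#' @export
input_degenerate_mers <- function(reads, region = target_region("A")) {
  a <- filter_target_read(reads, c(region$i5_anchor, region$i5_anchor_div))
  mer <- substr(reads, a + 1L, a + 8L)
  mer[a == 0L | nchar(mer) < 8L | grepl("[^ACGT]", mer)] <- NA_character_
  mer
}

#' Degenerate-sequence enrichment per (8-mer, distance)
#'
#' Relative abundances are formed per sample (input: per 8-mer; output: per
#' (8-mer, distance) over all calls, primer pairs pooled), and the
#' fold-change of each (8-mer, distance) is its output abundance divided by
#' the position-agnostic input abundance of the 8-mer, log2-transformed.
#' Combinations absent from the output are not listed; output combinations
#' whose 8-mer lacks input counts are flagged undefined.
#'
#' @param input_mers character vector of input 8-mers (`NA`s ignored), as
#'   from [input_degenerate_mers()].
#' @param calls data.frame of output calls (from [call_integration()];
#'   no-calls ignored).
#' @return object of class `degenerate_enrichment` (data.frame: mer8,
#'   distance, input_count, output_count, input_fraction, output_fraction,
#'   fold_change, log2_fc, defined, censored).
#' @export
degenerate_enrichment <- function(input_mers, calls) {
  input_mers <- input_mers[!is.na(input_mers)]
  calls <- calls[!is.na(calls$distance) & !is.na(calls$degenerate_8mer), ,
                 drop = FALSE]
  in_tab <- table(input_mers)
  n_in <- sum(in_tab)
  key <- paste(calls$degenerate_8mer, calls$distance, sep = ":")
  out_tab <- table(key)
  n_out <- sum(out_tab)
  parts <- strsplit(names(out_tab), ":", fixed = TRUE)
  mer <- vapply(parts, `[`, "", 1L)
  dist <- as.integer(vapply(parts, `[`, "", 2L))
  ic <- as.integer(in_tab[mer])
  ic[is.na(ic)] <- 0L
  oc <- as.integer(out_tab)
  in_frac <- ic / n_in
  out_frac <- oc / n_out
  fc <- ifelse(ic > 0L, out_frac / in_frac, NA_real_)
  res <- data.frame(mer8 = mer, distance = dist,
                    input_count = ic, output_count = oc,
                    input_fraction = in_frac, output_fraction = out_frac,
                    fold_change = fc, log2_fc = log2(fc),
                    defined = ic > 0L,
                    censored = FALSE,
                    stringsAsFactors = FALSE)
  res <- res[order(-ifelse(is.na(res$fold_change), -Inf, res$fold_change),
                   res$mer8, res$distance), ]
  rownames(res) <- NULL
  structure(res, n_input = n_in, n_output = n_out,
            class = c("degenerate_enrichment", "data.frame"))
}

# map one enriched (8-mer, distance) into TSD-relative columns; returns a
# 2-column matrix (window column index, base index)
mer_window_cells <- function(mer, distance) {
  q <- 43:50
  j <- q - distance + 8L # window column index 1..11
  keep <- j >= 1L & j <= 11L
  b <- match(strsplit(mer, "", fixed = TRUE)[[1]], DNA_BASES)
  cbind(j[keep], b[keep])
}

#' Pool enriched degenerate sequences into a TSD-relative logo
#'
#' Per library: keep (8-mer, distance) combinations with fold-change at
#' least `threshold`, rank by fold-change, select the top `top_k` across
#' all integration positions, and map each selected 8-mer's bases into
#' TSD-relative coordinates given its called distance. Only
#' degenerate-derived bases contribute. Libraries are pooled, so two full
#' libraries at `top_k = 5000` yield 10 000 nucleotide observations at
#' every fully covered position.
#'
#' @param enrich a `degenerate_enrichment` or a list of them (libraries).
#' @param threshold minimum fold-change (default 4).
#' @param top_k sequences kept per library (default 5000); when fewer
#'   survive, all are used and the shortfall recorded.
#' @return a [pfm][logo_from_sites] over the 11 window positions, with
#'   attributes `n_selected` and `shortfall` (per library).
#' @export
build_logo <- function(enrich, threshold = 4, top_k = 5000L) {
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  if (inherits(enrich, "degenerate_enrichment")) enrich <- list(enrich)
  counts <- matrix(0L, 4L, length(WINDOW_POSITIONS),
                   dimnames = list(DNA_BASES, WINDOW_POSITIONS))
  n_sel <- integer(length(enrich))
  shortfall <- integer(length(enrich))
  for (lib in seq_along(enrich)) {
    e <- enrich[[lib]]
    keep <- e[!is.na(e$fold_change) & e$fold_change >= threshold, ,
              drop = FALSE]
    keep <- keep[order(-keep$fold_change, keep$mer8, keep$distance), ,
                 drop = FALSE]
    if (nrow(keep) < top_k) shortfall[lib] <- top_k - nrow(keep)
    keep <- utils::head(keep, top_k)
    n_sel[lib] <- nrow(keep)
    for (i in seq_len(nrow(keep))) {
      cells <- mer_window_cells(keep$mer8[i], keep$distance[i])
      for (r in seq_len(nrow(cells))) {
        counts[cells[r, 2L], cells[r, 1L]] <-
          counts[cells[r, 2L], cells[r, 1L]] + 1L
      }
    }
  }
  out <- new_pfm(counts)
  attr(out, "n_selected") <- n_sel
  attr(out, "shortfall") <- shortfall
  out
}

#' Distance distributions by motif placement
#'
#' Partitions output calls by the offset(s) of an IUPAC motif within the
#' degenerate 8-mer (reads with exactly one occurrence form one class per
#' offset; multi-occurrence offset combinations are kept separate) and
#' returns the empirical integration-distance distribution per class.
#' 8-mers with no motif occurrence are excluded.
#'
#' @param calls data.frame of calls (from [call_integration()] or the
#'   simulator truth).
#' @param motif IUPAC motif, default `"CWG"` (the preferred central TSD
#'   motif).
#' @return data.frame with columns `class` (e.g. `"2"`, `"2+5"`),
#'   `n_occurrences`, `distance`, `n`; attribute `modal` gives the modal
#'   distance per class.
#' @export
motif_distance_distribution <- function(calls, motif = "CWG") {
  calls <- calls[!is.na(calls$distance), , drop = FALSE]
  mer_col <- if ("degenerate_8mer" %in% names(calls)) "degenerate_8mer"
             else "mer8"
  mers <- calls[[mer_col]]
  uniq <- unique(mers)
  offs <- lapply(uniq, function(m) iupac_scan(m, motif)$start)
  key <- vapply(offs, function(o) paste(o, collapse = "+"), character(1))
  nocc <- lengths(offs)
  map <- stats::setNames(key, uniq)
  nmap <- stats::setNames(nocc, uniq)
  cls <- map[mers]
  keep <- nmap[mers] > 0L
  df <- data.frame(class = unname(cls[keep]),
                   n_occurrences = unname(nmap[mers][keep]),
                   distance = calls$distance[keep])
  agg <- stats::aggregate(list(n = rep(1L, nrow(df))),
                          by = df[c("class", "n_occurrences", "distance")],
                          FUN = sum)
  agg <- agg[order(agg$class, agg$distance), ]
  rownames(agg) <- NULL
  modal <- vapply(split(agg, agg$class), function(g) {
    g$distance[which.max(g$n)]
  }, integer(1))
  structure(agg, modal = modal, class = c("motif_distance", "data.frame"))
}

#' Fit an insertion preference model from enrichment data
#'
#' Model weights are the column frequencies of the pooled enrichment logo
#' ([build_logo()]); positions with fewer than `min_obs` pooled
#' observations fall back to uniform weights and are flagged uncovered
#' (frequencies from a handful of sequences carry no usable signal).
#'
#' @inheritParams build_logo
#' @param min_obs minimum pooled observations per position (default 50).
#' @return an `insertion_pref_model`.
#' @export
fit_preference_model <- function(enrich, threshold = 4, top_k = 5000L,
                                 min_obs = 50L) {
  logo <- build_logo(enrich, threshold = threshold, top_k = top_k)
  freq <- pfm_frequencies(logo)
  covered <- !is.na(freq[1L, ]) & colSums(unclass(logo)) >= min_obs
  freq[, !covered] <- 0.25
  insertion_pref_model(freq, covered = covered)
}

#' Rank candidate integration distances for a downstream sequence
#'
#' Scores each distance `d` in the detection window as the sum of
#' log-weights of the bases in the TSD-relative window -3..+3 (TSD ending
#' at `d`), and ranks distances by score. Ties are broken by ascending
#' distance. Distances whose window extends past the sequence are skipped
#' and recorded.
#'
#' @param model an `insertion_pref_model`.
#' @param downstream_seq plain ACGT sequence in downstream coordinates
#'   (position 1 = first bp after the 32-bp target).
#' @param distances candidate distances (default 43-56).
#' @return data.frame (`distance`, `score`, `rank`) ordered by rank, with
#'   attribute `skipped` listing distances lacking a full window.
#' @export
predict_sites <- function(model, downstream_seq,
                          distances = DISTANCE_WINDOW[1]:DISTANCE_WINDOW[2]) {
  stopifnot(inherits(model, "insertion_pref_model"))
  downstream_seq <- toupper(downstream_seq)
  stopifnot_dna(downstream_seq, "downstream sequence")
  lw <- model_logw(model)
  L <- nchar(downstream_seq)
  skipped <- distances[distances - 7L < 1L | distances + 3L > L]
  use <- setdiff(distances, skipped)
  score <- vapply(use, function(d) {
    win <- strsplit(substr(downstream_seq, d - 7L, d + 3L), "",
                    fixed = TRUE)[[1]]
    sum(lw[cbind(match(win, DNA_BASES), seq_len(11L))])
  }, numeric(1))
  ord <- order(-score, use)
  res <- data.frame(distance = use[ord], score = score[ord],
                    rank = seq_along(use))
  structure(res, skipped = skipped, class = c("site_prediction",
                                              "data.frame"))
}

#' @export
predict.insertion_pref_model <- function(object, downstream_seq, ...) {
  predict_sites(object, downstream_seq, ...)
}
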