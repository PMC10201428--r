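# Programmatic generation of barcoded transposon-end variant manifests.
#
# The screen's design categories are reproduced generatively (truncation
# series, tiled substitutions, binding-site identity/spacing/inversion/
# addition variants) rather than as a literal catalog; the historical screen
# designed its exact variant lists by hand. Substitutions use base
# complementation (a maximal unambiguous perturbation) and truncations use a
# fixed low-complexity filler free of binding-site and IHF consensus
# matches, so overall element size is preserved.

VARIANT_CATEGORIES <- c("wildtype", "truncation", "substitution",
                        "tbs_identity", "tbs_spacing", "tbs_inversion",
                        "tbs_addition", "terminal_end", "flank", "palindrome",
                        "linker")

new_variant <- function(variant_id, side, category, end_sequence, description) {
  data.frame(variant_id = variant_id, side = side, category = category,
             end_sequence = end_sequence, barcode = NA_character_,
             description = description, stringsAsFactors = FALSE)
}

#' Serial truncation variants
#'
#' Variant k replaces the innermost `k * step` bases of the end with a fixed
#' neutral CA-repeat filler, emulating progressive truncation from the
#' interior without changing overall element size.
#'
#' @param end a `transposon_end`.
#' @param step truncation increment in bp (>= 1).
#' @return data.frame of variants (`floor(length/step)` rows).
#' @export
design_truncations <- function(end, step = 1L) {
  stopifnot(inherits(end, "transposon_end"))
  step <- as.integer(step)
  L <- nchar(end$sequence)
  if (step < 1L) stop("step must be >= 1", call. = FALSE)
  if (step > L) stop("step exceeds end length", call. = FALSE)
  n <- L %/% step
  pre <- toupper(substr(end$side, 1, 1))
  out <- lapply(seq_len(n), function(k) {
    cut <- L - k * step + 1L
    seq <- paste0(substr(end$sequence, 1L, cut - 1L), ca_filler(k * step))
    new_variant(sprintf("%s_trunc_%03d", pre, k), end$side, "truncation", seq,
                sprintf("innermost %d bp replaced by filler (positions %d-%d)",
                        k * step, cut, L))
  })
  do.call(rbind, out)
}

#' Tiled substitution variants
#'
#' For each window width `w`, every start offset is tiled (overlapping
#' windows), so each base away from the ends is covered by exactly `w`
#' windows. Each variant complements every base within its window.
#'
#' @param end a `transposon_end`.
#' @param widths subset of `c(1, 2, 4)`.
#' @return data.frame of variants.
#' @export
design_substitutions <- function(end, widths = c(1L, 2L, 4L)) {
  stopifnot(inherits(end, "transposon_end"))
  widths <- as.integer(widths)
  if (!all(widths %in% c(1L, 2L, 4L))) {
    stop("widths must be a subset of {1, 2, 4}", call. = FALSE)
  }
  L <- nchar(end$sequence)
  pre <- toupper(substr(end$side, 1, 1))
  out <- list()
  for (w in widths) {
    for (s in seq_len(L - w + 1L)) {
      win <- substr(end$sequence, s, s + w - 1L)
      seq <- paste0(substr(end$sequence, 1L, s - 1L), dna_complement(win),
                    substr(end$sequence, s + w, L))
      out[[length(out) + 1L]] <- new_variant(
        sprintf("%s_sub%d_%03d", pre, w, s), end$side, "substitution", seq,
        sprintf("%d-bp complement substitution at positions %d-%d",
                w, s, s + w - 1L))
    }
  }
  do.call(rbind, out)
}

#' Binding-site identity, spacing, inversion and addition variants
#'
#' * `identity`: every assignment of the pooled binding sites to the end's
#'   TBS slots (`length(tbs_pool)^n_sites` variants, 27 for 3 slots over a
#'   per-end pool of 3; pass the full six-site pool for cross-end swaps).
#' * `spacing`: changes the gap upstream of a chosen TBS by
#'   `params$deltas` bp (insertion of CA filler, or deletion into the gap).
#' * `inversion`: reverse-complements each selected TBS.
#' * `addition`: inserts a fourth binding site, between the last two TBSs
#'   on the left end or distal to the last TBS on the right end.
#'
#' @param end a `transposon_end`.
#' @param tbs_pool named character vector of binding-site sequences.
#' @param mode one of `"identity"`, `"spacing"`, `"inversion"`, `"addition"`.
#' @param params list; `spacing` uses `deltas` (integer vector) and
#'   optionally `after` (TBS index whose upstream gap is modified, default 2),
#'   `inversion` uses `sites` (labels, default all), `addition` uses
#'   `site` (sequence to insert, default first pool entry).
#' @return data.frame of variants.
#' @export
design_tbs_variants <- function(end, tbs_pool = fixture_tbs_set(),
                                mode = c("identity", "spacing", "inversion",
                                         "addition"),
                                params = list()) {
  stopifnot(inherits(end, "transposon_end"))
  mode <- match.arg(mode)
  pre <- toupper(substr(end$side, 1, 1))
  s <- end$sequence
  tb <- end$tbs
  switch(mode,
    identity = {
      n_sites <- nrow(tb)
      pool <- params$pool %||% tbs_pool[grepl(paste0("^", pre), names(tbs_pool))]
      if (length(pool) == 0L) pool <- tbs_pool
      grid <- expand.grid(rep(list(seq_along(pool)), n_sites))
      out <- lapply(seq_len(nrow(grid)), function(i) {
        seq <- s
        for (j in seq_len(n_sites)) {
          substr(seq, tb$start[j], tb$end[j]) <- pool[[grid[i, j]]]
        }
        new_variant(sprintf("%s_ident_%03d", pre, i), end$side, "tbs_identity",
                    seq, paste0("TBS assignment ",
                                paste(names(pool)[unlist(grid[i, ])],
                                      collapse = "-")))
      })
      do.call(rbind, out)
    },
    spacing = {
      deltas <- params$deltas %||% c(-2L, -1L, 1L, 2L)
      after <- params$after %||% 2L
      if (after < 2L || after > nrow(tb)) {
        stop("spacing requires a TBS index with an upstream gap", call. = FALSE)
      }
      gap_start <- tb$end[after - 1L] + 1L
      gap_len <- tb$start[after] - gap_start
      out <- lapply(deltas, function(d) {
        if (d < 0 && -d > gap_len) {
          stop(sprintf("spacing deletion of %d bp exceeds the %d-bp gap",
                       -d, gap_len), call. = FALSE)
        }
        seq <- if (d >= 0) {
          paste0(substr(s, 1L, gap_start - 1L), ca_filler(d),
                 substr(s, gap_start, nchar(s)))
        } else {
          paste0(substr(s, 1L, gap_start - 1L),
                 substr(s, gap_start - d, nchar(s)))
        }
        new_variant(sprintf("%s_space_%s%d", pre, ifelse(d >= 0, "p", "m"),
                            abs(d)),
                    end$side, "tbs_spacing", seq,
                    sprintf("gap before %s changed by %+d bp",
                            tb$label[after], d))
      })
      do.call(rbind, out)
    },
    inversion = {
      sites <- params$sites %||% tb$label
      out <- lapply(sites, function(lb) {
        j <- match(lb, tb$label)
        seq <- s
        substr(seq, tb$start[j], tb$end[j]) <-
          dna_revcomp(substr(s, tb$start[j], tb$end[j]))
        new_variant(sprintf("%s_inv_%s", pre, lb), end$side, "tbs_inversion",
                    seq, sprintf("%s reverse-complemented", lb))
      })
      do.call(rbind, out)
    },
    addition = {
      site <- params$site %||% tbs_pool[[1L]]
      n <- nrow(tb)
      ins_at <- if (end$side == "left") {
        # between the last two binding sites, mid-gap
        tb$end[n - 1L] + (tb$start[n] - tb$end[n - 1L]) %/% 2L
      } else {
        nchar(s) # distal to the last binding site
      }
      seq <- paste0(substr(s, 1L, ins_at), site,
                    substr(s, ins_at + 1L, nchar(s)))
      new_variant(sprintf("%s_add_1", pre), end$side, "tbs_addition", seq,
                  sprintf("extra TBS inserted after position %d", ins_at))
    })
}

# greedy distance-3 barcode sampler; deterministic under the caller's RNG
sample_barcodes <- function(n, length = 10L, max_tries = 200L) {
  accepted <- character(0)
  acc_mat <- NULL
  tries <- 0L
  while (length(accepted) < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("barcode space exhausted: cannot reach pairwise Hamming distance 3",
           call. = FALSE)
    }
    batch <- unique(random_dna(max(2L * (n - length(accepted)), 32L), length))
    bm <- seq_matrix(batch)
    for (i in seq_along(batch)) {
      cand <- bm[i, , drop = TRUE]
      if (is.null(acc_mat) ||
          all(rowSums(acc_mat != matrix(cand, nrow(acc_mat), length,
                                        byrow = TRUE)) >= 3L)) {
        accepted <- c(accepted, batch[i])
        acc_mat <- rbind(acc_mat, cand)
        if (length(accepted) == n) break
      }
    }
  }
  accepted
}

#' Assign unique barcodes and append wild-type members
#'
#' Draws 10-nt barcodes with pairwise Hamming distance >= 3 (one sequencing
#' error cannot convert one valid barcode into another), assigns one per
#' variant, and appends four wild-type members carrying identical end
#' sequences under their own unique barcodes.
#'
#' @param variants data.frame from the `design_*` generators.
#' @param wt_sequence the wild-type end sequence for the four spike-ins.
#' @param seed integer seed making the assignment deterministic.
#' @param barcode_length barcode length in nt (default 10).
#' @return a `variant_manifest`: the variant data.frame with barcodes, plus
#'   attributes `side` and `wt_ids`.
#' @export
assign_barcodes <- function(variants, wt_sequence, seed,
                            barcode_length = 10L) {
  stopifnot(is.data.frame(variants), nrow(variants) > 0L)
  side <- unique(variants$side)
  stopifnot(length(side) == 1L)
  wt_sequence <- toupper(wt_sequence)
  stopifnot_dna(wt_sequence, "wt_sequence")
  wt <- do.call(rbind, lapply(1:4, function(i) {
    new_variant(sprintf("%s_WT_%d", toupper(substr(side, 1, 1)), i), side,
                "wildtype", wt_sequence, "wild-type end, unique barcode")
  }))
  manifest <- rbind(variants, wt)
  if (anyDuplicated(manifest$variant_id)) {
    stop("variant_id values must be unique", call. = FALSE)
  }
  withr::with_seed(seed, {
    manifest$barcode <- sample_barcodes(nrow(manifest), barcode_length)
  })
  structure(manifest, side = side, wt_ids = wt$variant_id,
            class = c("variant_manifest", "data.frame"))
}

#' Wild-type member ids of a manifest
#' @param manifest a `variant_manifest` (or manifest data.frame with a
#'   `category` column).
#' @return character vector of the wild-type variant ids.
#' @export
wt_ids <- function(manifest) {
  attr(manifest, "wt_ids") %||%
    manifest$variant_id[manifest$category == "wildtype"]
}

#' Validate manifest invariants
#'
#' Checks barcode uniqueness and pairwise Hamming distance >= 3, ACGT
#' alphabet, unique variant ids, and the presence of exactly four wild-type
#' members with identical end sequences.
#'
#' @param manifest manifest data.frame.
#' @return invisibly `TRUE`; stops with a message naming the violated rule.
#' @export
validate_manifest <- function(manifest) {
  stopifnot(is.data.frame(manifest))
  need <- c("variant_id", "side", "category", "end_sequence", "barcode")
  miss <- setdiff(need, names(manifest))
  if (length(miss) > 0) {
    stop("manifest lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(manifest$variant_id)) {
    stop("duplicate variant_id", call. = FALSE)
  }
  stopifnot_dna(manifest$end_sequence, "end_sequence")
  stopifnot_dna(manifest$barcode, "barcode")
  if (length(unique(nchar(manifest$barcode))) != 1L) {
    stop("barcodes must share one length", call. = FALSE)
  }
  bm <- seq_matrix(manifest$barcode)
  n <- nrow(bm)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      d <- rowSums(bm[(i + 1L):n, , drop = FALSE] !=
                     matrix(bm[i, ], n - i, ncol(bm), byrow = TRUE))
      if (any(d < 3L)) {
        stop(sprintf("barcodes '%s' and '%s' are within Hamming distance 2",
                     manifest$barcode[i],
                     manifest$barcode[i + which(d < 3L)[1L]]), call. = FALSE)
      }
    }
  }
  wt <- manifest[manifest$category == "wildtype", , drop = FALSE]
  if (nrow(wt) != 4L) {
    stop(sprintf("manifest must contain exactly 4 wildtype members (found %d)",
                 nrow(wt)), call. = FALSE)
  }
  if (length(unique(wt$end_sequence)) != 1L) {
    stop("wildtype members must share one end sequence", call. = FALSE)
  }
  invisible(TRUE)
}

#' Read and write variant manifests as TSV
#'
#' Columns: variant_id, side, category, end_sequence, barcode, description.
#'
#' @param manifest manifest data.frame.
#' @param path file path.
#' @param provenance optional character vector of `#`-prefixed header lines.
#' @export
write_manifest <- function(manifest, path, provenance = character(0)) {
  write_tsv_prov(as.data.frame(manifest), path, provenance)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- read_tsv_prov(path)
  need <- c("variant_id", "side", "category", "end_sequence", "barcode")
  miss <- setdiff(need, names(m))
  if (length(miss) > 0) {
    stop(sprintf("malformed manifest '%s': missing column(s) %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  bad <- which(is.na(m$barcode) | grepl("[^ACGT]", m$barcode))
  if (length(bad) > 0) {
    stop(sprintf("malformed manifest '%s': invalid barcode in row %d", path,
                 bad[1L]), call. = FALSE)
  }
  structure(m, side = unique(m$side),
            wt_ids = m$variant_id[m$category == "wildtype"],
            class = c("variant_manifest", "data.frame"))
}
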