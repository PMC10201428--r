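# Transposon-end ORF analysis and constrained recoding for in-frame
# protein tagging. The integrated end remains as a "scar" at the insertion
# site; recoding turns it into a benign peptide linker by replacing stop
# codons and codons for bulky/charged residues, while a mutability mask
# protects bases the screen showed to be intolerant (the conserved TBS
# positions by default).

# residues tolerated in a linker: everything but stops and the default
# bulky/charged set below
DEFAULT_DISALLOWED <- c("W", "F", "Y", "R", "K", "D", "E", "H", "P")

split_codons <- function(dna, frame) {
  stopifnot(frame %in% 1:3)
  L <- nchar(dna)
  starts <- seq.int(frame, L - 2L, by = 3L)
  if (length(starts) == 0L) return(character(0))
  substring(dna, starts, starts + 2L)
}

#' Translate DNA in a given frame
#'
#' @param dna DNA string.
#' @param frame reading frame 1-3.
#' @return amino-acid string (stops as `*`); trailing partial codons are
#'   dropped.
#' @export
translate_dna <- function(dna, frame = 1L) {
  dna <- toupper(dna)
  stopifnot_dna(dna, "dna")
  paste(GENETIC_CODE_TABLE[split_codons(dna, frame)], collapse = "")
}

#' Stop codons per reading frame
#'
#' @param end_dna DNA string (e.g. a transposon end, tip-inward).
#' @return list of three integer vectors: 1-based codon indices of
#'   TAA/TAG/TGA in frames 1-3.
#' @examples
#' find_stops("TAATAG") # frame 1: codons 1 and 2
#' @export
find_stops <- function(end_dna) {
  end_dna <- toupper(end_dna)
  stopifnot_dna(end_dna, "end_dna")
  lapply(stats::setNames(1:3, paste0("frame", 1:3)), function(f) {
    which(split_codons(end_dna, f) %in% STOP_CODONS)
  })
}

# default immutable mask: conserved TBS footprint positions (1, 6-8, 12-14)
# of every annotated binding site, i.e. the positions the substitution
# screen reports as intolerant
#' @rdname design_linkers
#' @param end a `transposon_end`.
#' @export
conserved_tbs_mask <- function(end) {
  stopifnot(inherits(end, "transposon_end"))
  sort(unlist(lapply(seq_len(nrow(end$tbs)), function(i) {
    end$tbs$start[i] - 1L + TBS_CONSERVED_POS
  })))
}

# all single/multi-base replacement codons for `codon` that encode an
# allowed residue and only touch mutable bases; returns those with the
# fewest edits
codon_fixes <- function(codon, allowed, mutable) {
  base_opts <- lapply(1:3, function(i) {
    if (mutable[i]) DNA_BASES else substr(codon, i, i)
  })
  cands <- apply(expand.grid(base_opts, stringsAsFactors = FALSE), 1L,
                 paste, collapse = "")
  cands <- cands[GENETIC_CODE_TABLE[cands] %in% allowed]
  if (length(cands) == 0L) return(character(0))
  edits <- vapply(cands, function(c2) {
    sum(strsplit(c2, "")[[1]] != strsplit(codon, "")[[1]])
  }, integer(1))
  sort(cands[edits == min(edits)])
}

#' Recode a transposon-end reading frame into a benign linker
#'
#' Minimal-edit recoding: every codon of the chosen frame that is a stop or
#' encodes a disallowed residue is replaced by a codon for an allowed
#' residue using the fewest base changes, never touching bases in the
#' immutable mask. All co-optimal per-codon replacements are combined;
#' when the combination count exceeds `max_variants`, the first
#' `max_variants` in deterministic order are returned and the total is
#' recorded.
#'
#' @param end_dna DNA string (length preserved in every variant).
#' @param frame reading frame 1-3.
#' @param disallowed residues to eliminate besides stops (default
#'   bulky/charged: W F Y R K D E H P).
#' @param immutable_mask integer positions (1-based, within `end_dna`) that
#'   must not change; see [conserved_tbs_mask()].
#' @param max_variants cap on emitted combinations (default 50).
#' @return list of `linker_variant` objects (fields: frame, dna, protein,
#'   edits data.frame, violations); attribute `n_total` gives the full
#'   co-optimal combination count.
#' @export
design_linkers <- function(end_dna, frame = 1L,
                           disallowed = DEFAULT_DISALLOWED,
                           immutable_mask = integer(0),
                           max_variants = 50L) {
  end_dna <- toupper(end_dna)
  stopifnot_dna(end_dna, "end_dna")
  stopifnot(frame %in% 1:3)
  allowed <- setdiff(unique(GENETIC_CODE_TABLE), c("*", disallowed))
  codons <- split_codons(end_dna, frame)
  starts <- seq.int(frame, by = 3L, length.out = length(codons))
  offending <- which(GENETIC_CODE_TABLE[codons] %in% c("*", disallowed))
  fixes <- vector("list", length(offending))
  for (k in seq_along(offending)) {
    i <- offending[k]
    mutable <- !((starts[i] + 0:2) %in% immutable_mask)
    fx <- codon_fixes(codons[i], allowed, mutable)
    if (length(fx) == 0L) {
      stop(sprintf(paste0("unresolvable codon %s at codon %d (frame %d): ",
                          "every allowed replacement requires a masked base"),
                   codons[i], i, frame), call. = FALSE)
    }
    fixes[[k]] <- fx
  }
  n_total <- prod(lengths(fixes))
  combos <- if (length(fixes) == 0L) list(integer(0)) else {
    grid <- expand.grid(lapply(fixes, seq_along))
    lapply(seq_len(min(nrow(grid), max_variants)), function(r) {
      unlist(grid[r, ], use.names = FALSE)
    })
  }
  variants <- lapply(seq_along(combos), function(v) {
    dna <- end_dna
    edits <- data.frame(codon_index = integer(0), position = integer(0),
                        from = character(0), to = character(0))
    for (k in seq_along(offending)) {
      i <- offending[k]
      new_codon <- fixes[[k]][combos[[v]][k]]
      substr(dna, starts[i], starts[i] + 2L) <- new_codon
      edits <- rbind(edits, data.frame(codon_index = i, position = starts[i],
                                       from = codons[i], to = new_codon))
    }
    protein <- translate_dna(dna, frame)
    resid <- strsplit(protein, "")[[1]]
    violations <- which(resid %in% c("*", disallowed))
    structure(list(name = sprintf("ORF%d%s", frame, letters[v]),
                   frame = frame, dna = dna, protein = protein,
                   edits = edits, violations = violations),
              class = "linker_variant")
  })
  ok <- vapply(variants, function(v) length(v$violations) == 0L, logical(1))
  structure(variants[ok], n_total = n_total)
}

#' @export
print.linker_variant <- function(x, ...) {
  cat(sprintf("<linker_variant> %s: %d edits, peptide %s\n",
              x$name, nrow(x$edits), x$protein))
  invisible(x)
}

#' Build an in-frame tagging fusion
#'
#' Concatenates `gene[1..insertion_offset]`, the (recoded) transposon-end
#' linker and a promoterless/startless cargo ORF, and translates the joint
#' reading frame. Frame shifts and internal stop codons yield a structured
#' failure report rather than a protein.
#'
#' @param gene_dna coding sequence of the tagged gene (no stop included up
#'   to the insertion point).
#' @param insertion_offset bases of `gene_dna` retained before the linker
#'   (must be within the gene).
#' @param end_variant_dna linker DNA (a `linker_variant$dna` or raw end).
#' @param cargo_orf cargo coding sequence lacking start codon and promoter.
#' @return list of class `fusion_result`: `in_frame`, `protein`,
#'   `n_codons`, `internal_stops` (codon indices), `frame_shift`.
#' @export
build_fusion <- function(gene_dna, insertion_offset, end_variant_dna,
                         cargo_orf) {
  gene_dna <- toupper(gene_dna); cargo_orf <- toupper(cargo_orf)
  end_variant_dna <- toupper(end_variant_dna)
  stopifnot_dna(c(gene_dna, end_variant_dna, cargo_orf), "fusion parts")
  if (insertion_offset < 1L || insertion_offset > nchar(gene_dna)) {
    stop("insertion_offset outside the gene", call. = FALSE)
  }
  joint <- paste0(substr(gene_dna, 1L, insertion_offset), end_variant_dna,
                  cargo_orf)
  frame_shift <- nchar(joint) %% 3L != 0L ||
    insertion_offset %% 3L != 0L || nchar(end_variant_dna) %% 3L != 0L
  protein <- translate_dna(joint, 1L)
  resid <- strsplit(protein, "")[[1]]
  internal_stops <- which(resid == "*")
  ok <- !frame_shift && length(internal_stops) == 0L
  structure(list(in_frame = ok,
                 protein = if (ok) protein else NA_character_,
                 n_codons = nchar(joint) %/% 3L,
                 internal_stops = internal_stops,
                 frame_shift = frame_shift),
            class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  if (x$in_frame) {
    cat(sprintf("<fusion_result> in-frame, %d codons\n", x$n_codons))
  } else {
    cat(sprintf(
      "<fusion_result> FAILED: frame_shift=%s, internal stops at %s\n",
      x$frame_shift,
      if (length(x$internal_stops)) paste(x$internal_stops, collapse = ",")
      else "none"))
  }
  invisible(x)
}

#' Average protein mass in kDa
#'
#' Sum of average residue masses plus one water, divided by 1000. An empty
#' protein returns the water mass alone with a warning.
#'
#' @param protein amino-acid string (one-letter codes, no stops).
#' @return mass in kDa.
#' @examples
#' protein_mw("G") # 0.07507
#' @export
protein_mw <- function(protein) {
  protein <- toupper(protein)
  if (nchar(protein) == 0L) {
    warning("empty protein: returning water mass only")
    return(WATER_MASS / 1000)
  }
  resid <- strsplit(protein, "")[[1]]
  unknown <- setdiff(resid, names(RESIDUE_MASSES))
  if (length(unknown) > 0) {
    stop("unknown residue(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  (sum(RESIDUE_MASSES[resid]) + WATER_MASS) / 1000
}

#' Packaged superfolder GFP
#'
#' Reads the packaged sfGFP coding sequence (a synthetic reverse
#' translation of the standard 239-residue superfolder GFP) and returns
#' the CDS, its translation and the expected average mass.
#'
#' @return list with `cds`, `protein`, `mass_kda`.
#' @export
sfgfp <- function() {
  path <- system.file("extdata", "sfgfp_synthetic_cds.fasta",
                      package = "castscreen")
  cds <- unname(read_fasta(path)[1L])
  protein <- sub("\\*$", "", translate_dna(cds, 1L))
  list(cds = cds, protein = protein, mass_kda = protein_mw(protein))
}
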