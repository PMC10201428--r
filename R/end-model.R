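# Transposon-end architecture: terminal ends, TnsB binding sites (TBSs),
# IHF site and mini-transposon geometry.
#
# The native VchCAST end sequences are not printed in the source literature,
# so the packaged wild-type fixture is a synthetic sequence that satisfies
# every documented architectural constraint: 147-nt left end and 75-nt right
# end (57-nt minimal), 8-bp terminal ends beginning with the conserved TG
# dinucleotide, three 14-nt TBSs per end sharing the conserved positions
# 1, 6-8 and 12-14, and a perfect IHF consensus match (5'-WATCARNNNNTTR-3')
# between L1 and L2. All downstream analyses are architecture-based, never
# native-sequence-based.

TBS_LENGTH <- 14L
TBS_CONSERVED_POS <- c(1L, 6L, 7L, 8L, 12L, 13L, 14L)
TBS_CONSENSUS <- "TNNNNGTCNNNGCA"
IHF_CONSENSUS <- "WATCARNNNNTTR"

# the six fixture TBSs: identical at the conserved positions, varied elsewhere
FIXTURE_TBS <- c(
  L1 = "TACGAGTCACTGCA",
  L2 = "TCCTGGTCGTAGCA",
  L3 = "TGAACGTCTCGGCA",
  R1 = "TAGGTGTCCATGCA",
  R2 = "TCATCGTCTGCGCA",
  R3 = "TGTCAGTCATGGCA"
)

LEFT_TERMINAL <- "TGTTGACT"
RIGHT_TERMINAL <- "TGGTCGAT"
IHF_FIXTURE_SITE <- "AATCAGCAAATTA" # perfect WATCARNNNNTTR match

# 19-nt fixed primer-binding sequence at the cargo-proximal terminus of the
# end, used for donor-junction barcode extraction
PRIMER19 <- "GACCTTAGCGTCAATGTCG"

#' Fixed constants of the transposon-end architecture
#'
#' @return `tbs_consensus()`: the IUPAC consensus used to locate TnsB
#'   binding sites (conserved positions 1, 6-8 and 12-14 of the 14-nt
#'   footprint); `ihf_consensus()`: the IHF consensus 5'-WATCARNNNNTTR-3';
#'   `fixture_tbs_set()`: the six packaged TBS sequences L1-L3/R1-R3;
#'   `donor_primer19()`: the fixed 19-nt primer-binding sequence used for
#'   barcode extraction.
#' @export
tbs_consensus <- function() TBS_CONSENSUS

#' @rdname tbs_consensus
#' @export
ihf_consensus <- function() IHF_CONSENSUS

#' @rdname tbs_consensus
#' @export
fixture_tbs_set <- function() FIXTURE_TBS

#' @rdname tbs_consensus
#' @export
donor_primer19 <- function() PRIMER19

#' Construct a transposon end model
#'
#' @param side `"left"` or `"right"`.
#' @param sequence DNA string, transposon-centric 5'->3' from the tip inward
#'   (position 1 = first base of the 8-bp terminal end).
#' @param tbs data.frame with columns `label`, `start`, `end` (1-based,
#'   closed) ordered tip -> interior.
#' @param ihf_site optional `c(start, end)` of an IHF consensus match;
#'   left end only, must lie strictly between the first two TBSs.
#' @return object of class `transposon_end`.
#' @export
transposon_end <- function(side, sequence, tbs, ihf_site = NULL) {
  side <- match.arg(side, c("left", "right"))
  sequence <- toupper(sequence)
  stopifnot_dna(sequence, "end sequence")
  if (substr(sequence, 1, 2) != "TG") {
    stop("no terminal TG: end must begin with the conserved TG dinucleotide",
         call. = FALSE)
  }
  stopifnot(is.data.frame(tbs), all(c("label", "start", "end") %in% names(tbs)))
  tbs <- tbs[order(tbs$start), , drop = FALSE]
  if (any(tbs$end - tbs$start + 1L != TBS_LENGTH)) {
    stop(sprintf("all TBS intervals must span %d nt", TBS_LENGTH), call. = FALSE)
  }
  if (nrow(tbs) > 1L && any(tbs$start[-1L] <= tbs$end[-nrow(tbs)])) {
    stop("TBS intervals must be non-overlapping", call. = FALSE)
  }
  if (tbs$start[1L] <= 8L) {
    stop("first TBS overlaps the 8-bp terminal end", call. = FALSE)
  }
  if (!is.null(ihf_site)) {
    if (side != "left") stop("ihf_site is defined for the left end only",
                             call. = FALSE)
    stopifnot(length(ihf_site) == 2L)
    if (!(ihf_site[1] > tbs$end[1L] && ihf_site[2] < tbs$start[2L])) {
      stop("ihf_site must lie strictly between the first two TBSs",
           call. = FALSE)
    }
  }
  structure(
    list(side = side,
         sequence = sequence,
         terminal_end = substr(sequence, 1L, 8L),
         tbs = tbs,
         ihf_site = ihf_site),
    class = "transposon_end")
}

#' @export
print.transposon_end <- function(x, ...) {
  cat(sprintf("<transposon_end> %s end, %d nt, terminal end %s\n",
              x$side, nchar(x$sequence), x$terminal_end))
  cat(sprintf("  TBSs: %s\n",
              paste(sprintf("%s[%d-%d]", x$tbs$label, x$tbs$start, x$tbs$end),
                    collapse = " ")))
  if (!is.null(x$ihf_site)) {
    cat(sprintf("  IHF site: [%d-%d] %s\n", x$ihf_site[1], x$ihf_site[2],
                substr(x$sequence, x$ihf_site[1], x$ihf_site[2])))
  }
  invisible(x)
}

#' Extract the sequence of one TBS interval
#' @param end a `transposon_end`.
#' @param label TBS label, e.g. `"L2"`.
#' @return DNA string of the binding site.
#' @export
tbs_sequence <- function(end, label) {
  i <- match(label, end$tbs$label)
  if (is.na(i)) stop(sprintf("no TBS labeled '%s'", label), call. = FALSE)
  substr(end$sequence, end$tbs$start[i], end$tbs$end[i])
}

#' Construct a mini-transposon
#'
#' @param left_end,right_end `transposon_end` objects.
#' @param cargo DNA string between the two ends.
#' @param flank_5,flank_3 5-nt donor context on each side.
#' @return object of class `mini_transposon` whose `length` equals
#'   `nchar(left) + nchar(cargo) + nchar(right)`.
#' @export
mini_transposon <- function(left_end, right_end, cargo,
                            flank_5 = "CCGGA", flank_3 = "TCCGG") {
  stopifnot(inherits(left_end, "transposon_end"),
            inherits(right_end, "transposon_end"),
            left_end$side == "left", right_end$side == "right",
            nchar(flank_5) == 5L, nchar(flank_3) == 5L)
  cargo <- toupper(cargo)
  stopifnot_dna(cargo, "cargo")
  structure(
    list(left_end = left_end, right_end = right_end, cargo = cargo,
         flank_5 = toupper(flank_5), flank_3 = toupper(flank_3)),
    class = "mini_transposon")
}

#' @export
length.mini_transposon <- function(x) {
  nchar(x$left_end$sequence) + nchar(x$cargo) + nchar(x$right_end$sequence)
}

#' @export
print.mini_transposon <- function(x, ...) {
  cat(sprintf("<mini_transposon> %d nt total (left %d + cargo %d + right %d)\n",
              length(x), nchar(x$left_end$sequence), nchar(x$cargo),
              nchar(x$right_end$sequence)))
  invisible(x)
}

#' Full donor-centric sequence of a mini-transposon
#'
#' Concatenates the left end, cargo and the *reverse complement* of the
#' right end (both ends are stored tip-inward, so on the donor top strand
#' the right end runs tip-outward at the 3' boundary).
#'
#' @param x a `mini_transposon`.
#' @param with_flanks include the 5-nt donor context on each side.
#' @return DNA string.
#' @export
mini_tn_sequence <- function(x, with_flanks = FALSE) {
  s <- paste0(x$left_end$sequence, x$cargo, dna_revcomp(x$right_end$sequence))
  if (with_flanks) s <- paste0(x$flank_5, s, x$flank_3)
  s
}

# deterministic cargo: seeded draw, re-drawn until free of architecture
# motifs (TBS consensus, IHF consensus, primer19) on both strands
make_fixture_cargo <- function(len) {
  withr::with_seed(20230775L, {
    repeat {
      cargo <- random_dna(1L, len)
      clean <- nrow(iupac_scan(cargo, TBS_CONSENSUS, both_strands = TRUE)) == 0 &&
        nrow(iupac_scan(cargo, IHF_CONSENSUS, both_strands = TRUE)) == 0 &&
        !grepl(PRIMER19, cargo, fixed = TRUE) &&
        !grepl(PRIMER19, dna_revcomp(cargo), fixed = TRUE)
      if (clean) return(cargo)
    }
  })
}

ca_filler <- function(len) {
  substr(strrep("CCA", ceiling(len / 3) + 1L), 1L, len)
}

fixture_left_sequence <- function() {
  paste0(
    LEFT_TERMINAL,                        # 1-8
    FIXTURE_TBS[["L1"]],                  # 9-22
    "CCA", IHF_FIXTURE_SITE, "CCACCA",    # 23-44 (IHF at 26-38)
    FIXTURE_TBS[["L2"]],                  # 45-58
    ca_filler(21L),                       # 59-79
    FIXTURE_TBS[["L3"]],                  # 80-93
    ca_filler(54L)                        # 94-147
  )
}

fixture_right_sequence <- function() {
  paste0(
    RIGHT_TERMINAL,                       # 1-8
    FIXTURE_TBS[["R1"]],                  # 9-22
    "CCTAACTAGCTGA",                      # 23-35 (stops in all three frames)
    FIXTURE_TBS[["R2"]],                  # 36-49
    "CCACCACC",                           # 50-57 (minimal end boundary)
    FIXTURE_TBS[["R3"]],                  # 58-71
    "CCAC"                                # 72-75
  )
}

#' Wild-type mini-transposon fixture
#'
#' Deterministic synthetic mini-transposon reproducing the documented
#' architecture: 775 nt total, a 147-nt left end and a 75-nt right end
#' delimited by 8-bp terminal ends beginning TG, three 14-nt TBSs per end
#' sharing the conserved footprint positions, and a perfect IHF consensus
#' match between L1 and L2 of the left end. The tip-proximal 57 nt of the
#' right end form the minimal right end (two TBSs; stop codons in all three
#' reading frames).
#'
#' @param minimal_right use the 57-nt minimal right end instead of the
#'   default 75-nt end (total length shrinks accordingly).
#' @return a `mini_transposon`.
#' @examples
#' tn <- make_wt_fixture()
#' length(tn) # 775
#' @export
make_wt_fixture <- function(minimal_right = FALSE) {
  left <- transposon_end(
    "left", fixture_left_sequence(),
    data.frame(label = c("L1", "L2", "L3"),
               start = c(9L, 45L, 80L), end = c(22L, 58L, 93L)),
    ihf_site = c(26L, 38L))
  rseq <- fixture_right_sequence()
  if (minimal_right) {
    right <- transposon_end(
      "right", substr(rseq, 1L, 57L),
      data.frame(label = c("R1", "R2"),
                 start = c(9L, 36L), end = c(22L, 49L)))
  } else {
    right <- transposon_end(
      "right", rseq,
      data.frame(label = c("R1", "R2", "R3"),
                 start = c(9L, 36L, 58L), end = c(22L, 49L, 71L)))
  }
  cargo_len <- 775L - 147L - nchar(rseq) # 553
  mini_transposon(left, right, make_fixture_cargo(cargo_len))
}

#' Annotate a transposon end by consensus scanning
#'
#' Locates TBS intervals by scanning the end tip -> interior with an IUPAC
#' consensus and labels them `L1..`/`R1..` in order of distance from the tip.
#' Overlapping consensus hits are resolved greedily from the tip.
#'
#' @param sequence DNA string, tip-inward orientation.
#' @param side `"left"` or `"right"`.
#' @param tbs_motif IUPAC consensus of the binding-site footprint.
#' @param min_sites minimum number of binding sites required (default 2,
#'   the minimal functional right end).
#' @param annotate_ihf also scan for an IHF consensus match between the
#'   first two TBSs (left end only).
#' @return a `transposon_end`.
#' @export
annotate_end <- function(sequence, side, tbs_motif = tbs_consensus(),
                         min_sites = 2L, annotate_ihf = (side == "left")) {
  side <- match.arg(side, c("left", "right"))
  sequence <- toupper(sequence)
  stopifnot_dna(sequence, "end sequence")
  if (nchar(sequence) < 8L + nchar(tbs_motif)) {
    stop("sequence shorter than terminal end + one binding site", call. = FALSE)
  }
  if (substr(sequence, 1, 2) != "TG") {
    stop("no terminal TG", call. = FALSE)
  }
  hits <- iupac_scan(sequence, tbs_motif)
  hits <- hits[hits$start > 8L, , drop = FALSE]
  starts <- integer(0)
  last_end <- 8L
  for (s in hits$start) {
    if (s > last_end) {
      starts <- c(starts, s)
      last_end <- s + nchar(tbs_motif) - 1L
    }
  }
  if (length(starts) < min_sites) {
    stop(sprintf("insufficient TBS matches: found %d, need >= %d",
                 length(starts), min_sites), call. = FALSE)
  }
  tbs <- data.frame(
    label = paste0(toupper(substr(side, 1, 1)), seq_along(starts)),
    start = starts,
    end = starts + nchar(tbs_motif) - 1L)
  ihf <- NULL
  if (annotate_ihf && side == "left" && nrow(tbs) >= 2L) {
    gap_start <- tbs$end[1L] + 1L
    gap_end <- tbs$start[2L] - 1L
    if (gap_end - gap_start + 1L >= nchar(IHF_CONSENSUS)) {
      gap <- substr(sequence, gap_start, gap_end)
      ih <- iupac_scan(gap, IHF_CONSENSUS)
      if (nrow(ih) > 0) {
        ihf <- c(gap_start + ih$start[1L] - 1L,
                 gap_start + ih$start[1L] + nchar(IHF_CONSENSUS) - 2L)
      }
    }
  }
  transposon_end(side, sequence, tbs, ihf_site = ihf)
}

#' Interval annotation table of a transposon end
#'
#' @param end a `transposon_end`.
#' @return data.frame (feature, label, start, end, sequence) covering the
#'   terminal end, every TBS and the IHF site when present; suitable for
#'   TSV export via [write_tsv_prov] conventions.
#' @export
end_annotation_table <- function(end) {
  stopifnot(inherits(end, "transposon_end"))
  rows <- data.frame(feature = "terminal_end", label = "terminal",
                     start = 1L, end = 8L,
                     sequence = end$terminal_end)
  rows <- rbind(rows, data.frame(
    feature = "tbs", label = end$tbs$label,
    start = end$tbs$start, end = end$tbs$end,
    sequence = substring(end$sequence, end$tbs$start, end$tbs$end)))
  if (!is.null(end$ihf_site)) {
    rows <- rbind(rows, data.frame(
      feature = "ihf_site", label = "IHF",
      start = end$ihf_site[1], end = end$ihf_site[2],
      sequence = substr(end$sequence, end$ihf_site[1], end$ihf_site[2])))
  }
  rownames(rows) <- NULL
  rows
}

# ---- genetic code ---------------------------------------------------------

GENETIC_CODE_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Expasy average residue masses (Da); water added once per chain
RESIDUE_MASSES <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)
WATER_MASS <- 18.01524

#' The standard genetic code and residue mass table
#'
#' @return `genetic_code_table()`: list with `code` (64 codon -> amino acid,
#'   stops as `"*"`), `stops` (the three stop codons), `residue_masses`
#'   (average masses, Da) and `water_mass` (Da).
#' @export
genetic_code_table <- function() {
  list(code = GENETIC_CODE_TABLE, stops = STOP_CODONS,
       residue_masses = RESIDUE_MASSES, water_mass = WATER_MASS)
}
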