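---
title: "Pooled transposon-end and target-site screens: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled transposon-end and target-site screens: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(castscreen)
```

## The system and the two screens

CRISPR-associated transposases (CASTs) are Tn7-family mobile elements that
use a nuclease-deficient CRISPR effector for RNA-guided DNA integration.
Two DNA substrates determine how well integration works: the **transposon
ends** (the left and right terminal sequences, each carrying an 8-bp
terminal end beginning with the conserved TG dinucleotide and a series of
14-nt TnsB binding sites, TBSs), and the **target site**, where the
transposase inserts the element 43–56 bp downstream of the 32-bp
crRNA-matched sequence, duplicating 5 bp at the insertion point (the
target-site duplication, TSD).

`castscreen` implements the computational side of two pooled screens over
these substrates:

* a **donor screen**, in which thousands of barcoded transposon-end
  variants compete in one reaction and deep sequencing of input and
  integrated (output) pools yields a relative integration efficiency per
  variant; and
* a **target screen**, in which integration is directed into an 8-bp
  degenerate region and junction reads reveal which insertion-site
  sequences and distances the transposase prefers.

Both screens come with first-class simulators that plant known ground
truth, so every estimator in the package can be validated end to end.

## Coordinates and fixtures

All coordinates are 1-based closed intervals, the R/Bioconductor
convention. Transposon ends are stored tip-inward: position 1 is the first
base of the terminal end, so both ends begin `TG`. On the target, position
1 is the first base downstream of the 32-bp target; the degenerate region
occupies positions 43–50 ("42 bp downstream"), a call at distance `d`
places the junction at position `d`, the TSD spans `d-4..d`, and the
scored window (TSD-relative −3…+3) spans `d-7..d+3`.

The native end sequences are not published as plain text, so
`make_wt_fixture()` builds a deterministic *synthetic* mini-transposon
satisfying every documented architectural constraint: 775 bp total with a
147-bp left end and 75-bp right end; six 14-nt TBSs agreeing at the
conserved footprint positions 1, 6–8 and 12–14; a perfect IHF consensus
match (`WATCARNNNNTTR`) between L1 and L2; and a 57-nt minimal right end
exposing two TBSs and carrying stop codons in all three reading frames.
Every test in the package is architecture-based, never
native-sequence-based. One documented discrepancy: the wild-type IHF site
reported for this system (`AATCAGCAAACTTA`, 14 nt) does not in fact match
the 13-nt consensus at any offset; the fixture embeds a perfect consensus
match instead and the package makes no claim about the native site.

## The donor quantification model

Reads are filtered for a perfect match to the fixed 19-nt primer-binding
sequence; the 10 nt immediately downstream form the barcode, matched
exactly against the manifest (mismatching reads are discarded and
counted). With input and output counts $c^{in}_v, c^{out}_v$:

$$\mathrm{fc}_v = \frac{c^{out}_v / \sum_w c^{out}_w}
                       {c^{in}_v / \sum_w c^{in}_w},
\qquad
\mathrm{score}_v = \frac{\mathrm{fc}_v}
                        {\tfrac14\sum_{u \in WT}\mathrm{fc}_u},$$

log2 applied last. The four wild-type spike-ins (identical ends, unique
barcodes) therefore have mean normalized score exactly 1. Variants with
zero input counts are reported undefined rather than smoothed; a
pseudocount argument exists but defaults to 0 because the original
analysis used none. Barcodes are assigned with pairwise Hamming distance
≥ 3 so a single sequencing error cannot convert one valid barcode into
another; extraction still requires exact matches, as in the original
filtering rules.

**Barcode uncoupling.** PCR recombination reattaches a variant's barcode
to another variant's end. The simulator re-draws an uncoupled read's
barcode from the other members proportional to library abundance; because
the re-drawn barcode is independent of the donor variant, the expected
fold-change remains monotone in the true efficiency, which is why rank
recovery survives uncoupling rates of ~0.35 — the package's quantitative
restatement of the original argument that uncoupling did not prevent
efficiency estimation. `coupling_qc()` measures uncoupling directly from
paired barcode/end reads: a pair is correct iff the mate carries the
manifest end of the barcode's variant (exact identity), so the coupling
simulator is error-free by default — base errors would conflate
sequencing error with recombination.

## The target-site model

The insertion preference model assigns each TSD-relative window position a
nucleotide weight vector (rows sum to 1 per position). A candidate
distance is scored as the sum of log-weights of the 11 window bases;
`predict_sites()` ranks distances by score with ties broken by ascending
distance (documented, deterministic).

The default planted model encodes the documented biases: a central Y/W/R
triplet at TSD positions 2–4 whose preferred realization is `CWG`
(dominant weights 0.82 C / 0.12 T at T2, 0.47/0.47 A/T at T3, 0.82 G /
0.12 A at T4), D (not C) at −3 and H (not G) at +3 (0.3/0.3/0.3 vs 0.1),
uniform elsewhere. The strong central concentration is deliberate: the
mean per-position weight over random bases is always 1/4, so only a
dominant base well above 1/2 lets motif-bearing clones clear a four-fold
enrichment over the pool average — the regime in which the published
pooling rule (four-fold threshold, then top 5000 sequences per library)
selects genuine signal. A flatter YWR model is constructable via
`insertion_pref_model()`, but under it four-fold sequence-level enrichment
is mathematically unattainable regardless of depth.

**Generative model.** The input library is a finite pool of clones
(default 30 000, a scraped-plate bottleneck) carrying uniform random
8-mers. Input reads sample clones uniformly; output molecules are drawn
proportional to each clone's total integration propensity
$A(s) = \sum_{d,o} \prod_p w_p(s)$ and then receive a distance from the
conditional $P(d\,|\,s)$ and an orientation (default 0.9 T-RL / 0.1 T-LR,
the dominant orientation for this system). Reads follow the amplicon
design: i5 reads start with the exact 34-nt anchor (35-nt for the
extra-diversity primers) and cross the junction into 20 nt of the
proximal end; i7 reads start with the 45/46-nt downstream anchor and
cross the duplicated TSD into the distal end. The backbone of the
synthetic target region uses only C and A (plus the diversity bases and
the −3 flank positions), chosen so that no transposon-end 20-mer and no
viable central triplet can arise from fixed sequence, and so that no
distance is handicapped by its backbone −3 base; target B differs from
target A solely by a disfavored C at position 42, the −3 position of the
49-bp distance.

**Calling.** After anchor filtering, candidate junction offsets for
distances 43–56 are tested in ascending order for an exact 20-nt match to
either end; the first match wins, the matched end fixes the orientation,
and an ambiguous double match is a counted no-call. The 8-mer is
assembled from the i5 read (positions 43..d) and, when the junction
truncates it, completed from the i7 read across the TSD (the i5 copy wins
on overlap). The packaged end fixtures are verified aperiodic over their
first 20 nt, which together with the C/A backbone makes calling on
error-free reads exact — the suite asserts 0 miscalls on 10^4 reads.

**Logos and fitting.** Per library, (8-mer, distance) combinations with
fold-change ≥ 4 are ranked, the top 5000 kept ("use all, record the
shortfall" when fewer survive), and each selected 8-mer's bases mapped
into TSD-relative columns given its distance; only degenerate-derived
bases contribute, so two full libraries pool to 10 000 observations at
every fully covered position. Information content is 2 − H bits per
column with no small-sample correction (plain WebLogo-style columns).
`fit_preference_model()` normalizes the pooled columns into weights;
columns with fewer than 50 pooled observations fall back to uniform and
are flagged uncovered, since frequencies from a handful of sequences
carry no usable signal. Censored (−∞) enrichments are excluded from
ranking; enrichment denominators are position-agnostic input 8-mer
abundances (the input has no distance), with per-(8-mer, distance) output
counts pooled across the two primer pairs.

## Linker recoding

Integrated ends remain as sequence scars; `design_linkers()` turns the
minimal right end into a benign in-frame peptide. Offending codons (stops
plus a configurable bulky/charged set, default W F Y R K D E H P — the
original report never enumerates its set) are replaced by minimum-edit
codons for allowed residues, never touching an immutable mask; the
default mask is the conserved TBS footprint (positions 1, 6–8, 12–14 of
each annotated site), wiring the mutability results into the designer.
All co-optimal solutions are enumerated (capped, deterministic order),
and accepted variants provably satisfy zero violations; minimality is
tested against exhaustive search. `build_fusion()` checks reading-frame
arithmetic and internal stops for gene–linker–cargo fusions, and
`protein_mw()` uses average residue masses (the packaged 239-residue
superfolder GFP computes to 26.8 kDa at one decimal).

## Auxiliary quantification

qPCR efficiency is $2^{\Delta Cq}$ with $\Delta Cq = Cq_{ref} - Cq_{target}$,
so rarer integration products give efficiencies below 1 (the sign
convention is fixed here because the source wording is ambiguous);
replicates average efficiencies after exponentiation by default, with
dCq-first averaging available. Tn7 attachment-site amplicons are
classified by exact 65-nt prefix against the expected products
(unintegrated, or integration at 0–30 bp in either orientation); the
prefix table is verified pairwise distinct at construction, and
classification is a strict partition.

## Simulation sizes and what passing tests show

The routine suite runs at reduced depth (10^3–10^4 reads); the
acceptance-style checks use the documented study conditions: 200-variant
donor libraries at 10^5 reads with uncoupling 0.35 and 0.1% base error
(Spearman recovery ≥ 0.9), 5×10^4 coupling pairs (rate recovered ±0.02),
10^4 error-free junction reads (exact calls), and 10^5 output reads over
a 30 000-clone pool with the input sequenced at 4×10^5 reads (two input
runs summed was the original practice) for logo recovery and refit
consistency (per-position total variation ≤ 0.05 across positions covered
in both fits).

The simulators reproduce the statistical structure the estimators assume —
multinomial sampling, abundance dispersion, uncoupling, uniform
substitution error, motif-driven distance choice — but not everything
about real data: no amplification bias beyond uncoupling, no indels or
chimeras within the end sequence, constant base quality, and a synthetic
(not native) end sequence. Passing tests therefore demonstrate estimator
correctness and robustness under the modelled noise, not performance on
any particular sequencing run.

## Known limitations

* The exact historical variant catalogs (1549 left / 1849 right members)
  live in supplementary material; the generators reproduce the design
  categories, not the literal lists.
* The truncation filler and substitution rule (complementation) are
  package design choices; the original variants were designed ad hoc.
* Orientation-specific donor quantification is handled as separate
  samples through the same pipeline; no cross-orientation normalization
  is attempted, mirroring the per-amplicon-set analysis.
* IUPAC scanning tolerates mismatches via a parameter, but no default
  mismatch tolerance is claimed for cross-system consensus conservation.
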