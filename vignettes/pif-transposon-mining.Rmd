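---
title: "Mining PIF-like transposons: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining PIF-like transposons: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pifminer)
```

## The element model

`pifminer` targets class-II (cut-and-paste) DNA transposons of the
*PIF/Harbinger* superfamily, using the anatomy of *PePIF1* from
*Phalaenopsis equestris* as its concrete model:

* a 19-bp terminal inverted repeat (TIR) with the degenerate consensus
  `GGGYCYGTTTGGGGCAGCT` (Y = C/T), identical at both ends of the element
  (the 3' copy reverse-complemented);
* a 3-bp target-site duplication (TSD), preferentially `TTA`, created on
  both flanks when the transposase re-ligates the staggered cut;
* two head-to-tail internal proteins between the TIRs: ORF1 (272 aa,
  Myb/SANT-like) and a transposase (427 aa, DDE catalytic triad);
* weakly conserved family-specific sub-terminal regions just inside each
  TIR — the landing sites of transposon-display primers;
* an autonomous full length of 5,053 bp for family A; family B copies run
  longer (6-8 kb) and their proteins share only about 51.6% (transposase)
  and 37.4% (ORF1) amino-acid identity with family A, far below the
  family threshold.

Around an intact autonomous element the superfamily accumulates
defective derivatives — copies missing ORF1, the transposase, one or
both TIRs — and miniature inverted-repeat transposable elements (MITEs):
short (mostly 200-300 bp) non-coding copies that keep the TIRs and
sub-terminal regions and are amplified in trans.

## The mining procedure

1. **Degenerate motif scan** (`scan_motif`). Both strands are scanned
   for the TIR consensus. Degenerate positions match their IUPAC class
   at zero cost; the mismatch budget (`max_mismatch`, default 2) applies
   to the remaining positions, and `N` never matches. The published
   screen used BLAST with an E-value cutoff, which has no exact
   motif-mismatch equivalent; two mismatches over the 17 fixed positions
   is a comparable stringency and is exposed as a parameter rather than
   claimed equivalent.
2. **De novo inverted repeats** (`discover_inverted_repeats`). For
   unknown elements, maximal exact inverted-repeat pairs with arm length
   >= `min_match` are enumerated. The default of 12 reads the
   "more than 11-bp matches" screening convention as >= 12. Maximality
   is defined subject to the two arms staying disjoint; a palindromic
   run crossing its own centre is truncated at the centre.
3. **TIR pairing** (`pair_tirs`). Forward hits are paired greedily, left
   to right, with downstream reverse-complement hits within a span
   window (`min_span` 50 bp to `max_span` 30,000 bp — the maximum length
   allowed between two TIRs of one element). Each hit is used once.
   Tie-break order: TSD-valid pairings first, then smallest span, then
   leftmost right TIR. Smallest span avoids chimeric calls across
   neighbouring elements; whether TSD validity was required for
   acceptance in the original screen is not stated, so validity is
   reported as a flag rather than used as a filter.
4. **Coding evidence** (`detect_coding`). Each candidate is translated
   in all six frames; stop-free segments of at least `min_hsp` (30)
   residues are locally aligned (BLOSUM62, gap open 11 / extend 1 —
   standard protein defaults) against the ORF1/transposase references
   after a shared-5-mer prescreen. Like the translated-search tools this
   replaces, high-scoring pairs from one frame are tiled: coverage is
   the union of aligned reference spans, identity the length-weighted
   mean. This makes detection robust to the premature stop codons that
   accumulate in diverging copies. Thresholds default to 30% identity
   and 50% coverage — the identity floor is set well below the ~36-37%
   ORF1 divergence observed between related families, and the coverage
   floor lets the largest exon of a multi-exon gene qualify, since
   spliced ORFs are deliberately not reconstructed.
5. **Classification** (`classify_element`). Deterministic rule over the
   presence flags: both TIRs with both proteins is `AUTONOMOUS`; both
   TIRs with one protein is `DEF_NO_ORF1` / `DEF_NO_TPASE`; both TIRs
   without coding is `MITE_LIKE` up to `mite_max_len` (800 bp — the
   observed miniature copies are 200-300 bp, and the headroom avoids
   absorbing 1-2 kb defective copies) and `DEF_NO_CODING` beyond it;
   one TIR is `DEF_ONE_TIR`; coding without TIRs is
   `DEF_NO_TIR_FRAGMENT`. The exact criteria separating partially
   coding defective subclasses are not fully enumerable from the source
   material, so the thresholds are exposed rather than guessed.
6. **Families** (`cluster_families`). The 80-80-80 rule — identity
   >= 80% over >= 80% coverage of both sequences and >= 80 aligned
   units — defines a pairwise relation whose single-linkage closure is
   the family partition. Single linkage is the default because the rule
   is stated pairwise; complete linkage is available. The rule is
   applied at the DNA level over the full element by default; because
   the reported family divergence is protein-level, protein identities
   for the ORF1/transposase regions are computed by the same machinery
   (`pairwise_identity`, levels `protein_*`). Identity is counted over
   alignment columns after trimming terminal gaps, so a short fragment
   inside a long element scores high identity but low coverage.

### Recovery of TIR-less copies in the pipeline

Copies that lost one or both TIRs cannot be found by TIR pairing. The
pipeline (`mine_elements`) therefore also scans for the family-specific
sub-terminal blocks as 60-bp anchors (mismatch budget
`anchor_max_mismatch`, default 6 = 10% divergence) and pairs 5'/3'
anchors of the same family; immediately adjacent TIR hits then extend
the bounds and set the TIR presence flags. This anchor strategy stands
in for whole-element homology mapping (the original screen mapped known
element sequences genome-wide with BLASTN) and relies on defective
copies retaining their sub-terminal regions — the generator's default,
and a prerequisite for transposon display to see them at all.

## Transposon display in silico

`digest_genome` cuts at every `CTAG` after the first base (BfaI,
`C^TAG`); fragments tile the scaffold. `simulate_display` anneals the
family sub-terminal primer wherever it matches (exact by default;
`primer_max_mismatch` available since the sub-terminal regions are only
weakly conserved), extends in the primer's 3' direction to the nearest
cut site, and reports the amplicon length as primer-to-cut distance plus
`adapter_len`. The selective dinucleotide is read from the two genomic
bases immediately interior to the cut — the bases the
adapter-complementary `+NN` primer interrogates — so each amplicon falls
in exactly one of 16 bins; the published assay used 8 of them, the
default here. Amplicons outside the gel window (default 50-700 bp, a
typical polyacrylamide display range; the source does not state one) are
dropped. Only the selective (second-round) amplification is modelled:
pre-selective amplification and touchdown cycling affect efficiency, not
band position. `diff_profiles` then reports bands present in some
samples and absent in others — the new-band / lost-band readout used to
demonstrate active transposition across micropropagation generations.
Amplicon lengths are exact integers, so the default length-matching
tolerance is 0.

## The synthetic-data generator

`generate_dataset` emulates the study conditions, not real chromatin:

* a uniform-random background (default GC 0.44, 2 Mb for the demo
  spec); no isochore or repeat structure beyond the planted copies;
* planted copies of every structural class, each insertion duplicating
  the 3 bases at the target site. By default target sites are re-drawn
  until they read `TTA` (`tsd_force_tta`) — the observed preference —
  while the duplication mechanics work at any site;
* per-copy divergence by substitution only (`mutation_rate`, default
  0.02), so planted coordinates stay exact — which is what makes ±2-bp
  boundary scoring meaningful. Indels, nested insertions and truncation
  gradients of real TE landscapes are not simulated; elements are
  planted on the forward strand. Passing recovery tests here shows the
  machinery is correct, not that real-genome recall will match;
* family templates with fixed internal spacers, so copies of one family
  are identical before mutation — the premise of family clustering. The
  coding fixtures are synthetic stand-ins generated at the published
  inter-family divergence (51.5% transposase, 37.5% ORF1 identity
  realized) and are intronless by design;
* gene models placed so configurable fractions of elements fall in
  exons (0.1) and introns (0.3), echoing the roughly 1:3
  coding-to-intronic ratio reported for genic insertions, plus
  element-free genes up to `n_genes`;
* a variant genome with `variant_extra_insertions` additional copies —
  MITE-like family-B insertions, mirroring the observation that new
  transposition events in this system trace to the B family and are
  mediated by miniature copies.

All randomness flows from one integer seed; identical spec and seed
give byte-identical FASTA/GFF3/TSV outputs.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; GFF3 output is 1-based
  closed. The evaluator refuses GFF3 input with a start below 1.
* An element flush against a scaffold edge gets sentinel `NNN` TSD
  flanks and `tsd_valid = FALSE` instead of an error.
* A region shorter than two arms returns an empty inverted-repeat set;
  an element shorter than one codon returns empty coding evidence; a
  scaffold without the restriction site is a single fragment; a primer
  absent from the genome gives an empty profile with a warning.
* Candidates with no TIRs and no coding evidence are unclassifiable and
  get `NA` rather than a guessed class.
* Family labels are deterministic (clusters ordered by smallest member
  name), so the partition is invariant under input permutation.
* Insertion-site draws that collide or miss a `TTA` site are re-drawn up
  to 1,000 times before the generator errors out.
* Intergenic distance ties are broken toward the lower-coordinate gene;
  the element-to-gene relation counts any overlap with the gene span,
  and an exon call takes priority over intron when an element straddles
  a boundary, coding disruption being the stronger call. For intergenic
  copies only the nearest gene is reported (one convention, stated
  here, rather than both).

## Problem sizes used in the checks

The packaged checks run at desk scale by choice: recovery is scored on
a 5-Mb genome with 200 planted copies (12 autonomous, 88 defective, 100
MITE-like — a MITE-heavy inventory like the observed one) at 2%
divergence, where the pipeline reaches recall and precision 0.99 with
perfect class assignment; oracle-equivalence suites compare every
scanning, digest, intersection and clustering primitive against naive
enumerations on inputs up to 10^5 bases; the display check plants one
extra insertion into a 1-Mb genome and verifies a new band at the
brute-force-predicted length, with all 16 selective dinucleotides
scored and a 2-mismatch primer tolerance pinned for full ascertainment
of the diverged planted copies. Genome-scale inventories (thousands of
copies on gigabase assemblies) are the intended application but are not
reproduced by the checks.

## Known limitations

* Substitution-only divergence in the generator; no indel realism, so
  the ±2-bp recovery tolerance is not stressed by coordinate drift.
* Spliced ORFs are not reconstructed; a heavily intron-fragmented gene
  is detected only through its largest exon.
* The anchor-based recovery of TIR-less copies presumes intact
  sub-terminal regions; copies diverged beyond the anchor budget (or
  the TIR mismatch budget) are invisible, as they would be to the
  motif screen it emulates.
* Display simulation ignores PCR bias, fluorescence intensity and gel
  nonlinearity; bands are exact fragment lengths.
* The E-value cutoff of the original BLAST screens has no exact
  counterpart in motif-mismatch space; parameter equivalence is not
  claimed, only comparable stringency.
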