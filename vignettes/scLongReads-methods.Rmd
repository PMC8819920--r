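---
title: "Methods: single-cell long-read demultiplexing, UMI merging, isoform and immune-receptor analysis"
author: "scLongReads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell long-read demultiplexing, UMI merging, isoform and immune-receptor analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The data model

Droplet-based 3' single-cell chemistry places a 16 nt cell barcode and a
10 nt unique molecular identifier (UMI) directly adjacent to each other in
the oligo-dT primer, downstream of a constant PCR priming site. A
full-length cDNA consensus read therefore looks like

```
[adapter][cell barcode, 16 nt][10X UMI, 10 nt][oligo-dT][transcript, revcomp]
```

on one strand or its reverse complement on the other. Rolling-circle
consensus protocols additionally circularize each cDNA with a DNA splint
that carries its own molecular identifier, unique per circularization
event. `ChemistryConfig` holds this layout: the default adapter is the
constant priming site of the 10X primer, and the splint UMI is modelled as
a cassette `[flank1][splint UMI][flank2]` appended to the read, with
configurable flanks. The real splint sequence varies between protocols (and
is not standardised), so extraction is anchor-based and fully
configurable; the default splint-UMI length is 12 nt (see below for why).

The identifiers support two sequential deduplication steps with distinct
meanings: reads sharing a splint UMI are re-reads of one circularized
molecule; reads sharing a 10X UMI (after splint merging) are PCR copies of
one reverse-transcribed RNA molecule.

## Barcode assignment

The whitelist is the `expectedCells` most frequent exact observed barcodes
(default 1500, a typical per-run cell target), ties broken
lexicographically. No knee-point detection is attempted: at realistic
per-cell read depth every true barcode is observed far more often than any
errored variant, so simple counting suffices; the full count table is
returned so users can inspect the distribution.

Assignment uses two explicit Levenshtein criteria. With `L1` the distance
from the observed barcode to the nearest whitelist entry and `L2` the
distance to the second nearest, a read is assigned iff `L1 < 3` and
`L1 < L2 - 1`. The second rule makes a distance tie (`L1 == L2`)
unassignable, which is the literal reading we implement: ambiguity is a
status, not an error. With a single-entry whitelist `L2` is defined as
infinity. `L1`/`L2` are computed over barcode-length windows only, not
barcode+UMI, because the criteria are stated on the cellular identifier.

Adapters are located on both strands by semi-global alignment under unit
edit cost with a budget of 20% of the adapter length (rounded down; 4
edits for the 22 nt default). The search is the Myers bit-parallel
algorithm; a classical DP implementation of the same search is kept in the
package and pinned to it by a property test, so the fast path always has an
oracle. An equally-good match on both strands is reported
`ambiguous_adapter` and treated as unlocatable.

## UMI merging

"Similar" UMIs are those within `umiMaxEdits = 1` Levenshtein distance: at
10-12 nt and ~98% read accuracy, almost all UMI read errors are single
events. Grouping is single-linkage via union-find; the partition is
order-independent, and the representative of a group is the member with
the highest subread count, then the longest sequence, then the smallest
read id. For the 1-edit case candidate pairs are found by a pigeonhole
bucket on exact half-prefixes/half-suffixes, so merging stays near-linear
in the number of distinct UMIs.

Merging runs across all reads at once — before the final per-cell output —
first on splint UMIs, then on the representatives' 10X UMIs. This order
matters: a merged group can therefore span two cell assignments (a chance
UMI collision between cells), and exactly those groups are discarded
afterwards. Merging per cell first would make the discard rule vacuous.

The short-read-style dedup (`illuminaDedup`) is deliberately different:
exact (barcode, UMI) matching only, keeping molecules with raw read
coverage strictly greater than 3.

## What the simulator states, and what it does not

The generator emits reads in the exact layout above, with ground truth for
every read's cell, molecule, circularization event, transcript and strand.
Its stated world:

* error rates default to 1% substitutions and 0.5% each insertion and
  deletion — the ~98%-accuracy consensus-read regime; error-free runs are
  the exactness fixtures;
* duplication is two independent Bernoulli layers ("one extra copy" each):
  `tenxDupRate` duplicates a molecule (new circularization, same 10X UMI),
  `splintDupRate` duplicates a circularization event (same splint UMI),
  mirroring the two sequential merge steps;
* strands are uniform 50/50, and errors are applied last;
* **UMIs are drawn pairwise at Levenshtein distance >= 2** ("separated"
  mode). This is the one place the generator is deliberately cleaner than
  reality: with truly random 10-mers, thousands of molecules already
  produce many chance distance-1 pairs, and "exact recovery of the true
  molecule count" would not be a well-defined target under a 1-edit merge
  threshold. Separated UMIs make truth recovery exact, so any failure is a
  pipeline defect, not generator noise. The `"unique"` mode (distinctness
  only) exists because distance-2 sphere packing caps out near 15k
  10-mers; the 50k-read demultiplexing benchmark uses it, as UMI merging
  plays no role there. Consequence: green merge tests establish
  correctness of the grouping logic, not robustness to real-world UMI
  collision rates — the cross-cell discard fixture covers the collision
  path explicitly.
* the splint-UMI default length is 12 nt so that separated draws remain
  feasible at simulated scales (4^12 is roomy; 4^8 is not).

The simulator does not model raw-signal artifacts, quality scores,
expression realism, or junction biology beyond 0-8 nt random insertions in
recombined receptor transcripts (enough to exercise segment assignment,
nothing more).

## Isoform merging and differential usage

A model's splice chain is the ordered list of its intron boundaries
(0-based, PSL convention). Two models link iff (i) chains are equivalent:
equal length and per-site identical, with a 1 bp shift tolerated only when
one model's support is at least `abundanceRatio = 5` times the other's
(the ratio quantifies "much less abundant", which has no canonical value;
5 is conservative and configurable); and (ii) start and end sites are each
within `endWindow = 10` nt. Grouping is iterative (union-find), so members
of one group may be further than 10 nt apart when connected through an
intermediate model — intended behaviour, verified against a brute-force
transitive-closure oracle. Comparisons are strand-aware within a
chromosome; coordinates are 0-based half-open throughout and bit-exact on
PSL round trips.

Differential isoform usage per gene: build the isoform-by-cell-type count
table from per-cell supports, keep cell types where the gene is expressed,
require at least 2 cell types and 2 isoforms, then a Pearson chi-square
contingency test without continuity correction (the 2x2 closed form
`n(ad-bc)^2/((a+b)(c+d)(a+c)(b+d))` is the test's own oracle). P-values
are BH-corrected across tested genes and flagged at corrected p < 0.01.
Whether such a threshold should apply to raw or corrected p is genuinely
ambiguous in common usage; we apply it post-correction and always report
both, so either reading is recoverable. Cells with zero isoforms for a
gene contribute nothing — no pseudo-counts.

## Immune receptors

Locus extraction takes primary alignments only and selects reads
overlapping a BED interval of a locus by >= 1 base (half-open semantics).
An example GRCh38 BED ships as data, never hard-coded. V-filtering demands
a local alignment to some V reference at >= 80% identity over >= 100
columns (match 2, mismatch -2, gap open -4, extend -1); screening uses the
Myers distance and only the best candidate is scored exactly, which is
deterministic and two orders of magnitude faster than all-pairs
Smith-Waterman. J, D, and constant calls share the identity threshold with
class-specific minimum aligned lengths (25, 10, 50 nt — D segments are
~16 nt, constant regions long), and calls must be positionally ordered
V-(D)-J-C along the consensus; violators are dropped and flagged rather
than silently kept.

The per-cell consensus is the medoid read polished by per-column majority
vote over global alignments of all members to it. A pure column vote
cannot repair a deletion the medoid itself carries, which caps identity
near 99.8% at 1% indel rates; the vote therefore also splices in
insertions (relative to the medoid) supported by a strict majority of
members, restoring those bases. Ties keep the medoid base; insertion-string
ties pick the lexicographically smallest. The result is independent of
read order. This is simpler than partial-order alignment and sufficient at
supported error rates, but it is a known divergence from graph-based
consensus tools and will degrade sooner at higher indel rates.

Pairing: an IG pair is an annotated IGH plus an annotated light chain (IGK
or IGL; higher read support wins when both exist, ties to IGK), a TCR pair
is TRA plus TRB, and unpaired cells report which chains were detected.
Cells with several IGH isotype consensuses additionally report whether all
isotypes share one V call — the signature of alternative splicing products
of a single rearrangement rather than a second allele.

## Numerical choices and degenerate inputs

* All randomness flows through R's RNG (including the C++ paths), so a
  single `set.seed()` reproduces any simulation byte-for-byte.
* Distance ties everywhere break deterministically (score, then length,
  then lexicographic id).
* Degenerate chi-square tables (one informative row or column after
  pruning) are `not_testable` statuses, not errors; unlocatable adapters,
  unfound splint UMIs, and unannotatable consensuses are likewise statuses.
* Empty inputs (no reads, empty PSL) return empty, well-formed objects.
* The processing pipeline itself consumes no randomness: identical inputs
  give byte-identical outputs, which the test suite asserts.

## Limitations

* No re-consensus of merged reads from subreads, and no directional
  (network-collapse) UMI correction; representative selection stands in
  for re-polishing.
* Isoform models enter via PSL from an external caller; no isoform
  discovery, GTF conversion, or category classification.
* No CDR3/junction analysis, somatic hypermutation, or clonal lineage
  inference; segment references are user-supplied FASTA.
* Thresholds quantifying prose ("similar", "much less abundant",
  "high-quality match") are explicit parameters with the defaults above;
  none are knee-point or data-adaptive.
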