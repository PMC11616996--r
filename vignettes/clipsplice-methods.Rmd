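---
title: "Methods: joint analysis of CLIP peaks and alternative splicing"
author: "clipsplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint analysis of CLIP peaks and alternative splicing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clipsplice)
```

## Scope and model

`clipsplice` sits downstream of read alignment, peak calling and the
differential models: its inputs are CLIP peak intervals (BED), splicing
event tables in the rMATS tab-separated dialect, differential-expression
tables (gene, log2 fold change, adjusted p), a genome FASTA and a GTF
annotation. It does not reimplement the DESeq2 or rMATS statistics — their
output tables are taken as authoritative. In particular the table's ΔPSI
column is never replaced by a recomputation from the replicate inclusion
levels; the reader only warns when the two disagree by more than 0.05,
because silently "fixing" an upstream tool's column would change its
semantics.

All internal coordinates are 0-based half-open genomic intervals. GTF
(1-based closed) converts at the boundary, BED passes through unchanged.
A single convention throughout removes the usual off-by-one drift between
interval operations, and makes boundary rules statable bit-exactly (see
the high-confidence window below).

## Filtering rules

Differential expression: retained iff `padj < 0.05` (strict) and
`|2^log2fc| >= 2`. Differential splicing: retained iff `fdr <= 0.05`,
`|ΔPSI| >= 0.05` (both inclusive) and at least 10 inclusion+skipping
junction reads in either condition. The strict/inclusive mix follows the
thresholds as printed where each rule is defined. The read rule sums
replicate counts within a condition by default — the weakest defensible
reading of "detected in at least 10 reads in either condition" — and a
`per_replicate` flag switches to the stricter per-replicate reading,
since the intended granularity is not stated.

Cross-comparison event identity uses the tuple (event type, contig,
strand, full coordinates) rather than the table's numeric IDs, which are
not stable across runs.

## Peak-to-region assignment

Peaks are assigned one label among 5'UTR/CDS/intron/3'UTR. The label
comes from the same-strand protein-coding transcript region with the
maximal per-base overlap (summed over a region's intervals within one
transcript); ties break by CDS > 5'UTR > 3'UTR > intron, then by the
transcript with the longest CDS. No published rule exists for this step;
max-overlap with exon-favoring priority is the choice that reproduces the
qualitative exon/intron binding dichotomy such analyses report, and it is
deterministic. Antisense peaks (no same-strand coding transcript) are
excluded from composition counts, matching analyses restricted to
protein-coding genes. Composition percentages are taken over all assigned
peaks, so assignment rows carrying labels outside the four standard
regions still count in the denominator.

Non-coding transcripts are excluded from region derivation entirely: a
transcript without a CDS has no UTR/CDS decomposition, and including it
would only add unlabeled exonic sequence.

## Metaprofiles

Coverage is binary per site — the inputs are peak intervals, not read
pileups, so depth weighting would manufacture precision the data do not
carry. At a 5' splice site, offset 0 is the first intronic base and
negative offsets are exonic; at a 3' splice site, offset 0 is the first
base of the downstream exon and negative offsets are intronic (both in
transcript orientation, mirrored on the minus strand). The value at an
offset is the fraction of sites with at least one same-strand peak
covering that base; offsets that run beyond the flanking feature still
count in the denominator so values are comparable across offsets. The
default half-window of 300 nt and the 100-bins-per-region transcript
profile are declared defaults of this package, chosen to cover the
near-splice-site range where SR-protein binding concentrates.

## Motif enrichment

Peak sequences are extracted in transcript orientation (minus-strand
peaks reverse-complemented). Words are hexamers by default, matching the
length of the motifs such analyses report; `k` is configurable. Windows
containing N are dropped from numerator and denominator. The background
is a dinucleotide-preserving shuffle of the same peak set
(Altschul–Erikson: a uniformly sampled last-edge tree over the
dinucleotide transition multigraph, remaining out-edges permuted, then an
Eulerian walk), the conservative standard for RBP motif work because it
preserves CpG-like composition that mononucleotide shuffles destroy.
Per-kmer significance is a two-sample unequal-variance (Welch) t-test on
per-sequence frequencies — group variances are not asserted equal
anywhere — with degenerate all-equal frequencies reported as p = 1.
Raw p-values are reported without multiple-testing correction by default,
as in the motif tables this reproduces; a correction can be applied to
the returned table with `p.adjust`.

## Cassette-exon features

For skipped-exon events, upstream/downstream are transcript-orientation
directions. Features: exon GC (%), full-length flanking-intron GC (%),
downstream-intron:exon GC ratio, and upstream/downstream intron:exon
length ratios. Intron GC uses the full intron length (a capped window is
not used; whether the original feature battery capped it is unstated).
Events at a transcript's first/last exon (no flanking intron) are skipped
with a message; exons with 0% GC are skipped rather than dividing by
zero. Non-SE event types are excluded from feature analysis: the features
are defined by the cassette-exon geometry.

Group comparisons use the Mann–Whitney U test: exact enumeration for
combined n ≤ 20 without ties, tie-corrected normal approximation
otherwise (via `stats::wilcox.test`; an independent enumeration oracle
checks the exact path in the test suite).

## Integration

A peak is condition-unique iff no same-strand peak of the other condition
overlaps it by ≥ 1 nt — the weakest defensible reading of "uniquely
detected"; uniqueness is decided per peak, not per transcript. The
high-confidence rule calls a (peak, event) hit iff the peak overlaps
`[exon_start − flank, exon_end + flank)` (half-open, flank = 250 nt
default) with each flank truncated at the far end of the flanking intron,
so flanks are intronic by construction and never reach the neighboring
exon. Bit-exactly: a peak must cover at least one base at intronic offset
≤ 249 from the exon boundary; a peak beginning exactly 250 bases into the
intron misses. The three-way cross-reference collapses to gene level
(expression is gene-level, splicing and peaks transcript-level); a
transcript counts as expression-changed if its gene does.

PSI from isoform abundances is `100 × larger / total`; the isoform ratio
is `larger/smaller` after each is divided by its loading-control value (a
shared control cancels).

## The synthetic generator

The generator emulates the statistical structure the analysis assumes,
with one master seed and sub-generators drawing from documented offsets
(genome = seed, peaks = seed+1, splicing = seed+2, expression = seed+3).
Every gene has five exons; exon 3 is the cassette exon and carries a
planted class:

| parameter | default | what it emulates |
|---|---|---|
| exonic peak fraction | 0.569 / 0.832 per condition | the intron→exon binding shift between conditions |
| planted hexamers | CACACA / GAAGAA | CA-rich vs GA-rich condition-specific motifs |
| hexamer insertion probability | 0.3 per peak | partial motif penetrance |
| cassette GC targets | 53.4 / 50.0 / 51.2 % (included/skipped/other), sd 4 | the included-vs-skipped GC shift |
| intron:exon length-ratio medians | 12.4–10.6 / 19.5–20.0 / 14.2–13.3 | shorter introns around included exons |
| planted DE directions | 273 up / 241 down / 486 null | a balanced expression response |

Planted quantities (region mixtures, significant-event counts, direction
counts) are allocated by exact count; randomness enters only through
placement and noise, so truth-recovery tests are exact wherever possible.
Non-significant events each fail exactly one filter (high FDR, small
|ΔPSI|, or sub-threshold reads, cycling), so a single filtering bug
cannot hide behind another predicate. Background composition outside
planted motifs is i.i.d. at the configured GC — the simplest null for
motif testing.

What the generator does **not** emulate: splice-site consensus sequences
(GT/AG dinucleotides are not written), realistic transcript/exon length
distributions, overlapping genes, isoform diversity within a gene, read-
level noise, or peak-caller artifacts. Passing tests therefore
demonstrate correctness of the interval arithmetic, statistics and
bookkeeping under the planted model — not robustness to the full
messiness of real libraries.

## Numerical choices and problem sizes

- Motif t-statistics are computed in closed form across all observed
  k-mers at once and cross-checked against `stats::t.test` per k-mer in
  the tests; ranking is ascending p, then descending foreground mean,
  then lexicographic k-mer for a deterministic total order.
- The dinucleotide shuffle resamples its last-edge tree until connected —
  for hexamer-scale alphabets this accepts within a few tries.
- Reports serialize with fixed key order and full precision
  (`digits = NA`), which is what makes the end-to-end byte-identity
  determinism contract testable.
- Test-suite problem sizes were chosen as the smallest that exercise each
  property convincingly: oracle-equivalence runs 1000+ random instances
  of ~10–60 nt intervals; the motif benchmark uses 20 replicates of 500
  peaks at insertion probability 0.3; the feature-shift benchmark uses
  100 detection replicates (n = 300/group, medians 53 vs 50, sd 4) and
  1000 null replicates for type-I calibration, run through the
  generator's sequence-level exon simulator rather than whole genomes so
  the replicate counts stay cheap.

## Known limitations

- One transcript anchors each peak label; gene-level ambiguity between
  isoforms is resolved by the longest-CDS rule rather than by
  expression-weighted assignment.
- The splicing-table dialect carries skipped-exon-style coordinate
  columns for all five event types; RI/MXE/A5SS/A3SS rows are filtered
  and counted but only SE rows enter feature and overlap analyses.
- Metaprofiles and compositions treat each peak set as one replicate;
  replicate-level reproducibility analysis (e.g. IDR) is out of scope.
- `region_composition` percentages use the assigned-peak total as the
  denominator; unassigned (antisense) peaks are excluded upstream.
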