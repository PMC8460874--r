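---
title: "Detecting Alu exonization from RNA-seq: models and methods"
author: "aluex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting Alu exonization from RNA-seq: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aluex)
```

## The problem

*Alu* elements are ~300 bp primate SINE retrotransposons with on the order
of a million genomic copies, mostly intronic. An intronic *Alu* can be
recruited into mature mRNA when mutations activate cryptic splice sites —
*exonization* — typically when the element lies antisense to its host gene.
Two situations demand different detection strategies:

* **Fixed elements** (present in the reference genome): the exonized
  sequence maps normally, so exonization shows up in assembled transcript
  models as an extra internal exon overlapping an annotated repeat.
* **Non-reference elements** (polymorphic or rare insertions absent from
  the reference): the *Alu*-bearing reads cannot be placed. Evidence
  survives only in non-concordant read pairs whose mapped mate anchors the
  locus while the unmapped mate carries *Alu* sequence.

`aluex` implements both arms, plus the characterization layer
(cassette-exon detection, percent-spliced-in, tissue specificity), an
excision-based calibration protocol, and a seedable synthetic-data
generator so the entire pipeline is testable with no external downloads.

## Coordinates

All internal coordinates are 1-based and inclusive at both ends (the
GTF/SAM convention); an exon `start..end` has length `end - start + 1`.
BED input is converted at the I/O boundary. This convention is forced by
the arithmetic of exon lengths the rest of the package reports.

## Fixed-element arm

Per-sample assembled transcript models (GTF) are intersected with the
repeat annotation. A candidate call must satisfy three filters:

1. the exon is **internal** to its transcript (at least one exon on each
   side — terminal exons are dominated by 3'-end artifacts);
2. the repeat is **antisense** to the transcript strand, the orientation
   that dominates exonization biology (unstranded transcripts cannot be
   tested and are dropped, counted in a skip report);
3. the exon length L satisfies **40 < L < 400** (strict bounds, both
   configurable): shorter calls are below the plausible exon size for this
   element family, longer ones are usually intron-retention fragments.

The reading-frame class is `L mod 3`. Calls merge across samples by exact
exon coordinates; distinct exon variants over one element remain separate
rows sharing a locus id, because one element is frequently exonized with
several alternative boundaries. An exon is *known* only on exact
coordinate identity with an annotated exon — looser matching rules are not
reproducible and would inflate the known class.

Because transcript assembly can miss a lowly expressed exon in individual
samples, support can be **rescued** from junction evidence: a sample is
added to an exon's support set iff *both* flanking introns have at least
`min_reads` (default 1) spliced-read support there. Requiring both
junctions keeps single-sided mapping noise out.

## Cassette events and PSI

Only *simple* skipping events are considered: an inclusion isoform
(..., A, E, B, ...) and a skipping isoform (..., A, B, ...) with
*identical* flanking exons A and B. This isolates the effect of the exon
from changes in its context. For an event with inclusion junction counts
L, R and skipping junction count S (exact-boundary spliced-alignment
counts; near-miss junctions are not merged),

$$PSI = \frac{L + R}{L + R + 2S}.$$

The factor 2 balances one skipping junction against two inclusion
junctions. Samples with `L + R + S < 10` reads cannot give a stable
estimate and are undefined. The cohort summary is the median per-sample
PSI (mean by option), categorized as **minor** (PSI < 0.35), **equal**
(0.35 <= PSI < 0.65) or **major** (PSI >= 0.65). The published category
boundaries leave [0.35, 0.36) unassigned; we close the gap at 0.35 so
that both stated inequalities are preserved and the classes partition
[0, 1].

## Tissue specificity

The input is an intron-by-sample count matrix with a sample-to-tissue
map. An intron is *present* in a tissue when at least 15% of that
tissue's samples have >= 10 reads (both thresholds configurable, the
percentage compared inclusively). The *absence* test builds, per tissue
with N_t samples, the expected number absent E_t = 0.85 N_t (kept
fractional, not rounded) and the observed number absent O_t (samples with
< 10 reads), drops tissues with O_t < E_t (absent only at the margin of
error), and refers

$$X^2 = \sum_t \frac{(O_t - E_t)^2}{E_t}$$

to a chi-square with k - 1 degrees of freedom over the k retained
columns. With fewer than two retained columns the test is degenerate and
returns p = 1. A 2-by-k independence reading of the same table is
available behind a flag, but the explicit expected row makes
goodness-of-fit the natural default. An intron is tissue-specific when it
is present in exactly one tissue and the absence test gives p <= 0.001
(inclusive comparison).

A power note: the per-column statistic of a fully absent tissue is
(0.15 N_t)^2 / (0.85 N_t) ~ 0.0265 N_t, while each retained column also
adds a degree of freedom. Significance at 0.001 therefore requires
cohort-scale tissues — hundreds of samples each, as in the consortium
data this procedure is designed for. The package's property tests use
300 samples per tissue for this reason; toy matrices with ~20 samples per
tissue can never reject, and no multiple-testing correction is applied by
default (a Bonferroni option exists).

## Non-reference arm

**Classifier.** Reads are classified as *Alu*/non-*Alu* with a canonical
k-mer index (k = 31, the standard exact-matching k) over a library of the
consensus plus the annotated genomic instances. A read is an *Alu* read
when >= 10% of its k-mers hit. The low threshold is deliberate: the most
informative mates are chimeric exon–*Alu* reads that may carry only a few
dozen *Alu* bases.

**Candidates.** A candidate pair has exactly one mapped mate (the
*anchor*), is non-concordant, and its unmapped mate classifies as *Alu*.
Anchors must overlap an annotated exon; an anchor overlapping several
exons is evaluated in every exon context but counted once per gene.

**Signal test.** The mate is aligned against concatenations of the anchor
exon, the consensus (both orientations), and the neighbouring annotated
exon (both flank arrangements), with a spliced local aligner: match +1,
mismatch -1, gap open -2, gap extension -0.5, and *free* target gaps that
start at a segment end or land at a segment start. The free moves act
like introns: a read can jump from the end of an exon into the middle of
the consensus, because the insertion point within the element is unknown.
Identity counts matches over aligned columns with ordinary gaps included
and splice moves excluded; query coverage is the aligned query span over
the read length. A match is a **signal** when coverage >= 80%, identity
> 80% (strict), and >= 10 *Alu* bases are covered.

**Shadow test.** The same mate is searched against 500 bp intronic
windows on both sides of the anchor exon (unprocessed pre-mRNA) and
against the genomic region from the anchor exon to the farther of its two
neighbouring exons (a local genomic copy). Any local alignment with
coverage >= 80% and identity >= 93% (both inclusive) marks the read a
**shadow** — sequence the locus itself can explain. Both windows are
searched because the stated procedure does not fix a side; the window
is truncated at contig edges.

**Categories and clustering.** Each mate lands in exactly one of
S (signal, not shadow), RU (shadow, not signal), SRU (both), none
(neither); the hybrid pool SN counts S together with none. The published
prose defines RU as shadows "regardless of the signal test" yet also
defines SRU; the partition above is the only reading in which both
classes exist, so s <= sn always holds. Anchors cluster by single-linkage
genomic overlap, separately per (orientation, category).

**Context filter.** With s, sn, ru, sru the vicinity's category counts, a
putative insertion requires all of: `s >= MIN_SIGNALS`,
`sn >= MIN_SIGNALNONE`, `s/sn >= MIN_S2SN`, `s/sru >= MIN_S2SRU`,
`s/ru >= MIN_S2RU`. Ratios with a zero denominator are +Inf and satisfy
their condition — the absence of shadows is the strongest possible
evidence. Defaults are the calibration optimum (2, 5, 0, 2, 0.5).

**Insertion interval.** Per S cluster, the interval runs from the cluster
boundary, in the direction the anchors point, to the nearest cluster of
opposing orientation, or to the gene end when none exists. Base-pair
precise breakpoints are out of reach by construction — repeat-derived
reads cannot pin them. A call is flagged repeat-rich when more than 50%
of its interval is covered by annotated repeats (configurable; the
published analyses separate repeat-rich context without stating a rule).

**Assembly and prioritization.** The reads of the bounding clusters are
assembled with a deliberately simple stranded de Bruijn assembler
(k = 23; maximal unambiguous paths; one round of tip trimming at <= 2k;
no bubble popping, so haplotypes emerge as separate contigs). An external
assembler can be substituted upstream of the contig table. Contigs are
aligned to the gene region on both strands; those *without* a
high-quality match (>= 90% identity at >= 80% contig coverage, both
inclusive) are the prioritized candidates — sequence the reference cannot
explain.

## Calibration protocol

The simulation reference is built by excising expressed elements from a
genome and shifting all downstream annotation coordinates left by the
cumulative deleted length (exon sequence content is preserved exactly;
elements overlapping annotated exons are excluded from excision). The
genes that hosted excised elements form the gold standard, counted as
genes, not loci. Performance is Sn = TP/|gold|, Pr = TP/(TP+FP),
F = 2·Sn·Pr/(Sn+Pr) (0 when Sn+Pr = 0), Acc = (Sn+Pr)/2. The context
filter is a pure arithmetic gate, so the vicinity count table is computed
once and the 4,200-tuple grid — MIN_SIGNALS in {1, 2}, MIN_SIGNALNONE in
1..10, MIN_S2SN in 0..0.5 by 0.1, MIN_S2SRU in 0..2 by 0.5, MIN_S2RU in
{0, 0.05, 0.1, 0.15, 0.2, 0.25, 0.5} — is re-scored without re-alignment,
ranked by F with precision then sensitivity as tie-breaks.

## The synthetic-data generator

`generate_locus_set()` builds one gene per toy chromosome (+ strand,
1 kb intergenic padding), with 4–6 exons of 120–250 bp and introns of
550–900 bp — large enough to host an embedded element with flanks. Event
roles are assigned deterministically: 5 genes carry a planted
non-reference insert, 5 a fixed exonization (an antisense intronic copy
plus an isoform exonizing a 120–180 bp window of it), 3 a decoy intronic
copy with no event, and the remaining 7 are clean. Genomic copies are
mutated from the bundled consensus at 8% per-base divergence (old, fixed
elements); planted inserts at 2% (polymorphic insertions are young,
consensus-near copies). The bundled consensus is itself synthetic — a
fixed ~300 bp AluY-like sequence with an A-rich linker and poly-A tail —
which is sufficient because every component is exercised against the same
library.

`simulate_reads()` emits 2x100 bp pairs (fragment 250 +/- 25 bp, fold
coverage 8, error rate 0.002) directly as alignment records: the
generator knows every read's origin, so no external aligner is needed.
Reads carrying >= 20 bases of novel-insert sequence, and pre-mRNA reads
overlapping an intronic copy by >= 20 bases, are emitted unmapped with
their pair non-concordant — emulating how a mapper discards unplaceable
or heavily multi-mapping repeat reads (shorter repeat overlaps are
soft-clipped or mapped through, as a real aligner would). Mature reads
over a fixed exonized exon stay mapped: their unique flanking context is
what lets assembly-based detection work. 15% of fragments come from
unspliced pre-mRNA. Each planted insertion receives at least 5 guaranteed
junction-spanning pairs (mapped anchor in the adjacent exon, unmapped
mate across the exon/insert junction). A mis-set-concordance-flag
probability models mapping noise and defaults to 0.

What the generator does **not** emulate: base-quality models, RNA
editing, expression heterogeneity beyond uniform coverage, soft-clip
breakpoint signatures, multi-gene loci, and minus-strand genes (the
callers are strand-symmetric through the reverse-complement search, but
the toy genes are all plus-strand). Passing the end-to-end tests
therefore demonstrates algorithmic correctness under controlled
conditions, not performance on real tissue data.

## Numerical choices

* Alignment DP is computed row-vectorized with a scalar traceback;
  score-tie resolution prefers diagonal moves over gaps over splice
  jumps, and comparisons use an epsilon of 1e-6 on half-integer scores.
* A paid target gap cannot immediately follow a free splice jump (the
  jump subsumes it in every case that matters biologically: junction
  reads enter a segment either at its boundary or via the free move).
* The tie order for ranking calibration tuples is F, then precision,
  then sensitivity — precision is the scarcer commodity in this problem.
* `evaluate_predictions()` defines 0/0 as 0 for precision and F.
* Degenerate inputs: empty queries error; empty candidate sets flow
  through as zero-row tables; an exon at a contig edge truncates its
  shadow window rather than erroring.

## Problem sizes in the shipped tests

The test suite and the acceptance script run the full study at 20 genes,
5 planted insertions with 5 signal pairs each, 5 fixed exonizations and 3
decoys (the generator defaults), with 100 aligner-oracle instances at
query <= 60 bp against ~400 bp three-segment targets. These sizes give
non-trivial read depth (~2,500 records) while keeping a full run in
about a minute.

## Known limitations

* Known/novel classification is exact-coordinate; fuzzy exon matching is
  intentionally out of scope.
* The insertion caller reports intervals, not breakpoints, and one
  vicinity per gene; two independent insertions in one gene merge into
  one call unit, matching the gene-level gold standard of the
  calibration protocol.
* The internal assembler has no error correction; at realistic error
  rates it relies on the k-mer spectrum being dominated by correct
  23-mers, which holds at the depths used here.
* The shadow region test is one-sided (toward the farther neighbouring
  exon); a copy hiding on the nearer side beyond the 500 bp unspliced
  window can escape it. The context-filter ratios exist precisely to
  tolerate such imperfect shadow classification.
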