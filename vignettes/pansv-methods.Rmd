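---
title: "pansv: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pansv: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pansv)
```

# Overview

`pansv` implements the computational core of an assembly-based crop
pan-genome study: whole-genome alignment of chromosome-scale assemblies to a
reference, extraction and classification of variants from collinear blocks,
short-read validation of large InDels, genotyping of structural variants
(SVs) on a variation graph across a population, selection statistics
contrasting wild and cultivated groups, and gene-based pan-genome analysis.
Because the real datasets behind such studies are tens of gigabases of
sequencing data, every stage here is exercised on synthetic genomes with
recorded truth: the simulator is a first-class module, and the test suite
measures recall, precision, concordance and parameter recovery against that
truth.

# The alignment and variant model

## Anchors, segments, blocks

Alignment is anchor-based. Anchors are maximal exact matches seeded by
k-mers (default k = 20) that occur exactly once in the reference; seeding on
reference-unique k-mers keeps the subsequent one-to-one resolution tractable
while maximal extension recovers the full matched run. Both strands are
scanned; minus-strand anchors carry forward-strand query coordinates plus a
strand flag.

Co-linear anchors separated by at most `max_anchor_gap` (default 500 bp) on
both genomes are merged into scored alignment segments; inter-anchor gaps
are aligned globally (Biostrings) and identity is matched columns over
aligned columns. The small default gap deliberately breaks segments at
SV-scale differences, so that rearranged pieces (inverted or translocated
segments) survive the one-to-one filter as independent segments — the same
role the alignment break length plays in the standard genome-alignment
tools this stage mirrors.

One-to-one filtering keeps segments with identity ≥ 90% and length ≥ 200 bp
and then selects the maximum-weight set (weight = identity × length)
mutually non-overlapping on both the reference and the query axis. The
conflict graph is solved exactly per connected component (branch and bound;
components are small in practice, with a greedy fallback above 20 vertices).
Two engineering details matter here:

* *Overlap tolerance.* Maximal exact matches extend by chance a few bases
  across a true breakpoint (the same phenomenon that produces junction
  microhomology). Overlaps of ≤ 50 bp are therefore not conflicts; after
  selection, residual overlaps are trimmed from the lighter segment so that
  every genome position is covered by at most one segment.
* *Non-overlap, not order.* One-to-one consistency is defined as
  non-overlap on each axis rather than monotone order, because inversions
  and translocations must survive filtering to be detectable at all.

Collinear blocks chain same-strand, order-consistent segments whose
reference and query gaps are both ≤ 50 kb. A gap is not chained across when
another retained segment occupies it on either genome — that segment is an
inverted or translocated piece, and chaining across it would smear the
rearrangement into thousands of spurious substitutions. Chaining is
idempotent.

## Rearrangements

Per reference chromosome, the dominant query partner and strand are
determined; dominance is by block count with a span tie-break, because a
single inversion may cover most of a chromosome and still be the flanked
minority. Minus-strand blocks in plus context are inversions (those at or
above 1 Mb are reported as a separate megabase-scale class); blocks without
same-strand flanks on both sides are flagged low-confidence rather than
dropped, mirroring the manual checking such calls receive in practice.
Blocks mapping to a non-dominant chromosome are inter-chromosomal
translocations; blocks breaking the maximum-span monotone query order are
intra-chromosomal ones. Translocations whose span contains N are excluded.

## In-block differences and variant classes

Within a block, differences are extracted by word-anchor decomposition:
maximal matches seeded at `wordsize` (default 10) are chained
left-to-right, shared prefixes/suffixes of each unmatched pair are trimmed,
and the remaining pairs are emitted. Word hits are only used where their
maximal extension reaches 2 × wordsize; chance 10-mer hits inside a
genuinely divergent replacement would otherwise fragment it. For large
inputs the seed length rises to 20 (10-mers stop being unique at megabase
scale) while the extension threshold is unchanged. Concatenating anchors
and difference pairs reconstructs both block sequences exactly — a tested
invariant.

Classification uses the 50 bp size boundary, with 50 bp itself in the SV
class (the size definitions of the SV classes all read "at least 50 bp";
where small-InDel phrasing is ambiguous at exactly 50, the SV reading is
used consistently and logged as a constant, `sv_size_min` in the pipeline
configuration). Pure InDels have exact breakpoints by construction and are
canonical; replacements with both alleles non-empty and unequal are complex
at ≥ 50 bp and classified as small InDels by net length change below it.
Equal-length mismatch runs longer than 1 bp are decomposed into single-base
SNPs by the diff layer, which is why `classify_variant()` rejects them —
the enum has no multi-nucleotide substitution class, and decomposition is
the behaviour an SNP-caller downstream expects.

Complex calls are re-examined in 1 kb reference flank context: if the
global alignment of the two alleles with flanks is exact matches plus a
single contiguous gap, the call is promoted to canonical with refined
coordinates; allele content is conserved and promotions never drop calls.
All pure InDels are left-aligned (repeat-context normalisation), which
makes breakpoint comparisons exact between calls and truth.

A deletion's breakpoint microhomology is the longest exact sequence shared
by its two junctions, evaluated on both sides and capped at
`min(deletion span, 25 bp)`; the measure is reported but never used as a
filter. Gene-context annotation labels CDS, promoter (default window
3000 bp upstream of the TSS — promoter SVs are reported in the literature
without a stated window; 3 kb covers the upstream distances quoted for the
worked examples and is configurable), intron and intergenic variants, and
calls a CDS InDel in-frame only when its length is divisible by 3 *and* it
starts on a codon boundary; everything else is a frameshift.

# Read-depth support

Read depth counts placements with mapping quality ≥ 20 after collapsing
duplicate pairs. A deletion is RD-supported when the mean depth of its 1 kb
flanks is more than three times the mean depth of the deleted region and
the region mean is below 3; means are arithmetic with zeros included, and
truncated flanks at chromosome ends are used at their truncated length.
When the region mean is exactly 0 the fold ratio is taken as +Inf and the
"more than threefold" test passes — the limiting case of the rule.
Insertions are evaluated by swapping the reference: the insertion becomes a
deletion spanning the inserted sequence on the carrier genome, and the same
rule applies with reads mapped to that genome. The swap is an involution.

At desk scale, read "mapping" uses the simulator's truth placements lifted
through the truth variant table. The liftover clips reads at variant
junctions (as an aligner would soft-clip them), drops reads starting in
sequence with no image in the target genome, maps inversion interiors to
the same interval, and maps reads inside a translocated segment to the
partner chromosome, keeping concordantly mapped pairs. The support rule
itself is mapping-method-agnostic.

# Variation graph and genotyping

The graph embeds insertions, deletions, complex replacements and
inversions into the linear reference: reference chromosomes are split at
every SV boundary, deletions add a bypass edge, insertions and replacements
an alternative node, and inversions reuse the reference segment through
reversed-orientation edges. Translocations are not part of the graph. The
reference path is preserved byte-for-byte — a tested invariant — and the
graph round-trips through GFA 1.0.

Genotyping is allele-path re-alignment rather than universal graph
alignment: for each site the two allele spellings (reference flank +
allele + flank) are indexed by k-mers; a read is assigned to an allele when
it matches that spelling near-exactly (≤ 2 mismatches) *and* spans an
allele junction with at least 15 bp on each side — reads that fit entirely
in shared flank are uninformative by construction. Reads with mapping or
base quality below 5 are excluded. Genotypes follow the support ratio: alt
fraction ≥ 0.8 is alt/alt, ≤ 0.2 ref/ref, otherwise ref/alt (selfed inbred
panels are haploid-style, so heterozygous calls flag conflicts); fewer
than 3 informative reads gives `missing`. The 0.8/0.2 thresholds and the
minimum support are package decisions — no published values exist for
them — and are configurable.

# Selection statistics

Per-site diversity is the unbiased heterozygosity 2·p·q·n/(n−1) from
haplotype counts; window π is the site sum divided by the window length
(default 10 kb tiling windows — the windowing of the original scan is not
published, and 10 kb resolves the desk-scale simulations). Sweeps are the
top 5% of windows by π_wild/π_cultivated, optionally intersected with the
top 5% of an externally computed second statistic (e.g. XP-CLR, which this
package deliberately does not re-implement); without it the scan is
labelled ratio-only. Ratio-undefined windows (π_c = 0 with π_w > 0) sort
as +Inf — a diversity wipe-out in cultivated lines is the strongest sweep
signal, not a missing value.

Domestication-associated SVs (dSVs) overlap a sweep over strictly more
than 50% of their reference extent; zero-extent insertions count by their
anchor point. Highly divergent SVs (hdSVs) come from two-sided Fisher
exact tests on per-site carrier × group tables (missing genotypes leave
the margins), BH-adjusted, at FDR < 0.01. `fisher_exact()` and `bh_fdr()`
delegate to `stats::fisher.test()` and `stats::p.adjust()`; the test suite
verifies both against an exhaustive hypergeometric enumeration oracle and
the hand-computed step-down formula. Expression screening computes
per-tissue log2((cultivated + 1)/(wild + 1)) for CDS- and promoter-context
SV–gene links and flags |log2FC| ≥ 1.5 in any tissue; the 1 TPM pseudocount
stabilises fold-changes at low expression.

# Pan-genome of genes

Genes are clustered across accessions by single-linkage over pairwise
local alignments at ≥ 95% identity and ≥ 50% coverage of the shorter
sequence (coverage measured as aligned non-gap columns). Single linkage is
an explicit choice: the clustering tool used at full scale does not
document its internal linkage, and single linkage makes the partition
order-invariant and testable. A k-mer containment prefilter skips clearly
unrelated pairs. Representatives prefer a reference-accession gene, then
the longest CDS, with lexicographic id as the tie-break. Pan/core
accumulation curves are simulated over random accession orderings
(default 100), and enrichment is a one-sided (over-representation) Fisher
test per term with BH adjustment at FDR < 0.05.

# The synthetic-data module

The simulator emulates what the pipeline needs and nothing more: a
multi-chromosome i.i.d. random reference with a target GC content;
implanted SNPs, small InDels, canonical (pure) and complex (replacement)
large InDels, inversions and cut-and-paste translocations, placed by
rejection sampling with ≥ 500 bp spacing (so in-block diffing is
unambiguous), away from N runs and chromosome ends; paired-end reads with
uniform fragment placement, Gaussian insert sizes and substitution-only
errors; two-group panels with per-site group allele frequencies and
per-accession personalized genomes; and per-group per-tissue TPM tables
with implanted log2 fold-changes. The derived genome *is* the reference
with the truth applied — reconstruction is the defining contract — and all
generators are deterministic under a seed.

What the simulator does not emulate bounds what the green test suite can
show about real data: there are no repeat landscapes or segmental
duplications (anchor uniqueness is much harder in real genomes), no indel
sequencing errors, no alignment-scale assembly errors beyond the
positional self-call model, and no transcript-level read simulation behind
the expression tables. Recall and precision measured here are therefore
upper bounds specific to repeat-free sequence; the algorithmic contracts
(classification boundaries, filters, statistics, graph construction,
genotype thresholds) are what the tests pin down exactly.

# Problem sizes and numerical choices

The shipped tests and the acceptance script run, per invocation, one
5 Mb / 200-variant caller evaluation, one 20-accession × 50-site
genotyping panel at 20× on a 500 kb reference, a 30× read-depth
evaluation, a 1 Mb / 50-sample sweep recovery, exhaustive Fisher
enumeration to n = 10 plus seeded random tables with margins ≤ 30, and a
12-accession × 18-family pan-gene analysis — sizes chosen so the whole
suite completes in minutes on one CPU while every stage still runs at a
scale where its failure modes (chance k-mer collisions, junction
overhangs, boundary ties) actually occur.

Tie-breaks and degenerate inputs are all deterministic: leftmost
coordinate for equal-weight chains and equal-rank sweep windows,
lexicographic id for equal-length representatives, left-alignment for
InDel positions, and explicit errors for empty inputs, zero-length
regions, out-of-bounds coordinates and foreground sets that are not
subsets of their background.

# Known limitations

* Translocation breakpoints are reported at anchor resolution (within a
  few bases), not base-pair refined; inversion boundaries inherit the same
  junction ambiguity when flanking bases match by chance, and the
  evaluation treats both with a small positional tolerance.
* The genotyper's allele-path re-alignment assumes SV sites are far enough
  apart that a read spans at most a few sites; densely overlapping SVs
  share reads across sites but are not jointly phased.
* Split-read/read-pair evidence, XP-CLR, GWAS and K_a/K_s are out of
  scope by design; sweep scans without the second statistic are labelled
  ratio-only.
* The self-call assembly-error mask expects positional evidence produced
  elsewhere (or simulated); the package does not realign reads to call it.
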