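# pansv

Assembly-based structural variant discovery and pan-genome analysis for
inbred crop accessions, with a synthetic-data module that makes the whole
pipeline testable against known truth.

## Who this is for

Plant and crop genomicists who have (or want to prototype against)
chromosome-scale assemblies of multiple accessions of one species and need
the computational chain that turns them into a pan-genome analysis:

1. **Alignment & discovery** — anchor-based whole-genome alignment of each
   query assembly to the reference (maximal exact matches seeded by
   reference-unique 20-mers), one-to-one filtering (identity ≥ 90%,
   length ≥ 200 bp, maximum-weight non-overlapping selection), chaining
   into collinear blocks (≤ 50 kb internal gaps), and word-anchor in-block
   diffing. Variants are classified by the 50 bp boundary: SNPs, small
   InDels (< 50 bp), **canonical** large InDels (exact breakpoints, one
   allele empty), **complex** InDels (a replacement of one sequence by
   another of different length), inversions (< 1 Mb and megabase-scale)
   and translocations. Complex breakpoints are re-aligned in 1 kb flank
   context and promoted to canonical when they resolve; deletion-junction
   microhomology is reported.
2. **Read-depth validation** — a deletion is *RD supported* when its 1 kb
   flanks average more than 3× the deleted region's depth and the region
   averages < 3; insertions are evaluated by swapping the reference
   (insertion → deletion on the carrier genome; the swap is an involution).
3. **Graph genotyping** — insertions, deletions and inversions are embedded
   in a variation graph that preserves the linear reference path
   byte-for-byte (GFA 1.0 I/O); SV sites are genotyped from short reads by
   allele-path re-alignment with junction-spanning support counts
   (mapq/baseq < 5 excluded).
4. **Selection statistics** — windowed nucleotide diversity π per group,
   wild/cultivated ratio sweeps (top 5% windows), domestication-associated
   SVs (> 50% overlap with sweeps), highly divergent SVs (Fisher exact,
   FDR < 0.01), π-ratio ≥ 3 annotation, and SV-linked expression screening
   (|log2FC| ≥ 1.5 in any tissue).
5. **Pan-genome of genes** — single-linkage clustering at ≥ 95% identity /
   ≥ 50% coverage, core/dispensable classification, representative
   selection, pan/core accumulation curves, Fisher set enrichment
   (FDR < 0.05).

Every stage is driven end-to-end on simulated genomes: `simulate_reference()`,
`implant_variants()` (with recorded truth in both coordinate systems),
`simulate_reads()`, `simulate_population()` and `simulate_gene_families()`.

## Worked example

Simulate a two-chromosome 400 kb reference, implant 40 variants of all
classes, call them back, and evaluate against truth:

```r
library(pansv)

ref  <- simulate_reference(2, 200000, gc = 0.4, seed = 42)
spec <- variant_spec(n_snp = 20, n_small_ins = 5, n_small_del = 5,
                     n_can_ins = 5, n_can_del = 5,
                     n_com_ins = 3, n_com_del = 3,
                     n_inv = 1, n_trans = 1, inv_range = c(5000, 20000))
imp  <- implant_variants(ref, spec, seed = 7, accession_id = "acc1")

res   <- call_variants(ref, imp$genome)
truth <- left_align_variants(imp$truth, ref)
evaluate_calls(res$variants, truth)
#>          group n_truth n_called recall precision
#>    small_indel      10       10      1         1
#>        complex       6        6      1         1
#>            snp      20       20      1         1
#>      canonical      10       10      1         1
#>  translocation       1        1      1         1
#>      inversion       1        1      1         1
```

Every implanted variant is recovered; SNPs, small InDels and canonical SVs
are matched at exact breakpoints after left-alignment, so a recall of 1 for
the canonical group also means every breakpoint is base-exact. Calls carry
identifiers in the `SV_{TYPE}_{chrom}G{index}` scheme:

```r
head(res$variants[, c("id", "variant_class", "ref_chrom", "ref_start", "ref_end")], 3)
#>                  id variant_class ref_chrom ref_start ref_end
#>   VAR_SDEL_1G000010     SMALL_DEL      chr1      5325    5369
#>   VAR_SDEL_1G000020     SMALL_DEL      chr1     10921   10944
#>  SV_COMDEL_1G000010       COM_DEL      chr1     15064   15587
```

and a canonical deletion can be queried for junction microhomology:

```r
del <- res$variants[res$variants$variant_class == "CAN_DEL", ][1, ]
detect_microhomology(del, ref$chromosomes[[del$ref_chrom]])
#>       variant_id homology_seq homology_len  side
#>  SV_DEL_1G000010            T            1 right
```

(a 1 bp shared base — random sequence; an engineered 5 bp `CCACC` junction
yields `homology_len = 5`). Downstream, `build_graph()` +
`genotype_population()` genotype the SV sites across a simulated panel,
`nucleotide_diversity()` + `sweep_regions()` + `call_dsv()` + `call_hdsv()`
run the selection scan, and `cluster_genes()` + `pan_core_curve()` the
gene-based pan-genome. `run_pipeline(pansv_config(seed = 1))` chains all
stages and writes VCF/BED/GFA/TSV outputs.

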