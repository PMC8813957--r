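# End-to-end pipeline driver over synthetic data.

#' Pipeline configuration with the study's threshold defaults
#'
#' Collects every tunable threshold of the pipeline with its default:
#' the 50 bp SV size boundary, 90% / 200 bp one-to-one alignment filters,
#' 50 kb block gap, 1 kb refinement and RD flanks, RD 3x / <3 depth rule,
#' mapq/baseq 5 genotyping exclusions, top-5% sweep windows, >50% dSV
#' overlap, FDR 0.01 (hdSV) and 0.05 (enrichment), |log2FC| 1.5, pi-ratio 3,
#' and 95% identity / 50% coverage gene clustering.
#'
#' @param seed Master seed for every stage.
#' @param n_chrom,chrom_length Synthetic reference shape.
#' @param spec Variant implantation spec ([variant_spec()]).
#' @param coverage Read coverage for support/genotyping stages.
#' @param n_wild,n_cultivated Panel group sizes.
#' @param ... Overrides for any stored threshold.
#' @return A `pansv_config` list.
#' @export
pansv_config <- function(seed = 1L, n_chrom = 2L, chrom_length = 300000L,
                         spec = variant_spec(n_snp = 40L, n_small_ins = 10L,
                                             n_small_del = 10L,
                                             n_can_ins = 10L, n_can_del = 10L,
                                             n_com_ins = 5L, n_com_del = 5L),
                         coverage = 20, n_wild = 6L, n_cultivated = 10L,
                         ...) {
  cfg <- list(
    seed = seed, n_chrom = n_chrom, chrom_length = chrom_length,
    spec = spec, coverage = coverage, n_wild = n_wild,
    n_cultivated = n_cultivated,
    sv_size_min = SV_SIZE_MIN,
    min_identity = 90, min_length = 200L, max_gap = 50000L,
    min_anchor_len = 20L, wordsize = 10L,
    flank = 1000L, rd_fold = 3, rd_max_region = 3,
    min_map_q = 5L, min_base_q = 5L, min_support = 3L,
    top_fraction = 0.05, overlap_fraction = 0.5,
    fdr_hdsv = 0.01, fdr_enrich = 0.05, lfc_threshold = 1.5,
    pi_ratio = 3, window = 10000L, step = 10000L,
    cluster_identity = 0.95, cluster_coverage = 0.50)
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "pansv_config")
}

#' Run the full pipeline on synthetic data
#'
#' Executes the stages in dependency order: simulate reference and a derived
#' accession, align and call variants, evaluate against truth, read-depth
#' support, variation-graph construction and population genotyping,
#' selection statistics, and pan-gene clustering with accumulation curve.
#' All randomness derives from `config$seed`; a rerun with the same seed
#' produces an identical summary. Outputs (VCF, BED, GFA, TSV tables and a
#' JSON-like summary) are written under `out_dir` when given.
#'
#' @param config A `pansv_config`.
#' @param out_dir Optional output directory.
#' @return List of per-stage results plus `summary` (named numeric vector).
#' @export
run_pipeline <- function(config = pansv_config(), out_dir = NULL) {
  cfg <- config
  ref <- simulate_reference(cfg$n_chrom, cfg$chrom_length, gc = 0.4,
                            seed = cfg$seed, accession_id = "ref")
  imp <- implant_variants(ref, cfg$spec, seed = cfg$seed + 1L,
                          accession_id = "acc1")
  calls <- call_variants(ref, imp$genome, wordsize = cfg$wordsize,
                         min_anchor_len = cfg$min_anchor_len,
                         min_identity = cfg$min_identity,
                         min_length = cfg$min_length, max_gap = cfg$max_gap)
  truth_norm <- left_align_variants(imp$truth, ref)
  ev <- evaluate_calls(calls$variants, truth_norm)

  # read-depth support of called deletions
  reads <- simulate_reads(imp$genome, cfg$coverage, seed = cfg$seed + 2L)
  lifted <- liftover_placements(reads, imp$truth, "to_reference")
  depth <- depth_profile(lifted, ref)
  dels <- calls$variants[calls$variants$variant_class %in%
                           c("CAN_DEL", "COM_DEL"), , drop = FALSE]
  rd <- do.call(rbind, lapply(seq_len(nrow(dels)), function(i)
    rd_support(dels[i, ], depth, cfg$flank)))

  # graph + panel genotyping over the canonical InDel sites
  sv_sites <- imp$truth[imp$truth$variant_class %in% LARGE_INDEL_CLASSES, ,
                        drop = FALSE]
  sv_sites$id <- variant_ids(sv_sites)
  graph <- build_graph(ref, sv_sites)
  panel <- simulate_population(ref, sv_sites, cfg$n_wild, cfg$n_cultivated,
                               p_wild = 0.8, p_cult = 0.2,
                               coverage = cfg$coverage,
                               seed = cfg$seed + 3L)
  gt <- genotype_population(graph, panel)

  # selection statistics on the genotyped panel
  hd <- call_hdsv(gt$genotypes, panel$accessions$group, cfg$fdr_hdsv)

  # pan-gene stage
  accs <- c("ref", sprintf("acc%02d", 1:5))
  fam <- simulate_gene_families(accs, n_core = 12L, n_dispensable = 8L,
                                seed = cfg$seed + 4L)
  cl <- cluster_genes(fam$genes, cfg$cluster_identity, cfg$cluster_coverage)
  cl <- classify_core_dispensable(cl, length(accs))
  curve <- pan_core_curve(cl, accs, n_orderings = 30L, seed = cfg$seed + 5L)

  summary <- c(
    n_variants_called = nrow(calls$variants),
    snp_recall = ev$recall[ev$group == "snp"],
    canonical_recall = ev$recall[ev$group == "canonical"],
    canonical_precision = ev$precision[ev$group == "canonical"],
    rd_supported_fraction = if (!is.null(rd) && nrow(rd))
      mean(rd$rd_supported) else NA_real_,
    genotype_concordance = gt$concordance,
    n_hdsv = sum(hd$hdsv),
    n_clusters = nrow(cl),
    n_core = sum(cl$status == "core"),
    pan_final = curve$pan_mean[length(accs)])

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_vcf(calls$variants, ref, file.path(out_dir, "variants.vcf"))
    write_bed(calls$variants, file.path(out_dir, "variants.bed"))
    write_gfa(graph, file.path(out_dir, "graph.gfa"))
    write_tsv(ev, file.path(out_dir, "evaluation.tsv"))
    write_tsv(hd, file.path(out_dir, "hdsv.tsv"))
    write_tsv(cl[, c("cluster_id", "n_genes", "n_accessions", "status")],
              file.path(out_dir, "clusters.tsv"))
    write_tsv(curve, file.path(out_dir, "pan_curve.tsv"))
    write_tsv(data.frame(metric = names(summary), value = unname(summary)),
              file.path(out_dir, "summary.tsv"))
  }
  list(reference = ref, truth = imp$truth, calls = calls, evaluation = ev,
       rd_support = rd, graph = graph, panel = panel, genotyping = gt,
       hdsv = hd, clusters = cl, curve = curve, summary = summary)
}
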