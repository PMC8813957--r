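test_that("classify_variant implements the 50 bp class boundary exactly", {
  expect_equal(classify_variant(1, 1, TRUE), "SNP")
  expect_equal(classify_variant(4895, 0, TRUE), "CAN_DEL")
  expect_equal(classify_variant(10, 802, FALSE), "COM_INS")
  expect_equal(classify_variant(0, 49, TRUE), "SMALL_INS")
  expect_equal(classify_variant(0, 50, TRUE), "CAN_INS")
  expect_equal(classify_variant(49, 0, TRUE), "SMALL_DEL")
  expect_equal(classify_variant(50, 0, TRUE), "CAN_DEL")
  expect_equal(classify_variant(120, 300, FALSE), "COM_INS")
  expect_equal(classify_variant(300, 120, FALSE), "COM_DEL")
  # sub-50 replacements classify as small InDels by net length change
  expect_equal(classify_variant(5, 20, FALSE), "SMALL_INS")
  expect_error(classify_variant(0, 0, TRUE))
  expect_error(classify_variant(3, 3, TRUE))
})

test_that("diff_block emits the expected raw difference pairs", {
  set.seed(5)
  s <- paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")
  blk <- function(qlen) data.frame(ref_start = 0, ref_end = 5000,
                                   qry_start = 0, qry_end = qlen,
                                   strand = "+", stringsAsFactors = FALSE)
  expect_equal(nrow(diff_block(blk(5000), s, s)), 0L)

  q <- s
  orig <- substr(q, 2500, 2500)
  substr(q, 2500, 2500) <- setdiff(c("A", "C", "G", "T"), orig)[1]
  d <- diff_block(blk(5000), s, q)
  expect_equal(nrow(d), 1L)
  expect_equal(nchar(d$ref_seg), 1L)
  expect_equal(nchar(d$qry_seg), 1L)
  expect_equal(d$ref_start, 2499)

  q2 <- paste0(substr(s, 1, 2500), substr(s, 2561, 5000))  # 60 bp deletion
  d2 <- diff_block(data.frame(ref_start = 0, ref_end = 5000, qry_start = 0,
                              qry_end = 4940, strand = "+"), s, q2)
  expect_equal(nrow(d2), 1L)
  expect_equal(nchar(d2$ref_seg), 60L)
  expect_equal(d2$qry_seg, "")
})

test_that("diff pairs reconstruct both block sequences", {
  fx <- fixture_small()
  aln <- align_genomes(fx$ref, fx$imp$genome)
  b <- aln$blocks[1, ]
  d <- diff_block(b, fx$ref$chromosomes[[b$ref_chrom]],
                  fx$imp$genome$chromosomes[[b$qry_chrom]])
  # splice the query segments into the reference span: must equal the query
  ref_seq <- fx$ref$chromosomes[[b$ref_chrom]]
  out <- character(0)
  cursor <- b$ref_start
  for (i in seq_len(nrow(d))) {
    out <- c(out, substr(ref_seq, cursor + 1, d$ref_start[i]), d$qry_seg[i])
    cursor <- d$ref_end[i]
  }
  out <- c(out, substr(ref_seq, cursor + 1, b$ref_end))
  expect_identical(paste(out, collapse = ""),
                   substr(fx$imp$genome$chromosomes[[b$qry_chrom]],
                          b$qry_start + 1, b$qry_end))
})

test_that("refine_breakpoints promotes resolvable complex calls only", {
  ref <- simulate_reference(1, 20000, 0.5, seed = 81)
  chrom <- ref$chromosomes[[1]]
  # a clean 80 bp insertion mis-reported as a complex replacement whose
  # alleles share affixes with the true context
  ins <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
  v <- data.frame(id = NA, variant_class = "COM_INS", ref_chrom = "chr1",
                  ref_start = 5000, ref_end = 5010,
                  ref_allele = substr(chrom, 5001, 5010),
                  alt_allele = paste0(substr(chrom, 5001, 5005), ins,
                                      substr(chrom, 5006, 5010)),
                  qry_chrom = "chr1", qry_start = 5000, qry_end = 5090,
                  strand = "+", precise = FALSE, accession_id = "a",
                  stringsAsFactors = FALSE)
  r <- refine_breakpoints(v, ref)
  expect_equal(r$variant_class, "CAN_INS")
  expect_true(r$precise)
  expect_equal(nchar(r$alt_allele), 80L)
  expect_equal(r$ref_allele, "")

  # genuinely divergent replacement stays complex
  v2 <- v
  v2$ref_allele <- paste(sample(c("A", "C", "G", "T"), 120, TRUE),
                         collapse = "")
  v2$alt_allele <- paste(sample(c("A", "C", "G", "T"), 300, TRUE),
                         collapse = "")
  v2$ref_end <- v2$ref_start + 120
  r2 <- refine_breakpoints(v2, ref)
  expect_equal(r2$variant_class, "COM_INS")

  # canonical variants are untouched
  v3 <- v; v3$variant_class <- "CAN_INS"; v3$precise <- TRUE
  expect_identical(refine_breakpoints(v3, ref), v3)
})

test_that("N filtering and assembly-error masking apply the stated thresholds", {
  v <- data.frame(id = c("a", "b", "c"),
                  variant_class = c("CAN_INS", "CAN_DEL", "SNP"),
                  ref_chrom = "chr1", ref_start = c(10, 500, 900),
                  ref_end = c(10, 560, 901),
                  ref_allele = c("", paste(rep("A", 60), collapse = ""), "G"),
                  alt_allele = c("ACGTNACGT", "", "T"),
                  qry_chrom = "chr1", qry_start = 0, qry_end = 0,
                  strand = "+", precise = TRUE, accession_id = "x",
                  stringsAsFactors = FALSE)
  out <- filter_n_content(v)
  expect_equal(out$id, c("b", "c"))
  expect_equal(as.integer(attr(out, "removed")["CAN_INS"]), 1L)

  sc <- data.frame(chrom = "chr1", pos = 900L, base_q = 30, map_q = 60,
                   depth = 50)
  expect_equal(nrow(mask_assembly_errors(v, sc)), 2L)
  sc$depth <- 250
  expect_equal(nrow(mask_assembly_errors(v, sc)), 3L)
  sc$depth <- 50; sc$base_q <- 20
  expect_equal(nrow(mask_assembly_errors(v, sc)), 3L)
  expect_equal(nrow(mask_assembly_errors(v, sc[0, ])), 3L)
})

test_that("microhomology detection finds junction-shared sequence", {
  set.seed(9)
  flank <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")
  # deletion whose interior starts with CCACC and whose right flank also
  # starts with CCACC: 5 bp right homology
  del_body <- paste0("CCACC", flank(46))
  ref_seq <- paste0(flank(200), del_body, "CCACC", flank(195))
  del <- data.frame(id = "d1", variant_class = "CAN_DEL", ref_chrom = "chr1",
                    ref_start = 200, ref_end = 251, stringsAsFactors = FALSE)
  mh <- detect_microhomology(del, ref_seq)
  expect_equal(mh$homology_len, 5L)
  expect_equal(mh$homology_seq, "CCACC")

  # homopolymer: homology capped at min(span, max_len)
  hp <- paste0(flank(100), paste(rep("A", 60), collapse = ""), flank(100))
  del2 <- data.frame(id = "d2", variant_class = "CAN_DEL",
                     ref_chrom = "chr1", ref_start = 110, ref_end = 120,
                     stringsAsFactors = FALSE)
  mh2 <- detect_microhomology(del2, hp)
  expect_equal(mh2$homology_len, 10L)
  del3 <- data.frame(id = "d3", variant_class = "CAN_DEL",
                     ref_chrom = "chr1", ref_start = 105, ref_end = 145,
                     stringsAsFactors = FALSE)
  expect_equal(detect_microhomology(del3, hp)$homology_len, 15L)

  # junctions with nothing shared
  ref3 <- paste0(paste(rep("AC", 100), collapse = ""), "GGGGTTTTGGGG",
                 paste(rep("TG", 100), collapse = ""))
  del4 <- data.frame(id = "d4", variant_class = "CAN_DEL",
                     ref_chrom = "chr1", ref_start = 200, ref_end = 212,
                     stringsAsFactors = FALSE)
  expect_equal(detect_microhomology(del4, ref3)$homology_len, 0L)
})

test_that("gene overlap annotation yields contexts and coding consequences", {
  genes <- data.frame(gene_id = "G1", chrom = "chr1", strand = "+",
                      gene_start = 10000L, gene_end = 13000L,
                      cds_start = 10200L, cds_end = 12800L,
                      stringsAsFactors = FALSE)
  mk <- function(cls, s, e, ra, aa)
    data.frame(id = "v", variant_class = cls, ref_chrom = "chr1",
               ref_start = s, ref_end = e, ref_allele = ra, alt_allele = aa,
               qry_chrom = "chr1", qry_start = 0, qry_end = 0, strand = "+",
               precise = TRUE, accession_id = "x", stringsAsFactors = FALSE)

  # 51 bp codon-aligned CDS deletion: loss of 17 amino acids
  del51 <- mk("CAN_DEL", 10200 + 33 * 3, 10200 + 33 * 3 + 51,
              paste(rep("A", 51), collapse = ""), "")
  a1 <- annotate_gene_overlap(del51, genes)
  expect_equal(a1$context, "CDS-SV")
  expect_equal(a1$consequence, "in_frame_aa_loss")
  expect_equal(a1$aa_change, 17L)

  # 76 bp insertion 100 bp upstream of the TSS: promoter-SV
  ins76 <- mk("CAN_INS", 9900, 9900, "", paste(rep("C", 76), collapse = ""))
  expect_equal(annotate_gene_overlap(ins76, genes)$context, "promoter-SV")

  # 50 bp CDS deletion: frameshift
  del50 <- mk("CAN_DEL", 10200 + 33 * 3, 10200 + 33 * 3 + 50,
              paste(rep("A", 50), collapse = ""), "")
  expect_equal(annotate_gene_overlap(del50, genes)$consequence, "frameshift")

  # codon-misaligned in-frame-length deletion is still a frameshift label?
  # no: length divisible by 3 but off the codon boundary -> frameshift
  del51b <- mk("CAN_DEL", 10200 + 100, 10200 + 151,
               paste(rep("A", 51), collapse = ""), "")
  expect_equal(annotate_gene_overlap(del51b, genes)$consequence, "frameshift")

  # intron and intergenic contexts; bounds checking
  intron <- mk("SNP", 10050, 10051, "A", "G")
  expect_equal(annotate_gene_overlap(intron, genes)$context, "intron-SV")
  inter <- mk("SNP", 50000, 50001, "A", "G")
  expect_equal(annotate_gene_overlap(inter, genes)$context, "intergenic")
  g <- simulate_reference(1, 20000, 0.5, seed = 1)
  expect_error(annotate_gene_overlap(inter, genes, ref_genome = g))
})

test_that("canonical and complex counts are conserved through refinement", {
  fx <- fixture_small()
  res <- call_variants(fx$ref, fx$imp$genome)
  truth <- fx$imp$truth
  n_large_truth <- sum(truth$variant_class %in%
                         c("CAN_INS", "CAN_DEL", "COM_INS", "COM_DEL"))
  n_large_called <- sum(res$variants$variant_class %in%
                          c("CAN_INS", "CAN_DEL", "COM_INS", "COM_DEL"))
  expect_equal(n_large_called, n_large_truth)
})

test_that("variant ids follow the SV_{TYPE}_{chrom}G{index} scheme", {
  v <- data.frame(variant_class = c("CAN_INS", "CAN_DEL", "CAN_INS"),
                  ref_chrom = c("chr7", "chr7", "chr7"),
                  ref_start = c(100, 50, 900), stringsAsFactors = FALSE)
  ids <- variant_ids(v)
  expect_equal(ids, c("SV_INS_7G000010", "SV_DEL_7G000010",
                      "SV_INS_7G000020"))
})
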