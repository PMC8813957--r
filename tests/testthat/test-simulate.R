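test_that("simulate_reference respects size, GC and determinism contracts", {
  g <- simulate_reference(1, 10000, 0.5, seed = 1)
  expect_length(g$chromosomes, 1L)
  expect_equal(nchar(g$chromosomes[[1]]), 10000L)

  g2 <- simulate_reference(1, 10000, 0.5, seed = 1)
  expect_identical(g$chromosomes, g2$chromosomes)

  g3 <- simulate_reference(3, 100000, 0.35, seed = 7)
  bases <- table(strsplit(paste(g3$chromosomes, collapse = ""), "")[[1]])
  gc <- sum(bases[c("G", "C")]) / sum(bases)
  expect_gt(gc, 0.33); expect_lt(gc, 0.37)

  expect_error(simulate_reference(0, 10000))
  expect_error(simulate_reference(1, 500))
})

test_that("implant_variants does length bookkeeping per class", {
  ref <- simulate_reference(1, 20000, 0.5, seed = 3)
  spec <- variant_spec(n_can_del = 1, canonical_range = c(60, 60))
  imp <- implant_variants(ref, spec, seed = 4)
  expect_equal(nchar(imp$genome$chromosomes[[1]]),
               nchar(ref$chromosomes[[1]]) - 60L)

  # complex insertion: 10 bp replaced by 802 bp, net +792
  spec2 <- variant_spec(n_com_ins = 1, complex_major_range = c(802, 802),
                        complex_minor_range = c(10, 10))
  imp2 <- implant_variants(ref, spec2, seed = 5)
  expect_equal(nchar(imp2$genome$chromosomes[[1]]),
               nchar(ref$chromosomes[[1]]) + 792L)
  expect_equal(imp2$truth$variant_class, "COM_INS")
  expect_equal(nchar(imp2$truth$ref_allele), 10L)
  expect_equal(nchar(imp2$truth$alt_allele), 802L)
})

test_that("applying the truth to the reference reproduces the derived genome", {
  fx <- fixture_small()
  rebuilt <- apply_variants(fx$ref, fx$imp$truth, accession_id = "acc1")
  expect_identical(rebuilt$genome$chromosomes, fx$imp$genome$chromosomes)
})

test_that("a naive character diff recovers every implanted truth interval", {
  ref <- simulate_reference(1, 12000, 0.5, seed = 11)
  spec <- variant_spec(n_snp = 3, n_small_del = 2, n_can_ins = 2,
                       canonical_range = c(50, 120))
  imp <- implant_variants(ref, spec, seed = 12, min_spacing = 600,
                          edge_buffer = 600)
  d <- naive_diff(ref$chromosomes[[1]], imp$genome$chromosomes[[1]])
  truth <- left_align_variants(imp$truth, ref)
  # the greedy oracle emits the rightmost-shifted equivalent of each InDel;
  # match on interval lengths with a small positional shift allowance
  for (i in seq_len(nrow(truth))) {
    hit <- abs(d$a_start - truth$ref_start[i]) <= 10L &
      (d$a_end - d$a_start) ==
        (truth$ref_end[i] - truth$ref_start[i]) &
      (d$b_end - d$b_start) == nchar(truth$alt_allele[i])
    expect_true(any(hit), info = paste("truth row", i))
  }
  expect_equal(nrow(d), nrow(truth))
})

test_that("simulated SV size classes respect the 50 bp boundary exactly", {
  fx <- fixture_small()
  t <- fx$imp$truth
  small <- t$variant_class %in% c("SMALL_INS", "SMALL_DEL")
  large <- t$variant_class %in% c("CAN_INS", "CAN_DEL", "COM_INS", "COM_DEL")
  sz <- pmax(nchar(t$ref_allele), nchar(t$alt_allele))
  expect_true(all(sz[small] < 50))
  expect_true(all(sz[large] >= 50))
})

test_that("read simulation hits requested depth and is exact at error 0", {
  g <- simulate_reference(1, 100000, 0.5, seed = 21)
  reads <- simulate_reads(g, 30, seed = 22)
  dp <- depth_profile(reads, g)
  expect_lt(abs(mean(dp[[1]]) - 30) / 30, 0.1)

  idx <- sample(nrow(reads), 50)
  for (i in idx) {
    expect_true(grepl(reads$seq1[i], g$chromosomes[[1]], fixed = TRUE))
    rc2 <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(reads$seq2[i])))
    expect_true(grepl(rc2, g$chromosomes[[1]], fixed = TRUE))
  }
  expect_error(simulate_reads(g, 0))
})

test_that("interior depth histogram is consistent with Poisson(30)", {
  g <- simulate_reference(1, 100000, 0.5, seed = 31)
  reads <- simulate_reads(g, 30, seed = 32)
  dp <- depth_profile(reads, g)[[1]]
  # positions spaced beyond the fragment length are effectively independent
  d <- dp[seq(2000, 98000, by = 700)]
  breaks <- c(-Inf, 22, 26, 29, 32, 36, Inf)
  obs <- table(cut(d, breaks))
  pr <- diff(ppois(c(-1, 22, 26, 29, 32, 36, Inf), 30))
  cs <- suppressWarnings(chisq.test(as.numeric(obs), p = pr / sum(pr)))
  expect_gt(cs$p.value, 0.01)
  expect_lt(abs(mean(dp) - 30), 3)
})

test_that("population panel reproduces group frequencies and implanted fold-changes", {
  ref <- simulate_reference(1, 30000, 0.5, seed = 41)
  spec <- variant_spec(n_can_ins = 2, n_can_del = 2)
  imp <- implant_variants(ref, spec, seed = 42)
  panel <- simulate_population(ref, imp$truth, 20, 40,
                               p_wild = 1.0, p_cult = 0.0, seed = 43,
                               expression_spec = data.frame(
                                 gene_id = "g1", tissue = "root", lfc = 2))
  wild <- panel$accessions$group == "wild"
  expect_true(all(panel$genotypes[, wild] == "alt/alt"))
  expect_true(all(panel$genotypes[, !wild] == "ref/ref"))

  panel2 <- simulate_population(ref, imp$truth, 20, 40, 1.0, 0.0, seed = 43)
  expect_identical(panel$genotypes, panel2$genotypes)

  ex <- panel$expression
  r_w <- ex$tpm[ex$gene_id == "g1" & ex$tissue == "root" & ex$group == "wild"]
  r_c <- ex$tpm[ex$gene_id == "g1" & ex$tissue == "root" &
                  ex$group == "cultivated"]
  expect_lt(abs(log2(r_c / r_w) - 2), 0.5)
  expect_error(simulate_population(ref, imp$truth, 1, 5, 0.5, 0.5))
})

test_that("liftover drops reads without an image and clips at junctions", {
  ref <- simulate_reference(1, 30000, 0.5, seed = 51)
  spec <- variant_spec(n_can_del = 1, n_can_ins = 1,
                       canonical_range = c(200, 200))
  imp <- implant_variants(ref, spec, seed = 52)
  reads <- simulate_reads(imp$genome, 25, seed = 53)
  lifted <- liftover_placements(reads, imp$truth, "to_reference")
  del <- imp$truth[imp$truth$variant_class == "CAN_DEL", ]
  dp <- depth_profile(lifted, ref)[[del$ref_chrom]]
  expect_equal(sum(dp[(del$ref_start + 1):del$ref_end]), 0)
  rl <- attr(lifted, "read_len")
  expect_true(all(lifted$end1 - lifted$start1 <= rl))
})
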