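test_that("find_anchors recovers exact matches on both strands", {
  set.seed(1)
  s <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = "")
  a <- find_anchors(s, s)
  plus <- a[a$strand == "+", ]
  expect_equal(nrow(plus), 1L)
  expect_equal(plus$ref_start, 0); expect_equal(plus$ref_end, 10000)
  expect_equal(plus$qry_start, 0); expect_equal(plus$qry_end, 10000)

  q <- s
  orig <- substr(q, 5001, 5001)
  substr(q, 5001, 5001) <- setdiff(c("A", "C", "G", "T"), orig)[1]
  a2 <- find_anchors(s, q)
  plus2 <- a2[a2$strand == "+", ]
  expect_equal(nrow(plus2), 2L)
  expect_equal(sort(plus2$ref_start), c(0, 5001))
  expect_equal(sort(plus2$ref_end), c(5000, 10000))

  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  a3 <- find_anchors(s, rc)
  minus <- a3[a3$strand == "-", ]
  expect_equal(nrow(minus), 1L)
  expect_equal(minus$length, 10000)
})

test_that("extend_and_score merges near anchors and splits distant ones", {
  set.seed(2)
  left <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  gap <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
  right <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  ref <- paste0(left, gap, right)

  # matching gap: single segment at identity 100
  a <- find_anchors(ref, ref)
  sg <- extend_and_score(a, ref, ref)
  expect_equal(nrow(sg), 1L)
  expect_equal(sg$identity, 100)

  # 10 bp insertion in the gap reduces identity via the gap columns
  qry <- paste0(left, substr(gap, 1, 15), "ACGTACGTAC", substr(gap, 16, 30),
                right)
  a2 <- find_anchors(ref, qry)
  sg2 <- extend_and_score(a2, ref, qry)
  expect_equal(nrow(sg2), 1L)
  expect_lt(sg2$identity, 100)
  expect_gte(sg2$identity, 100 * 6030 / 6040 - 0.2)

  # anchors far apart stay separate segments
  far <- paste(sample(c("A", "C", "G", "T"), 100000, TRUE), collapse = "")
  ref3 <- paste0(left, far, right)
  qry3 <- paste0(left, paste(sample(c("A", "C", "G", "T"), 100000, TRUE),
                             collapse = ""), right)
  a3 <- find_anchors(ref3, qry3)
  sg3 <- extend_and_score(a3, ref3, qry3, max_anchor_gap = 500)
  expect_gte(nrow(sg3), 2L)
})

test_that("one-to-one filtering enforces thresholds and max-weight selection", {
  seg <- function(rs, re, qs, qe, id, st = "+") {
    data.frame(ref_start = rs, ref_end = re, qry_start = qs, qry_end = qe,
               strand = st, aligned_length = re - rs, identity = id,
               n_anchors = 1L, stringsAsFactors = FALSE)
  }
  expect_equal(nrow(filter_one_to_one(seg(0, 1000, 0, 1000, 89))), 0L)
  expect_equal(nrow(filter_one_to_one(seg(0, 150, 0, 150, 99))), 0L)

  # two query segments over the same reference interval: heavier one wins
  s2 <- rbind(seg(0, 1000, 0, 1000, 99), seg(0, 900, 5000, 5900, 95))
  out <- filter_one_to_one(s2)
  expect_equal(nrow(out), 1L)
  expect_equal(out$qry_start, 0)
})

test_that("one-to-one selection equals brute force on random segment sets", {
  set.seed(33)
  for (rep in 1:25) {
    n <- sample(3:9, 1)
    s <- data.frame(
      ref_start = sample(0:2000, n), qry_start = sample(0:2000, n),
      strand = "+", identity = round(runif(n, 91, 100), 1),
      stringsAsFactors = FALSE)
    len <- sample(200:800, n, replace = TRUE)
    s$ref_end <- s$ref_start + len
    s$qry_end <- s$qry_start + len
    s$aligned_length <- len
    s$n_anchors <- 1L
    w <- s$identity * len
    got <- filter_one_to_one(s, overlap_tol = 0L)
    brute <- mwis_brute(s, w)
    got_w <- sum(got$identity * (got$ref_end - got$ref_start))
    expect_equal(got_w, brute$weight, tolerance = 1e-9)
  }
})

test_that("retained segments cover each genome position at most once", {
  fx <- fixture_small()
  aln <- align_genomes(fx$ref, fx$imp$genome)
  s <- aln$segments
  for (ax in c("ref", "qry")) {
    ch <- s[[paste0(ax, "_chrom")]]
    for (cn in unique(ch)) {
      k <- ch == cn
      ir <- IRanges::IRanges(start = s[[paste0(ax, "_start")]][k] + 1L,
                             end = s[[paste0(ax, "_end")]][k])
      cov <- IRanges::coverage(ir)
      expect_lte(max(S4Vectors::runValue(cov)), 1L)
    }
  }
})

test_that("block chaining obeys the gap threshold and is idempotent", {
  seg <- function(rs, re, qs, qe, st = "+") {
    data.frame(ref_start = rs, ref_end = re, qry_start = qs, qry_end = qe,
               strand = st, aligned_length = re - rs, identity = 99,
               n_anchors = 1L, stringsAsFactors = FALSE)
  }
  one <- seg(0, 1000, 0, 1000)
  b1 <- chain_collinear_blocks(one)
  expect_equal(nrow(b1), 1L)
  expect_equal(b1$ref_start, 0); expect_equal(b1$ref_end, 1000)

  close_pair <- rbind(seg(0, 1000, 0, 1000), seg(11000, 12000, 11000, 12000))
  expect_equal(nrow(chain_collinear_blocks(close_pair)), 1L)
  far_pair <- rbind(seg(0, 1000, 0, 1000), seg(61000, 62000, 11000, 12000))
  expect_equal(nrow(chain_collinear_blocks(far_pair)), 2L)

  flip <- rbind(seg(0, 1000, 0, 1000), seg(1100, 2000, 1100, 2000, "-"),
                seg(2100, 3000, 2100, 3000))
  expect_equal(nrow(chain_collinear_blocks(flip)), 3L)

  # idempotence: chaining the blocks (as segments) reproduces them
  b <- chain_collinear_blocks(close_pair)
  b2 <- chain_collinear_blocks(data.frame(
    ref_start = b$ref_start, ref_end = b$ref_end, qry_start = b$qry_start,
    qry_end = b$qry_end, strand = b$strand,
    aligned_length = b$aligned_length, identity = b$identity,
    n_anchors = 1L, stringsAsFactors = FALSE))
  expect_equal(b2$ref_start, b$ref_start)
  expect_equal(b2$ref_end, b$ref_end)
})

test_that("blocks tile variant-free genome pairs almost completely", {
  ref <- simulate_reference(2, 100000, 0.5, seed = 61)
  qry <- ref; qry$accession_id <- "copy"
  aln <- align_genomes(ref, qry)
  for (cn in names(ref$chromosomes)) {
    b <- aln$blocks[aln$blocks$ref_chrom == cn, ]
    covered <- sum(b$ref_end - b$ref_start)
    expect_gte(covered / nchar(ref$chromosomes[[cn]]), 0.99)
  }
})

test_that("implanted rearrangements are detected in the right classes", {
  ref <- simulate_reference(2, 400000, 0.45, seed = 71)
  spec <- variant_spec(n_inv = 1, n_trans = 1, inv_range = c(100000, 100000),
                       trans_range = c(5000, 5000))
  imp <- implant_variants(ref, spec, seed = 72)
  aln <- align_genomes(ref, imp$genome)
  re <- detect_rearrangements(aln$blocks, ref_genome = ref)
  tinv <- imp$truth[imp$truth$variant_class == "INV", ]
  expect_equal(nrow(re$inversions), 1L)
  expect_lt(abs(re$inversions$ref_start - tinv$ref_start), 25)
  expect_lt(abs(re$inversions$ref_end - tinv$ref_end), 25)
  expect_equal(nrow(re$megabase_inversions), 0L)

  ttr <- imp$truth[imp$truth$variant_class == "TRANS", ]
  expect_equal(nrow(re$translocations), 1L)
  expect_equal(re$translocations$type, "inter")
  expect_lt(abs(re$translocations$ref_start - ttr$ref_start), 25)

  # megabase-scale inversion lands in its own class
  ref2 <- simulate_reference(1, 3000000, 0.45, seed = 73)
  spec2 <- variant_spec(n_inv = 1, inv_range = c(2000000, 2000000))
  imp2 <- implant_variants(ref2, spec2, seed = 74)
  aln2 <- align_genomes(ref2, imp2$genome)
  re2 <- detect_rearrangements(aln2$blocks, ref_genome = ref2)
  expect_equal(nrow(re2$inversions), 0L)
  expect_equal(nrow(re2$megabase_inversions), 1L)
  expect_gte(re2$megabase_inversions$size, 1e6)
})
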