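test_that("windowed diversity matches the pairwise-difference oracle", {
  # 2 haplotypes, 1 difference, 100 bp window: pi = 0.01
  m <- matrix(c(0L, 1L), nrow = 1)
  tr <- nucleotide_diversity(cbind(m, m), data.frame(chrom = "c", pos = 50L),
                             groups = rep(c("wild", "cultivated"), each = 2),
                             seq_lengths = c(c = 100L), window = 100L,
                             step = 100L)
  expect_equal(tr$pi_wild, 0.01)

  # random matrices with <= 8 haplotypes vs enumeration of all pairs
  set.seed(301)
  for (rep in 1:10) {
    nh <- sample(3:8, 1)
    ns <- sample(5:30, 1)
    g <- matrix(rbinom(nh * ns, 1, runif(1, 0.2, 0.8)), nrow = ns)
    pos <- data.frame(chrom = "c", pos = sort(sample(0:999, ns)))
    tr <- nucleotide_diversity(cbind(g, g),
                               groups = rep(c("wild", "cultivated"),
                                            each = nh),
                               site_pos = pos, seq_lengths = c(c = 1000L),
                               window = 1000L, step = 1000L)
    expect_equal(tr$pi_wild, pi_pairwise(g) / 1000, tolerance = 1e-12)
  }

  # monomorphic window
  g0 <- matrix(0L, 3, 4)
  tr0 <- nucleotide_diversity(g0, data.frame(chrom = "c", pos = c(1L, 2L, 3L)),
                              groups = rep(c("wild", "cultivated"), each = 2),
                              seq_lengths = c(c = 100L), window = 100L,
                              step = 100L)
  expect_equal(tr0$pi_wild, 0)
  expect_error(nucleotide_diversity(g0, data.frame(chrom = "c", pos = 1:3),
                                    groups = rep(c("wild", "cultivated"),
                                                 each = 2),
                                    seq_lengths = c(c = 100L),
                                    window = 50L, step = 100L))
})

test_that("sweep selection takes exactly the top windows and merges neighbours", {
  set.seed(302)
  track <- data.frame(chrom = "c", start = seq(0, 99) * 1000,
                      end = seq(1, 100) * 1000,
                      pi_wild = 1, pi_cult = 1,
                      undefined_ratio = FALSE,
                      ratio = runif(100, 0.5, 2), stringsAsFactors = FALSE)
  track$ratio[c(10, 11, 12, 40, 80)] <- c(9, 8, 7, 6, 5)
  sw <- sweep_regions(track)
  expect_equal(sum(sw$n_windows), 5L)
  expect_equal(sw$start, c(9000, 39000, 79000))  # 3 merged regions
  expect_equal(attr(sw, "mode"), "ratio_only")

  # disjoint top sets of the two statistics: empty sweep list
  extra <- runif(100); extra[c(10, 11, 12, 40, 80)] <- 0
  sw2 <- sweep_regions(track, extra_stat = extra)
  expect_equal(nrow(sw2), 0L)

  # order invariance
  perm <- sample(100)
  sw3 <- sweep_regions(track[perm, ])
  expect_equal(sw3$start, sw$start)
  expect_error(sweep_regions(track[1:10, ]))
})

test_that("dSV overlap rule is strict at 50%", {
  sweeps <- data.frame(chrom = "c", start = 1000L, end = 2000L)
  sv <- function(s, e) data.frame(ref_chrom = "c", ref_start = s,
                                  ref_end = e, stringsAsFactors = FALSE)
  expect_true(call_dsv(sv(949, 1049), sweeps) == FALSE)  # 49 of 100 bp
  expect_true(call_dsv(sv(951, 1051), sweeps))           # 51 of 100 bp
  expect_false(call_dsv(sv(950, 1050), sweeps))   # exactly 50 of 100: not >
  expect_true(call_dsv(sv(1949, 2049), sweeps))   # 51 of 100 bp
  expect_false(call_dsv(sv(1951, 2051), sweeps))  # 49 of 100 bp
  expect_true(call_dsv(sv(1200, 1300), sweeps))    # fully inside
  # insertion: anchor point decides
  expect_true(call_dsv(sv(1500, 1500), sweeps))
  expect_false(call_dsv(sv(500, 500), sweeps))
})

test_that("fisher_exact equals hypergeometric enumeration on small tables", {
  expect_equal(fisher_exact(matrix(c(0, 10, 10, 0), 2)),
               fisher_enum(matrix(c(0, 10, 10, 0), 2)), tolerance = 1e-9)
  # exhaustive over all margin configurations with n <= 12
  for (n in 2:12) {
    for (r1 in 1:(n - 1)) {
      for (c1 in 1:(n - 1)) {
        ks <- max(0, r1 + c1 - n):min(r1, c1)
        for (a in ks) {
          tab <- matrix(c(a, r1 - a, c1 - a, n - r1 - c1 + a), 2)
          expect_equal(fisher_exact(tab), fisher_enum(tab),
                       tolerance = 1e-9)
        }
      }
    }
  }
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)))
})

test_that("fisher_exact equals enumeration on random tables with margins <= 30", {
  set.seed(303)
  draw <- function(lo, hi) if (lo >= hi) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
  for (rep in 1:400) {
    r1 <- draw(1, 30); c1 <- draw(1, 30)
    n <- draw(max(r1, c1), min(60, min(r1, c1) + 30))
    a <- draw(max(0, r1 + c1 - n), min(r1, c1))
    tab <- matrix(c(a, r1 - a, c1 - a, n - r1 - c1 + a), 2)
    expect_equal(fisher_exact(tab), fisher_enum(tab), tolerance = 1e-9)
  }
})

test_that("bh_fdr matches the step-down definition", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205)
  m <- length(p)
  manual <- rev(cummin(rev(sort(p) * m / seq_len(m))))[rank(p)]
  expect_equal(bh_fdr(p), manual)
  expect_error(bh_fdr(c(0.5, 1.2)))
})

test_that("hdSV calling flags fixed differences and shrinks with the threshold", {
  gm <- matrix("ref/ref", 2, 60,
               dimnames = list(c("s1", "s2"), paste0("a", 1:60)))
  gm[1, 1:20] <- "alt/alt"            # all wild carry, no cultivated does
  gm[2, c(1:6, 21:32)] <- "alt/alt"   # same frequency in both groups
  groups <- rep(c("wild", "cultivated"), c(20, 40))
  hd <- call_hdsv(gm, groups)
  expect_true(hd$hdsv[hd$site_id == "s1"])
  expect_false(hd$hdsv[hd$site_id == "s2"])
  expect_equal(hd$p_value[hd$site_id == "s2"], 1, tolerance = 1e-9)

  hd_strict <- call_hdsv(gm, groups, fdr_threshold = 1e-20)
  expect_lte(sum(hd_strict$hdsv), sum(hd$hdsv))

  # degenerate group: skipped and flagged
  gm2 <- gm; gm2[, 1:20] <- "missing"
  hd2 <- call_hdsv(gm2, groups)
  expect_true(all(hd2$degenerate))
})

test_that("pi-ratio annotation is inclusive at 3 and treats 0-diversity as Inf", {
  track <- data.frame(chrom = "c", start = c(0L, 100L, 200L),
                      end = c(100L, 200L, 300L),
                      pi_wild = c(1, 1, 0.5), pi_cult = c(1 / 3, 1 / 2.9, 0),
                      undefined_ratio = c(FALSE, FALSE, TRUE),
                      ratio = c(3.0, 2.9, Inf), stringsAsFactors = FALSE)
  svs <- data.frame(ref_chrom = "c", ref_start = c(10L, 110L, 210L, 900L),
                    ref_end = c(20L, 120L, 220L, 910L),
                    stringsAsFactors = FALSE)
  fl <- annotate_pi_ratio(svs, track)
  expect_equal(fl, c(TRUE, FALSE, TRUE, NA))
})

test_that("expression screening flags |log2FC| >= 1.5 in any tissue", {
  expr <- rbind(
    data.frame(gene_id = "g1", tissue = "root", group = "wild", tpm = 2),
    data.frame(gene_id = "g1", tissue = "root", group = "cultivated",
               tpm = 8),
    data.frame(gene_id = "g2", tissue = "root", group = "wild", tpm = 4),
    data.frame(gene_id = "g2", tissue = "root", group = "cultivated",
               tpm = 4 * 2^1.5),
    data.frame(gene_id = "g3", tissue = "root", group = "wild", tpm = 5),
    data.frame(gene_id = "g3", tissue = "root", group = "cultivated",
               tpm = 5))
  links <- data.frame(sv_id = c("v1", "v2", "v3", "v4"),
                      gene_id = c("g1", "g2", "g3", "g1"),
                      context = c("CDS-SV", "promoter-SV", "CDS-SV",
                                  "intron-SV"), stringsAsFactors = FALSE)
  ef <- expression_effect(links, expr, pseudocount = 0)
  expect_equal(ef$log2fc[ef$sv_id == "v1"], 2)
  expect_true(ef$flagged[ef$sv_id == "v1"])
  expect_true(ef$flagged[ef$sv_id == "v2"])      # exactly 1.5, inclusive
  expect_false(ef$flagged[ef$sv_id == "v3"])
  expect_false("v4" %in% ef$sv_id)               # intron context ineligible
  bad <- expr; bad$tpm[1] <- -1
  expect_error(expression_effect(links, bad))
})

test_that("an implanted diversity reduction is recovered as a sweep", {
  set.seed(304)
  L <- 1000000L; nsites <- 4000
  pos <- sort(sample.int(L, nsites)) - 1L
  pw <- runif(nsites, 0.2, 0.8)
  pc <- pw
  lo <- 400000L; hi <- 450000L
  insw <- pos >= lo & pos < hi
  pc[insw] <- runif(sum(insw), 0.005, 0.03)   # ~10x lower expected 2pq
  gw <- sapply(1:20, function(j) rbinom(nsites, 1, pw))
  gc <- sapply(1:30, function(j) rbinom(nsites, 1, pc))
  tr <- nucleotide_diversity(cbind(gw, gc),
                             data.frame(chrom = "c", pos = pos),
                             groups = rep(c("wild", "cultivated"), c(20, 30)),
                             seq_lengths = c(c = L))
  sw <- sweep_regions(tr)
  inter <- sum(pmax(0, pmin(sw$end, hi) - pmax(sw$start, lo)))
  uni <- sum(sw$end - sw$start) + (hi - lo) - inter
  expect_gte(inter / uni, 0.7)
})
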