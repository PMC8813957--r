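# Windowed nucleotide diversity, sweep scan, dSV/hdSV calling and
# SV-expression screening.

#' Windowed nucleotide diversity for two groups
#'
#' Per-site diversity is the unbiased heterozygosity 2*p*q*n/(n-1) computed
#' from haplotype counts; window values are site sums divided by the window
#' length (monomorphic sites contribute 0). Windows are tiled per
#' chromosome with the given step. The wild/cultivated ratio is Inf
#' (flagged) where the cultivated diversity is 0.
#'
#' @param genotypes 0/1 matrix, sites x haplotypes.
#' @param site_pos Data.frame with `chrom` and `pos` (0-based) per site.
#' @param groups `"wild"`/`"cultivated"` label per haplotype (column).
#' @param seq_lengths Named vector of chromosome lengths.
#' @param window,step Window and step in bp (window >= step required).
#' @return `DiversityTrack` data.frame: chrom, start, end, pi_wild, pi_cult,
#'   ratio, undefined_ratio.
#' @export
nucleotide_diversity <- function(genotypes, site_pos, groups, seq_lengths,
                                 window = 10000L, step = 10000L) {
  if (window < step) stop("window must be >= step")
  if (min(table(groups)) < 2L) stop("need >= 2 haplotypes per group")
  pi_site <- function(m) {
    n <- ncol(m)
    p <- rowMeans(m)
    2 * p * (1 - p) * n / (n - 1)
  }
  pw <- pi_site(genotypes[, groups == "wild", drop = FALSE])
  pc <- pi_site(genotypes[, groups == "cultivated", drop = FALSE])
  out <- list()
  for (cn in names(seq_lengths)) {
    starts <- seq(0L, max(0L, seq_lengths[[cn]] - 1L), by = step)
    ends <- pmin(starts + window, seq_lengths[[cn]])
    sel <- site_pos$chrom == cn
    idx <- findInterval(site_pos$pos[sel], starts)
    sw <- tapply(pw[sel], factor(idx, levels = seq_along(starts)), sum)
    sc <- tapply(pc[sel], factor(idx, levels = seq_along(starts)), sum)
    sw[is.na(sw)] <- 0; sc[is.na(sc)] <- 0
    out[[cn]] <- data.frame(
      chrom = cn, start = starts, end = ends,
      pi_wild = as.numeric(sw) / (ends - starts),
      pi_cult = as.numeric(sc) / (ends - starts),
      stringsAsFactors = FALSE)
  }
  tr <- do.call(rbind, out)
  tr$undefined_ratio <- tr$pi_cult == 0
  tr$ratio <- ifelse(tr$undefined_ratio,
                     ifelse(tr$pi_wild > 0, Inf, NA), tr$pi_wild / tr$pi_cult)
  rownames(tr) <- NULL
  tr
}

#' Identify sweep regions from top-quantile windows
#'
#' Selects the top `top_fraction` windows of the wild/cultivated diversity
#' ratio (ties broken by coordinate), intersects with the top windows of an
#' optional second statistic (e.g. an externally computed XP-CLR track), and
#' merges adjacent qualifying windows. With no `extra_stat` the result is a
#' ratio-only scan and is labelled as such.
#'
#' @param track `DiversityTrack` from [nucleotide_diversity()].
#' @param top_fraction Fraction of windows taken (default 0.05).
#' @param extra_stat Optional numeric vector, one value per track window.
#' @return Data.frame of merged sweep regions (chrom, start, end,
#'   n_windows); attribute `mode` is `"ratio_only"` or `"ratio+extra"`.
#' @export
sweep_regions <- function(track, top_fraction = 0.05, extra_stat = NULL) {
  n <- nrow(track)
  if (n < 20L) stop("need >= 20 windows")
  k <- max(1L, floor(top_fraction * n))
  top_of <- function(stat) {
    ord <- order(-stat, track$chrom, track$start, na.last = TRUE)
    sort(ord[seq_len(k)])
  }
  ratio <- track$ratio
  ratio[is.na(ratio)] <- -Inf
  sel <- top_of(ratio)
  if (!is.null(extra_stat)) {
    stopifnot(length(extra_stat) == n)
    sel <- intersect(sel, top_of(extra_stat))
  }
  if (!length(sel)) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_windows = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "mode") <- if (is.null(extra_stat)) "ratio_only" else
      "ratio+extra"
    return(out)
  }
  w <- track[sel, , drop = FALSE]
  w <- w[order(w$chrom, w$start), , drop = FALSE]
  merged <- list()
  cur <- w[1, c("chrom", "start", "end")]
  cur$n_windows <- 1L
  for (i in seq_len(nrow(w))[-1]) {
    if (w$chrom[i] == cur$chrom && w$start[i] <= cur$end) {
      cur$end <- max(cur$end, w$end[i])
      cur$n_windows <- cur$n_windows + 1L
    } else {
      merged[[length(merged) + 1L]] <- cur
      cur <- w[i, c("chrom", "start", "end")]
      cur$n_windows <- 1L
    }
  }
  merged[[length(merged) + 1L]] <- cur
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  attr(out, "mode") <- if (is.null(extra_stat)) "ratio_only" else
    "ratio+extra"
  out
}

#' Flag domestication-associated SVs (dSVs)
#'
#' An SV is a dSV when strictly more than `overlap_fraction` of its
#' reference extent overlaps a sweep region. Insertions have zero reference
#' extent and count as inside a sweep iff their anchor position is.
#'
#' @param svs Variant data.frame.
#' @param sweeps Sweep regions (chrom, start, end).
#' @param overlap_fraction Overlap threshold (default 0.5, strict).
#' @return Logical vector per SV.
#' @export
call_dsv <- function(svs, sweeps, overlap_fraction = 0.5) {
  vapply(seq_len(nrow(svs)), function(i) {
    sw <- sweeps[sweeps$chrom == svs$ref_chrom[i], , drop = FALSE]
    if (!nrow(sw)) return(FALSE)
    len <- svs$ref_end[i] - svs$ref_start[i]
    if (len == 0L)
      return(any(svs$ref_start[i] >= sw$start & svs$ref_start[i] < sw$end))
    ov <- sum(pmax(0L, pmin(sw$end, svs$ref_end[i]) -
                        pmax(sw$start, svs$ref_start[i])))
    ov / len > overlap_fraction
  }, logical(1))
}

#' Two-sided Fisher exact test p-value for a 2x2 table
#'
#' Sum of hypergeometric probabilities of tables at most as probable as the
#' observed one (the classical two-sided convention).
#'
#' @param table 2x2 matrix of non-negative counts.
#' @return The p-value.
#' @export
fisher_exact <- function(table) {
  if (any(table < 0)) stop("negative counts")
  stats::fisher.test(table)$p.value
}

#' Benjamini-Hochberg adjusted q-values
#' @param p_values Numeric vector of p-values in the unit interval.
#' @return Vector of q-values (step-down minima of p*(m/rank)).
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values outside [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Identify highly divergent SVs (hdSVs) between groups
#'
#' Per SV, a 2x2 carrier/non-carrier x wild/cultivated table (missing
#' genotypes excluded from the margins) is tested with a two-sided Fisher
#' exact test; p-values are BH-adjusted across all tested SVs and sites
#' with q below `fdr_threshold` are hdSVs. Sites with an empty group are
#' skipped and flagged.
#'
#' @param genotypes Character matrix, sites x accessions.
#' @param groups Group label per accession.
#' @param fdr_threshold FDR cutoff (default 0.01).
#' @return Data.frame (`DivergenceTest`): site_id, carrier/total counts per
#'   group, p_value, q_value, hdsv, degenerate.
#' @export
call_hdsv <- function(genotypes, groups, fdr_threshold = 0.01) {
  cf <- carrier_frequencies(genotypes, groups)
  w <- cf[cf$group == "wild", ]
  c_ <- cf[cf$group == "cultivated", ]
  m <- merge(w, c_, by = "site_id", suffixes = c("_wild", "_cult"))
  m$degenerate <- m$n_wild == 0L | m$n_cult == 0L
  m$p_value <- NA_real_
  for (i in which(!m$degenerate)) {
    tab <- matrix(c(m$n_carrier_wild[i], m$n_wild[i] - m$n_carrier_wild[i],
                    m$n_carrier_cult[i], m$n_cult[i] - m$n_carrier_cult[i]),
                  nrow = 2)
    m$p_value[i] <- fisher_exact(tab)
  }
  m$q_value <- NA_real_
  m$q_value[!m$degenerate] <- bh_fdr(m$p_value[!m$degenerate])
  m$hdsv <- !is.na(m$q_value) & m$q_value < fdr_threshold
  m[, c("site_id", "n_wild", "n_carrier_wild", "n_cult", "n_carrier_cult",
        "p_value", "q_value", "hdsv", "degenerate")]
}

#' Flag SVs in regions of elevated wild/cultivated diversity ratio
#'
#' An SV is flagged when the track window containing its midpoint has a
#' ratio at or above `ratio_threshold`; undefined ratios (cultivated
#' diversity 0 with wild diversity > 0) are treated as +Inf and flagged.
#' SVs outside the track get NA.
#'
#' @param svs Variant data.frame.
#' @param track `DiversityTrack`.
#' @param ratio_threshold Inclusive threshold (default 3).
#' @return Logical vector per SV (NA where uncovered).
#' @export
annotate_pi_ratio <- function(svs, track, ratio_threshold = 3) {
  vapply(seq_len(nrow(svs)), function(i) {
    mid <- (svs$ref_start[i] + svs$ref_end[i]) %/% 2L
    w <- which(track$chrom == svs$ref_chrom[i] & track$start <= mid &
               track$end > mid)
    if (!length(w)) return(NA)
    r <- track$ratio[w[1]]
    if (is.na(r)) return(NA)
    r >= ratio_threshold
  }, logical(1))
}

#' Screen SV-linked genes for expression effects
#'
#' Per-tissue log2((cultivated + pseudocount) / (wild + pseudocount)) for
#' each SV-gene link; a link is flagged when any tissue reaches
#' `|log2FC| >= lfc_threshold`. Only CDS- and promoter-context SVs are
#' eligible.
#'
#' @param links Data.frame: sv_id, gene_id, context.
#' @param expression Data.frame: gene_id, tissue, group, tpm (>= 0).
#' @param lfc_threshold Inclusive threshold (default 1.5).
#' @param pseudocount Added to both TPM values (default 1).
#' @return Data.frame (`ExpressionEffect`): one row per link x tissue with
#'   `log2fc`, plus per-link `flagged`.
#' @export
expression_effect <- function(links, expression, lfc_threshold = 1.5,
                              pseudocount = 1) {
  if (any(expression$tpm < 0)) stop("negative expression values")
  links <- links[links$context %in% c("CDS-SV", "promoter-SV", "CDS",
                                      "promoter"), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(links))) {
    e <- expression[expression$gene_id == links$gene_id[i], , drop = FALSE]
    wide <- merge(e[e$group == "wild", c("tissue", "tpm")],
                  e[e$group == "cultivated", c("tissue", "tpm")],
                  by = "tissue", suffixes = c("_wild", "_cult"))
    lfc <- log2((wide$tpm_cult + pseudocount) /
                (wide$tpm_wild + pseudocount))
    out[[length(out) + 1L]] <- data.frame(
      sv_id = links$sv_id[i], gene_id = links$gene_id[i],
      context = links$context[i], tissue = wide$tissue, log2fc = lfc,
      flagged = any(abs(lfc) >= lfc_threshold), stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(sv_id = character(), gene_id = character(),
                      context = character(), tissue = character(),
                      log2fc = numeric(), flagged = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}
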