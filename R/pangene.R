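# Gene-based pan-genome: clustering, core/dispensable status,
# representatives, accumulation curves and set enrichment.

# local-alignment identity and coverage of the shorter sequence
pair_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(a, b, type = "local")
  cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
  shorter <- min(nchar(a), nchar(b))
  aligned <- Biostrings::nmatch(aln) + Biostrings::nmismatch(aln)
  c(identity = if (cols > 0) Biostrings::nmatch(aln) / cols else 0,
    coverage = if (shorter > 0) aligned / shorter else 0)
}

kmer_set <- function(seq, k = 8L) {
  n <- nchar(seq)
  if (n < k) return(seq)
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

#' Cluster genes across accessions into pan-gene clusters
#'
#' Single-linkage clustering over pairwise local alignments: two genes are
#' linked when alignment identity is at least `min_identity` and the aligned
#' region covers at least `min_coverage` of the shorter sequence. A k-mer
#' containment prefilter skips clearly unrelated pairs. Every gene ends up
#' in exactly one cluster; the result is invariant to input order.
#'
#' @param genes Data.frame: `gene_id`, `accession_id`, `cds_sequence` (and
#'   optionally `length`; defaults to nchar of the CDS).
#' @param min_identity Identity threshold (default 0.95).
#' @param min_coverage Coverage-of-shorter threshold (default 0.50).
#' @return Data.frame of clusters: `cluster_id`, `n_genes`,
#'   `n_accessions`, list-columns `gene_ids` and `accessions`.
#' @export
cluster_genes <- function(genes, min_identity = 0.95, min_coverage = 0.50) {
  if (!nrow(genes)) stop("cluster_genes: empty input")
  genes <- genes[order(genes$gene_id), , drop = FALSE]
  n <- nrow(genes)
  ks <- lapply(genes$cds_sequence, kmer_set)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union2 <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (find(i) == find(j)) next
      shared <- length(intersect(ks[[i]], ks[[j]])) /
        min(length(ks[[i]]), length(ks[[j]]))
      if (shared < 0.3) next
      pid <- pair_identity(genes$cds_sequence[i], genes$cds_sequence[j])
      if (pid["identity"] >= min_identity && pid["coverage"] >= min_coverage)
        union2(i, j)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  ids <- match(roots, sort(unique(roots)))
  out <- do.call(rbind, lapply(sort(unique(ids)), function(ci) {
    m <- which(ids == ci)
    data.frame(cluster_id = sprintf("CL%05d", ci), n_genes = length(m),
               n_accessions = length(unique(genes$accession_id[m])),
               gene_ids = I(list(genes$gene_id[m])),
               accessions = I(list(unique(genes$accession_id[m]))),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Classify clusters as core or dispensable
#'
#' Core clusters contain genes from all accessions; dispensable clusters
#' lack at least one accession.
#'
#' @param clusters Cluster data.frame from [cluster_genes()].
#' @param n_accessions Size of the accession universe.
#' @return The clusters with a `status` column; per-status counts in
#'   `attr(, "counts")`.
#' @export
classify_core_dispensable <- function(clusters, n_accessions) {
  clusters$status <- ifelse(clusters$n_accessions == n_accessions,
                            "core", "dispensable")
  attr(clusters, "counts") <- table(clusters$status)
  clusters
}

#' Select the representative gene of a cluster
#'
#' A gene from the reference accession is preferred; otherwise the longest
#' gene is chosen, with length ties broken by the lexicographically smaller
#' gene id.
#'
#' @param cluster One cluster row (with `gene_ids` list-column).
#' @param genes The gene table (for accession and length lookup).
#' @param reference_accession Accession id of the reference.
#' @return The representative gene id.
#' @export
select_representative <- function(cluster, genes,
                                  reference_accession = "ref") {
  ids <- cluster$gene_ids[[1]]
  g <- genes[match(ids, genes$gene_id), , drop = FALSE]
  len <- if ("length" %in% names(g)) g$length else nchar(g$cds_sequence)
  is_ref <- g$accession_id == reference_accession
  if (any(is_ref)) {
    cand <- which(is_ref)
  } else {
    cand <- which(len == max(len))
  }
  sort(g$gene_id[cand])[1]
}

#' Pan/core accumulation curves over random accession orderings
#'
#' For each random ordering of the accessions, cumulative pan (union of
#' clusters seen) and core (clusters present in every accession so far)
#' counts are computed; means and standard deviations are taken across
#' orderings. Pan is non-decreasing and core non-increasing for every
#' ordering, and the endpoints equal the total and core cluster counts.
#'
#' @param clusters Cluster data.frame (with `accessions` list-column).
#' @param accessions Character vector: the accession universe.
#' @param n_orderings Number of random orderings (default 100).
#' @param seed Integer seed.
#' @return `PanCurve` data.frame: k, pan_mean, pan_sd, core_mean, core_sd,
#'   added_mean; the per-ordering matrices are in `attr(, "pan")` /
#'   `attr(, "core")`.
#' @export
pan_core_curve <- function(clusters, accessions, n_orderings = 100L,
                           seed = 1L) {
  N <- length(accessions)
  if (N < 2L) stop("need >= 2 accessions")
  set.seed(seed)
  member <- vapply(accessions, function(a)
    vapply(clusters$accessions, function(x) a %in% x, logical(1)),
    logical(nrow(clusters)))  # clusters x accessions
  dim(member) <- c(nrow(clusters), N)
  pan <- matrix(0L, n_orderings, N)
  core <- matrix(0L, n_orderings, N)
  for (r in seq_len(n_orderings)) {
    ord <- sample.int(N)
    seen <- rep(FALSE, nrow(clusters))
    inall <- rep(TRUE, nrow(clusters))
    for (k in seq_len(N)) {
      seen <- seen | member[, ord[k]]
      inall <- inall & member[, ord[k]]
      pan[r, k] <- sum(seen)
      core[r, k] <- sum(inall)
    }
  }
  out <- data.frame(
    k = seq_len(N),
    pan_mean = colMeans(pan), pan_sd = apply(pan, 2, stats::sd),
    core_mean = colMeans(core), core_sd = apply(core, 2, stats::sd),
    added_mean = colMeans(cbind(pan[, 1, drop = FALSE],
                                t(diff(t(pan))))))
  attr(out, "pan") <- pan
  attr(out, "core") <- core
  out
}

#' Fisher-based set enrichment of terms in a gene set
#'
#' One-sided (over-representation) Fisher exact test per term on the
#' foreground-vs-background 2x2 table, BH adjustment across terms, and
#' significance at FDR < `fdr`.
#'
#' @param foreground Character vector of gene ids (subset of background).
#' @param background Character vector of gene ids.
#' @param term_map Data.frame: gene_id, term.
#' @param fdr FDR threshold (default 0.05).
#' @return Data.frame per term: counts, p_value, q_value, enriched.
#' @export
set_enrichment <- function(foreground, background, term_map, fdr = 0.05) {
  if (!all(foreground %in% background))
    stop("foreground must be a subset of background")
  if (!length(foreground))
    return(data.frame(term = character(), fg_with = integer(),
                      fg_without = integer(), bg_with = integer(),
                      bg_without = integer(), p_value = numeric(),
                      q_value = numeric(), enriched = logical(),
                      stringsAsFactors = FALSE))
  terms <- sort(unique(term_map$term))
  n_fg <- length(foreground); n_bg <- length(background)
  out <- do.call(rbind, lapply(terms, function(tm) {
    with_term <- unique(term_map$gene_id[term_map$term == tm])
    a <- sum(foreground %in% with_term)
    b <- n_fg - a
    cc <- sum(background %in% with_term) - a
    d <- n_bg - n_fg - cc
    p <- stats::fisher.test(matrix(c(a, b, cc, d), 2),
                            alternative = "greater")$p.value
    data.frame(term = tm, fg_with = a, fg_without = b, bg_with = cc + a,
               bg_without = d + b, p_value = p, stringsAsFactors = FALSE)
  }))
  out$q_value <- bh_fdr(out$p_value)
  out$enriched <- out$q_value < fdr
  rownames(out) <- NULL
  out
}

#' Simulate gene families across accessions with known truth
#'
#' Each family has an ancestral CDS (length a multiple of 3); members in
#' each carrying accession differ by a few substitutions (within-family
#' identity well above the clustering threshold). Core families are present
#' in every accession; each dispensable family is absent from a random
#' non-empty subset of non-reference accessions.
#'
#' @param accessions Character vector of accession ids; the first is treated
#'   as the reference.
#' @param n_core,n_dispensable Family counts.
#' @param len_range CDS length range (rounded to codons).
#' @param sub_rate Per-base substitution rate within a family.
#' @param seed Integer seed.
#' @return List: `genes` (gene table), `truth` (family, accession
#'   membership), with family ids recorded per gene.
#' @export
simulate_gene_families <- function(accessions, n_core = 20L,
                                   n_dispensable = 10L,
                                   len_range = c(300L, 1200L),
                                   sub_rate = 0.01, seed = 1L) {
  set.seed(seed)
  fams <- list(); genes <- list()
  n_fam <- n_core + n_dispensable
  for (f in seq_len(n_fam)) {
    L <- 3L * (sample_range(len_range[1], len_range[2]) %/% 3L)
    anc <- random_dna(L)
    status <- if (f <= n_core) "core" else "dispensable"
    present <- accessions
    if (status == "dispensable") {
      k <- sample.int(length(accessions) - 1L, 1L)
      absent <- sample(accessions[-1], k)
      present <- setdiff(accessions, absent)
    }
    fams[[f]] <- data.frame(family = sprintf("FAM%04d", f), status = status,
                            n_present = length(present),
                            accessions = I(list(present)),
                            stringsAsFactors = FALSE)
    for (a in present) {
      s <- anc
      nmut <- rbinom(1L, L, sub_rate)
      if (nmut > 0L) {
        pos <- sample.int(L, nmut)
        ch <- strsplit(s, "")[[1]]
        ch[pos] <- vapply(ch[pos], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
        s <- paste(ch, collapse = "")
      }
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = sprintf("%s_FAM%04d", a, f), accession_id = a,
        family = sprintf("FAM%04d", f), cds_sequence = s,
        length = nchar(s), stringsAsFactors = FALSE)
    }
  }
  list(genes = do.call(rbind, genes), truth = do.call(rbind, fams))
}
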