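# Short-read support evaluation for large InDels via the read-depth rule.

#' Per-position read depth from read placements
#'
#' Counts only placements with mapping quality >= `min_mapq`; duplicate
#' pairs (identical placement of both mates) are collapsed to one.
#'
#' @param reads Read data.frame from [simulate_reads()] (possibly lifted
#'   with [liftover_placements()]).
#' @param genome The genome the placements refer to.
#' @param min_mapq Mapping-quality cutoff (default 20).
#' @return A `DepthTrack`: named list of integer per-position depth vectors,
#'   one per chromosome.
#' @export
depth_profile <- function(reads, genome, min_mapq = 20L) {
  rl <- attr(reads, "read_len")
  if (is.null(rl)) rl <- nchar(reads$seq1[1])
  r <- reads[reads$mapq >= min_mapq, , drop = FALSE]
  r <- r[!duplicated(paste(r$chrom, r$start1, r$start2)), , drop = FALSE]
  e1 <- if ("end1" %in% names(r)) r$end1 else r$start1 + rl
  e2 <- if ("end2" %in% names(r)) r$end2 else r$start2 + rl
  out <- lapply(names(genome$chromosomes), function(cn) {
    k <- r$chrom == cn
    .interval_depth_cpp(c(r$start1[k], r$start2[k]), c(e1[k], e2[k]),
                        nchar(genome$chromosomes[[cn]]))
  })
  names(out) <- names(genome$chromosomes)
  out
}

#' Read-depth support call for one deletion
#'
#' A deletion is RD supported when the mean coverage of its 1 kb left and
#' right flanking regions is more than threefold the mean coverage of the
#' deletion region and the region coverage is below 3. Coverages are simple
#' arithmetic means of per-base depth (zeros included); flanks truncated at
#' chromosome ends are used at their truncated length.
#'
#' @param deletion One CAN_DEL/COM_DEL row of a variant data.frame.
#' @param depth DepthTrack from [depth_profile()].
#' @param flank Flank length in bp (default 1000).
#' @return Data.frame (`SupportCall`): `variant_id`, `rd_supported`,
#'   `region_depth`, `flank_depth`, `fold`.
#' @export
rd_support <- function(deletion, depth, flank = 1000L) {
  stopifnot(deletion$variant_class[1] %in% c("CAN_DEL", "COM_DEL"))
  s <- deletion$ref_start[1]; e <- deletion$ref_end[1]
  if (e <= s) stop("zero-length deletion region")
  d <- depth[[deletion$ref_chrom[1]]]
  L <- length(d)
  region <- mean(d[(s + 1L):e])
  lf <- d[max(1L, s - flank + 1L):s]
  rf <- d[(e + 1L):min(L, e + flank)]
  flank_depth <- mean(c(lf, rf))
  fold <- if (region == 0) Inf else flank_depth / region
  data.frame(variant_id = if (!is.null(deletion$id)) deletion$id[1]
             else NA_character_,
             rd_supported = (flank_depth > 3 * region) && (region < 3),
             region_depth = region, flank_depth = flank_depth, fold = fold,
             stringsAsFactors = FALSE)
}

#' Swap the reference: turn an insertion into a deletion on the query genome
#'
#' Because precise SVs have exact breakpoints in both genomes, an insertion
#' relative to the reference is a deletion relative to the carrier (query)
#' genome. The returned variant spans the inserted sequence on the query, so
#' [rd_support()] applies with reads mapped to the query genome. The swap is
#' an involution: swapping twice returns the original variant.
#'
#' @param insertion One insertion row (query coordinates populated).
#' @return The swapped variant row.
#' @export
swap_reference <- function(insertion) {
  v <- insertion[1, , drop = FALSE]
  if (is.na(v$qry_start) || is.na(v$qry_end))
    stop("swap_reference: query coordinates missing")
  swap_class <- c(CAN_INS = "CAN_DEL", CAN_DEL = "CAN_INS",
                  COM_INS = "COM_DEL", COM_DEL = "COM_INS")[v$variant_class]
  if (is.na(swap_class)) stop("swap_reference: not a large InDel")
  out <- v
  out$variant_class <- unname(swap_class)
  out$ref_chrom <- v$qry_chrom; out$qry_chrom <- v$ref_chrom
  out$ref_start <- v$qry_start; out$qry_start <- v$ref_start
  out$ref_end <- v$qry_end; out$qry_end <- v$ref_end
  out$ref_allele <- v$alt_allele; out$alt_allele <- v$ref_allele
  out
}

#' Summarise read-depth support per variant class
#'
#' @param calls Data.frame of support calls (one per variant).
#' @param variants The corresponding variant data.frame.
#' @return Data.frame: class, n, n_supported, fraction.
#' @export
support_summary <- function(calls, variants) {
  m <- merge(calls, variants[, c("id", "variant_class")],
             by.x = "variant_id", by.y = "id")
  out <- do.call(rbind, lapply(split(m, m$variant_class), function(g)
    data.frame(variant_class = g$variant_class[1], n = nrow(g),
               n_supported = sum(g$rd_supported),
               fraction = mean(g$rd_supported), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
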