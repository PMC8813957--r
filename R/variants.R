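#' Classify a variant by allele lengths
#'
#' The 50 bp size boundary separates small InDels from SVs; 50 bp itself
#' belongs to the SV class. Pure InDels (one allele empty) have exact
#' breakpoints by construction and are canonical at or above 50 bp.
#' Replacements (both alleles non-empty, unequal length) are complex at or
#' above 50 bp and are classified as small InDels by net length change below
#' it. Equal-length mismatches longer than 1 bp are decomposed into
#' single-base SNPs by the diff layer and are rejected here.
#'
#' @param ref_len,alt_len Allele lengths in bp (not both 0).
#' @param precise Whether the breakpoints are exact (complex calls are not).
#' @return One of `"SNP"`, `"SMALL_INS"`, `"SMALL_DEL"`, `"CAN_INS"`,
#'   `"CAN_DEL"`, `"COM_INS"`, `"COM_DEL"`.
#' @export
classify_variant <- function(ref_len, alt_len, precise = TRUE) {
  stopifnot(length(ref_len) == length(alt_len))
  if (any(ref_len < 0 | alt_len < 0)) stop("negative allele length")
  if (any(ref_len == 0 & alt_len == 0)) stop("both allele lengths are zero")
  if (any(ref_len == alt_len & ref_len > 1L))
    stop("equal-length alleles > 1 bp: decompose into SNPs upstream")
  precise <- rep_len(precise, length(ref_len))
  mx <- pmax(ref_len, alt_len)
  mn <- pmin(ref_len, alt_len)
  ins <- alt_len > ref_len
  out <- character(length(ref_len))
  out[ref_len == 1L & alt_len == 1L] <- "SNP"
  small <- mx < SV_SIZE_MIN & out == ""
  out[small & ins] <- "SMALL_INS"
  out[small & !ins] <- "SMALL_DEL"
  large <- mx >= SV_SIZE_MIN & out == ""
  canon <- large & (mn == 0L) & precise
  out[canon & ins] <- "CAN_INS"
  out[canon & !ins] <- "CAN_DEL"
  compl <- large & out == ""
  out[compl & ins] <- "COM_INS"
  out[compl & !ins] <- "COM_DEL"
  out
}

empty_variants <- function() {
  data.frame(id = character(), variant_class = character(),
             ref_chrom = character(), ref_start = integer(),
             ref_end = integer(), ref_allele = character(),
             alt_allele = character(), qry_chrom = character(),
             qry_start = integer(), qry_end = integer(),
             strand = character(), precise = logical(),
             accession_id = character(), stringsAsFactors = FALSE)
}

#' Turn raw difference pairs into classified variant records
#'
#' @param pairs Difference pairs from [diff_block()] with `ref_chrom` /
#'   `qry_chrom` columns added.
#' @param accession_id Accession the query assembly belongs to.
#' @return Variant data.frame (unnormalised; see [left_align_variants()]).
#' @export
extract_variants <- function(pairs, accession_id = "qry") {
  if (is.null(pairs) || !nrow(pairs)) return(empty_variants())
  rl <- nchar(pairs$ref_seg); al <- nchar(pairs$qry_seg)
  precise <- pmin(rl, al) == 0L | (rl == 1L & al == 1L)
  cls <- classify_variant(rl, al, precise)
  data.frame(id = NA_character_, variant_class = cls,
             ref_chrom = pairs$ref_chrom,
             ref_start = pairs$ref_start, ref_end = pairs$ref_end,
             ref_allele = pairs$ref_seg, alt_allele = pairs$qry_seg,
             qry_chrom = pairs$qry_chrom,
             qry_start = pairs$qry_start, qry_end = pairs$qry_end,
             strand = pairs$strand, precise = precise,
             accession_id = accession_id, stringsAsFactors = FALSE)
}

#' Assign identifiers following the SV_{TYPE}_{chrom}G{index} scheme
#'
#' SV classes get the `SV_` prefix with tokens INS/DEL/COMINS/COMDEL/INV/
#' TRANS; SNPs and small InDels get `VAR_` with tokens SNP/SINS/SDEL. The
#' index is assigned per (token, chromosome) in reference-sorted order, in
#' steps of 10, zero-padded to 6 digits.
#'
#' @param variants Variant (or truth) data.frame.
#' @return Character vector of ids, parallel to the rows.
#' @export
variant_ids <- function(variants) {
  token <- c(SNP = "VAR_SNP", SMALL_INS = "VAR_SINS", SMALL_DEL = "VAR_SDEL",
             CAN_INS = "SV_INS", CAN_DEL = "SV_DEL",
             COM_INS = "SV_COMINS", COM_DEL = "SV_COMDEL",
             INV = "SV_INV", TRANS = "SV_TRANS")[variants$variant_class]
  chrom_num <- sub("^[^0-9]*", "", variants$ref_chrom)
  key <- paste(token, chrom_num)
  ids <- character(nrow(variants))
  for (k in unique(key)) {
    sel <- which(key == k)
    ord <- order(variants$ref_start[sel])
    ids[sel[ord]] <- sprintf("%s_%sG%06d", token[sel][1],
                             chrom_num[sel][1], 10L * seq_along(sel))
  }
  ids
}

#' Left-align pure InDels against the reference
#'
#' Shifts insertion/deletion breakpoints to their leftmost equivalent
#' position (repeat-context normalisation), so that calls and truth compare
#' exactly. SNPs, complex variants, inversions and translocations are
#' returned unchanged.
#'
#' @param variants Variant data.frame.
#' @param genome Reference `pansv_genome`.
#' @return The data.frame with normalised `ref_start`/`ref_end` and alleles.
#' @export
left_align_variants <- function(variants, genome) {
  for (i in seq_len(nrow(variants))) {
    rl <- nchar(variants$ref_allele[i]); al <- nchar(variants$alt_allele[i])
    if (min(rl, al) != 0L || max(rl, al) == 0L) next
    chrom <- genome$chromosomes[[variants$ref_chrom[i]]]
    s <- variants$ref_start[i]
    allele <- if (rl > 0L) variants$ref_allele[i] else variants$alt_allele[i]
    n <- nchar(allele)
    shift <- 0L
    while (s - shift > 0L &&
           substr(chrom, s - shift, s - shift) ==
           substr(allele, n - (shift %% n), n - (shift %% n))) {
      shift <- shift + 1L
    }
    if (shift > 0L) {
      s2 <- s - shift
      if (rl > 0L) {
        variants$ref_start[i] <- s2
        variants$ref_end[i] <- s2 + rl
        variants$ref_allele[i] <- substr(chrom, s2 + 1L, s2 + rl)
      } else {
        variants$ref_start[i] <- s2
        variants$ref_end[i] <- s2
        rot <- shift %% n
        if (rot > 0L)
          allele <- paste0(substr(allele, n - rot + 1L, n),
                           substr(allele, 1L, n - rot))
        variants$alt_allele[i] <- allele
      }
      variants$qry_start[i] <- variants$qry_start[i] - shift
      variants$qry_end[i] <- variants$qry_end[i] - shift
    }
  }
  variants
}

#' Refine complex breakpoints by flank re-alignment
#'
#' For complex calls, first trims shared allele prefixes/suffixes; if the
#' pair reduces to a pure InDel it is promoted to the canonical (or small)
#' class. Otherwise the alleles are re-aligned in 1 kb reference flank
#' context; when the global alignment consists of exact matches plus exactly
#' one contiguous gap in one sequence, the variant is re-emitted as canonical
#' with updated coordinates. Allele content is conserved: applying the
#' refined variant to the reference yields the same query sequence.
#' Refining a canonical variant is a no-op; promotions never drop variants.
#'
#' @param variants Variant data.frame.
#' @param ref_genome Reference `pansv_genome` (flank source).
#' @param flank Flank length in bp (default 1000; truncated at chromosome
#'   ends).
#' @return The data.frame with refined rows updated.
#' @export
refine_breakpoints <- function(variants, ref_genome, flank = 1000L) {
  for (i in seq_len(nrow(variants))) {
    if (!variants$variant_class[i] %in% c("COM_INS", "COM_DEL")) next
    ra <- variants$ref_allele[i]; aa <- variants$alt_allele[i]
    l <- lcp_len(ra, aa)
    t <- lcs_len(ra, aa, min(nchar(ra), nchar(aa)) - l)
    ra2 <- substr(ra, l + 1L, nchar(ra) - t)
    aa2 <- substr(aa, l + 1L, nchar(aa) - t)
    if (nchar(ra2) == 0L || nchar(aa2) == 0L) {
      # clean InDel after trimming: promote
      variants$ref_start[i] <- variants$ref_start[i] + l
      variants$ref_end[i] <- variants$ref_end[i] - t
      variants$qry_start[i] <- variants$qry_start[i] + l
      variants$qry_end[i] <- variants$qry_end[i] - t
      variants$ref_allele[i] <- ra2
      variants$alt_allele[i] <- aa2
      variants$precise[i] <- TRUE
      variants$variant_class[i] <- classify_variant(nchar(ra2), nchar(aa2),
                                                    TRUE)
      next
    }
    chrom <- ref_genome$chromosomes[[variants$ref_chrom[i]]]
    s <- variants$ref_start[i]; e <- variants$ref_end[i]
    lf <- substr(chrom, max(1L, s - flank + 1L), s)
    rf <- substr(chrom, e + 1L, min(nchar(chrom), e + flank))
    s1 <- paste0(lf, ra, rf)
    s2 <- paste0(lf, aa, rf)
    aln <- Biostrings::pairwiseAlignment(s1, s2, type = "global")
    p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    q <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    gap_p <- p == "-"; gap_q <- q == "-"
    mism <- !gap_p & !gap_q & p != q
    one_gap_run <- function(g) {
      r <- rle(g)
      sum(r$values) == 1L
    }
    clean <- !any(mism) &&
      ((any(gap_p) && !any(gap_q) && one_gap_run(gap_p)) ||
       (any(gap_q) && !any(gap_p) && one_gap_run(gap_q)))
    if (!clean) next
    g <- if (any(gap_p)) gap_p else gap_q
    gs <- which(g)[1] - 1L           # columns before the gap
    glen <- sum(g)
    pos0 <- s - nchar(lf)            # 0-based ref position of s1 start
    if (any(gap_q)) {                # gap in query: deletion from reference
      ds <- pos0 + gs
      variants$ref_start[i] <- ds
      variants$ref_end[i] <- ds + glen
      variants$ref_allele[i] <- substr(chrom, ds + 1L, ds + glen)
      variants$alt_allele[i] <- ""
      variants$qry_end[i] <- variants$qry_start[i]
    } else {                         # gap in reference pattern: insertion
      ins <- paste(q[g], collapse = "")
      ds <- pos0 + gs
      variants$ref_start[i] <- ds
      variants$ref_end[i] <- ds
      variants$ref_allele[i] <- ""
      variants$alt_allele[i] <- ins
    }
    variants$precise[i] <- TRUE
    variants$variant_class[i] <- classify_variant(
      nchar(variants$ref_allele[i]), nchar(variants$alt_allele[i]), TRUE)
  }
  variants
}

#' Exclude SVs containing unknown (N) sequence
#'
#' @param variants Variant data.frame.
#' @return Retained variants; per-class removal counts in
#'   `attr(, "removed")`.
#' @export
filter_n_content <- function(variants) {
  is_sv <- variants$variant_class %in% c(LARGE_INDEL_CLASSES, "INV", "TRANS")
  has_n <- grepl("N", variants$ref_allele, fixed = TRUE) |
    grepl("N", variants$alt_allele, fixed = TRUE)
  drop <- is_sv & has_n
  out <- variants[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- table(variants$variant_class[drop])
  out
}

#' Mask variants at assembly-error positions
#'
#' A self-call (a homozygous variant seen when mapping an accession's reads
#' back to its own assembly) qualifies as evidence of an assembly error when
#' base quality > 20, mapping quality > 30 and 2 < read depth < 200;
#' variants whose reference footprint contains a qualifying self-call
#' position are removed.
#'
#' @param variants Variant data.frame.
#' @param self_calls Data.frame with `chrom`, `pos` (0-based), `base_q`,
#'   `map_q`, `depth`.
#' @return Retained variants; removal count in `attr(, "n_masked")`.
#' @export
mask_assembly_errors <- function(variants, self_calls) {
  if (is.null(self_calls) || !nrow(self_calls)) {
    attr(variants, "n_masked") <- 0L
    return(variants)
  }
  q <- self_calls[self_calls$base_q > 20 & self_calls$map_q > 30 &
                  self_calls$depth > 2 & self_calls$depth < 200, ,
                  drop = FALSE]
  if (!nrow(q)) {
    attr(variants, "n_masked") <- 0L
    return(variants)
  }
  hit <- vapply(seq_len(nrow(variants)), function(i) {
    w <- max(1L, variants$ref_end[i] - variants$ref_start[i])
    any(q$chrom == variants$ref_chrom[i] &
        q$pos >= variants$ref_start[i] &
        q$pos < variants$ref_start[i] + w)
  }, logical(1))
  out <- variants[!hit, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_masked") <- sum(hit)
  out
}

#' Detect microhomology at deletion breakpoints
#'
#' Reports the longest exact sequence shared by the two junctions of a
#' deletion: right homology is the longest k with
#' `ref[start, start+k) == ref[end, end+k)`, left homology the analogous
#' shared suffix; the maximum of the two is reported with its sequence.
#' Homology length is capped at `min(deletion span, max_len)`; k = 0 is a
#' valid result.
#'
#' @param deletion One canonical-deletion row of a variant data.frame.
#' @param ref_seq Reference chromosome sequence the deletion lies on.
#' @param max_len Maximum homology length considered (default 25 bp).
#' @return Data.frame: `variant_id`, `homology_seq`, `homology_len`, `side`.
#' @export
detect_microhomology <- function(deletion, ref_seq, max_len = 25L) {
  stopifnot(deletion$variant_class[1] %in% c("CAN_DEL"))
  s <- deletion$ref_start[1]; e <- deletion$ref_end[1]
  span <- e - s
  cap <- min(span, max_len, nchar(ref_seq) - e, s)
  right <- lcp_len(substr(ref_seq, s + 1L, s + cap),
                   substr(ref_seq, e + 1L, e + cap))
  left <- lcs_len(substr(ref_seq, s - cap + 1L, s),
                  substr(ref_seq, e - cap + 1L, e), cap)
  len <- max(right, left)
  side <- if (len == 0L) "none"
    else if (right == left) "both"
    else if (right > left) "right" else "left"
  seq <- if (len == 0L) ""
    else if (right >= left) substr(ref_seq, s + 1L, s + len)
    else substr(ref_seq, s - len + 1L, s)
  data.frame(variant_id = if (!is.null(deletion$id)) deletion$id[1]
             else NA_character_,
             homology_seq = seq, homology_len = len, side = side,
             stringsAsFactors = FALSE)
}

#' Annotate variants with gene context and coding consequence
#'
#' Labels each variant `CDS-SV` (overlaps a coding interval), `promoter-SV`
#' (within `promoter_window` bp upstream of the TSS on the gene's strand),
#' `intron-SV` (inside the gene span but not the CDS) or `intergenic`. For
#' CDS InDels, a length-L change with L mod 3 = 0 placed at a codon boundary
#' is in-frame (amino-acid gain/loss of L/3); anything else is a frameshift.
#'
#' @param variants Variant data.frame.
#' @param genes Data.frame with `gene_id`, `chrom`, `strand`, `gene_start`,
#'   `gene_end`, `cds_start`, `cds_end` (0-based half-open).
#' @param promoter_window Promoter window upstream of the TSS (default 3000).
#' @param ref_genome Optional genome for bounds checking.
#' @return The variants with `context`, `gene_id`, `consequence`,
#'   `aa_change` columns added.
#' @export
annotate_gene_overlap <- function(variants, genes, promoter_window = 3000L,
                                  ref_genome = NULL) {
  if (!is.null(ref_genome)) {
    len <- nchar(ref_genome$chromosomes)[variants$ref_chrom]
    if (any(is.na(len)) || any(variants$ref_end > len) ||
        any(variants$ref_start < 0L))
      stop("variant beyond chromosome bounds")
  }
  variants$context <- "intergenic"
  variants$gene_id <- NA_character_
  variants$consequence <- NA_character_
  variants$aa_change <- NA_integer_
  for (i in seq_len(nrow(variants))) {
    s <- variants$ref_start[i]
    e <- max(variants$ref_end[i], s + 1L)   # insertions: anchor point
    g <- genes[genes$chrom == variants$ref_chrom[i], , drop = FALSE]
    if (!nrow(g)) next
    cds_hit <- which(s < g$cds_end & e > g$cds_start)
    prom_hit <- which(
      (g$strand == "+" & e > g$gene_start - promoter_window &
         s < g$gene_start) |
      (g$strand == "-" & s < g$gene_end + promoter_window &
         e > g$gene_end))
    gene_hit <- which(s < g$gene_end & e > g$gene_start)
    if (length(cds_hit)) {
      j <- cds_hit[1]
      variants$context[i] <- "CDS-SV"
      variants$gene_id[i] <- g$gene_id[j]
      rl <- nchar(variants$ref_allele[i]); al <- nchar(variants$alt_allele[i])
      if (min(rl, al) == 0L && max(rl, al) > 0L) {
        L <- max(rl, al)
        codon_aligned <- if (g$strand[j] == "+")
          (s - g$cds_start[j]) %% 3L == 0L
        else (g$cds_end[j] - e) %% 3L == 0L
        if (L %% 3L == 0L && codon_aligned) {
          variants$consequence[i] <- if (rl > al) "in_frame_aa_loss"
            else "in_frame_aa_gain"
          variants$aa_change[i] <- L %/% 3L
        } else {
          variants$consequence[i] <- "frameshift"
        }
      }
    } else if (length(prom_hit)) {
      variants$context[i] <- "promoter-SV"
      variants$gene_id[i] <- g$gene_id[prom_hit[1]]
    } else if (length(gene_hit)) {
      variants$context[i] <- "intron-SV"
      variants$gene_id[i] <- g$gene_id[gene_hit[1]]
    }
  }
  variants
}

#' Call variants between a query assembly and the reference
#'
#' End-to-end assembly-vs-reference discovery: anchor alignment, one-to-one
#' filtering, collinear-block chaining, rearrangement detection, in-block
#' diffing, classification, complex-breakpoint refinement, N filtering,
#' left-alignment and id assignment. InDel echoes of detected translocations
#' (the deletion at the source and the insertion at the destination) are
#' suppressed so each rearrangement is reported once.
#'
#' @param ref_genome,qry_genome `pansv_genome` objects.
#' @param wordsize In-block word size (default 10).
#' @param self_calls Optional assembly-error evidence for
#'   [mask_assembly_errors()].
#' @param ... Passed to [align_genomes()].
#' @return List: `variants` (incl. INV/TRANS records), `blocks`,
#'   `rearrangements`.
#' @export
call_variants <- function(ref_genome, qry_genome, wordsize = 10L,
                          self_calls = NULL, ...) {
  aln <- align_genomes(ref_genome, qry_genome, ...)
  rearr <- detect_rearrangements(aln$blocks, ref_genome = ref_genome)
  acc <- qry_genome$accession_id
  vars <- list()
  for (i in seq_len(nrow(aln$blocks))) {
    b <- aln$blocks[i, ]
    pr <- diff_block(b, ref_genome$chromosomes[[b$ref_chrom]],
                     qry_genome$chromosomes[[b$qry_chrom]], wordsize)
    if (!nrow(pr)) next
    pr$ref_chrom <- b$ref_chrom
    pr$qry_chrom <- b$qry_chrom
    vars[[length(vars) + 1L]] <- extract_variants(pr, acc)
  }
  v <- if (length(vars)) do.call(rbind, vars) else empty_variants()
  v <- refine_breakpoints(v, ref_genome)
  v <- left_align_variants(v, ref_genome)
  # suppress InDel echoes of translocations: a deletion matching a source
  # interval, or an insertion whose allele is the translocated segment
  tra <- rearr$translocations
  if (nrow(tra) && nrow(v)) {
    seg_seqs <- vapply(seq_len(nrow(tra)), function(i)
      substr(ref_genome$chromosomes[[tra$ref_chrom[i]]],
             tra$ref_start[i] + 1L, tra$ref_end[i]), character(1))
    del_echo <- v$alt_allele == "" & vapply(seq_len(nrow(v)), function(i)
      any(tra$ref_chrom == v$ref_chrom[i] &
          abs(tra$ref_start - v$ref_start[i]) <= 25L &
          abs(tra$ref_end - v$ref_end[i]) <= 25L), logical(1))
    seg_len <- nchar(seg_seqs)
    ins_echo <- v$ref_allele == "" & vapply(seq_len(nrow(v)), function(i) {
      al <- nchar(v$alt_allele[i])
      any(abs(seg_len - al) <= 50L &
          vapply(seg_seqs, function(s)
            grepl(v$alt_allele[i], s, fixed = TRUE) ||
            grepl(s, v$alt_allele[i], fixed = TRUE), logical(1)))
    }, logical(1))
    v <- v[!(del_echo | ins_echo), , drop = FALSE]
  }
  # rearrangement records
  inv_all <- rbind(rearr$inversions, rearr$megabase_inversions)
  if (nrow(inv_all)) {
    iv <- data.frame(id = NA_character_, variant_class = "INV",
                     ref_chrom = inv_all$ref_chrom,
                     ref_start = inv_all$ref_start,
                     ref_end = inv_all$ref_end,
                     ref_allele = "", alt_allele = "",
                     qry_chrom = inv_all$qry_chrom,
                     qry_start = inv_all$qry_start,
                     qry_end = inv_all$qry_end,
                     strand = "-", precise = FALSE, accession_id = acc,
                     stringsAsFactors = FALSE)
    v <- rbind(v, iv)
  }
  if (nrow(tra)) {
    tv <- data.frame(id = NA_character_, variant_class = "TRANS",
                     ref_chrom = tra$ref_chrom, ref_start = tra$ref_start,
                     ref_end = tra$ref_end, ref_allele = "", alt_allele = "",
                     qry_chrom = tra$qry_chrom, qry_start = tra$qry_start,
                     qry_end = tra$qry_end, strand = "+", precise = FALSE,
                     accession_id = acc, stringsAsFactors = FALSE)
    v <- rbind(v, tv)
  }
  v <- filter_n_content(v)
  if (!is.null(self_calls)) v <- mask_assembly_errors(v, self_calls)
  # deduplicate identical calls from adjacent blocks
  key <- paste(v$ref_chrom, v$ref_start, v$ref_end, v$alt_allele)
  v <- v[!duplicated(key), , drop = FALSE]
  v <- v[order(v$ref_chrom, v$ref_start), , drop = FALSE]
  rownames(v) <- NULL
  if (nrow(v)) v$id <- variant_ids(v)
  list(variants = v, blocks = aln$blocks, rearrangements = rearr)
}

#' Compare called variants with simulator truth
#'
#' SNPs, small InDels and canonical SVs are matched exactly on
#' (class, chromosome, start, end, alt allele) after left-alignment of both
#' sets; complex SVs, inversions and translocations are matched by class and
#' breakpoints within `slop` bp.
#'
#' @param called Variant data.frame from [call_variants()].
#' @param truth Truth table (left-aligned against the same reference).
#' @param slop Breakpoint tolerance for imprecise classes (default 20 bp).
#' @return Data.frame of per-class-group recall/precision plus counts; the
#'   per-truth-row match indicator is attached as `attr(, "truth_matched")`.
#' @export
evaluate_calls <- function(called, truth, slop = 20L) {
  grp <- function(cls) {
    ifelse(cls == "SNP", "snp",
    ifelse(cls %in% c("SMALL_INS", "SMALL_DEL"), "small_indel",
    ifelse(cls %in% c("CAN_INS", "CAN_DEL"), "canonical",
    ifelse(cls %in% c("COM_INS", "COM_DEL"), "complex",
    ifelse(cls == "INV", "inversion", "translocation")))))
  }
  called$grp <- grp(called$variant_class)
  truth$grp <- grp(truth$variant_class)
  exact_grp <- c("snp", "small_indel", "canonical")
  truth_matched <- logical(nrow(truth))
  called_matched <- logical(nrow(called))
  for (i in seq_len(nrow(truth))) {
    if (truth$grp[i] %in% exact_grp) {
      hit <- which(!called_matched & called$grp == truth$grp[i] &
        called$ref_chrom == truth$ref_chrom[i] &
        called$ref_start == truth$ref_start[i] &
        called$ref_end == truth$ref_end[i] &
        called$alt_allele == truth$alt_allele[i])
    } else if (truth$grp[i] == "complex") {
      hit <- which(!called_matched & called$grp == "complex" &
        called$ref_chrom == truth$ref_chrom[i] &
        abs(called$ref_start - truth$ref_start[i]) <= slop &
        abs(called$ref_end - truth$ref_end[i]) <= slop)
    } else {
      hit <- which(!called_matched & called$grp == truth$grp[i] &
        called$ref_chrom == truth$ref_chrom[i] &
        abs(called$ref_start - truth$ref_start[i]) <= slop &
        abs(called$ref_end - truth$ref_end[i]) <= slop)
    }
    if (length(hit)) {
      truth_matched[i] <- TRUE
      called_matched[hit[1]] <- TRUE
    }
  }
  groups <- unique(c(truth$grp, called$grp))
  out <- do.call(rbind, lapply(groups, function(g) {
    nt <- sum(truth$grp == g); nc <- sum(called$grp == g)
    data.frame(group = g, n_truth = nt, n_called = nc,
               recall = if (nt) sum(truth_matched[truth$grp == g]) / nt
                        else NA_real_,
               precision = if (nc) sum(called_matched[called$grp == g]) / nc
                           else NA_real_,
               stringsAsFactors = FALSE)
  }))
  attr(out, "truth_matched") <- truth_matched
  out
}
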