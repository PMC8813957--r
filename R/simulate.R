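#' Simulate a multi-chromosome reference genome
#'
#' Generates i.i.d. random DNA with a target GC content. Chromosomes are named
#' `chr1 ... chrN`. Used as the stand-in reference against which derived
#' accessions, reads and population panels are simulated.
#'
#' @param n_chrom Number of chromosomes (>= 1).
#' @param chrom_length Length of each chromosome in bp (>= 10000).
#' @param gc Target GC fraction in (0, 1).
#' @param seed Integer seed; the genome is reproducible for a fixed seed.
#' @param accession_id Identifier stored with the genome.
#' @return A `pansv_genome`: list with `accession_id` and `chromosomes`
#'   (named character vector of DNA sequences).
#' @export
simulate_reference <- function(n_chrom, chrom_length, gc = 0.5, seed = 1L,
                               accession_id = "ref") {
  if (n_chrom < 1L) stop("n_chrom must be >= 1")
  if (chrom_length < 10000L) stop("chrom_length must be >= 10000")
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  set.seed(seed)
  chroms <- vapply(seq_len(n_chrom), function(i) random_dna(chrom_length, gc),
                   character(1))
  names(chroms) <- paste0("chr", seq_len(n_chrom))
  new_genome(accession_id, chroms)
}

new_genome <- function(accession_id, chromosomes) {
  stopifnot(!anyDuplicated(names(chromosomes)), all(nchar(chromosomes) > 0L))
  structure(list(accession_id = accession_id, chromosomes = chromosomes),
            class = "pansv_genome")
}

#' @export
print.pansv_genome <- function(x, ...) {
  cat(sprintf("pansv_genome '%s': %d chromosome(s), %s bp total\n",
              x$accession_id, length(x$chromosomes),
              format(sum(nchar(x$chromosomes)), big.mark = ",")))
  invisible(x)
}

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# uniform draw from [lo, hi]; avoids sample()'s length-1 surprise
sample_range <- function(lo, hi) {
  if (lo >= hi) return(as.integer(lo))
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Variant implantation specification
#'
#' Per-class counts and size ranges for [implant_variants()]. `size` refers to
#' the major allele (the inserted sequence for insertion classes, the deleted
#' reference segment for deletion classes, the inverted/translocated segment
#' for INV/TRANS). Complex classes additionally carry a minor-side range
#' (the shorter of the replaced/replacing pair).
#'
#' @param n_snp,n_small_ins,n_small_del,n_can_ins,n_can_del,n_com_ins,n_com_del,n_inv,n_trans
#'   Counts per variant class.
#' @param small_range,canonical_range,complex_major_range,inv_range,trans_range
#'   Inclusive size ranges (bp) for the major allele of each class.
#' @param complex_minor_range Size range of the complex minor side.
#' @return A data.frame with one row per class to be implanted.
#' @export
variant_spec <- function(n_snp = 0L, n_small_ins = 0L, n_small_del = 0L,
                         n_can_ins = 0L, n_can_del = 0L,
                         n_com_ins = 0L, n_com_del = 0L,
                         n_inv = 0L, n_trans = 0L,
                         small_range = c(1L, 49L),
                         canonical_range = c(50L, 1000L),
                         complex_major_range = c(60L, 800L),
                         complex_minor_range = c(10L, 40L),
                         inv_range = c(1000L, 100000L),
                         trans_range = c(2000L, 10000L)) {
  rng <- function(cls) switch(cls,
    SNP = c(1L, 1L),
    SMALL_INS = small_range, SMALL_DEL = small_range,
    CAN_INS = canonical_range, CAN_DEL = canonical_range,
    COM_INS = complex_major_range, COM_DEL = complex_major_range,
    INV = inv_range, TRANS = trans_range)
  counts <- c(SNP = n_snp, SMALL_INS = n_small_ins, SMALL_DEL = n_small_del,
              CAN_INS = n_can_ins, CAN_DEL = n_can_del,
              COM_INS = n_com_ins, COM_DEL = n_com_del,
              INV = n_inv, TRANS = n_trans)
  counts <- counts[counts > 0L]
  if (!length(counts)) stop("variant_spec: all counts are zero")
  out <- do.call(rbind, lapply(names(counts), function(cls) {
    r <- rng(cls)
    data.frame(variant_class = cls, count = as.integer(counts[[cls]]),
               min_size = r[1], max_size = r[2],
               minor_min = complex_minor_range[1],
               minor_max = complex_minor_range[2],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

empty_truth <- function() {
  data.frame(accession_id = character(), variant_class = character(),
             ref_chrom = character(), ref_start = integer(),
             ref_end = integer(), ref_allele = character(),
             alt_allele = character(), dest_chrom = character(),
             dest_pos = integer(), qry_chrom = character(),
             qry_start = integer(), qry_end = integer(),
             stringsAsFactors = FALSE)
}

#' Implant variants into a reference genome
#'
#' Places the requested numbers of SNPs, small InDels, canonical and complex
#' large InDels, inversions and translocations at random non-overlapping
#' positions (rejection sampling with a minimum inter-variant spacing so that
#' in-block diffing is unambiguous), applies them, and records the truth in
#' both reference and derived coordinates. Placement avoids N runs and
#' chromosome ends.
#'
#' @param reference A `pansv_genome`.
#' @param spec Data.frame from [variant_spec()].
#' @param seed Integer seed.
#' @param min_spacing Minimum distance in bp between reference footprints of
#'   distinct variants (default 500).
#' @param edge_buffer Distance kept free at chromosome ends (default 2000 bp).
#' @param accession_id Identifier of the derived accession.
#' @return List with `genome` (the derived `pansv_genome`) and `truth`
#'   (data.frame of truth variants; 0-based half-open reference intervals,
#'   derived coordinates in `qry_*` columns).
#' @export
implant_variants <- function(reference, spec, seed = 1L, min_spacing = 500L,
                             edge_buffer = 2000L, accession_id = "derived") {
  set.seed(seed)
  chroms <- reference$chromosomes
  chrom_names <- names(chroms)
  chrom_len <- nchar(chroms)
  # occupied reference intervals per chromosome (including spacing)
  occupied <- lapply(chrom_names, function(x)
    IRanges::IRanges(start = integer(), width = integer()))
  names(occupied) <- chrom_names

  place <- function(footprint, cls) {
    # returns c(chrom_index, start0) for a free slot, or errors
    for (try in seq_len(2000L)) {
      ci <- sample.int(length(chroms), 1L,
                       prob = pmax(chrom_len - 2 * edge_buffer - footprint, 1))
      lo <- edge_buffer
      hi <- chrom_len[ci] - edge_buffer - footprint
      if (hi <= lo) next
      s <- lo + sample.int(hi - lo, 1L)  # 0-based start
      cand <- IRanges::IRanges(start = s + 1L - min_spacing,
                               width = footprint + 2L * min_spacing)
      if (length(IRanges::findOverlaps(cand, occupied[[ci]])) > 0L) next
      seg <- substr(chroms[[ci]], s + 1L, s + max(footprint, 1L))
      if (grepl("N", seg, fixed = TRUE)) next
      occupied[[ci]] <<- c(occupied[[ci]],
                           IRanges::IRanges(start = s + 1L,
                                            width = max(footprint, 1L)))
      return(c(ci, s))
    }
    stop(sprintf("implant_variants: could not place a %s variant; density too high",
                 cls))
  }

  rows <- list()
  for (i in seq_len(nrow(spec))) {
    cls <- spec$variant_class[i]
    for (j in seq_len(spec$count[i])) {
      size <- sample_range(spec$min_size[i], spec$max_size[i])
      if (cls == "SNP") {
        p <- place(1L, cls)
        ref_base <- substr(chroms[[p[1]]], p[2] + 1L, p[2] + 1L)
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref_base), 1L)
        rows[[length(rows) + 1L]] <- list(cls, chrom_names[p[1]], p[2],
                                          p[2] + 1L, ref_base, alt, NA, NA)
      } else if (cls %in% c("SMALL_INS", "CAN_INS")) {
        p <- place(0L, cls)
        rows[[length(rows) + 1L]] <- list(cls, chrom_names[p[1]], p[2], p[2],
                                          "", random_dna(size), NA, NA)
      } else if (cls %in% c("SMALL_DEL", "CAN_DEL")) {
        p <- place(size, cls)
        rows[[length(rows) + 1L]] <- list(cls, chrom_names[p[1]], p[2],
                                          p[2] + size,
                                          substr(chroms[[p[1]]], p[2] + 1L,
                                                 p[2] + size), "", NA, NA)
      } else if (cls %in% c("COM_INS", "COM_DEL")) {
        minor <- sample_range(spec$minor_min[i], spec$minor_max[i])
        if (minor >= size) minor <- max(1L, size - 1L)
        ref_len <- if (cls == "COM_INS") minor else size
        alt_len <- if (cls == "COM_INS") size else minor
        p <- place(ref_len, cls)
        rows[[length(rows) + 1L]] <- list(cls, chrom_names[p[1]], p[2],
                                          p[2] + ref_len,
                                          substr(chroms[[p[1]]], p[2] + 1L,
                                                 p[2] + ref_len),
                                          random_dna(alt_len), NA, NA)
      } else if (cls == "INV") {
        p <- place(size, cls)
        seg <- substr(chroms[[p[1]]], p[2] + 1L, p[2] + size)
        rows[[length(rows) + 1L]] <- list(cls, chrom_names[p[1]], p[2],
                                          p[2] + size, seg, revcomp(seg),
                                          NA, NA)
      } else if (cls == "TRANS") {
        if (length(chroms) < 2L)
          stop("implant_variants: TRANS requires >= 2 chromosomes")
        p <- place(size, cls)
        repeat {
          d <- place(0L, cls)
          if (d[1] != p[1]) break
        }
        seg <- substr(chroms[[p[1]]], p[2] + 1L, p[2] + size)
        rows[[length(rows) + 1L]] <- list(cls, chrom_names[p[1]], p[2],
                                          p[2] + size, seg, seg,
                                          chrom_names[d[1]], d[2])
      }
    }
  }
  truth <- do.call(rbind, lapply(rows, function(r)
    data.frame(accession_id = accession_id, variant_class = r[[1]],
               ref_chrom = r[[2]], ref_start = r[[3]], ref_end = r[[4]],
               ref_allele = r[[5]], alt_allele = r[[6]],
               dest_chrom = as.character(r[[7]]),
               dest_pos = as.integer(r[[8]]), stringsAsFactors = FALSE)))
  truth <- truth[order(match(truth$ref_chrom, chrom_names), truth$ref_start), ]
  rownames(truth) <- NULL
  res <- apply_variants(reference, truth, accession_id = accession_id)
  list(genome = res$genome, truth = res$truth)
}

#' Apply truth variants to a reference genome
#'
#' Rebuilds the derived genome by applying the truth table left-to-right and
#' computes derived (`qry_*`) coordinates for every variant. Translocations
#' are applied as a deletion at the source plus an insertion at the
#' destination. This is the reconstruction contract of the simulator: the
#' derived genome is, byte for byte, the reference with the truth applied.
#'
#' @param reference A `pansv_genome`.
#' @param truth Truth data.frame as produced by [implant_variants()] (the
#'   `qry_*` columns, if present, are recomputed).
#' @param accession_id Identifier of the derived genome.
#' @return List with `genome` and `truth` (with `qry_chrom`, `qry_start`,
#'   `qry_end` filled in).
#' @export
apply_variants <- function(reference, truth, accession_id = "derived") {
  chroms <- reference$chromosomes
  if (is.null(truth) || nrow(truth) == 0L) {
    t0 <- empty_truth()
    return(list(genome = new_genome(accession_id, chroms), truth = t0))
  }
  # expand TRANS into a delete edit (source) + insert edit (destination)
  edits <- list()
  for (i in seq_len(nrow(truth))) {
    v <- truth[i, ]
    if (v$variant_class == "TRANS") {
      edits[[length(edits) + 1L]] <- data.frame(
        chrom = v$ref_chrom, start = v$ref_start, end = v$ref_end,
        alt = "", truth_row = i, role = "trans_src", stringsAsFactors = FALSE)
      edits[[length(edits) + 1L]] <- data.frame(
        chrom = v$dest_chrom, start = v$dest_pos, end = v$dest_pos,
        alt = v$alt_allele, truth_row = i, role = "trans_dst",
        stringsAsFactors = FALSE)
    } else {
      edits[[length(edits) + 1L]] <- data.frame(
        chrom = v$ref_chrom, start = v$ref_start, end = v$ref_end,
        alt = v$alt_allele, truth_row = i, role = "main",
        stringsAsFactors = FALSE)
    }
  }
  edits <- do.call(rbind, edits)
  truth$qry_chrom <- NA_character_
  truth$qry_start <- NA_integer_
  truth$qry_end <- NA_integer_

  out <- chroms
  edits$qry_start <- NA_integer_
  edits$qry_end <- NA_integer_
  for (cn in names(chroms)) {
    sel <- which(edits$chrom == cn)
    if (!length(sel)) next
    sel <- sel[order(edits$start[sel])]
    e <- edits[sel, , drop = FALSE]
    if (any(e$start[-1] < e$end[-nrow(e)]))
      stop("apply_variants: overlapping edits on ", cn)
    seq0 <- chroms[[cn]]
    pieces <- character(0)
    cursor <- 0L   # 0-based position on reference
    offset <- 0L   # derived - reference coordinate shift so far
    for (k in seq_len(nrow(e))) {
      s <- e$start[k]; en <- e$end[k]; alt <- e$alt[k]
      ref_seg <- if (en > s) substr(seq0, s + 1L, en) else ""
      ti <- e$truth_row[k]
      if (e$role[k] == "main" &&
          !identical(ref_seg, truth$ref_allele[ti]))
        stop("apply_variants: ref_allele mismatch at ", cn, ":", s)
      pieces <- c(pieces, substr(seq0, cursor + 1L, s), alt)
      qs <- s + offset
      edits$qry_start[sel[k]] <- qs
      edits$qry_end[sel[k]] <- qs + nchar(alt)
      if (e$role[k] != "trans_src") {
        truth$qry_chrom[ti] <- cn
        truth$qry_start[ti] <- qs
        truth$qry_end[ti] <- qs + nchar(alt)
      }
      offset <- offset + nchar(alt) - (en - s)
      cursor <- en
    }
    pieces <- c(pieces, substr(seq0, cursor + 1L, nchar(seq0)))
    out[[cn]] <- paste(pieces, collapse = "")
  }
  edits$variant_class <- truth$variant_class[edits$truth_row]
  attr(truth, "edits") <- edits
  list(genome = new_genome(accession_id, out), truth = truth)
}

#' Simulate paired-end reads with truth placements
#'
#' Uniform fragment placement, fixed read length, Gaussian insert size,
#' substitution errors only. Each read records its true placement (0-based
#' start of each mate on the source genome's forward strand) so downstream
#' stages can use oracle mappings instead of a read aligner.
#'
#' @param genome A `pansv_genome`.
#' @param coverage Requested mean depth (fold, > 0).
#' @param read_len Read length in bp.
#' @param insert_mean,insert_sd Insert-size distribution (fragment length).
#' @param error_rate Per-base substitution error rate.
#' @param seed Integer seed.
#' @param mapq Mapping quality recorded for every placement.
#' @param baseq Base quality recorded for every read.
#' @return Data.frame with one row per pair: `read_id`, `chrom`, `start1`,
#'   `start2` (0-based forward-strand starts), `seq1`, `seq2` (R2 given as
#'   reverse complement, sequencer orientation), `mapq`, `baseq`.
#' @export
simulate_reads <- function(genome, coverage, read_len = 100L,
                           insert_mean = 300L, insert_sd = 30L,
                           error_rate = 0, seed = 1L, mapq = 60L, baseq = 40L) {
  if (coverage <= 0) stop("coverage must be > 0")
  min_len <- min(nchar(genome$chromosomes))
  if (!(read_len < insert_mean && insert_mean < min_len))
    stop("need read_len < insert_mean < min chromosome length")
  set.seed(seed)
  res <- lapply(names(genome$chromosomes), function(cn) {
    seq0 <- genome$chromosomes[[cn]]
    L <- nchar(seq0)
    n_pairs <- max(1L, round(coverage * L / (2 * read_len)))
    ins <- pmax(read_len + 1L, pmin(L,
            round(rnorm(n_pairs, insert_mean, insert_sd))))
    s <- floor(runif(n_pairs, 0, L - ins + 1))  # 0-based fragment start
    s1 <- s
    s2 <- s + ins - read_len
    seq1 <- substring(seq0, s1 + 1L, s1 + read_len)
    seq2 <- revcomp(substring(seq0, s2 + 1L, s2 + read_len))
    if (error_rate > 0) {
      seq1 <- add_sub_errors(seq1, error_rate)
      seq2 <- add_sub_errors(seq2, error_rate)
    }
    data.frame(read_id = sprintf("%s_%s_%06d", genome$accession_id, cn,
                                 seq_len(n_pairs)),
               chrom = cn, start1 = as.integer(s1), start2 = as.integer(s2),
               seq1 = seq1, seq2 = seq2, mapq = as.integer(mapq),
               baseq = as.integer(baseq), stringsAsFactors = FALSE)
  })
  reads <- do.call(rbind, res)
  attr(reads, "read_len") <- as.integer(read_len)
  attr(reads, "accession_id") <- genome$accession_id
  reads
}

add_sub_errors <- function(seqs, error_rate) {
  rl <- nchar(seqs[1])
  n_err <- rbinom(length(seqs), rl, error_rate)
  idx <- which(n_err > 0L)
  for (i in idx) {
    pos <- sample.int(rl, n_err[i])
    ch <- strsplit(seqs[i], "")[[1]]
    ch[pos] <- vapply(ch[pos], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Lift read placements between derived and reference coordinates
#'
#' Piecewise-constant offset map built from the truth table of one accession.
#' Placements that start inside sequence absent from the target genome
#' (inserted sequence when lifting to the reference; deleted sequence when
#' lifting to the derived genome) have no image and are dropped, mimicking
#' unmapped or clipped reads. Inversion interiors are mapped to the same
#' interval; translocated segments are dropped.
#'
#' @param reads Read data.frame from [simulate_reads()].
#' @param truth Truth table of the accession the reads came from (or of the
#'   carrier genome when lifting reference reads onto it).
#' @param direction `"to_reference"` (derived coords -> reference) or
#'   `"to_derived"`.
#' @return The read data.frame with `start1`/`start2` re-expressed in target
#'   coordinates; unmappable pairs removed.
#' @export
liftover_placements <- function(reads, truth,
                                direction = c("to_reference", "to_derived")) {
  direction <- match.arg(direction)
  edits <- attr(truth, "edits")
  if (is.null(edits)) {
    if (any(truth$variant_class == "TRANS"))
      stop("liftover with translocations needs the truth table produced by ",
           "implant_variants()/apply_variants()")
    edits <- data.frame(chrom = truth$ref_chrom, start = truth$ref_start,
                        end = truth$ref_end, truth_row = seq_len(nrow(truth)),
                        role = "main", qry_start = truth$qry_start,
                        qry_end = truth$qry_end,
                        variant_class = truth$variant_class,
                        stringsAsFactors = FALSE)
  }
  if (direction == "to_reference") {
    src_start <- edits$qry_start; src_end <- edits$qry_end
    dst_start <- edits$start; dst_end <- edits$end
  } else {
    src_start <- edits$start; src_end <- edits$end
    dst_start <- edits$qry_start; dst_end <- edits$qry_end
  }
  rl <- attr(reads, "read_len")
  if (is.null(rl)) rl <- nchar(reads$seq1[1])
  lift_one <- function(chrom, pos) {
    # pos: 0-based mate starts on source coords of one chromosome; returns
    # lifted chrom/start and clipped end (reads are clipped at the next
    # variant junction, as an aligner would soft-clip them)
    res <- data.frame(chrom = rep(chrom, length(pos)),
                      start = rep(NA_integer_, length(pos)),
                      end = rep(NA_integer_, length(pos)))
    sel <- which(edits$chrom == chrom)
    if (!length(sel)) {
      res$start <- pos; res$end <- pos + rl
      return(res)
    }
    o <- sel[order(src_start[sel])]
    ss <- src_start[o]; se <- src_end[o]
    ds <- dst_start[o]; de <- dst_end[o]
    i <- findInterval(pos, ss)
    clip <- rep(rl, length(pos))
    before <- i == 0L
    res$start[before] <- pos[before]
    clip[before] <- pmin(rl, ss[1] - pos[before])
    inside <- !before & pos < se[pmax(i, 1L)]
    after <- !before & !inside
    ia <- i[after]
    res$start[after] <- pos[after] - se[ia] + de[ia]
    nxt <- c(ss, Inf)[ia + 1L]
    clip[after] <- pmin(rl, nxt - pos[after])
    # inside a variant's source interval: inversions map to the same
    # interval; translocated segments map to their partner chromosome
    for (w in which(inside)) {
      j <- o[i[w]]
      ti <- edits$truth_row[j]
      off <- pos[w] - src_start[j]
      if (edits$variant_class[j] == "INV") {
        res$start[w] <- dst_start[j] + off
        clip[w] <- min(rl, src_end[j] - pos[w])
      } else if (edits$variant_class[j] == "TRANS") {
        if (direction == "to_reference" && edits$role[j] == "trans_dst") {
          res$chrom[w] <- truth$ref_chrom[ti]
          res$start[w] <- truth$ref_start[ti] + off
          clip[w] <- min(rl, src_end[j] - pos[w])
        } else if (direction == "to_derived" &&
                   edits$role[j] == "trans_src") {
          res$chrom[w] <- truth$qry_chrom[ti]
          res$start[w] <- truth$qry_start[ti] + off
          clip[w] <- min(rl, src_end[j] - pos[w])
        }
      }
    }
    res$end <- res$start + clip
    res
  }
  reads$end1 <- reads$start1 + rl
  reads$end2 <- reads$start2 + rl
  reads$chrom2 <- reads$chrom
  for (cn in unique(reads$chrom)) {
    k <- reads$chrom == cn
    l1 <- lift_one(cn, reads$start1[k])
    l2 <- lift_one(cn, reads$start2[k])
    reads$chrom[k] <- l1$chrom
    reads$start1[k] <- l1$start; reads$end1[k] <- l1$end
    reads$chrom2[k] <- l2$chrom
    reads$start2[k] <- l2$start; reads$end2[k] <- l2$end
  }
  # keep concordant mapped pairs
  out <- reads[!is.na(reads$start1) & !is.na(reads$start2) &
                 reads$chrom == reads$chrom2, , drop = FALSE]
  out$chrom2 <- NULL
  attr(out, "read_len") <- rl
  out
}

#' Simulate a two-group population panel
#'
#' Draws per-accession SV genotypes from group-specific allele frequencies,
#' builds each accession's personalized genome, simulates its read set, and
#' generates a per-tissue expression table with implanted fold-changes for
#' designated SV-linked genes. Truth genotypes are haploid-style
#' presence/absence by default (selfed inbred lines); `ploidy = 2` samples
#' two alleles per accession for the genotyper's heterozygous path.
#'
#' @param reference A `pansv_genome`.
#' @param truth_svs Truth table of candidate SV sites (non-overlapping).
#' @param n_wild,n_cultivated Group sizes (each >= 2).
#' @param p_wild,p_cult Per-site alt-allele frequencies (recycled to the
#'   number of sites).
#' @param coverage,read_len,insert_mean,error_rate Read-simulation settings;
#'   `coverage = 0` skips read generation.
#' @param expression_spec Optional data.frame (`gene_id`, `tissue`, `lfc`)
#'   of implanted cultivated-vs-wild log2 fold-changes.
#' @param genes Optional gene table (`gene_id` at minimum); defaults to the
#'   genes named in `expression_spec`.
#' @param tissues Tissue names for the expression table.
#' @param ploidy 1 (presence/absence) or 2.
#' @param seed Integer seed.
#' @return A `pansv_panel`: `accessions`, `sites`, `genotypes` (sites x
#'   accessions character matrix over ref/ref, ref/alt, alt/alt), `genomes`,
#'   `read_sets`, `truths` (per-accession applied truth tables), `expression`.
#' @export
simulate_population <- function(reference, truth_svs, n_wild, n_cultivated,
                                p_wild, p_cult, coverage = 0,
                                read_len = 100L, insert_mean = 300L,
                                error_rate = 0, expression_spec = NULL,
                                genes = NULL,
                                tissues = c("root", "stem", "leaf",
                                            "male_flower", "female_flower",
                                            "fruit", "tendril"),
                                ploidy = 1L, seed = 1L) {
  if (n_wild < 2L || n_cultivated < 2L) stop("group sizes must be >= 2")
  n_sites <- nrow(truth_svs)
  p_wild <- rep_len(p_wild, n_sites)
  p_cult <- rep_len(p_cult, n_sites)
  if (any(p_wild < 0 | p_wild > 1 | p_cult < 0 | p_cult > 1))
    stop("allele frequencies must be in [0, 1]")
  set.seed(seed)
  acc <- data.frame(
    accession_id = c(sprintf("wild_%02d", seq_len(n_wild)),
                     sprintf("cult_%02d", seq_len(n_cultivated))),
    group = rep(c("wild", "cultivated"), c(n_wild, n_cultivated)),
    subgroup = rep(c("Indian-wild", "cultivated"), c(n_wild, n_cultivated)),
    stringsAsFactors = FALSE)
  site_ids <- variant_ids(truth_svs)
  geno <- matrix("ref/ref", nrow = n_sites, ncol = nrow(acc),
                 dimnames = list(site_ids, acc$accession_id))
  for (j in seq_len(nrow(acc))) {
    p <- if (acc$group[j] == "wild") p_wild else p_cult
    n_alt <- rbinom(n_sites, ploidy, p)
    idx <- if (ploidy == 1L) ifelse(n_alt > 0L, 3L, 1L) else n_alt + 1L
    geno[, j] <- c("ref/ref", "ref/alt", "alt/alt")[idx]
  }
  acc_seeds <- sample.int(.Machine$integer.max - 1L, nrow(acc))
  genomes <- vector("list", nrow(acc)); names(genomes) <- acc$accession_id
  truths <- genomes; read_sets <- genomes
  for (j in seq_len(nrow(acc))) {
    carried <- geno[, j] != "ref/ref"
    res <- apply_variants(reference, truth_svs[carried, , drop = FALSE],
                          accession_id = acc$accession_id[j])
    genomes[[j]] <- res$genome
    truths[[j]] <- res$truth
    if (coverage > 0)
      read_sets[[j]] <- simulate_reads(res$genome, coverage,
                                       read_len = read_len,
                                       insert_mean = insert_mean,
                                       error_rate = error_rate,
                                       seed = acc_seeds[j])
  }
  expr <- NULL
  if (!is.null(expression_spec) || !is.null(genes)) {
    gene_ids <- unique(c(expression_spec$gene_id, genes$gene_id))
    base <- setNames(runif(length(gene_ids), 5, 50), gene_ids)
    expr <- expand.grid(gene_id = gene_ids, tissue = tissues,
                        group = c("wild", "cultivated"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    lfc <- rep(0, nrow(expr))
    if (!is.null(expression_spec)) {
      for (i in seq_len(nrow(expression_spec))) {
        hit <- expr$gene_id == expression_spec$gene_id[i] &
          expr$tissue == expression_spec$tissue[i] &
          expr$group == "cultivated"
        lfc[hit] <- expression_spec$lfc[i]
      }
    }
    expr$tpm <- base[expr$gene_id] * 2^lfc * exp(rnorm(nrow(expr), 0, 0.05))
  }
  structure(list(accessions = acc, sites = truth_svs, site_ids = site_ids,
                 genotypes = geno, genomes = genomes, truths = truths,
                 read_sets = read_sets, expression = expr),
            class = "pansv_panel")
}

#' @export
print.pansv_panel <- function(x, ...) {
  cat(sprintf("pansv_panel: %d accessions (%d wild, %d cultivated), %d SV sites\n",
              nrow(x$accessions), sum(x$accessions$group == "wild"),
              sum(x$accessions$group == "cultivated"), nrow(x$sites)))
  invisible(x)
}
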