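#' Find maximal exact-match anchors between two sequences
#'
#' Seeds with k-mers that occur exactly once in the reference (MUM-like) and
#' extends them to maximal exact matches, on both strands. Query coordinates
#' of minus-strand anchors are reported on the forward query strand with a
#' strand flag.
#'
#' @param ref_seq,qry_seq DNA strings.
#' @param min_anchor_len Seed/minimum match length (>= 8).
#' @return Data.frame: `ref_start`, `ref_end`, `qry_start`, `qry_end`
#'   (0-based half-open, forward strands), `strand`, `length`.
#' @export
find_anchors <- function(ref_seq, qry_seq, min_anchor_len = 20L) {
  if (!nzchar(ref_seq) || !nzchar(qry_seq)) stop("empty sequence")
  if (min_anchor_len < 8L) stop("min_anchor_len must be >= 8")
  nq <- nchar(qry_seq)
  fwd <- .anchors_cpp(ref_seq, qry_seq, min_anchor_len)
  rev <- .anchors_cpp(ref_seq, revcomp(qry_seq), min_anchor_len)
  fwd <- data.frame(ref_start = fwd$ref_start, ref_end = fwd$ref_start + fwd$length,
                    qry_start = fwd$qry_start, qry_end = fwd$qry_start + fwd$length,
                    strand = rep("+", nrow(fwd)), length = fwd$length,
                    stringsAsFactors = FALSE)
  rev <- data.frame(ref_start = rev$ref_start, ref_end = rev$ref_start + rev$length,
                    qry_start = nq - (rev$qry_start + rev$length),
                    qry_end = nq - rev$qry_start,
                    strand = rep("-", nrow(rev)), length = rev$length,
                    stringsAsFactors = FALSE)
  out <- rbind(fwd, rev)
  out <- out[out$length >= min_anchor_len, , drop = FALSE]
  out <- out[order(out$strand, out$ref_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# oriented query start: position in the query as read on the anchor's strand
oriented_qstart <- function(a, nq) {
  ifelse(a$strand == "+", a$qry_start, nq - a$qry_end)
}

#' Merge co-linear anchors into scored alignment segments
#'
#' Sweeps anchors in reference order and attaches each to the open segment
#' with the nearest diagonal whose reference and query gaps are both at most
#' `max_anchor_gap`; overlapping anchors are trimmed. Inter-anchor gaps are
#' aligned pairwise (global) to compute segment identity as matched columns /
#' aligned columns x 100.
#'
#' @param anchors Output of [find_anchors()] on the same sequence pair.
#' @param ref_seq,qry_seq The sequences the anchors were computed on.
#' @param max_anchor_gap Maximum gap (bp, on either genome) between
#'   consecutive anchors of one segment.
#' @return Data.frame of segments: coordinates as in [find_anchors()] plus
#'   `aligned_length` (alignment columns), `identity` (percent), `n_anchors`.
#' @export
extend_and_score <- function(anchors, ref_seq, qry_seq,
                             max_anchor_gap = 500L) {
  if (nrow(anchors) == 0L) return(empty_segments())
  nq <- nchar(qry_seq)
  qry_rc <- NULL
  out <- list()
  for (st in unique(anchors$strand)) {
    a <- anchors[anchors$strand == st, , drop = FALSE]
    if (st == "-" && is.null(qry_rc)) qry_rc <- revcomp(qry_seq)
    qseq <- if (st == "+") qry_seq else qry_rc
    a$q0 <- oriented_qstart(a, nq)
    a <- a[order(a$ref_start, a$q0), , drop = FALSE]
    # open segments: list of anchor index vectors + last (ref_end, q_end)
    segs <- list()
    last_re <- numeric(0); last_qe <- numeric(0)
    members <- list()
    for (i in seq_len(nrow(a))) {
      rs <- a$ref_start[i]; qs <- a$q0[i]; len <- a$length[i]
      cand <- which(rs - last_re <= max_anchor_gap &
                    qs - last_qe <= max_anchor_gap &
                    rs - last_re > -len & qs - last_qe > -len &
                    last_re - rs < max_anchor_gap)
      trim <- if (length(cand))
        pmax(last_re[cand] - rs, last_qe[cand] - qs, 0) else numeric(0)
      cand <- cand[trim < len]
      trim <- trim[trim < len]
      if (length(cand)) {
        diag_shift <- abs((rs - qs) - (last_re[cand] - last_qe[cand]))
        k <- cand[which.min(diag_shift)]
        tr <- trim[which.min(diag_shift)]
        members[[k]] <- c(members[[k]], i)
        a$ref_start[i] <- rs + tr; a$q0[i] <- qs + tr
        a$length[i] <- len - tr
        last_re[k] <- a$ref_start[i] + a$length[i]
        last_qe[k] <- a$q0[i] + a$length[i]
      } else {
        members[[length(members) + 1L]] <- i
        last_re <- c(last_re, rs + len)
        last_qe <- c(last_qe, qs + len)
      }
    }
    for (m in members) {
      aa <- a[m, , drop = FALSE]
      matches <- sum(aa$length)
      columns <- sum(aa$length)
      if (nrow(aa) > 1L) {
        for (j in seq_len(nrow(aa) - 1L)) {
          g_ref <- substr(ref_seq, aa$ref_start[j] + aa$length[j] + 1L,
                          aa$ref_start[j + 1L])
          g_qry <- substr(qseq, aa$q0[j] + aa$length[j] + 1L,
                          aa$q0[j + 1L])
          sc <- gap_alignment_score(g_ref, g_qry)
          matches <- matches + sc["matches"]
          columns <- columns + sc["columns"]
        }
      }
      q0s <- aa$q0[1]
      q0e <- aa$q0[nrow(aa)] + aa$length[nrow(aa)]
      out[[length(out) + 1L]] <- data.frame(
        ref_start = aa$ref_start[1],
        ref_end = aa$ref_start[nrow(aa)] + aa$length[nrow(aa)],
        qry_start = if (st == "+") q0s else nq - q0e,
        qry_end = if (st == "+") q0e else nq - q0s,
        strand = st,
        aligned_length = as.integer(columns),
        identity = if (columns > 0) 100 * matches / columns else 0,
        n_anchors = nrow(aa), stringsAsFactors = FALSE)
    }
  }
  segs <- do.call(rbind, out)
  segs <- segs[order(segs$ref_start), , drop = FALSE]
  rownames(segs) <- NULL
  segs
}

empty_segments <- function() {
  data.frame(ref_start = integer(), ref_end = integer(),
             qry_start = integer(), qry_end = integer(),
             strand = character(), aligned_length = integer(),
             identity = numeric(), n_anchors = integer(),
             stringsAsFactors = FALSE)
}

# matches and columns contributed by one inter-anchor gap pair
gap_alignment_score <- function(g_ref, g_qry) {
  l1 <- nchar(g_ref); l2 <- nchar(g_qry)
  if (l1 == 0L && l2 == 0L) return(c(matches = 0, columns = 0))
  if (l1 == 0L || l2 == 0L) return(c(matches = 0, columns = max(l1, l2)))
  if (as.double(l1) * l2 > 2.5e7)   # huge divergent gap: count as unaligned
    return(c(matches = 0, columns = max(l1, l2)))
  aln <- Biostrings::pairwiseAlignment(g_ref, g_qry, type = "global")
  cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
  c(matches = Biostrings::nmatch(aln), columns = cols)
}

#' One-to-one filtering of alignment segments
#'
#' Drops segments below the identity/length thresholds, then keeps the
#' maximum-weight (weight = identity x length) set of segments that is
#' mutually non-overlapping on both the reference and the query axis.
#' Solved exactly per connected component of the conflict graph.
#'
#' @param segments Segment data.frame (optionally with `ref_chrom` /
#'   `qry_chrom` columns for genome-scale input).
#' @param min_identity Minimum percent identity (default 90).
#' @param min_length Minimum aligned length in bp (default 200).
#' @param overlap_tol Overlap (bp) tolerated before two segments conflict;
#'   maximal matches extend a few bases across true breakpoints by chance,
#'   and such terminal overlaps are trimmed from the lighter segment after
#'   selection instead of excluding it (default 50).
#' @return The retained segments, sorted by reference coordinate.
#' @export
filter_one_to_one <- function(segments, min_identity = 90, min_length = 200L,
                              overlap_tol = 50L) {
  s <- segments[segments$identity >= min_identity &
                (segments$ref_end - segments$ref_start) >= min_length, ,
                drop = FALSE]
  if (nrow(s) <= 1L) { rownames(s) <- NULL; return(s) }
  rc <- if ("ref_chrom" %in% names(s)) s$ref_chrom else rep("*", nrow(s))
  qc <- if ("qry_chrom" %in% names(s)) s$qry_chrom else rep("*", nrow(s))
  # conflicts: overlap beyond the tolerance on either axis (small terminal
  # overlaps arise from chance extension of maximal matches across
  # breakpoints and are trimmed below instead of causing exclusion)
  ref_ir <- IRanges::IRanges(start = s$ref_start + 1L, end = s$ref_end)
  qry_ir <- IRanges::IRanges(start = s$qry_start + 1L, end = s$qry_end)
  ov_r <- IRanges::findOverlaps(ref_ir, ref_ir,
                                minoverlap = overlap_tol + 1L)
  ov_q <- IRanges::findOverlaps(qry_ir, qry_ir,
                                minoverlap = overlap_tol + 1L)
  pairs <- rbind(
    cbind(S4Vectors::queryHits(ov_r), S4Vectors::subjectHits(ov_r))[
      rc[S4Vectors::queryHits(ov_r)] == rc[S4Vectors::subjectHits(ov_r)], ,
      drop = FALSE],
    cbind(S4Vectors::queryHits(ov_q), S4Vectors::subjectHits(ov_q))[
      qc[S4Vectors::queryHits(ov_q)] == qc[S4Vectors::subjectHits(ov_q)], ,
      drop = FALSE])
  pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
  w <- s$identity * (s$ref_end - s$ref_start)
  keep <- mwis_select(nrow(s), pairs, w)
  # resolve residual (tolerated) overlaps by trimming the lighter segment,
  # so that reference and query positions end up covered by <= 1 segment
  keep <- keep[order(w[keep], decreasing = TRUE)]
  acc <- integer(0)
  final <- list()
  for (i in keep) {
    seg <- s[i, , drop = FALSE]
    for (j in acc) {
      o <- final[[as.character(j)]]
      # reference axis
      if (rc[i] == rc[j]) {
        ov_lo <- max(seg$ref_start, o$ref_start)
        ov_hi <- min(seg$ref_end, o$ref_end)
        if (ov_hi > ov_lo) {
          if (o$ref_start <= seg$ref_start)
            seg <- trim_segment(seg, "ref_left", ov_hi - seg$ref_start)
          else seg <- trim_segment(seg, "ref_right", seg$ref_end - ov_lo)
        }
      }
      if (is.null(seg)) break
      # query axis
      if (qc[i] == qc[j]) {
        ov_lo <- max(seg$qry_start, o$qry_start)
        ov_hi <- min(seg$qry_end, o$qry_end)
        if (ov_hi > ov_lo) {
          if (o$qry_start <= seg$qry_start)
            seg <- trim_segment(seg, "qry_left", ov_hi - seg$qry_start)
          else seg <- trim_segment(seg, "qry_right", seg$qry_end - ov_lo)
        }
      }
      if (is.null(seg)) break
    }
    if (!is.null(seg) && seg$ref_end - seg$ref_start >= min_length) {
      final[[as.character(i)]] <- seg
      acc <- c(acc, i)
    }
  }
  s <- do.call(rbind, final[as.character(sort(acc))])
  s <- s[order(if ("ref_chrom" %in% names(s)) s$ref_chrom else
                 rep("*", nrow(s)), s$ref_start), , drop = FALSE]
  rownames(s) <- NULL
  s
}

# trim k bp from one side of a segment, propagating to the other genome
trim_segment <- function(seg, side, k) {
  if (k <= 0L) return(seg)
  if (k >= seg$ref_end - seg$ref_start) return(NULL)
  plus <- seg$strand == "+"
  if (side == "ref_left") {
    seg$ref_start <- seg$ref_start + k
    if (plus) seg$qry_start <- seg$qry_start + k
    else seg$qry_end <- seg$qry_end - k
  } else if (side == "ref_right") {
    seg$ref_end <- seg$ref_end - k
    if (plus) seg$qry_end <- seg$qry_end - k
    else seg$qry_start <- seg$qry_start + k
  } else if (side == "qry_left") {
    seg$qry_start <- seg$qry_start + k
    if (plus) seg$ref_start <- seg$ref_start + k
    else seg$ref_end <- seg$ref_end - k
  } else {
    seg$qry_end <- seg$qry_end - k
    if (plus) seg$ref_end <- seg$ref_end - k
    else seg$ref_start <- seg$ref_start + k
  }
  seg$aligned_length <- max(0L, seg$aligned_length - k)
  seg
}

# maximum-weight independent set on the conflict graph; exact per component
# (branch and bound) for components up to `exact_max` vertices, greedy beyond
mwis_select <- function(n, conflict_pairs, weights, exact_max = 20L) {
  adj <- vector("list", n)
  for (i in seq_len(nrow(conflict_pairs))) {
    a <- conflict_pairs[i, 1]; b <- conflict_pairs[i, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  comp <- rep(NA_integer_, n); nc <- 0L
  for (v in seq_len(n)) {
    if (!is.na(comp[v])) next
    nc <- nc + 1L
    queue <- v
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      if (!is.na(comp[u])) next
      comp[u] <- nc
      queue <- c(queue, adj[[u]])
    }
  }
  keep <- integer(0)
  for (k in seq_len(nc)) {
    verts <- which(comp == k)
    if (length(verts) == 1L) { keep <- c(keep, verts); next }
    if (length(verts) <= exact_max) {
      keep <- c(keep, verts[mwis_exact(verts, adj, weights)])
    } else {
      ord <- verts[order(weights[verts], decreasing = TRUE)]
      chosen <- integer(0)
      for (v in ord)
        if (!any(adj[[v]] %in% chosen)) chosen <- c(chosen, v)
      keep <- c(keep, chosen)
    }
  }
  keep
}

mwis_exact <- function(verts, adj, weights) {
  idx <- seq_along(verts)
  pos <- setNames(idx, verts)
  local_adj <- lapply(verts, function(v) {
    nb <- adj[[v]]
    unname(pos[as.character(nb[nb %in% verts])])
  })
  w <- weights[verts]
  ord <- order(w, decreasing = TRUE)
  best <- list(weight = -Inf, set = integer(0))
  recurse <- function(avail, cur_set, cur_w) {
    if (!length(avail)) {
      if (cur_w > best$weight) best <<- list(weight = cur_w, set = cur_set)
      return(invisible())
    }
    if (cur_w + sum(w[avail]) <= best$weight) return(invisible())
    v <- avail[1]
    rest <- avail[-1]
    recurse(setdiff(rest, local_adj[[v]]), c(cur_set, v), cur_w + w[v])
    recurse(rest, cur_set, cur_w)
  }
  recurse(ord, integer(0), 0)
  best$set
}

#' Chain one-to-one segments into collinear blocks
#'
#' Joins same-strand, order-consistent segments whose reference and query
#' gaps are both at most `max_gap` into collinear blocks. Block spans cover
#' all member segments; a strand change or an over-long gap forces a block
#' boundary. Chaining is idempotent: re-chaining the returned blocks (as
#' segments) reproduces them.
#'
#' @param segments One-to-one filtered segments (optionally with chromosome
#'   columns).
#' @param max_gap Maximum internal gap in bp (default 50000).
#' @return Data.frame of blocks sorted by reference coordinate; the member
#'   segments, with a `block_id` column, are attached as
#'   `attr(, "segments")`.
#' @export
chain_collinear_blocks <- function(segments, max_gap = 50000L) {
  s <- segments
  if (!"ref_chrom" %in% names(s)) s$ref_chrom <- "*"
  if (!"qry_chrom" %in% names(s)) s$qry_chrom <- "*"
  s <- s[order(s$ref_chrom, s$ref_start), , drop = FALSE]
  s$block_id <- NA_integer_
  bid <- 0L
  blocks <- list()
  # a gap is blocked when another retained segment occupies it on either
  # genome (e.g. an inverted or translocated segment): block boundary forced
  for (key in unique(paste(s$ref_chrom, s$qry_chrom, s$strand))) {
    sel <- which(paste(s$ref_chrom, s$qry_chrom, s$strand) == key)
    ss <- s[sel, , drop = FALSE]
    cur <- 1L
    groups <- integer(nrow(ss))
    groups[1] <- cur
    if (nrow(ss) > 1L) for (i in 2:nrow(ss)) {
      rgap <- ss$ref_start[i] - ss$ref_end[i - 1L]
      qgap <- if (ss$strand[i] == "+") ss$qry_start[i] - ss$qry_end[i - 1L]
              else ss$qry_start[i - 1L] - ss$qry_end[i]
      qlo <- if (ss$strand[i] == "+") ss$qry_end[i - 1L] else ss$qry_end[i]
      qhi <- if (ss$strand[i] == "+") ss$qry_start[i] else ss$qry_start[i - 1L]
      occupied <- any(s$ref_chrom == ss$ref_chrom[i] &
                        pmin(s$ref_end, ss$ref_start[i]) >
                          pmax(s$ref_start, ss$ref_end[i - 1L])) ||
                  any(s$qry_chrom == ss$qry_chrom[i] &
                        pmin(s$qry_end, qhi) > pmax(s$qry_start, qlo))
      if (rgap >= 0 && rgap <= max_gap && qgap >= 0 && qgap <= max_gap &&
          !occupied)
        groups[i] <- cur
      else { cur <- cur + 1L; groups[i] <- cur }
    }
    for (g in unique(groups)) {
      bid <- bid + 1L
      m <- sel[groups == g]
      s$block_id[m] <- bid
      blocks[[bid]] <- data.frame(
        block_id = bid,
        ref_chrom = s$ref_chrom[m[1]],
        ref_start = min(s$ref_start[m]), ref_end = max(s$ref_end[m]),
        qry_chrom = s$qry_chrom[m[1]],
        qry_start = min(s$qry_start[m]), qry_end = max(s$qry_end[m]),
        strand = s$strand[m[1]],
        n_segments = length(m),
        aligned_length = sum(s$aligned_length[m]),
        identity = sum(s$identity[m] * s$aligned_length[m]) /
          max(1, sum(s$aligned_length[m])),
        stringsAsFactors = FALSE)
    }
  }
  b <- do.call(rbind, blocks)
  b <- b[order(b$ref_chrom, b$ref_start), , drop = FALSE]
  rownames(b) <- NULL
  attr(b, "segments") <- s
  b
}

#' Detect inversions and translocations from collinear blocks
#'
#' For each reference chromosome the dominant query partner chromosome and
#' strand are determined by aligned span. A minus-strand block nested in
#' plus-strand context is reported as an inversion (reference span = size);
#' inversions at or above `large_inv_threshold` are reported separately as
#' megabase-scale rearrangements. Inversions without same-strand flanking
#' blocks on both sides are flagged low-confidence. Blocks mapping to a
#' non-dominant query chromosome are inter-chromosomal translocations; blocks
#' breaking query order among same-partner blocks (maximum-span increasing
#' subsequence) are intra-chromosomal translocations. Translocations whose
#' reference span contains N are excluded when `ref_genome` is supplied.
#'
#' @param blocks Block data.frame from [chain_collinear_blocks()].
#' @param large_inv_threshold Size separating megabase-scale inversions
#'   (default 1e6 bp).
#' @param ref_genome Optional `pansv_genome` for the N-content filter.
#' @return List with data.frames `inversions`, `megabase_inversions`,
#'   `translocations` (column `type` is `intra` or `inter`).
#' @export
detect_rearrangements <- function(blocks, large_inv_threshold = 1e6,
                                  ref_genome = NULL) {
  inv <- list(); tra <- list()
  for (rc in unique(blocks$ref_chrom)) {
    b <- blocks[blocks$ref_chrom == rc, , drop = FALSE]
    b <- b[order(b$ref_start), , drop = FALSE]
    span <- b$ref_end - b$ref_start
    dom_q <- names(which.max(tapply(span, b$qry_chrom, sum)))
    inter <- b$qry_chrom != dom_q
    for (i in which(inter))
      tra[[length(tra) + 1L]] <- data.frame(
        ref_chrom = rc, ref_start = b$ref_start[i], ref_end = b$ref_end[i],
        qry_chrom = b$qry_chrom[i], qry_start = b$qry_start[i],
        qry_end = b$qry_end[i], type = "inter", stringsAsFactors = FALSE)
    d <- b[!inter, , drop = FALSE]
    if (!nrow(d)) next
    # dominant strand by block count (span tie-break): a single inversion
    # may span most of a chromosome, but it is still the flanked minority
    cnt <- table(d$strand)
    if (length(cnt) > 1L && cnt[1] == cnt[2]) {
      spand <- tapply(d$ref_end - d$ref_start, d$strand, sum)
      dom_strand <- names(which.max(spand))
    } else {
      dom_strand <- names(which.max(cnt))
    }
    opp <- which(d$strand != dom_strand)
    for (i in opp) {
      flanked <- i > 1L && i < nrow(d) &&
        d$strand[i - 1L] == dom_strand && d$strand[i + 1L] == dom_strand
      inv[[length(inv) + 1L]] <- data.frame(
        ref_chrom = rc, ref_start = d$ref_start[i], ref_end = d$ref_end[i],
        qry_chrom = d$qry_chrom[i], qry_start = d$qry_start[i],
        qry_end = d$qry_end[i], size = d$ref_end[i] - d$ref_start[i],
        low_confidence = !flanked, stringsAsFactors = FALSE)
    }
    # intra-chromosomal translocations among dominant-strand blocks:
    # blocks outside the maximum-span query-order-consistent subsequence
    dd <- d[d$strand == dom_strand, , drop = FALSE]
    if (nrow(dd) > 1L) {
      q <- if (dom_strand == "+") dd$qry_start else -dd$qry_start
      wt <- dd$ref_end - dd$ref_start
      n <- length(q)
      best_w <- wt; prev <- rep(0L, n)
      for (i in seq_len(n)) for (j in seq_len(i - 1L))
        if (q[j] < q[i] && best_w[j] + wt[i] > best_w[i]) {
          best_w[i] <- best_w[j] + wt[i]; prev[i] <- j
        }
      end <- which.max(best_w)
      in_lis <- logical(n)
      while (end > 0L) { in_lis[end] <- TRUE; end <- prev[end] }
      for (i in which(!in_lis))
        tra[[length(tra) + 1L]] <- data.frame(
          ref_chrom = rc, ref_start = dd$ref_start[i], ref_end = dd$ref_end[i],
          qry_chrom = dd$qry_chrom[i], qry_start = dd$qry_start[i],
          qry_end = dd$qry_end[i], type = "intra", stringsAsFactors = FALSE)
    }
  }
  inv <- if (length(inv)) do.call(rbind, inv) else
    data.frame(ref_chrom = character(), ref_start = integer(),
               ref_end = integer(), qry_chrom = character(),
               qry_start = integer(), qry_end = integer(), size = integer(),
               low_confidence = logical(), stringsAsFactors = FALSE)
  tra <- if (length(tra)) do.call(rbind, tra) else
    data.frame(ref_chrom = character(), ref_start = integer(),
               ref_end = integer(), qry_chrom = character(),
               qry_start = integer(), qry_end = integer(), type = character(),
               stringsAsFactors = FALSE)
  if (!is.null(ref_genome) && nrow(tra)) {
    has_n <- vapply(seq_len(nrow(tra)), function(i)
      grepl("N", substr(ref_genome$chromosomes[[tra$ref_chrom[i]]],
                        tra$ref_start[i] + 1L, tra$ref_end[i]), fixed = TRUE),
      logical(1))
    tra <- tra[!has_n, , drop = FALSE]
  }
  list(inversions = inv[inv$size < large_inv_threshold, , drop = FALSE],
       megabase_inversions = inv[inv$size >= large_inv_threshold, ,
                                 drop = FALSE],
       translocations = tra)
}

#' Anchor-align two genomes and chain collinear blocks
#'
#' Runs [find_anchors()] and [extend_and_score()] for every pair of
#' chromosomes, applies [filter_one_to_one()] genome-wide, and chains the
#' survivors into collinear blocks.
#'
#' @param ref_genome,qry_genome `pansv_genome` objects.
#' @param min_anchor_len,max_anchor_gap,min_identity,min_length,max_gap
#'   Stage parameters (see the stage functions).
#' @return List with `segments` (one-to-one filtered) and `blocks`.
#' @export
align_genomes <- function(ref_genome, qry_genome, min_anchor_len = 20L,
                          max_anchor_gap = 500L, min_identity = 90,
                          min_length = 200L, max_gap = 50000L) {
  segs <- list()
  for (rc in names(ref_genome$chromosomes)) {
    for (qc in names(qry_genome$chromosomes)) {
      anc <- find_anchors(ref_genome$chromosomes[[rc]],
                          qry_genome$chromosomes[[qc]], min_anchor_len)
      if (!nrow(anc)) next
      sg <- extend_and_score(anc, ref_genome$chromosomes[[rc]],
                             qry_genome$chromosomes[[qc]], max_anchor_gap)
      if (!nrow(sg)) next
      sg$ref_chrom <- rc
      sg$qry_chrom <- qc
      segs[[length(segs) + 1L]] <- sg
    }
  }
  if (!length(segs)) stop("align_genomes: no alignable sequence found")
  segs <- do.call(rbind, segs)
  oo <- filter_one_to_one(segs, min_identity, min_length)
  blocks <- chain_collinear_blocks(oo, max_gap)
  list(segments = oo, blocks = blocks)
}
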