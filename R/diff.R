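# In-block difference extraction: decompose a collinear block by exact word
# anchors and emit the unmatched segment pairs between them.

lcp_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  x <- charToRaw(substr(a, 1L, n)); y <- charToRaw(substr(b, 1L, n))
  d <- which(x != y)
  if (!length(d)) n else d[1] - 1L
}

lcs_len <- function(a, b, max_len) {
  n <- min(nchar(a), nchar(b), max_len)
  if (n == 0L) return(0L)
  x <- rev(charToRaw(substr(a, nchar(a) - n + 1L, nchar(a))))
  y <- rev(charToRaw(substr(b, nchar(b) - n + 1L, nchar(b))))
  d <- which(x != y)
  if (!length(d)) n else d[1] - 1L
}

# maximum-length chain of anchors strictly increasing and non-overlapping on
# both axes; ties broken leftmost. O(n^2) DP; anchor counts per block are
# small because anchors are maximal matches.
chain_anchors <- function(a) {
  n <- nrow(a)
  if (n == 0L) return(a)
  o <- order(a$ref_start, a$qry_start)
  a <- a[o, , drop = FALSE]
  re <- a$ref_start + a$length
  qe <- a$qry_start + a$length
  best <- a$length
  prev <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (re[j] <= a$ref_start[i] && qe[j] <= a$qry_start[i] &&
          best[j] + a$length[i] > best[i]) {
        best[i] <- best[j] + a$length[i]
        prev[i] <- j
      }
    }
  }
  end <- which.max(best)
  path <- integer(0)
  while (end > 0L) { path <- c(end, path); end <- prev[end] }
  a[path, , drop = FALSE]
}

# recursive refinement of one unmatched segment pair (block-local offsets)
refine_pair <- function(ref_seg, qry_seg, ref_off, qry_off, wordsize,
                        min_ext) {
  l <- lcp_len(ref_seg, qry_seg)
  t <- lcs_len(ref_seg, qry_seg, min(nchar(ref_seg), nchar(qry_seg)) - l)
  a <- substr(ref_seg, l + 1L, nchar(ref_seg) - t)
  b <- substr(qry_seg, l + 1L, nchar(qry_seg) - t)
  ro <- ref_off + l; qo <- qry_off + l
  la <- nchar(a); lb <- nchar(b)
  if (la == 0L && lb == 0L) return(NULL)
  if (la == 0L || lb == 0L)
    return(data.frame(ref_off = ro, ref_len = la, qry_off = qo, qry_len = lb,
                      ref_seg = a, qry_seg = b, stringsAsFactors = FALSE))
  if (la == 1L && lb == 1L)
    return(data.frame(ref_off = ro, ref_len = 1L, qry_off = qo, qry_len = 1L,
                      ref_seg = a, qry_seg = b, stringsAsFactors = FALSE))
  anc <- NULL
  if (la >= min_ext && lb >= min_ext) {
    # short words are only unique enough for small inputs; at large scale
    # seed with longer words (extension threshold min_ext is unchanged)
    k_eff <- if (as.double(la) * lb > 2.5e7) max(wordsize, 20L) else wordsize
    anc <- .anchors_cpp(a, b, k_eff)
    anc <- anc[anc$length >= min_ext, , drop = FALSE]
    if (nrow(anc)) {
      names(anc) <- c("ref_start", "qry_start", "length")
      anc <- chain_anchors(anc)
    }
  }
  if (is.null(anc) || !nrow(anc)) {
    if (la == lb) {
      # equal-length mismatch run: decompose into single-base substitutions
      x <- charToRaw(a); y <- charToRaw(b)
      pos <- which(x != y)
      return(do.call(rbind, lapply(pos, function(p)
        data.frame(ref_off = ro + p - 1L, ref_len = 1L,
                   qry_off = qo + p - 1L, qry_len = 1L,
                   ref_seg = substr(a, p, p), qry_seg = substr(b, p, p),
                   stringsAsFactors = FALSE))))
    }
    return(data.frame(ref_off = ro, ref_len = la, qry_off = qo, qry_len = lb,
                      ref_seg = a, qry_seg = b, stringsAsFactors = FALSE))
  }
  # recurse into the gaps around the chained word anchors
  out <- list()
  cr <- 0L; cq <- 0L
  for (i in seq_len(nrow(anc))) {
    out[[length(out) + 1L]] <- refine_pair(
      substr(a, cr + 1L, anc$ref_start[i]),
      substr(b, cq + 1L, anc$qry_start[i]),
      ro + cr, qo + cq, wordsize, min_ext)
    cr <- anc$ref_start[i] + anc$length[i]
    cq <- anc$qry_start[i] + anc$length[i]
  }
  out[[length(out) + 1L]] <- refine_pair(
    substr(a, cr + 1L, la), substr(b, cq + 1L, lb), ro + cr, qo + cq,
    wordsize, min_ext)
  do.call(rbind, out)
}

#' Extract raw difference pairs from one collinear block
#'
#' Decomposes the block's reference and query spans by exact word anchors
#' (maximal matches seeded at `wordsize`-mers, chained left-to-right) and
#' emits the unmatched segment pairs between consecutive anchors, after
#' trimming shared prefixes/suffixes. Concatenating matched anchors and the
#' returned pairs reconstructs both block sequences exactly. Minus-strand
#' blocks are diffed with the query reverse-complemented (strand normalised
#' to +); `qry_seg` is reported in that orientation, query coordinates on the
#' forward strand.
#'
#' @param block One block (row of the data.frame from
#'   [chain_collinear_blocks()], or any list with `ref_start`, `ref_end`,
#'   `qry_start`, `qry_end`, `strand`).
#' @param ref_seq,qry_seq Chromosome sequences the block lives on.
#' @param wordsize Word length for the in-block decomposition (default 10);
#'   word matches are only used where their maximal extension reaches
#'   `2 * wordsize`, which prevents chance word hits inside genuinely
#'   divergent replacements from fragmenting them.
#' @return Data.frame of difference pairs: `ref_start`, `ref_end`,
#'   `qry_start`, `qry_end` (0-based half-open), `ref_seg`, `qry_seg`,
#'   `strand`. Attribute `n_only` is TRUE for blocks of only-N content
#'   (no calls).
#' @export
diff_block <- function(block, ref_seq, qry_seq, wordsize = 10L) {
  rs <- block$ref_start[1]; re <- block$ref_end[1]
  qs <- block$qry_start[1]; qe <- block$qry_end[1]
  st <- block$strand[1]
  bref <- substr(ref_seq, rs + 1L, re)
  bqry <- substr(qry_seq, qs + 1L, qe)
  if (st == "-") bqry <- revcomp(bqry)
  empty <- data.frame(ref_start = integer(), ref_end = integer(),
                      qry_start = integer(), qry_end = integer(),
                      ref_seg = character(), qry_seg = character(),
                      strand = character(), stringsAsFactors = FALSE)
  if (grepl("^N+$", bref) || grepl("^N+$", bqry)) {
    attr(empty, "n_only") <- TRUE
    return(empty)
  }
  pairs <- refine_pair(bref, bqry, 0L, 0L, wordsize, 2L * wordsize)
  if (is.null(pairs) || !nrow(pairs)) {
    attr(empty, "n_only") <- FALSE
    return(empty)
  }
  qlen_block <- qe - qs
  out <- data.frame(
    ref_start = rs + pairs$ref_off,
    ref_end = rs + pairs$ref_off + pairs$ref_len,
    qry_start = if (st == "+") qs + pairs$qry_off else
      qs + qlen_block - (pairs$qry_off + pairs$qry_len),
    qry_end = if (st == "+") qs + pairs$qry_off + pairs$qry_len else
      qs + qlen_block - pairs$qry_off,
    ref_seg = pairs$ref_seg, qry_seg = pairs$qry_seg,
    strand = st, stringsAsFactors = FALSE)
  out <- out[order(out$ref_start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_only") <- FALSE
  out
}
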