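# Independent oracles used across the suite. These deliberately avoid the
# package's anchor/chaining machinery.

# naive greedy character diff: trims the common prefix, then at each mismatch
# searches for the nearest resynchronisation window of length `w` and emits
# the skipped segments as one difference pair (0-based half-open intervals)
naive_diff <- function(a, b, w = 20L) {
  out <- list()
  ia <- 0L; ib <- 0L
  na <- nchar(a); nb <- nchar(b)
  repeat {
    # advance over matching run
    while (ia < na && ib < nb &&
           substr(a, ia + 1L, ia + 1L) == substr(b, ib + 1L, ib + 1L)) {
      ia <- ia + 1L; ib <- ib + 1L
    }
    if (ia >= na && ib >= nb) break
    # resync: smallest i+j with a[ia+i ..+w) == b[ib+j ..+w)
    best <- NULL
    for (s in 0:(na + nb)) {
      for (i in 0:s) {
        j <- s - i
        if (ia + i + w > na || ib + j + w > nb) next
        if (substr(a, ia + i + 1L, ia + i + w) ==
            substr(b, ib + j + 1L, ib + j + w)) { best <- c(i, j); break }
      }
      if (!is.null(best)) break
    }
    if (is.null(best)) best <- c(na - ia, nb - ib)
    out[[length(out) + 1L]] <- data.frame(
      a_start = ia, a_end = ia + best[1], b_start = ib, b_end = ib + best[2])
    ia <- ia + best[1]; ib <- ib + best[2]
    if (best[1] == 0L && best[2] == 0L) break
  }
  if (!length(out)) return(data.frame(a_start = integer(), a_end = integer(),
                                      b_start = integer(), b_end = integer()))
  do.call(rbind, out)
}

# two-sided Fisher p by exhaustive hypergeometric enumeration
fisher_enum <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c_; n <- a + b + c_ + d
  ks <- max(0L, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(ks, c1, n - c1, r1)
  p_obs <- dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# average pairwise difference per site over all haplotype pairs
pi_pairwise <- function(m) {
  n <- ncol(m)
  tot <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    tot <- tot + sum(m[, i] != m[, j])
  tot / choose(n, 2)
}

# maximum-weight subset of segments non-overlapping on both axes, by
# exhaustive subset enumeration (n <= 12)
mwis_brute <- function(s, w) {
  n <- nrow(s)
  best_w <- -Inf; best <- integer(0)
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (!length(idx)) { if (0 > best_w) { best_w <- 0; best <- idx }; next }
    ok <- TRUE
    if (length(idx) > 1L) {
      for (i in seq_len(length(idx) - 1L)) for (j in (i + 1L):length(idx)) {
        x <- idx[i]; y <- idx[j]
        if (min(s$ref_end[x], s$ref_end[y]) >
              max(s$ref_start[x], s$ref_start[y]) ||
            min(s$qry_end[x], s$qry_end[y]) >
              max(s$qry_start[x], s$qry_start[y])) { ok <- FALSE; break }
        if (!ok) break
      }
    }
    if (ok && sum(w[idx]) > best_w) { best_w <- sum(w[idx]); best <- idx }
  }
  list(weight = best_w, set = best)
}

# small shared fixture: a 2 x 100 kb genome with a handful of variants
fixture_small <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    ref <- simulate_reference(2, 100000, 0.45, seed = 101)
    spec <- variant_spec(n_snp = 8, n_small_ins = 3, n_small_del = 3,
                         n_can_ins = 3, n_can_del = 3,
                         n_com_ins = 2, n_com_del = 2)
    imp <- implant_variants(ref, spec, seed = 102, accession_id = "acc1")
    cache <<- list(ref = ref, imp = imp)
    cache
  }
})
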