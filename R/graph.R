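# SV-integrated variation graph and short-read SV genotyping.

#' Build a variation graph from a reference and SVs
#'
#' Reference chromosomes are split into nodes at every SV boundary; a
#' deletion contributes one bypass edge, an insertion or complex replacement
#' one alternative node with two edges, and an inversion reuses the
#' reference segment through reversed-orientation edges. The linear
#' reference path is preserved: concatenating the `ref_path` node sequences
#' reproduces the reference byte for byte. Translocations are not part of
#' the graph.
#'
#' @param reference A `pansv_genome`.
#' @param svs Variant data.frame restricted to classes CAN_INS, CAN_DEL,
#'   COM_INS, COM_DEL, INV (others are dropped with a message). Duplicated
#'   sites (same chrom/start/end/alt) are collapsed.
#' @return A `pansv_graph`: `nodes`, `edges`, `ref_path` (named list of node
#'   id vectors), `sites` (per-SV data.frame), `reference`.
#' @export
build_graph <- function(reference, svs) {
  ok <- svs$variant_class %in% c(LARGE_INDEL_CLASSES, "INV")
  if (any(!ok))
    message("build_graph: dropping ", sum(!ok), " non-graph variants")
  svs <- svs[ok, , drop = FALSE]
  svs <- svs[!duplicated(paste(svs$ref_chrom, svs$ref_start, svs$ref_end,
                               svs$alt_allele)), , drop = FALSE]
  chrom_len <- nchar(reference$chromosomes)
  if (nrow(svs)) {
    if (any(svs$ref_start < 0L |
            svs$ref_end > chrom_len[svs$ref_chrom] |
            is.na(chrom_len[svs$ref_chrom])))
      stop("build_graph: SV coordinates outside the reference")
    # fill alleles from the reference where absent (e.g. INV records)
    for (i in seq_len(nrow(svs))) {
      seg <- substr(reference$chromosomes[[svs$ref_chrom[i]]],
                    svs$ref_start[i] + 1L, svs$ref_end[i])
      if (!nzchar(svs$ref_allele[i]) && svs$ref_end[i] > svs$ref_start[i])
        svs$ref_allele[i] <- seg
      if (svs$variant_class[i] == "INV" && !nzchar(svs$alt_allele[i]))
        svs$alt_allele[i] <- revcomp(seg)
    }
    if (!all(nzchar(svs$id) & !is.na(svs$id))) svs$id <- variant_ids(svs)
  }
  nodes <- list(); edges <- list(); ref_path <- list()
  next_id <- 0L
  node_at <- list()  # per chrom: data.frame(start, end, id)
  for (cn in names(reference$chromosomes)) {
    sv_c <- svs[svs$ref_chrom == cn, , drop = FALSE]
    bounds <- sort(unique(c(0L, chrom_len[[cn]],
                            sv_c$ref_start, sv_c$ref_end)))
    st <- bounds[-length(bounds)]; en <- bounds[-1]
    ids <- next_id + seq_along(st)
    next_id <- next_id + length(st)
    nodes[[length(nodes) + 1L]] <- data.frame(
      id = ids, chrom = cn, start = st, end = en,
      seq = substring(reference$chromosomes[[cn]], st + 1L, en),
      stringsAsFactors = FALSE)
    ref_path[[cn]] <- ids
    node_at[[cn]] <- data.frame(start = st, end = en, id = ids)
    if (length(ids) > 1L)
      edges[[length(edges) + 1L]] <- data.frame(
        from = ids[-length(ids)], from_orient = "+",
        to = ids[-1], to_orient = "+", stringsAsFactors = FALSE)
  }
  nodes <- do.call(rbind, nodes)
  sites <- list()
  for (i in seq_len(nrow(svs))) {
    cn <- svs$ref_chrom[i]; s <- svs$ref_start[i]; e <- svs$ref_end[i]
    na <- node_at[[cn]]
    pre <- na$id[na$end == s][1]      # node ending at s (NA at chrom start)
    post <- na$id[na$start == e][1]   # node starting at e
    inner <- na$id[na$start >= s & na$end <= e]
    cls <- svs$variant_class[i]
    if (cls == "CAN_DEL" || (cls == "COM_DEL" && !nzchar(svs$alt_allele[i]))) {
      edges[[length(edges) + 1L]] <- data.frame(
        from = pre, from_orient = "+", to = post, to_orient = "+",
        stringsAsFactors = FALSE)
      alt_nodes <- integer(0)
    } else if (cls == "INV") {
      rev_ids <- rev(inner)
      edges[[length(edges) + 1L]] <- data.frame(
        from = c(pre, rev_ids), from_orient = c("+", rep("-", length(rev_ids))),
        to = c(rev_ids, post), to_orient = c(rep("-", length(rev_ids)), "+"),
        stringsAsFactors = FALSE)
      alt_nodes <- rev_ids
    } else {
      next_id <- next_id + 1L
      nodes <- rbind(nodes, data.frame(
        id = next_id, chrom = NA_character_, start = NA_integer_,
        end = NA_integer_, seq = svs$alt_allele[i], stringsAsFactors = FALSE))
      edges[[length(edges) + 1L]] <- data.frame(
        from = c(pre, next_id), from_orient = "+",
        to = c(next_id, post), to_orient = "+", stringsAsFactors = FALSE)
      alt_nodes <- next_id
    }
    sites[[length(sites) + 1L]] <- data.frame(
      site_id = svs$id[i], variant_class = cls, chrom = cn,
      ref_start = s, ref_end = e, ref_allele = svs$ref_allele[i],
      alt_allele = svs$alt_allele[i],
      ref_nodes = I(list(c(pre, inner, post))),
      alt_nodes = I(list(c(pre, alt_nodes, post))),
      stringsAsFactors = FALSE)
  }
  sites <- if (length(sites)) do.call(rbind, sites) else NULL
  edges <- if (length(edges)) unique(do.call(rbind, edges)) else
    data.frame(from = integer(), from_orient = character(),
               to = integer(), to_orient = character(),
               stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, ref_path = ref_path,
                 sites = sites, reference = reference),
            class = "pansv_graph")
}

#' @export
print.pansv_graph <- function(x, ...) {
  cat(sprintf("pansv_graph: %d nodes, %d edges, %d SV sites, %d reference path(s)\n",
              nrow(x$nodes), nrow(x$edges),
              if (is.null(x$sites)) 0L else nrow(x$sites),
              length(x$ref_path)))
  invisible(x)
}

#' Spell the reference from the graph's reference path
#' @param graph A `pansv_graph`.
#' @return Named character vector of chromosome sequences.
#' @export
spell_ref_path <- function(graph) {
  vapply(graph$ref_path, function(ids)
    paste(graph$nodes$seq[match(ids, graph$nodes$id)], collapse = ""),
    character(1))
}

#' Write / read a variation graph as GFA 1.0
#'
#' S lines carry node sequences, L lines the oriented edges (overlap 0M),
#' and one P line per chromosome carries the reference path. `read_gfa()`
#' inverts `write_gfa()` losslessly (write-read-write is idempotent).
#'
#' @param graph A `pansv_graph`.
#' @param path Output file.
#' @return `write_gfa()` the path, invisibly; `read_gfa()` a list with
#'   `nodes`, `edges`, `ref_path`.
#' @export
write_gfa <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("H\tVN:Z:1.0", con)
  writeLines(sprintf("S\t%d\t%s", graph$nodes$id, graph$nodes$seq), con)
  e <- graph$edges
  if (nrow(e))
    writeLines(sprintf("L\t%d\t%s\t%d\t%s\t0M", e$from, e$from_orient,
                       e$to, e$to_orient), con)
  for (cn in names(graph$ref_path))
    writeLines(sprintf("P\t%s\t%s\t*", cn,
                       paste0(graph$ref_path[[cn]], "+", collapse = ",")),
               con)
  invisible(path)
}

#' @rdname write_gfa
#' @export
read_gfa <- function(path) {
  lines <- readLines(path)
  tag <- substr(lines, 1L, 1L)
  sf <- strsplit(lines[tag == "S"], "\t", fixed = TRUE)
  nodes <- data.frame(id = as.integer(vapply(sf, `[`, "", 2L)),
                      seq = vapply(sf, `[`, "", 3L), stringsAsFactors = FALSE)
  lf <- strsplit(lines[tag == "L"], "\t", fixed = TRUE)
  edges <- if (length(lf)) data.frame(
    from = as.integer(vapply(lf, `[`, "", 2L)),
    from_orient = vapply(lf, `[`, "", 3L),
    to = as.integer(vapply(lf, `[`, "", 4L)),
    to_orient = vapply(lf, `[`, "", 5L), stringsAsFactors = FALSE)
  else data.frame(from = integer(), from_orient = character(),
                  to = integer(), to_orient = character(),
                  stringsAsFactors = FALSE)
  pf <- strsplit(lines[tag == "P"], "\t", fixed = TRUE)
  ref_path <- lapply(pf, function(x)
    as.integer(sub("[+-]$", "", strsplit(x[3], ",", fixed = TRUE)[[1]])))
  names(ref_path) <- vapply(pf, `[`, "", 2L)
  list(nodes = nodes, edges = edges, ref_path = ref_path)
}

# allele spellings (flank + allele + flank) and junction offsets per site
site_spellings <- function(graph, flank) {
  sites <- graph$sites
  out <- list()
  for (i in seq_len(nrow(sites))) {
    cn <- sites$chrom[i]
    chrom <- graph$reference$chromosomes[[cn]]
    s <- sites$ref_start[i]; e <- sites$ref_end[i]
    lf <- substr(chrom, max(1L, s - flank + 1L), s)
    rf <- substr(chrom, e + 1L, min(nchar(chrom), e + flank))
    fl <- nchar(lf)
    out[[length(out) + 1L]] <- data.frame(
      site_id = sites$site_id[i], allele = c("ref", "alt"),
      seq = c(paste0(lf, sites$ref_allele[i], rf),
              paste0(lf, sites$alt_allele[i], rf)),
      j1 = fl, j2 = c(fl + (e - s), fl + nchar(sites$alt_allele[i])),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# k-mer index over spellings: for every k-mer position, (spelling row, offset)
spelling_index <- function(spell, k) {
  rows <- list()
  for (i in seq_len(nrow(spell))) {
    n <- nchar(spell$seq[i])
    if (n < k) next
    off <- 0:(n - k)
    rows[[length(rows) + 1L]] <- data.frame(
      kmer = substring(spell$seq[i], off + 1L, off + k),
      spell_row = i, offset = off, stringsAsFactors = FALSE)
  }
  kd <- do.call(rbind, rows)
  uk <- unique(kd$kmer)
  grp <- split(seq_len(nrow(kd)), factor(kd$kmer, levels = uk))
  list(kmers = uk, groups = grp, table = kd, k = k)
}

count_mismatches <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

# core read->allele assignment: support counts per (site, allele)
assign_reads <- function(spell, index, seqs, max_mm, junction_flank) {
  support <- matrix(0L, nrow = nrow(spell), ncol = 1L)
  k <- index$k
  rl <- nchar(seqs)
  probes1 <- substr(seqs, 1L, k)
  probes2 <- substr(seqs, rl - k + 1L, rl)
  m1 <- match(probes1, index$kmers)
  m2 <- match(probes2, index$kmers)
  cand_reads <- which(!is.na(m1) | !is.na(m2))
  for (ri in cand_reads) {
    hits <- list()
    if (!is.na(m1[ri]))
      hits[[1L]] <- cbind(index$table$spell_row[index$groups[[m1[ri]]]],
                          index$table$offset[index$groups[[m1[ri]]]] - 0L)
    if (!is.na(m2[ri]))
      hits[[2L]] <- cbind(index$table$spell_row[index$groups[[m2[ri]]]],
                          index$table$offset[index$groups[[m2[ri]]]] -
                            (rl[ri] - k))
    h <- unique(do.call(rbind, hits))
    seen <- character(0)
    for (j in seq_len(nrow(h))) {
      sr <- h[j, 1]; off <- h[j, 2]
      if (off < 0L || off + rl[ri] > nchar(spell$seq[sr])) next
      key <- paste(spell$site_id[sr], spell$allele[sr])
      if (key %in% seen) next
      frag <- substr(spell$seq[sr], off + 1L, off + rl[ri])
      if (count_mismatches(frag, seqs[ri]) > max_mm) next
      js <- unique(c(spell$j1[sr], spell$j2[sr]))
      spans <- any(js - off >= junction_flank &
                   off + rl[ri] - js >= junction_flank)
      if (!spans) next
      support[sr, 1L] <- support[sr, 1L] + 1L
      seen <- c(seen, key)
    }
  }
  support[, 1L]
}

call_genotype <- function(ref_n, alt_n, min_support, hom_frac = 0.8) {
  tot <- ref_n + alt_n
  out <- rep("missing", length(tot))
  f <- ifelse(tot > 0, alt_n / tot, NA)
  out[tot >= min_support & f >= hom_frac] <- "alt/alt"
  out[tot >= min_support & f <= 1 - hom_frac] <- "ref/ref"
  out[tot >= min_support & f > 1 - hom_frac & f < hom_frac] <- "ref/alt"
  out
}

#' Genotype one SV site from reads
#'
#' Reads passing the quality thresholds are assigned to the reference or
#' alternate allele by exact/near-exact match of their sequence against the
#' two allele-path spellings (reference flank + allele + flank); only reads
#' spanning an allele junction with at least `junction_flank` bases on each
#' side are informative. Genotype by support ratio: alt fraction >= 0.8 is
#' alt/alt, <= 0.2 ref/ref, otherwise ref/alt; fewer than `min_support`
#' informative reads gives `missing`.
#'
#' @param graph A `pansv_graph`.
#' @param site_id Site identifier (must exist in `graph$sites`).
#' @param reads Read data.frame (with `mapq` and `baseq` columns).
#' @param min_map_q,min_base_q Quality exclusion thresholds (default 5).
#' @param min_support Minimum informative reads for a call (default 3).
#' @param max_mm Maximum mismatches tolerated per read (default 2).
#' @param junction_flank Minimum bases on each side of a junction (default 15).
#' @return Data.frame (`SiteGenotype`): `site_id`, `ref_support`,
#'   `alt_support`, `genotype`.
#' @export
genotype_site <- function(graph, site_id, reads, min_map_q = 5L,
                          min_base_q = 5L, min_support = 3L, max_mm = 2L,
                          junction_flank = 15L) {
  if (!site_id %in% graph$sites$site_id) stop("unknown site id: ", site_id)
  res <- genotype_reads(graph, reads, min_map_q, min_base_q, min_support,
                        max_mm, junction_flank,
                        sites = graph$sites[graph$sites$site_id == site_id, ,
                                            drop = FALSE])
  res
}

genotype_reads <- function(graph, reads, min_map_q, min_base_q, min_support,
                           max_mm, junction_flank, sites = graph$sites) {
  g2 <- graph; g2$sites <- sites
  rl <- if (nrow(reads)) nchar(reads$seq1[1]) else 100L
  spell <- site_spellings(g2, flank = rl)
  if (nrow(reads)) {
    reads <- reads[reads$mapq >= min_map_q & reads$baseq >= min_base_q, ,
                   drop = FALSE]
  }
  if (!nrow(reads)) {
    return(data.frame(site_id = sites$site_id,
                      ref_support = 0L, alt_support = 0L,
                      genotype = "missing", stringsAsFactors = FALSE))
  }
  index <- spelling_index(spell, k = min(21L, rl))
  seqs <- c(reads$seq1, revcomp(reads$seq1), reads$seq2, revcomp(reads$seq2))
  supp <- assign_reads(spell, index, seqs, max_mm, junction_flank)
  ref_n <- supp[spell$allele == "ref"][match(sites$site_id,
             spell$site_id[spell$allele == "ref"])]
  alt_n <- supp[spell$allele == "alt"][match(sites$site_id,
             spell$site_id[spell$allele == "alt"])]
  data.frame(site_id = sites$site_id, ref_support = ref_n,
             alt_support = alt_n,
             genotype = call_genotype(ref_n, alt_n, min_support),
             stringsAsFactors = FALSE)
}

#' Genotype all sites across a population panel
#'
#' Runs the site genotyper on every accession's read set and assembles the
#' sites-by-accessions genotype matrix, per-site call rate and alt-allele
#' frequency, and (when the panel carries truth genotypes) the concordance
#' with truth.
#'
#' @param graph A `pansv_graph` built from the panel's SV sites.
#' @param panel A `pansv_panel` from [simulate_population()] (or any list
#'   with `accessions` and `read_sets`).
#' @param ... Passed to [genotype_site()]'s engine.
#' @return List: `genotypes` (character matrix), `support` (long data.frame),
#'   `site_stats`, `concordance` (or NA).
#' @export
genotype_population <- function(graph, panel, ...) {
  acc <- panel$accessions$accession_id
  sites <- graph$sites$site_id
  geno <- matrix("missing", nrow = length(sites), ncol = length(acc),
                 dimnames = list(sites, acc))
  supp <- list()
  for (j in seq_along(acc)) {
    reads <- panel$read_sets[[acc[j]]]
    if (is.null(reads))
      reads <- empty_reads()
    res <- genotype_reads(graph, reads, min_map_q = 5L, min_base_q = 5L,
                          min_support = 3L, max_mm = 2L,
                          junction_flank = 15L, ...)
    geno[res$site_id, j] <- res$genotype
    res$accession_id <- acc[j]
    supp[[j]] <- res
  }
  supp <- do.call(rbind, supp)
  called <- geno != "missing"
  alt_dose <- (geno == "ref/alt") + 2L * (geno == "alt/alt")
  site_stats <- data.frame(
    site_id = sites,
    call_rate = rowMeans(called),
    alt_freq = rowSums(alt_dose * called) / pmax(1L, 2L * rowSums(called)),
    stringsAsFactors = FALSE)
  conc <- NA_real_
  if (!is.null(panel$genotypes)) {
    truth <- panel$genotypes[match(sites, rownames(panel$genotypes)), acc,
                             drop = FALSE]
    conc <- mean(geno == truth)
  }
  list(genotypes = geno, support = supp, site_stats = site_stats,
       concordance = conc)
}

empty_reads <- function() {
  data.frame(read_id = character(), chrom = character(), start1 = integer(),
             start2 = integer(), seq1 = character(), seq2 = character(),
             mapq = integer(), baseq = integer(), stringsAsFactors = FALSE)
}

#' Per-group carrier frequencies from a genotype matrix
#'
#' An accession is a carrier at a site when its genotype contains the
#' alternate allele; missing genotypes are excluded from the denominator.
#'
#' @param genotypes Character matrix (sites x accessions).
#' @param groups Group label per accession (column).
#' @return Data.frame: site_id, group, n, n_carrier, frequency.
#' @export
carrier_frequencies <- function(genotypes, groups) {
  out <- list()
  for (g in unique(groups)) {
    m <- genotypes[, groups == g, drop = FALSE]
    nm <- m != "missing"
    carrier <- m %in% c("ref/alt", "alt/alt")
    dim(carrier) <- dim(m)
    out[[length(out) + 1L]] <- data.frame(
      site_id = rownames(genotypes), group = g,
      n = rowSums(nm), n_carrier = rowSums(carrier & nm),
      frequency = rowSums(carrier & nm) / pmax(1L, rowSums(nm)),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
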