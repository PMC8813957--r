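# Shared format readers/writers. Internal coordinates are 0-based half-open;
# VCF/GFF are 1-based at the boundary, BED stays 0-based half-open.

#' Read / write genomes as FASTA
#' @param genome A `pansv_genome`.
#' @param path File path.
#' @param accession_id Id given to a genome read from FASTA.
#' @return `write_fasta()` the path invisibly; `read_fasta()` a
#'   `pansv_genome`.
#' @export
write_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome$chromosomes)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path, accession_id = basename(path)) {
  x <- Biostrings::readDNAStringSet(path)
  chroms <- as.character(x)
  names(chroms) <- sub("\\s.*$", "", names(x))
  new_genome(accession_id, chroms)
}

#' Write paired-end reads as a pair of FASTQ files
#' @param reads Read data.frame from [simulate_reads()].
#' @param prefix Output prefix; writes `<prefix>_1.fastq`, `<prefix>_2.fastq`.
#' @return The two paths, invisibly.
#' @export
write_fastq <- function(reads, prefix) {
  paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
  qual <- function(seqs, q) vapply(nchar(seqs), function(n)
    paste(rep(rawToChar(as.raw(q + 33L)), n), collapse = ""), character(1))
  for (m in 1:2) {
    seqs <- reads[[paste0("seq", m)]]
    writeLines(as.vector(rbind(paste0("@", reads$read_id, "/", m),
                               seqs, "+", qual(seqs, reads$baseq))),
               paths[m])
  }
  invisible(paths)
}

#' Write variants as VCF 4.2
#'
#' Sequence-resolved InDels and SNPs follow the VCF anchor-base convention
#' (POS is the base immediately left of an InDel); inversions and
#' translocations are written as symbolic ALTs `<INV>` / `<TRA>` with END
#' (and CHR2/DEST for translocations) in INFO.
#'
#' @param variants Variant data.frame.
#' @param ref_genome Reference `pansv_genome` (anchor bases, contig header).
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_vcf <- function(variants, ref_genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=pansv",
               sprintf("##contig=<ID=%s,length=%d>",
                       names(ref_genome$chromosomes),
                       nchar(ref_genome$chromosomes)),
               "##INFO=<ID=SVCLASS,Number=1,Type=String,Description=\"Variant class\">",
               "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
               "##INFO=<ID=CHR2,Number=1,Type=String,Description=\"Destination chromosome\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    chrom <- ref_genome$chromosomes[[v$ref_chrom]]
    if (v$variant_class %in% c("INV", "TRANS")) {
      pos <- v$ref_start + 1L
      ref <- substr(chrom, pos, pos)
      alt <- if (v$variant_class == "INV") "<INV>" else "<TRA>"
      info <- sprintf("SVCLASS=%s;END=%d", v$variant_class, v$ref_end)
      if (v$variant_class == "TRANS" && !is.null(v$dest_chrom) &&
          !is.na(v$dest_chrom))
        info <- paste0(info, ";CHR2=", v$dest_chrom)
    } else if (v$variant_class == "SNP") {
      pos <- v$ref_start + 1L
      ref <- v$ref_allele
      alt <- v$alt_allele
      info <- "SVCLASS=SNP"
    } else {
      # anchor base immediately left of the InDel
      pos <- v$ref_start       # 1-based position of the anchor base
      anchor <- if (pos >= 1L) substr(chrom, pos, pos) else "N"
      ref <- paste0(anchor, v$ref_allele)
      alt <- paste0(anchor, v$alt_allele)
      info <- sprintf("SVCLASS=%s;END=%d", v$variant_class, v$ref_end)
    }
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s", v$ref_chrom,
                       max(pos, 1L), if (is.na(v$id)) "." else v$id,
                       ref, alt, info), con)
  }
  invisible(path)
}

#' Write intervals as BED (0-based half-open)
#' @param df Data.frame with `ref_chrom`/`chrom`, `ref_start`/`start`,
#'   `ref_end`/`end` and optionally `id`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_bed <- function(df, path) {
  chrom <- if ("ref_chrom" %in% names(df)) df$ref_chrom else df$chrom
  start <- if ("ref_start" %in% names(df)) df$ref_start else df$start
  end <- if ("ref_end" %in% names(df)) df$ref_end else df$end
  name <- if ("id" %in% names(df)) df$id else "."
  writeLines(sprintf("%s\t%d\t%d\t%s", chrom, start, end, name), path)
  invisible(path)
}

#' Read / write plain TSV tables
#' @param df Data.frame.
#' @param path File path.
#' @return `write_tsv()` the path invisibly; `read_tsv()` a data.frame.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
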