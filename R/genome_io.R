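#' Read a genome FASTA file
#'
#' Reads all records of a FASTA file into a named [Biostrings::DNAStringSet].
#' Record identifiers are truncated at the first whitespace; sequences are
#' uppercased so downstream scanning never has to case-fold.
#'
#' @param fasta_path path to a FASTA file.
#' @return a [Biostrings::DNAStringSet], one entry per chromosome/contig,
#'   named by FASTA identifier.
#' @export
read_genome <- function(fasta_path) {
  if (!file.exists(fasta_path)) fail("genome FASTA not found: %s", fasta_path)
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(fasta_path),
    error = function(e) fail("FASTA parse error in '%s': %s",
                             fasta_path, conditionMessage(e)))
  if (length(seqs) == 0L) fail("no sequences in FASTA file '%s'", fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  Biostrings::DNAStringSet(toupper(as.character(seqs)))
}

#' Read gene models from a GFF3 annotation
#'
#' Keeps `gene`-type features only. The transcription start site (TSS) is the
#' feature start for plus-strand genes and the feature end for minus-strand
#' genes (1-based genomic coordinates). Genes without a strand are excluded
#' with a warning; duplicated gene identifiers are an error.
#'
#' @param gff3_path path to a GFF3 file containing gene features.
#' @return data.frame with columns `gene_id`, `chrom`, `strand`, `start`,
#'   `end` (1-based inclusive feature span) and `tss` (1-based).
#' @export
read_annotation <- function(gff3_path) {
  if (!file.exists(gff3_path)) fail("annotation GFF3 not found: %s", gff3_path)
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  if (length(gr) == 0L) fail("no gene features in '%s'", gff3_path)
  ids <- gr$ID
  if (is.null(ids)) ids <- gr$Name
  if (is.null(ids) || anyNA(ids)) fail("gene feature without ID in '%s'", gff3_path)
  strand <- as.character(GenomicRanges::strand(gr))
  unstranded <- strand == "*"
  if (any(unstranded)) {
    warning(sprintf("excluding %d gene(s) without strand: %s",
                    sum(unstranded),
                    paste(ids[unstranded], collapse = ", ")))
    gr <- gr[!unstranded]
    ids <- ids[!unstranded]
    strand <- strand[!unstranded]
  }
  if (anyDuplicated(ids)) {
    fail("duplicate gene id in annotation: %s",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  start <- GenomicRanges::start(gr)
  end <- GenomicRanges::end(gr)
  data.frame(
    gene_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = strand,
    start = start,
    end = end,
    tss = ifelse(strand == "+", start, end),
    stringsAsFactors = FALSE
  )
}

#' Extract strand-aware 5'-regulatory regions
#'
#' For each gene the promoter is the `L` bases immediately upstream of the
#' TSS, i.e. TSS-relative positions `[-L, -1]`; the TSS base itself is
#' excluded (the upstream interval is half-open at the TSS). Promoters that
#' would run off a contig edge are truncated, not dropped, so the gene
#' universe stays stable for enrichment. The returned sequence is oriented
#' 5' to 3' along the gene: for minus-strand genes it is the reverse
#' complement of the plus-strand genomic slice.
#'
#' @param genes data.frame from [read_annotation()].
#' @param genome [Biostrings::DNAStringSet] from [read_genome()].
#' @param L promoter length in bp, in `[1, 2500]`.
#' @return data.frame with one row per gene: `gene_id`, `chrom`, `strand`,
#'   `start`, `end` (0-based half-open genomic span), `length`, `truncated`
#'   and `seq`.
#' @export
extract_promoters <- function(genes, genome, L = 1000L) {
  L <- as.integer(L)
  if (is.na(L) || L < 1L || L > 2500L) {
    fail("promoter length L must be in [1, 2500], got %s", L)
  }
  missing_chrom <- setdiff(unique(genes$chrom), names(genome))
  if (length(missing_chrom) > 0L) {
    fail("chromosome(s) absent from genome: %s",
         paste(missing_chrom, collapse = ", "))
  }
  chrom_len <- stats::setNames(Biostrings::width(genome), names(genome))
  n <- nrow(genes)
  start0 <- integer(n); end0 <- integer(n)
  for (i in seq_len(n)) {
    tss <- genes$tss[i]
    clen <- chrom_len[[genes$chrom[i]]]
    if (tss < 1L || tss > clen) {
      fail("TSS of gene %s outside chromosome %s", genes$gene_id[i],
           genes$chrom[i])
    }
    if (genes$strand[i] == "+") {
      # upstream [-L,-1] = 1-based [tss-L, tss-1] = 0-based [tss-1-L, tss-1)
      s <- tss - 1L - L; e <- tss - 1L
    } else {
      # upstream [-L,-1] = 1-based [tss+1, tss+L] = 0-based [tss, tss+L)
      s <- tss; e <- tss + L
    }
    start0[i] <- max(0L, s)
    end0[i] <- min(clen, e)
  }
  len <- end0 - start0
  seqs <- character(n)
  for (i in seq_len(n)) {
    if (len[i] <= 0L) { seqs[i] <- ""; next }
    s <- as.character(Biostrings::subseq(genome[[genes$chrom[i]]],
                                         start = start0[i] + 1L,
                                         end = end0[i]))
    seqs[i] <- if (genes$strand[i] == "-") revcomp(s) else s
  }
  data.frame(
    gene_id = genes$gene_id,
    chrom = genes$chrom,
    strand = genes$strand,
    tss = genes$tss,
    start = start0,
    end = end0,
    length = len,
    truncated = len < L,
    seq = seqs,
    stringsAsFactors = FALSE
  )
}

#' Convert genomic positions to TSS-relative coordinates
#'
#' Uses the no-zero convention: the base immediately upstream of the TSS
#' (along gene orientation) is -1, the TSS base itself is +1, the next
#' downstream base +2, and so on. There is no position 0.
#'
#' @param genomic_pos 1-based genomic position(s) on the gene's chromosome.
#' @param tss 1-based TSS position.
#' @param strand `"+"` or `"-"`.
#' @return signed integer position(s).
#' @seealso [tss_to_genomic()] for the inverse.
#' @export
#' @examples
#' tss_relative(999, tss = 1000, strand = "+")   # -1
#' tss_relative(1000, tss = 1000, strand = "+")  # +1
#' tss_relative(1001, tss = 1000, strand = "-")  # -1
tss_relative <- function(genomic_pos, tss, strand) {
  d <- if (strand == "+") genomic_pos - tss else tss - genomic_pos
  ifelse(d >= 0L, d + 1L, d)
}

#' Convert TSS-relative coordinates back to genomic positions
#'
#' Inverse of [tss_relative()] under the same no-zero convention.
#'
#' @inheritParams tss_relative
#' @param rel_pos signed TSS-relative position(s); 0 is invalid.
#' @return 1-based genomic position(s).
#' @export
tss_to_genomic <- function(rel_pos, tss, strand) {
  if (any(rel_pos == 0L)) fail("TSS-relative position 0 does not exist")
  d <- ifelse(rel_pos > 0L, rel_pos - 1L, rel_pos)
  if (strand == "+") tss + d else tss - d
}

#' Write promoters as BED6
#'
#' @param promoters data.frame from [extract_promoters()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_promoters_bed <- function(promoters, path) {
  bed <- data.frame(
    chrom = promoters$chrom,
    start = promoters$start,
    end = promoters$end,
    name = promoters$gene_id,
    score = 0L,
    strand = promoters$strand
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write promoter sequences as FASTA
#'
#' Sequences are written 5' to 3' along the gene, named by gene id.
#'
#' @inheritParams write_promoters_bed
#' @return the path, invisibly.
#' @export
write_promoters_fasta <- function(promoters, path) {
  dss <- Biostrings::DNAStringSet(promoters$seq)
  names(dss) <- promoters$gene_id
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}
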