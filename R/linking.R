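#' Read one TF binding-region (peak) file
#'
#' Accepts BED3+score (column 5 = height) or ENCODE narrowPeak; coordinates
#' stay 0-based half-open internally.
#'
#' @param path BED or narrowPeak file.
#' @param tf_id TF the peak set belongs to.
#' @param dialect peak-set dialect tag, `"col"` (native genomic DNA) or
#'   `"colamp"` (PCR-amplified, demethylated DNA).
#' @return data.frame with columns `tf_id`, `dialect`, `chrom`, `start`,
#'   `end`, `height`.
#' @export
read_peaks <- function(path, tf_id, dialect) {
  if (!dialect %in% c("col", "colamp")) {
    fail("unknown peak-set dialect '%s' (expected col or colamp)", dialect)
  }
  fmt <- if (grepl("\\.narrowPeak$", path)) "narrowPeak" else "BED"
  gr <- rtracklayer::import(path, format = fmt)
  height <- if (!is.null(gr$signalValue)) gr$signalValue else gr$score
  if (is.null(height)) height <- rep(0, length(gr))
  data.frame(
    tf_id = tf_id,
    dialect = dialect,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    height = as.numeric(height),
    stringsAsFactors = FALSE
  )
}

#' Read a directory of per-TF peak files
#'
#' Files must be named `<TF>_<dialect>.bed` (or `.narrowPeak`), e.g.
#' `TF01_col.bed`, `TF01_colamp.bed`.
#'
#' @param dir directory containing peak files.
#' @return one combined peak data.frame (see [read_peaks()]).
#' @export
read_peak_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.(bed|narrowPeak)$", full.names = TRUE)
  if (length(files) == 0L) fail("no peak files in '%s'", dir)
  sets <- lapply(files, function(f) {
    stem <- sub("\\.(bed|narrowPeak)$", "", basename(f))
    parts <- strsplit(stem, "_")[[1]]
    dialect <- parts[length(parts)]
    tf_id <- paste(parts[-length(parts)], collapse = "_")
    read_peaks(f, tf_id, dialect)
  })
  out <- do.call(rbind, sets)
  rownames(out) <- NULL
  out
}

#' Map TF binding regions onto gene promoters
#'
#' Emits one binding region per (peak, promoter) pair whose genomic overlap
#' is at least `min_overlap` bp (default 1). When `dialect_filter` is set
#' only peak sets of that dialect are used, mirroring the selection of
#' native-DNA ("col") DAP-seq peak sets.
#'
#' @param peaks data.frame from [read_peaks()]/[read_peak_dir()] or the
#'   fixture generator.
#' @param promoters data.frame from [extract_promoters()].
#' @param dialect_filter `NULL` (use all), `"col"` or `"colamp"`.
#' @param min_overlap minimum overlap in bp (default 1).
#' @return data.frame of binding regions: `tf_id`, `gene_id`, `chrom`,
#'   `start`, `end` (peak span, 0-based half-open), `dialect`, `height`,
#'   `overlap_bp`.
#' @export
map_peaks_to_promoters <- function(peaks, promoters, dialect_filter = NULL,
                                   min_overlap = 1L) {
  bad <- setdiff(unique(peaks$dialect), c("col", "colamp"))
  if (length(bad) > 0L) {
    fail("unknown peak-set dialect tag(s): %s", paste(bad, collapse = ", "))
  }
  if (!is.null(dialect_filter)) {
    if (!dialect_filter %in% c("col", "colamp")) {
      fail("unknown dialect_filter '%s'", dialect_filter)
    }
    peaks <- peaks[peaks$dialect == dialect_filter, , drop = FALSE]
  }
  empty <- data.frame(tf_id = character(), gene_id = character(),
                      chrom = character(), start = integer(), end = integer(),
                      dialect = character(), height = numeric(),
                      overlap_bp = integer(), stringsAsFactors = FALSE)
  if (nrow(peaks) == 0L || nrow(promoters) == 0L) return(empty)
  pk <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start + 1L, peaks$end))
  pr <- GenomicRanges::GRanges(promoters$chrom,
                               IRanges::IRanges(promoters$start + 1L,
                                                promoters$end))
  ov <- GenomicRanges::findOverlaps(pk, pr, minoverlap = min_overlap)
  if (length(ov) == 0L) return(empty)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  inter <- pmin(peaks$end[qi], promoters$end[si]) -
    pmax(peaks$start[qi], promoters$start[si])
  out <- data.frame(
    tf_id = peaks$tf_id[qi],
    gene_id = promoters$gene_id[si],
    chrom = peaks$chrom[qi],
    start = peaks$start[qi],
    end = peaks$end[qi],
    dialect = peaks$dialect[qi],
    height = peaks$height[qi],
    overlap_bp = as.integer(inter),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$tf_id, out$gene_id, out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

#' Localize motif hits inside same-TF binding regions
#'
#' A hit becomes a binding site iff its genomic span is fully contained in a
#' binding region of the same TF on the same gene (`mode = "contained"`,
#' the default); `mode = "overlap"` relaxes this to >= 1 bp overlap.
#'
#' @param hits data.frame from [scan_promoters()].
#' @param regions data.frame from [map_peaks_to_promoters()].
#' @param mode `"contained"` or `"overlap"`.
#' @return the retained hits with the supporting region's span appended
#'   (`region_start`, `region_end`, `region_height`, `dialect`).
#' @export
localize_sites <- function(hits, regions, mode = c("contained", "overlap")) {
  mode <- match.arg(mode)
  empty <- cbind(hits[0, , drop = FALSE],
                 data.frame(region_start = integer(), region_end = integer(),
                            region_height = numeric(), dialect = character()))
  if (nrow(hits) == 0L || nrow(regions) == 0L) return(empty)
  key_h <- paste(hits$tf_id, hits$gene_id)
  key_r <- paste(regions$tf_id, regions$gene_id)
  rows <- vector("list", nrow(hits))
  for (i in seq_len(nrow(hits))) {
    cand <- which(key_r == key_h[i] & regions$chrom == hits$chrom[i])
    if (length(cand) == 0L) next
    keep <- if (mode == "contained") {
      cand[regions$start[cand] <= hits$start[i] &
             hits$end[i] <= regions$end[cand]]
    } else {
      cand[pmin(regions$end[cand], hits$end[i]) >
             pmax(regions$start[cand], hits$start[i])]
    }
    if (length(keep) == 0L) next
    # widest supporting region wins ties deterministically
    r <- keep[order(regions$end[keep] - regions$start[keep],
                    regions$start[keep], decreasing = c(TRUE, FALSE),
                    method = "radix")][1]
    rows[[i]] <- cbind(hits[i, , drop = FALSE],
                       data.frame(region_start = regions$start[r],
                                  region_end = regions$end[r],
                                  region_height = regions$height[r],
                                  dialect = regions$dialect[r]))
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build TF-regulator to target-gene pairs
#'
#' One pair per (TF, gene) with at least one localized binding site on a
#' target gene that is a DEG annotated to an enriched biological process.
#' TFs absent from the metadata table (no motif/peak provenance) are
#' excluded with a warning.
#'
#' @param tf_meta TF metadata data.frame with at least `tf_id`, `family`
#'   (optionally `superclass`).
#' @param enriched_gene_map data.frame from [genes_of_enriched_terms()].
#' @param sites data.frame from [localize_sites()].
#' @return object of class `reg_pairs`: a list with `pairs` (one row per
#'   TF-gene pair: `tf_id`, `tf_family`, `gene_id`, `n_regions`, `n_sites`,
#'   `go_ids`) and `sites` (the per-BS rows restricted to those pairs, with
#'   `tf_family` appended), plus `gene_go` (the gene to GO map used).
#' @export
build_pairs <- function(tf_meta, enriched_gene_map, sites) {
  unknown <- setdiff(unique(sites$tf_id), tf_meta$tf_id)
  if (length(unknown) > 0L) {
    warning(sprintf("TF(s) without metadata excluded: %s",
                    paste(unknown, collapse = ", ")))
    sites <- sites[!sites$tf_id %in% unknown, , drop = FALSE]
  }
  sites <- sites[sites$gene_id %in% unique(enriched_gene_map$gene_id), ,
                 drop = FALSE]
  fam <- stats::setNames(tf_meta$family, tf_meta$tf_id)
  sites$tf_family <- unname(fam[sites$tf_id])
  go_by_gene <- split(enriched_gene_map$go_id, enriched_gene_map$gene_id)
  if (nrow(sites) == 0L) {
    pairs <- data.frame(tf_id = character(), tf_family = character(),
                        gene_id = character(), n_regions = integer(),
                        n_sites = integer(), go_ids = character(),
                        stringsAsFactors = FALSE)
  } else {
    key <- paste(sites$tf_id, sites$gene_id, sep = "\r")
    agg <- lapply(split(seq_len(nrow(sites)), key), function(idx) {
      s <- sites[idx, , drop = FALSE]
      data.frame(
        tf_id = s$tf_id[1], tf_family = s$tf_family[1],
        gene_id = s$gene_id[1],
        n_regions = length(unique(paste(s$region_start, s$region_end))),
        n_sites = nrow(s),
        go_ids = paste(sort(unique(go_by_gene[[s$gene_id[1]]])),
                       collapse = ";"),
        stringsAsFactors = FALSE
      )
    })
    pairs <- do.call(rbind, agg)
    pairs <- pairs[order(pairs$gene_id, pairs$tf_id), ]
    rownames(pairs) <- NULL
  }
  sites <- sites[order(sites$gene_id, sites$tf_id, sites$tss_start), ,
                 drop = FALSE]
  rownames(sites) <- NULL
  structure(list(pairs = pairs, sites = sites,
                 gene_go = enriched_gene_map),
            class = "reg_pairs")
}

#' @export
print.reg_pairs <- function(x, ...) {
  cat(sprintf("reg_pairs: %d TF-target pairs over %d genes, %d binding sites\n",
              nrow(x$pairs), length(unique(x$pairs$gene_id)),
              nrow(x$sites)))
  invisible(x)
}

#' Write output block 1 (one row per target gene)
#'
#' Per gene: the associated enriched GO terms with evidence codes and their
#' count, the list of regulator TFs with families and their count, and each
#' binding site's sequence, TSS-relative coordinates and strand.
#'
#' @param pairs `reg_pairs` object from [build_pairs()].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_block1 <- function(pairs, path) {
  genes <- sort(unique(pairs$pairs$gene_id))
  gmap <- pairs$gene_go
  rows <- lapply(genes, function(g) {
    gg <- gmap[gmap$gene_id == g, , drop = FALSE]
    gg <- gg[order(gg$go_id), , drop = FALSE]
    ev <- if ("evidence" %in% names(gg)) gg$evidence else rep("NA", nrow(gg))
    pp <- pairs$pairs[pairs$pairs$gene_id == g, , drop = FALSE]
    ss <- pairs$sites[pairs$sites$gene_id == g, , drop = FALSE]
    data.frame(
      gene_id = g,
      go_terms = paste(sprintf("%s(%s)", gg$go_id, ev), collapse = ";"),
      n_go = nrow(gg),
      regulators = paste(sprintf("%s(%s)", pp$tf_id, pp$tf_family),
                         collapse = ";"),
      n_tfs = nrow(pp),
      binding_sites = paste(
        sprintf("%s:%s@%d..%d(%s)", ss$tf_id, ss$seq, ss$tss_start,
                ss$tss_end, ss$strand), collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  write_tsv_file(do.call(rbind, rows), path)
}

#' Write output block 4 (one row per gene, GO term, TF, binding site)
#'
#' Genomic coordinates are written 1-based inclusive for genome-browser
#' display; the strand is the genomic strand harboring the site.
#'
#' @inheritParams write_block1
#' @return the path, invisibly.
#' @export
write_block4 <- function(pairs, path) {
  gmap <- pairs$gene_go
  ss <- pairs$sites
  rows <- list()
  for (g in sort(unique(ss$gene_id))) {
    gos <- sort(unique(gmap$go_id[gmap$gene_id == g]))
    sg <- ss[ss$gene_id == g, , drop = FALSE]
    for (go in gos) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g,
        go_id = go,
        tf_id = sg$tf_id,
        bs_seq = sg$seq,
        chrom = sg$chrom,
        start = sg$start + 1L,
        end = sg$end,
        strand = sg$genomic_strand,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows) == 0L) {
    data.frame(gene_id = character(), go_id = character(),
               tf_id = character(), bs_seq = character(),
               chrom = character(), start = integer(), end = integer(),
               strand = character(), stringsAsFactors = FALSE)
  } else do.call(rbind, rows)
  out <- out[order(out$gene_id, out$go_id, out$tf_id, out$start), ]
  rownames(out) <- NULL
  write_tsv_file(out, path)
}
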