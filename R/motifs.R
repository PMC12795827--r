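# Integer score grid used for PWM score discretization: 1/1000 bit.
# Scanning, cutoff calibration and the score-distribution DP all live on
# this grid, so "score >= cutoff" means the same thing everywhere.
SCORE_GRANULARITY <- 1000L

#' Construct a position frequency matrix (PFM)
#'
#' @param tf_id TF identifier.
#' @param counts numeric matrix of per-position nucleotide counts, either
#'   4 x w with rows A,C,G,T or w x 4 (transposed automatically).
#' @param source_dialect provenance tag: `"col"`, `"colamp"` or `"external"`.
#' @return object of class `pfm` with fields `tf_id`, `counts` (4 x w,
#'   rownames A,C,G,T) and `source_dialect`.
#' @export
pfm <- function(tf_id, counts, source_dialect = "external") {
  counts <- as.matrix(counts)
  if (ncol(counts) == 4L && nrow(counts) != 4L) counts <- t(counts)
  if (nrow(counts) != 4L) fail("PFM counts must have 4 nucleotide rows")
  if (ncol(counts) < 1L) fail("zero-width motif for %s", tf_id)
  if (any(counts < 0)) fail("negative counts in PFM for %s", tf_id)
  if (any(colSums(counts) <= 0)) {
    fail("PFM for %s has a column with non-positive total", tf_id)
  }
  rownames(counts) <- DNA_BASES
  structure(list(tf_id = tf_id, counts = counts,
                 source_dialect = source_dialect),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("PFM %s (width %d, source %s)\n",
              x$tf_id, ncol(x$counts), x$source_dialect))
  print(round(x$counts, 2))
  invisible(x)
}

#' Width of a motif
#' @param x a `pfm` or `pwm` object.
#' @return motif width in positions.
#' @export
motif_width <- function(x) ncol(if (inherits(x, "pfm")) x$counts else x$weights)

#' Consensus word of a PFM
#' @param x a `pfm` object.
#' @return character consensus (per-position argmax base; ties to the
#'   first of A,C,G,T).
#' @export
consensus <- function(x) {
  paste(DNA_BASES[apply(x$counts, 2, which.max)], collapse = "")
}

#' Read TF motifs from MEME-minimal or JASPAR text
#'
#' JASPAR input is the raw-count format (`>ID name` header followed by four
#' `A [ ... ]` rows); counts are preserved exactly. MEME-minimal
#' probability matrices are converted to counts by multiplying with
#' `nsites` when given, else by 100. Alphabets other than ACGT (DNA) are
#' rejected.
#'
#' @param path motif file path.
#' @param format `"auto"` (default; sniffs the header), `"meme"` or
#'   `"jaspar"`.
#' @return list of [pfm()] objects.
#' @export
read_motifs <- function(path, format = c("auto", "meme", "jaspar")) {
  format <- match.arg(format)
  if (!file.exists(path)) fail("motif file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    format <- if (any(grepl("^MEME version", lines))) "meme" else "jaspar"
  }
  if (format == "meme") parse_meme(lines, path) else parse_jaspar(lines, path)
}

parse_jaspar <- function(lines, path) {
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) fail("no motif headers in JASPAR file '%s'", path)
  out <- vector("list", length(hdr))
  bounds <- c(hdr, length(lines) + 1L)
  for (i in seq_along(hdr)) {
    id <- strsplit(sub("^>\\s*", "", lines[hdr[i]]), "\\s+")[[1]][1]
    block <- lines[(hdr[i] + 1L):(bounds[i + 1L] - 1L)]
    block <- block[nzchar(trimws(block))]
    rows <- list()
    for (ln in block) {
      m <- regmatches(ln, regexec("^\\s*([A-Za-z])\\s*\\[?([^]]*)\\]?\\s*$", ln))[[1]]
      if (length(m) < 3L) next
      base <- toupper(m[2])
      if (base == "U") fail("unsupported alphabet (U) in motif %s", id)
      nums <- as.numeric(strsplit(trimws(m[3]), "\\s+")[[1]])
      rows[[base]] <- nums
    }
    if (!setequal(names(rows), DNA_BASES)) {
      fail("motif %s in '%s' does not use the ACGT alphabet", id, path)
    }
    w <- unique(lengths(rows))
    if (length(w) != 1L || w == 0L) fail("ragged or zero-width motif %s", id)
    counts <- do.call(rbind, rows[DNA_BASES])
    out[[i]] <- pfm(id, counts)
  }
  out
}

parse_meme <- function(lines, path) {
  alpha <- grep("^ALPHABET", lines, value = TRUE)
  if (length(alpha) > 0L && grepl("U", alpha[1])) {
    fail("unsupported alphabet in MEME file '%s'", path)
  }
  motif_idx <- grep("^MOTIF\\b", lines)
  if (length(motif_idx) == 0L) fail("no MOTIF blocks in '%s'", path)
  out <- list()
  for (mi in motif_idx) {
    id <- strsplit(trimws(sub("^MOTIF", "", lines[mi])), "\\s+")[[1]][1]
    # find the letter-probability header after this MOTIF line
    rest <- lines[(mi + 1L):length(lines)]
    lp <- grep("^letter-probability matrix", rest)[1]
    if (is.na(lp)) fail("MOTIF %s without letter-probability matrix", id)
    hdr <- rest[lp]
    w <- as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", hdr))
    if (is.na(w) || w == 0L) fail("zero-width motif %s in '%s'", id, path)
    nsites <- if (grepl("nsites=", hdr)) {
      as.numeric(sub(".*nsites=\\s*([0-9.]+).*", "\\1", hdr))
    } else 100
    rows <- rest[(lp + 1L):(lp + w)]
    probs <- t(vapply(strsplit(trimws(rows), "\\s+"),
                      function(v) as.numeric(v[1:4]), numeric(4)))
    if (anyNA(probs)) fail("malformed probability row in motif %s", id)
    out[[length(out) + 1L]] <- pfm(id, t(probs) * nsites)
  }
  out
}

#' Write motifs in MEME-minimal format
#'
#' Counts are normalised to per-position probabilities; the column total of
#' the first position is written as `nsites` so [read_motifs()] round-trips
#' counts.
#'
#' @param pfms list of [pfm()] objects.
#' @param path output path.
#' @param background background frequencies written to the header.
#' @return the path, invisibly.
#' @export
write_meme <- function(pfms, path, background = rep(0.25, 4)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f",
                       background[1], background[2],
                       background[3], background[4]), ""), con)
  for (p in pfms) {
    w <- motif_width(p)
    nsites <- sum(p$counts[, 1])
    writeLines(sprintf("MOTIF %s", p$tf_id), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= %g E= 0",
                       w, nsites), con)
    probs <- sweep(p$counts, 2, colSums(p$counts), "/")
    for (j in seq_len(w)) {
      writeLines(sprintf(" %.6f %.6f %.6f %.6f",
                         probs[1, j], probs[2, j], probs[3, j], probs[4, j]), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Build a log2-odds position weight matrix from a PFM
#'
#' Weights are `log2((counts[n,i] + alpha*b[n]) / sum_n(counts[n,i] +
#' alpha*b[n]) / b[n])`: the pseudocount `alpha` is distributed over
#' nucleotides in proportion to the background. Weights are additionally
#' discretized to an integer grid of 1/1000 bit (`int_weights`), which is
#' the score definition used by scanning and cutoff calibration.
#'
#' @param x a [pfm()] object.
#' @param background numeric(4) background frequencies (A,C,G,T), strictly
#'   positive, summing to 1 within 1e-9.
#' @param pseudocount total pseudocount alpha added per column (default 1).
#' @return object of class `pwm` with `weights` (bits), `int_weights`,
#'   `background`, `pseudocount`, `max_score` and `min_score` (bits, on the
#'   discretized grid).
#' @export
pfm_to_pwm <- function(x, background = rep(0.25, 4), pseudocount = 1) {
  stopifnot(inherits(x, "pfm"))
  background <- as.numeric(background)
  if (length(background) != 4L || any(background <= 0)) {
    fail("background must be 4 strictly positive frequencies")
  }
  if (abs(sum(background) - 1) > 1e-9) {
    fail("background frequencies must sum to 1 (got %.12f)", sum(background))
  }
  adj <- x$counts + pseudocount * background   # recycles b down the 4 rows
  freq <- sweep(adj, 2, colSums(adj), "/")
  weights <- log2(freq / background)
  dimnames(weights) <- dimnames(x$counts)
  iw <- matrix(as.integer(round(weights * SCORE_GRANULARITY)),
               nrow = 4L, dimnames = dimnames(weights))
  structure(list(
    tf_id = x$tf_id,
    weights = weights,
    int_weights = iw,
    background = stats::setNames(background, DNA_BASES),
    pseudocount = pseudocount,
    max_score = sum(apply(iw, 2, max)) / SCORE_GRANULARITY,
    min_score = sum(apply(iw, 2, min)) / SCORE_GRANULARITY
  ), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM %s (width %d, score range [%.3f, %.3f] bits)\n",
              x$tf_id, motif_width(x), x$min_score, x$max_score))
  print(round(x$weights, 3))
  invisible(x)
}

# reverse-complement a PWM: reverse positions, swap A<->T and C<->G rows
revcomp_pwm <- function(pwm) {
  flip <- function(m) m[COMP_IDX, rev(seq_len(ncol(m))), drop = FALSE]
  pwm$weights <- flip(pwm$weights)
  pwm$int_weights <- flip(pwm$int_weights)
  rownames(pwm$weights) <- DNA_BASES
  rownames(pwm$int_weights) <- DNA_BASES
  pwm
}

#' Score a single word against a PWM
#'
#' Sum of per-position weights on the discretized grid. Any non-ACGT symbol
#' contributes 0 at its position (the background expectation).
#'
#' @param pwm a [pfm_to_pwm()] object.
#' @param word character word of exactly the motif width.
#' @return score in bits.
#' @export
score_word <- function(pwm, word) {
  w <- motif_width(pwm)
  if (nchar(word) != w) {
    fail("word length %d does not match motif width %d", nchar(word), w)
  }
  codes <- dna_codes(word)
  s <- 0L
  for (j in seq_len(w)) {
    if (!is.na(codes[j])) s <- s + pwm$int_weights[codes[j], j]
  }
  unname(s) / SCORE_GRANULARITY
}

#' Exact PWM score distribution under the background model
#'
#' Dynamic programming over positions: the distribution of the discretized
#' word score when each position is drawn i.i.d. from the PWM background.
#' Scores are integers on the 1/1000-bit grid.
#'
#' @param pwm a `pwm` object.
#' @param background optional alternative background (defaults to the PWM's).
#' @return data.frame with columns `score_int` (every attainable grid score
#'   between the minimum and maximum), `prob` and `tail` (P(score >= s)).
#' @export
score_distribution <- function(pwm, background = pwm$background) {
  iw <- pwm$int_weights
  w <- ncol(iw)
  probs <- 1
  minscore <- 0L
  for (j in seq_len(w)) {
    col <- iw[, j]
    cmin <- min(col); cmax <- max(col)
    newlen <- length(probs) + (cmax - cmin)
    newprobs <- numeric(newlen)
    for (n in 1:4) {
      off <- col[n] - cmin
      idx <- seq_along(probs) + off
      newprobs[idx] <- newprobs[idx] + probs * background[n]
    }
    probs <- newprobs
    minscore <- minscore + cmin
  }
  scores <- minscore + seq_along(probs) - 1L
  tail <- rev(cumsum(rev(probs)))
  data.frame(score_int = scores, prob = probs, tail = tail)
}

#' Calibrate a score cutoff at an exact background p-value
#'
#' Returns the smallest discretized score whose background tail probability
#' P(score >= cutoff) is at most `p_threshold`, computed by the exact
#' score-distribution DP. If no attainable score is rare enough (e.g.
#' `p_threshold` below 4^-w for a strict-consensus motif under a uniform
#' background) the maximum score is returned with a warning: only the
#' consensus-scoring set can pass.
#'
#' @param pwm a `pwm` object.
#' @param p_threshold required tail probability, in (0, 1).
#' @param background optional alternative background.
#' @return list with `cutoff` (bits, on the grid), `tail_p` (the attained
#'   tail probability at the cutoff) and `p_threshold`.
#' @export
calibrate_cutoff <- function(pwm, p_threshold, background = pwm$background) {
  if (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold > 1) {
    fail("p_threshold must be in (0, 1]")
  }
  dist <- score_distribution(pwm, background)
  ok <- which(dist$tail <= p_threshold)
  if (length(ok) == 0L) {
    warning(sprintf(
      "motif %s: no score has tail probability <= %g; using max score (tail %.3g)",
      pwm$tf_id, p_threshold, dist$tail[nrow(dist)]))
    i <- nrow(dist)
  } else {
    i <- ok[1]
  }
  list(cutoff = dist$score_int[i] / SCORE_GRANULARITY,
       tail_p = dist$tail[i],
       p_threshold = p_threshold)
}

# integer sliding-window scores of a coded sequence against integer weights;
# NA codes (ambiguity) contribute 0
window_scores <- function(codes, iw) {
  w <- ncol(iw)
  n <- length(codes)
  if (n < w) return(integer(0))
  scores <- integer(n - w + 1L)
  for (j in seq_len(w)) {
    v <- iw[, j][codes[j:(n - w + j)]]
    v[is.na(v)] <- 0L
    scores <- scores + v
  }
  scores
}

#' Scan promoters with calibrated PWMs on both strands
#'
#' Every window of the motif width on either strand whose discretized score
#' reaches the calibrated cutoff yields one hit (ties at the cutoff are
#' included; overlapping hits of the same TF are all reported). The one
#' cutoff is valid on both strands because the background is expected to be
#' strand-symmetric (see [background_composition()]). Hits carry genomic and
#' TSS-relative spans, the strand of the matched word relative to the gene
#' (`sense`/`antisense`), the genomic strand, and the matched sequence as
#' read on the matched strand.
#'
#' @param pwms list of `pwm` objects.
#' @param promoters data.frame from [extract_promoters()].
#' @param p_threshold background tail probability for cutoff calibration
#'   (default 1e-4).
#' @return data.frame of hits sorted by gene, TF, then 5'-to-3' position:
#'   columns `tf_id`, `gene_id`, `chrom`, `start`, `end` (0-based half-open
#'   genomic), `tss_start`, `tss_end` (no-zero TSS-relative, inclusive),
#'   `strand` (sense/antisense), `genomic_strand`, `score` (bits), `seq`.
#' @export
scan_promoters <- function(pwms, promoters, p_threshold = 1e-4) {
  if (nrow(promoters) == 0L) fail("no promoters to scan")
  rows <- list()
  for (pwm in pwms) {
    w <- motif_width(pwm)
    cal <- calibrate_cutoff(pwm, p_threshold)
    cutoff_int <- as.integer(round(cal$cutoff * SCORE_GRANULARITY))
    rc <- revcomp_pwm(pwm)
    for (g in seq_len(nrow(promoters))) {
      pr <- promoters[g, ]
      if (pr$length < w) {
        message(sprintf("promoter of %s (%d bp) shorter than motif %s (%d bp); skipped",
                        pr$gene_id, pr$length, pwm$tf_id, w))
        next
      }
      codes <- dna_codes(pr$seq)
      for (orient in c("sense", "antisense")) {
        iw <- if (orient == "sense") pwm$int_weights else rc$int_weights
        sc <- window_scores(codes, iw)
        hit_i <- which(sc >= cutoff_int)
        if (length(hit_i) == 0L) next
        Lp <- pr$length
        # promoter index i (1-based, along gene) covers TSS-relative i-Lp-1
        tss_start <- hit_i - Lp - 1L
        tss_end <- tss_start + w - 1L
        if (pr$strand == "+") {
          gstart <- pr$start + hit_i - 1L
        } else {
          gstart <- pr$end - hit_i - w + 1L
        }
        word <- substring(pr$seq, hit_i, hit_i + w - 1L)
        if (orient == "antisense") word <- revcomp(word)
        genomic_strand <- if ((pr$strand == "+") == (orient == "sense")) "+" else "-"
        rows[[length(rows) + 1L]] <- data.frame(
          tf_id = pwm$tf_id,
          gene_id = pr$gene_id,
          chrom = pr$chrom,
          start = gstart,
          end = gstart + w,
          tss_start = tss_start,
          tss_end = tss_end,
          strand = orient,
          genomic_strand = genomic_strand,
          score = sc[hit_i] / SCORE_GRANULARITY,
          seq = word,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(tf_id = character(), gene_id = character(),
                      chrom = character(), start = integer(), end = integer(),
                      tss_start = integer(), tss_end = integer(),
                      strand = character(), genomic_strand = character(),
                      score = numeric(), seq = character(),
                      stringsAsFactors = FALSE))
  }
  hits <- do.call(rbind, rows)
  hits <- hits[order(hits$gene_id, hits$tf_id, hits$tss_start, hits$strand), ]
  rownames(hits) <- NULL
  hits
}

#' Select the highest peaks of a peak set
#'
#' Keeps the `n` highest-height peaks; ties at the height boundary are
#' broken by (chrom, start) ascending. If the set has fewer than `n` peaks
#' all are returned. The default `n = 2000` mirrors the standard
#' top-2,000-peaks post-processing of DAP-seq peak sets.
#'
#' @param peakset data.frame with columns `chrom`, `start`, `end`, `height`
#'   (extra columns are preserved).
#' @param n number of peaks to keep (default 2000).
#' @return the filtered peak set, original column order preserved.
#' @export
select_top_peaks <- function(peakset, n = 2000L) {
  if (n < 1L) fail("n must be >= 1")
  ord <- order(-peakset$height, peakset$chrom, peakset$start)
  out <- peakset[utils::head(ord, n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Column-correlation similarity of two motifs
#'
#' Maximum over all alignment offsets and both orientations of the Pearson
#' correlation between the column-wise frequency vectors of the aligned
#' region (minimum aligned width 4). A convenience check only; it is not a
#' statistically calibrated motif comparison.
#'
#' @param pfm_a,pfm_b [pfm()] objects of width >= 4.
#' @return similarity in `[-1, 1]` (0 if no alignment has variance).
#' @export
compare_motifs <- function(pfm_a, pfm_b) {
  wa <- motif_width(pfm_a); wb <- motif_width(pfm_b)
  if (wa < 4L || wb < 4L) fail("compare_motifs requires widths >= 4")
  fa <- sweep(pfm_a$counts, 2, colSums(pfm_a$counts), "/")
  fb0 <- sweep(pfm_b$counts, 2, colSums(pfm_b$counts), "/")
  fb_rc <- fb0[COMP_IDX, rev(seq_len(wb)), drop = FALSE]
  best <- -Inf
  for (fb in list(fb0, fb_rc)) {
    for (off in seq(-(wb - 4L), wa - 4L)) {
      ja <- max(1L, 1L + off):min(wa, wb + off)
      jb <- ja - off
      if (length(ja) < 4L) next
      r <- suppressWarnings(stats::cor(as.vector(fa[, ja]), as.vector(fb[, jb])))
      if (!is.na(r) && r > best) best <- r
    }
  }
  if (!is.finite(best)) 0 else best
}

#' Write motif hits as TSV
#' @param hits data.frame from [scan_promoters()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_hits_tsv <- function(hits, path) write_tsv_file(hits, path)

#' Write motif hits as BED6+ (TF, score in bits, matched sequence and
#' TSS-relative span as extra columns)
#' @inheritParams write_hits_tsv
#' @return the path, invisibly.
#' @export
write_hits_bed <- function(hits, path) {
  bed <- data.frame(
    chrom = hits$chrom, start = hits$start, end = hits$end,
    name = paste(hits$tf_id, hits$gene_id, sep = "|"),
    score = hits$score, strand = hits$genomic_strand,
    tf = hits$tf_id, seq = hits$seq,
    tss_span = sprintf("%d..%d", hits$tss_start, hits$tss_end)
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
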