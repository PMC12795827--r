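# Shared fixtures, memoized so the seeded universe and the end-to-end run
# are generated once per test session.

.compcis_cache <- new.env(parent = emptyenv())

default_fixture <- function() {
  if (is.null(.compcis_cache$fx)) {
    dir <- file.path(tempdir(), "compcis-default-fixture")
    .compcis_cache$fx <- generate_fixture(fixture_config(seed = 1), dir)
  }
  .compcis_cache$fx
}

default_run <- function() {
  if (is.null(.compcis_cache$run)) {
    fx <- default_fixture()
    f <- fx$files
    cfg <- run_config(genome = f$genome, annotation = f$annotation,
                      motifs = f$motifs, peaks_dir = f$peaks_dir,
                      degs = f$degs, go = f$go, tf_meta = f$tf_meta,
                      out_dir = file.path(tempdir(), "compcis-default-run"))
    .compcis_cache$run <- suppressMessages(run_pipeline(cfg))
  }
  .compcis_cache$run
}

# tiny two-chromosome genome written to a temp FASTA
tiny_genome_fasta <- function(seqs) {
  path <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(seqs), function(n) c(paste0(">", n),
                                                      seqs[[n]]))), path)
  path
}

tiny_gff3 <- function(df) {
  path <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               sprintf("%s\ttest\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       df$chrom, df$start, df$end, df$strand, df$gene_id)),
             path)
  path
}

# one-row promoter table from a bare sequence (plus-strand gene whose
# promoter ends just before the TSS)
promoter_from_seq <- function(seq, gene_id = "gX", chrom = "c1") {
  L <- nchar(seq)
  data.frame(gene_id = gene_id, chrom = chrom, strand = "+",
             tss = L + 1L, start = 0L, end = L, length = L,
             truncated = FALSE, seq = seq, stringsAsFactors = FALSE)
}

# PFM with a dominant consensus word (85 vs 5 counts)
strong_pfm <- function(tf_id, word) {
  codes <- match(strsplit(word, "")[[1]], c("A", "C", "G", "T"))
  counts <- matrix(5, 4, length(codes))
  for (j in seq_along(codes)) counts[codes[j], j] <- 85
  pfm(tf_id, counts)
}

# brute-force PWM score distribution by enumerating all 4^w words
enumerate_distribution <- function(pwm) {
  w <- motif_width(pwm)
  grid <- as.matrix(expand.grid(rep(list(1:4), w)))
  sc <- integer(nrow(grid))
  pr <- rep(1, nrow(grid))
  for (j in seq_len(w)) {
    sc <- sc + pwm$int_weights[grid[, j], j]
    pr <- pr * pwm$background[grid[, j]]
  }
  agg <- tapply(pr, sc, sum)
  data.frame(score_int = as.integer(names(agg)),
             prob = as.numeric(agg))
}
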