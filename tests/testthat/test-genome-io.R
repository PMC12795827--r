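test_that("read_genome reads, names and uppercases FASTA records", {
  path <- tiny_genome_fasta(list(c1 = "ACGTACGTAC", c2 = "ggttaacc"))
  g <- read_genome(path)
  expect_setequal(names(g), c("c1", "c2"))
  expect_equal(unname(Biostrings::width(g)), c(10L, 8L))
  expect_identical(as.character(g[["c2"]]), "GGTTAACC")

  empty <- tempfile(fileext = ".fa")
  file.create(empty)
  expect_error(read_genome(empty), "no sequences")
})

test_that("read_annotation applies the strand-aware TSS convention", {
  ann <- tiny_gff3(data.frame(gene_id = c("gA", "gB"), chrom = "c1",
                              start = c(1001L, 1001L), end = c(2000L, 2000L),
                              strand = c("+", "-")))
  genes <- read_annotation(ann)
  expect_equal(genes$tss[genes$gene_id == "gA"], 1001L)
  expect_equal(genes$tss[genes$gene_id == "gB"], 2000L)
})

test_that("read_annotation rejects duplicates and drops strandless genes", {
  dup <- tiny_gff3(data.frame(gene_id = c("gA", "gA"), chrom = "c1",
                              start = c(10L, 500L), end = c(100L, 900L),
                              strand = "+"))
  expect_error(read_annotation(dup), "duplicate gene id")

  ns <- tiny_gff3(data.frame(gene_id = c("gA", "gB"), chrom = "c1",
                             start = c(10L, 500L), end = c(100L, 900L),
                             strand = c("+", ".")))
  expect_warning(genes <- read_annotation(ns), "without strand")
  expect_identical(genes$gene_id, "gA")
})

test_that("extract_promoters covers [-L,-1] and excludes the TSS base", {
  chrom <- paste(rep("ACGT", 1000), collapse = "")   # 4 kb
  path <- tiny_genome_fasta(list(c1 = chrom))
  genome <- read_genome(path)
  genes <- data.frame(gene_id = c("plus", "minus"), chrom = "c1",
                      strand = c("+", "-"), tss = c(1500L, 1500L),
                      stringsAsFactors = FALSE)
  pr <- extract_promoters(genes, genome, L = 1000)
  plus <- pr[pr$gene_id == "plus", ]
  minus <- pr[pr$gene_id == "minus", ]
  # plus strand: 1-based [500, 1499] = 0-based [499, 1499)
  expect_equal(c(plus$start, plus$end), c(499L, 1499L))
  # minus strand: 1-based [1501, 2500] = 0-based [1500, 2500)
  expect_equal(c(minus$start, minus$end), c(1500L, 2500L))
  expect_identical(plus$seq, substr(chrom, 500, 1499))
  expect_identical(minus$seq, revcomp(substr(chrom, 1501, 2500)))
  expect_false(any(pr$truncated))
})

test_that("promoters truncate at contig edges instead of dropping genes", {
  genome <- read_genome(tiny_genome_fasta(list(c1 = strrep("ACGT", 500))))
  genes <- data.frame(gene_id = "gE", chrom = "c1", strand = "+",
                      tss = 300L, stringsAsFactors = FALSE)
  pr <- extract_promoters(genes, genome, L = 1000)
  expect_equal(c(pr$start, pr$end, pr$length), c(0L, 299L, 299L))
  expect_true(pr$truncated)
})

test_that("promoter length is validated", {
  genome <- read_genome(tiny_genome_fasta(list(c1 = strrep("ACGT", 500))))
  genes <- data.frame(gene_id = "g", chrom = "c1", strand = "+", tss = 100L)
  expect_error(extract_promoters(genes, genome, L = 0), "\\[1, 2500\\]")
  expect_error(extract_promoters(genes, genome, L = 3000), "\\[1, 2500\\]")
})

test_that("TSS-relative coordinates follow the no-zero convention", {
  expect_equal(tss_relative(999, tss = 1000, strand = "+"), -1)
  expect_equal(tss_relative(1000, tss = 1000, strand = "+"), 1)
  expect_equal(tss_relative(1001, tss = 1000, strand = "-"), -1)
  expect_equal(tss_relative(1000, tss = 1000, strand = "-"), 1)
  expect_error(tss_to_genomic(0, tss = 1000, strand = "+"), "position 0")
})

test_that("genomic -> TSS-relative -> genomic round-trips over whole promoters", {
  run <- default_run()
  pr <- run$promoters
  for (i in sample(nrow(pr), 10)) {
    g <- pr[i, ]
    gpos <- (g$start + 1L):g$end          # 1-based genomic positions
    rel <- tss_relative(gpos, g$tss, g$strand)
    expect_false(any(rel == 0))
    expect_true(all(rel >= -g$length & rel <= -1))
    expect_equal(tss_to_genomic(rel, g$tss, g$strand), gpos)
  }
})

test_that("shorter promoters are gene-proximal suffixes of longer ones", {
  fx <- default_fixture()
  genome <- read_genome(fx$files$genome)
  genes <- read_annotation(fx$files$annotation)
  long <- extract_promoters(genes, genome, L = 1000)
  short <- extract_promoters(genes, genome, L = 500)
  for (g in genes$gene_id[1:10]) {
    a <- short$seq[short$gene_id == g]
    b <- long$seq[long$gene_id == g]
    expect_identical(a, substr(b, nchar(b) - nchar(a) + 1L, nchar(b)))
  }
})

test_that("minus-strand promoter sequences are reverse complements of the plus-strand slice", {
  fx <- default_fixture()
  genome <- read_genome(fx$files$genome)
  genes <- read_annotation(fx$files$annotation)
  pr <- extract_promoters(genes, genome, L = 1000)
  minus <- pr[pr$strand == "-", ][1:5, ]
  for (i in seq_len(nrow(minus))) {
    g <- minus[i, ]
    slice <- as.character(Biostrings::subseq(genome[[g$chrom]],
                                             g$start + 1L, g$end))
    expect_identical(g$seq, revcomp(slice))
  }
})
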