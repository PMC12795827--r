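test_that("JASPAR raw-count motifs are read exactly", {
  path <- tempfile(fileext = ".jaspar")
  writeLines(c(">M1 testmotif",
               "A [ 3  0 12  1  0  4 ]",
               "C [ 2  1  0  0 11  3 ]",
               "G [ 5 14  1  0  1  6 ]",
               "T [ 4  0  1 13  2  1 ]"), path)
  pfms <- read_motifs(path)
  expect_length(pfms, 1)
  expect_equal(motif_width(pfms[[1]]), 6)
  expect_equal(unname(pfms[[1]]$counts["G", ]), c(5, 14, 1, 0, 1, 6))
})

test_that("MEME probabilities convert to counts via nsites", {
  path <- tempfile(fileext = ".meme")
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "MOTIF M2", "letter-probability matrix: alength= 4 w= 4 nsites= 20 E= 0",
               " 0.50 0.25 0.15 0.10",
               " 0.10 0.50 0.20 0.20",
               " 0.25 0.25 0.25 0.25",
               " 0.00 0.00 0.00 1.00"), path)
  pfms <- read_motifs(path)
  expect_equal(unname(pfms[[1]]$counts[, 1]), c(10, 5, 3, 2))
  expect_equal(unname(pfms[[1]]$counts[, 4]), c(0, 0, 0, 20))
})

test_that("non-DNA alphabets are rejected", {
  path <- tempfile(fileext = ".txt")
  writeLines(c(">MU", "A [ 1 2 ]", "C [ 1 2 ]", "G [ 1 2 ]", "U [ 1 2 ]"),
             path)
  expect_error(read_motifs(path), "alphabet")
})

test_that("write_meme / read_motifs round-trips counts", {
  p <- strong_pfm("TFX", "ACGTAC")
  path <- tempfile(fileext = ".meme")
  write_meme(list(p), path)
  back <- read_motifs(path)
  expect_equal(back[[1]]$counts, p$counts, tolerance = 1e-3)
})

test_that("PWM weights follow the log-odds formula with background pseudocount", {
  # uniform column -> all-zero weights
  u <- pfm("U", matrix(4, 4, 4))
  pw <- pfm_to_pwm(u)
  expect_equal(unname(pw$weights), matrix(0, 4, 4))

  # single-base column, checked against an independent hand evaluation
  p <- pfm("P", matrix(c(8, 0, 0, 0), 4, 1))
  pw <- pfm_to_pwm(p, background = rep(0.25, 4), pseudocount = 1)
  expect_equal(unname(pw$weights["A", 1]), log2(((8 + 0.25) / 9) / 0.25),
               tolerance = 1e-12)
  expect_equal(unname(pw$weights["C", 1]), log2(((0 + 0.25) / 9) / 0.25),
               tolerance = 1e-12)
})

test_that("background must be valid", {
  p <- pfm("P", matrix(1, 4, 4))
  expect_error(pfm_to_pwm(p, background = c(0.3, 0.3, 0.3, 0.2)), "sum to 1")
  expect_error(pfm_to_pwm(p, background = c(1, 0, 0, 0)), "positive")
})

test_that("score_word sums per-position weights and zeroes ambiguity codes", {
  pw <- pfm_to_pwm(strong_pfm("T", "ACGTA"))
  expect_equal(score_word(pfm_to_pwm(pfm("U", matrix(4, 4, 5))), "ACGTA"), 0)
  expect_equal(score_word(pw, "NNNNN"), 0)
  expect_error(score_word(pw, "ACGT"), "length")

  set.seed(7)
  for (rep in 1:5) {
    word <- paste(sample(c("A", "C", "G", "T"), 5, TRUE), collapse = "")
    chars <- strsplit(word, "")[[1]]
    manual <- sum(vapply(1:5, function(j)
      pw$int_weights[chars[j], j], integer(1))) / 1000
    expect_equal(score_word(pw, word), manual)
  }
})

test_that("consensus scores max_score and anti-consensus min_score", {
  pw <- pfm_to_pwm(strong_pfm("T", "ACGTACG"))
  expect_equal(score_word(pw, "ACGTACG"), pw$max_score)
  worst <- paste(rownames(pw$int_weights)[apply(pw$int_weights, 2, which.min)],
                 collapse = "")
  expect_equal(score_word(pw, worst), pw$min_score)
})

test_that("cutoff calibration matches the exact score distribution", {
  # strict consensus, w=3, uniform background: only the consensus word
  # attains the maximum, with probability 1/64
  counts <- matrix(0, 4, 3); counts[cbind(c(1, 2, 3), 1:3)] <- 10
  pw <- pfm_to_pwm(pfm("S", counts))
  d <- score_distribution(pw)
  expect_equal(d$tail[nrow(d)], 1 / 64, tolerance = 1e-12)

  # p_threshold = 1 admits everything
  expect_equal(calibrate_cutoff(pw, 1)$cutoff, pw$min_score)

  # unreachable threshold falls back to max score with a warning
  expect_warning(cal <- calibrate_cutoff(pw, 1e-6), "max score")
  expect_equal(cal$cutoff, pw$max_score)
})

test_that("DP score distribution equals exhaustive enumeration for small motifs", {
  set.seed(11)
  for (w in c(4, 6)) {
    counts <- matrix(sample(0:20, 4 * w, TRUE) + 1, 4, w)
    bg <- c(0.3, 0.2, 0.2, 0.3)
    pw <- pfm_to_pwm(pfm("R", counts), background = bg)
    dp <- score_distribution(pw)
    dp <- dp[dp$prob > 0, ]
    bf <- enumerate_distribution(pw)
    expect_identical(dp$score_int, bf$score_int)
    expect_equal(dp$prob, bf$prob, tolerance = 1e-12)
  }
})

test_that("scanning finds planted words with correct strand and sequence", {
  word <- "ACGTTGCA"
  bgseq <- strrep("AACC", 50)   # word cannot occur in this background
  seq_sense <- paste0(substr(bgseq, 1, 80), word,
                      substr(bgseq, 89, 200))
  pw <- pfm_to_pwm(strong_pfm("TFZ", word))
  hits <- scan_promoters(list(pw), promoter_from_seq(seq_sense), 1e-4)
  expect_equal(nrow(hits), 1)
  expect_identical(hits$strand, "sense")
  expect_identical(hits$seq, word)

  seq_anti <- paste0(substr(bgseq, 1, 80), revcomp(word),
                     substr(bgseq, 89, 200))
  hits2 <- scan_promoters(list(pw), promoter_from_seq(seq_anti), 1e-4)
  expect_equal(nrow(hits2), 1)
  expect_identical(hits2$strand, "antisense")
  expect_identical(hits2$seq, word)
  expect_equal(hits2$score, hits$score)
})

test_that("scanning a reverse-complemented promoter mirrors the hit set", {
  fx <- default_fixture()
  run <- default_run()
  pr <- run$promoters[5, ]
  pfms <- read_motifs(fx$files$motifs)
  bg <- background_composition(run$promoters$seq)
  pw <- pfm_to_pwm(pfms[[1]], background = bg)
  h_fwd <- suppressWarnings(scan_promoters(list(pw), pr, 1e-3))
  pr_rc <- pr; pr_rc$seq <- revcomp(pr$seq)
  h_rc <- suppressWarnings(scan_promoters(list(pw), pr_rc, 1e-3))
  expect_equal(nrow(h_fwd), nrow(h_rc))
  key <- function(h) sort(paste(h$seq, round(h$score, 3)))
  expect_identical(key(h_fwd), key(h_rc))
  # positions mirror: promoter index i maps to Lp - w - i + 2
  if (nrow(h_fwd) > 0) {
    Lp <- pr$length; w <- motif_width(pw)
    i_fwd <- sort(h_fwd$tss_start + Lp + 1L)
    i_rc <- sort(Lp - w - (h_rc$tss_start + Lp + 1L) + 2L)
    expect_equal(i_fwd, i_rc)
  }
})

test_that("lowering the scan p-value threshold never adds hits", {
  run <- default_run()
  fx <- default_fixture()
  pfms <- read_motifs(fx$files$motifs)
  bg <- background_composition(run$promoters$seq)
  pw <- pfm_to_pwm(pfms[[3]], background = bg)
  pr <- run$promoters[1:10, ]
  n_loose <- nrow(suppressWarnings(scan_promoters(list(pw), pr, 1e-3)))
  n_mid <- nrow(suppressWarnings(scan_promoters(list(pw), pr, 1e-4)))
  n_tight <- nrow(suppressWarnings(scan_promoters(list(pw), pr, 1e-6)))
  expect_true(n_loose >= n_mid && n_mid >= n_tight)
})

test_that("promoters shorter than the motif are skipped with a message", {
  pw <- pfm_to_pwm(strong_pfm("T", "ACGTACGT"))
  short <- promoter_from_seq("ACGTA")
  expect_message(h <- scan_promoters(list(pw), short, 1e-4), "skipped")
  expect_equal(nrow(h), 0)
})

test_that("select_top_peaks keeps the highest peaks with deterministic ties", {
  pk <- data.frame(tf_id = "T", dialect = "col", chrom = "c1",
                   start = c(10, 20, 30, 40, 50), end = c(15, 25, 35, 45, 55),
                   height = c(3, 9, 1, 9, 5))
  top2 <- select_top_peaks(pk, 2)
  expect_equal(sort(top2$height), c(9, 9))
  expect_equal(top2$start, c(20, 40))   # ties by (chrom, start)
  expect_equal(nrow(select_top_peaks(pk, 100)), 5)
  expect_error(select_top_peaks(pk, 0), ">= 1")
})

test_that("motif similarity is 1 for self and reverse complement", {
  p <- strong_pfm("A", "ACGGTA")
  expect_equal(compare_motifs(p, p), 1, tolerance = 1e-12)
  rcp <- pfm("Arc", p$counts[4:1, ncol(p$counts):1])
  expect_equal(compare_motifs(p, rcp), 1, tolerance = 1e-12)
})

test_that("motif similarity equals the exhaustive alignment maximum", {
  a <- pfm("A", matrix(c(8, 1, 1, 2,  1, 9, 1, 1,  2, 1, 7, 2,  1, 1, 1, 9),
                       4, 4))
  b <- pfm("B", matrix(c(6, 2, 2, 2,  2, 8, 1, 1,  1, 2, 8, 1,  2, 2, 1, 7),
                       4, 4))
  # width-4 motifs admit exactly one alignment per orientation; compute the
  # expected value directly from the frequency vectors
  fa <- sweep(a$counts, 2, colSums(a$counts), "/")
  fb <- sweep(b$counts, 2, colSums(b$counts), "/")
  fb_rc <- fb[4:1, 4:1]
  expected <- max(cor(as.vector(fa), as.vector(fb)),
                  cor(as.vector(fa), as.vector(fb_rc)))
  expect_equal(compare_motifs(a, b), expected, tolerance = 1e-12)
  expect_error(compare_motifs(a, pfm("C", matrix(1, 4, 3))), "widths >= 4")
})
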