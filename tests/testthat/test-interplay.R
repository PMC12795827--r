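tf_records_demo <- function() {
  data.frame(
    tf_id = c("U1", "D1", "U2", "D2"),
    family = c("bZIP", "bZIP", "WRKY", "MYB"),
    superclass = c("Basic domains", "Basic domains",
                   "Beta-scaffold domains", "Helix-Turn-Helix domains"),
    direction = c("up", "down", "up", "down"),
    mode = c("activator", "activator", "suppressor", "activator"),
    effector_activity = c("weak_activator", "strong_activator",
                          "strong_activator", "weak_activator"),
    effector_strength = c(0.3, 0.9, 0.8, 0.2),
    stringsAsFactors = FALSE)
}

site_row <- function(tf, gene, start, end) {
  data.frame(tf_id = tf, gene_id = gene, chrom = "c1",
             start = start, end = end, tss_start = -200L, tss_end = -191L,
             strand = "sense", genomic_strand = "+", score = 10,
             seq = strrep("A", end - start), region_start = start - 50L,
             region_end = end + 50L, region_height = 5, dialect = "col",
             tf_family = "x", stringsAsFactors = FALSE)
}

pairs_of <- function(sites) {
  structure(list(pairs = unique(sites[c("tf_id", "gene_id")]),
                 sites = sites,
                 gene_go = data.frame(gene_id = unique(sites$gene_id),
                                      go_id = "GO:1", term = "p",
                                      evidence = "IEA")),
            class = "reg_pairs")
}

test_that("regulator classes combine direction and mode", {
  expect_identical(classify_tf("up", "activator"), "UA")
  expect_identical(classify_tf("up", "suppressor"), "US")
  expect_identical(classify_tf("down", "activator"), "DA")
  expect_identical(classify_tf("down", "suppressor"), "DS")
  expect_message(cls <- classify_tf("unchanged", "activator"), "no network class")
  expect_true(is.na(cls))
  expect_error(classify_tf("sideways", "activator"), "direction")
  expect_identical(subnetwork(c("UA", "US", "DA", "DS")),
                   c("A", "A", "R", "R"))
})

test_that("overlap fraction uses the shorter span as denominator", {
  expect_equal(overlap_fraction(c(100, 110), c(100, 110)), 1)
  expect_equal(overlap_fraction(c(100, 110), c(200, 210)), 0)
  # a 10 bp and a 9 bp span sharing 8 bp -> 8/9 of the shorter
  expect_equal(overlap_fraction(c(380, 390), c(382, 391)), 8 / 9)
  expect_equal(overlap_fraction(c(0, 8), c(1, 10)), 7 / 8)
  expect_error(overlap_fraction(c(5, 5), c(1, 10)), "zero-length")
  # symmetry
  set.seed(5)
  for (i in 1:20) {
    a <- sort(sample(0:50, 2)); b <- sort(sample(0:50, 2))
    if (a[1] == a[2] || b[1] == b[2]) next
    expect_equal(overlap_fraction(a, b), overlap_fraction(b, a))
  }
})

test_that("competition requires >1 TF, >80% overlap and opposite directions", {
  rec <- tf_records_demo()
  # one TF only: no candidate
  s1 <- site_row("U1", "g1", 500L, 508L)
  expect_equal(nrow(find_competition(pairs_of(s1), rec)), 0)

  # opposite directions, overlap 8/9 > 0.8: candidate
  s2 <- rbind(site_row("U1", "g1", 500L, 509L),
              site_row("D1", "g1", 501L, 510L))
  cand <- find_competition(pairs_of(s2), rec)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$tf_a, "U1")   # pair oriented (up, down)
  expect_equal(cand$tf_b, "D1")
  expect_equal(cand$overlap, 8 / 9)

  # concordant directions at 95% overlap: no candidate
  s3 <- rbind(site_row("U1", "g1", 500L, 520L),
              site_row("U2", "g1", 501L, 520L))
  expect_equal(nrow(find_competition(pairs_of(s3), rec)), 0)

  # overlap exactly at the threshold boundary is not "over" it
  s4 <- rbind(site_row("U1", "g1", 500L, 510L),
              site_row("D1", "g1", 502L, 512L))   # 8/10 = 0.8
  expect_equal(nrow(find_competition(pairs_of(s4), rec)), 0)
})

test_that("raising the overlap threshold never adds candidates", {
  run <- default_run()
  rec <- utils::read.delim(default_fixture()$files$tf_meta)
  n_08 <- nrow(find_competition(run$pairs, rec, 0.8))
  n_085 <- nrow(find_competition(run$pairs, rec, 0.85))
  n_095 <- nrow(find_competition(run$pairs, rec, 0.95))
  expect_true(n_08 >= n_085 && n_085 >= n_095)
})

test_that("cooperation needs proximity, one subnetwork and a mode/effector clash", {
  rec <- tf_records_demo()
  # U2 is a predicted suppressor with an activator-type effector domain
  s <- rbind(site_row("U1", "g1", 500L, 508L),
             site_row("U2", "g1", 520L, 528L))   # gap 12
  coop <- find_cooperation(pairs_of(s), rec, window = 50)
  expect_equal(nrow(coop), 1)
  expect_equal(coop$gap, 12L)
  expect_equal(coop$discordant_tf, "U2")
  expect_equal(coop$subnetwork, "A")

  # gap beyond the window: nothing
  s2 <- rbind(site_row("U1", "g1", 500L, 508L),
              site_row("U2", "g1", 708L, 716L))
  expect_equal(nrow(find_cooperation(pairs_of(s2), rec, window = 50)), 0)

  # different subnetworks: nothing
  s3 <- rbind(site_row("D2", "g1", 500L, 508L),
              site_row("U2", "g1", 520L, 528L))
  expect_equal(nrow(find_cooperation(pairs_of(s3), rec, window = 50)), 0)
})

test_that("competition and cooperation are mutually exclusive per site pair", {
  run <- default_run()
  rec <- utils::read.delim(default_fixture()$files$tf_meta)
  comp <- find_competition(run$pairs, rec)
  coop <- find_cooperation(run$pairs, rec)
  key <- function(d) paste(d$gene_id, pmin(d$tf_a, d$tf_b),
                           pmax(d$tf_a, d$tf_b), pmin(d$start_a, d$start_b))
  expect_length(intersect(key(comp), key(coop)), 0)
})

test_that("mechanism interpretation follows the replacement logic", {
  rec <- tf_records_demo()
  cand <- data.frame(tf_a = "U1", tf_b = "D1")  # up weak vs down strong
  expect_identical(interpret_mechanism(cand, rec, "down"),
                   "suppression_by_weak_activator_replacement")
  cand2 <- data.frame(tf_a = "U2", tf_b = "D2") # up strong vs down weak
  expect_identical(interpret_mechanism(cand2, rec, "up"),
                   "activation_by_strong_activator_replacement")
  # stronger incoming activator yet target goes down: unexplained
  expect_identical(interpret_mechanism(cand2, rec, "down"), "unexplained")
  # no activity data at all
  rec_na <- rec
  rec_na$effector_strength <- NA
  rec_na$effector_activity <- "unknown"
  expect_identical(interpret_mechanism(cand, rec_na, "down"),
                   "insufficient_activity_data")
})

test_that("candidate summaries count genes by direction category", {
  cands <- data.frame(
    gene_id = c(sprintf("d%02d", 1:12), sprintf("u%02d", 1:10),
                rep(sprintf("b%02d", 1:3), each = 2)),
    target_direction = c(rep("down", 12), rep("up", 10),
                         rep(c("down", "up"), 3)),
    stringsAsFactors = FALSE)
  s <- summarize_candidates(cands, suppressor_target_total = 79)
  expect_equal(unname(s$categories), c(12L, 10L, 3L))
  expect_equal(s$total, 25L)
  expect_equal(s$percent_of_suppressor_targets, 32L)

  empty <- summarize_candidates(cands[0, ], 79)
  expect_equal(empty$total, 0L)
  expect_equal(length(empty$family_table), 0L)
  # zero denominator omits the percentage
  expect_true(is.na(summarize_candidates(cands, 0)$percent_of_suppressor_targets))
})
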