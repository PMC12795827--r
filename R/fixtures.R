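#' Configuration for the synthetic test universe
#'
#' Defaults describe a toy-scale universe structured like real inputs:
#' 2 chromosomes of 100 kb, 60 genes with 1 kb 5'-regulatory regions, 8 TFs
#' with motif widths 6-10, DAP-seq-like peak sets of 150-300 bp around
#' planted sites, DEG lists in both directions, and a GO annotation with
#' one strongly enriched biological-process term. The seed fully determines
#' every emitted byte.
#'
#' The 8-TF panel is a fixed design (competition pairs use 1-shifted
#' consensus words so two exact words share >80 % of the shorter site; a
#' 2-shifted pair provides a 75 %-overlap decoy; a mode/effector-discordant
#' suppressor provides cooperation signal); counts of genes, sites,
#' clusters, GO terms and DEGs are tunable.
#'
#' @param seed integer RNG seed.
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param n_genes number of genes (alternating strands, split over
#'   chromosomes).
#' @param L promoter length in bp.
#' @param n_planted_per_tf ordinary (non-cluster) planted sites per TF;
#'   2 of them go to non-enriched genes.
#' @param n_competition_clusters planted competition clusters (split over
#'   the two opposite-direction TF pairs).
#' @param n_decoy_concordant planted overlapping clusters whose TFs share a
#'   direction (must never be reported).
#' @param n_decoy_lowoverlap planted opposite-direction clusters with
#'   overlap 6/8 = 0.75 (must never be reported).
#' @param n_cooperation_pairs planted cooperative site pairs (gap 12 bp).
#' @param n_offpeak_per_tf consensus sites planted without any supporting
#'   "col" peak ("colamp"-only coverage), exercising site localization and
#'   the dialect filter.
#' @param n_go_terms number of GO terms (>= 2; term 1 is the enriched one).
#' @param n_deg_down,n_deg_up DEG counts per direction.
#' @param n_enriched_up up-DEGs annotated to the enriched term (all
#'   down-DEGs are annotated to it).
#' @param n_enriched_bg non-DEG genes annotated to the enriched term.
#' @param n_pristine genes kept free of any planting, used as clean decoy
#'   promoters when checking scan false-positive rates.
#' @param composition background nucleotide frequencies (A,C,G,T).
#' @return a `fixture_config` list.
#' @export
fixture_config <- function(seed = 1L,
                           n_chromosomes = 2L,
                           chrom_length = 100000L,
                           n_genes = 60L,
                           L = 1000L,
                           n_planted_per_tf = 6L,
                           n_competition_clusters = 4L,
                           n_decoy_concordant = 2L,
                           n_decoy_lowoverlap = 2L,
                           n_cooperation_pairs = 2L,
                           n_offpeak_per_tf = 2L,
                           n_go_terms = 10L,
                           n_deg_down = 10L,
                           n_deg_up = 10L,
                           n_enriched_up = 6L,
                           n_enriched_bg = 2L,
                           n_pristine = 14L,
                           composition = c(0.3, 0.2, 0.2, 0.3)) {
  cfg <- as.list(environment())
  cfg$n_tfs <- 8L
  spacing <- (cfg$chrom_length - 2L * cfg$L - 1000L) %/%
    ceiling(cfg$n_genes / cfg$n_chromosomes)
  if (spacing < 2L * cfg$L + 100L) {
    fail("chromosomes too short for %d genes with L=%d (promoters would overlap)",
         cfg$n_genes, cfg$L)
  }
  cfg$spacing <- spacing
  nA <- ceiling(cfg$n_competition_clusters / 2)
  nB <- cfg$n_competition_clusters - nA
  if (cfg$n_deg_down < nA + cfg$n_decoy_concordant + cfg$n_cooperation_pairs + 2L) {
    fail("not enough down-DEG genes for the requested cluster counts")
  }
  if (cfg$n_deg_up < nB + cfg$n_decoy_lowoverlap + 2L) {
    fail("not enough up-DEG genes for the requested cluster counts")
  }
  if (cfg$n_genes < cfg$n_deg_down + cfg$n_deg_up + cfg$n_enriched_bg +
      cfg$n_pristine + 4L) {
    fail("n_genes too small for the DEG, background and pristine gene pools")
  }
  if (cfg$n_go_terms < 2L) fail("n_go_terms must be >= 2")
  if (abs(sum(cfg$composition) - 1) > 1e-9) {
    fail("composition must sum to 1")
  }
  class(cfg) <- "fixture_config"
  cfg
}

rand_word <- function(w, composition) {
  paste(sample(DNA_BASES, w, replace = TRUE, prob = composition), collapse = "")
}

# A consensus panel is usable only if no TF's word (either orientation) can
# lie across another TF's planted word at >80 % overlap of the shorter one
# with too few fixed mismatches -- otherwise a planted site of one TF could
# spawn an unplanned near-consensus hit of another at competing overlap.
# Since a p<=1e-4 cutoff can admit single-mismatch words, opposite-direction
# pairs (the only ones that could form spurious competition candidates)
# need >= 2 mismatches inside the overlap; same-direction pairs need >= 1.
# The deliberately shifted competition pairs are exempt at their design
# offset.
panel_words_ok <- function(words, dirs, exempt) {
  n <- length(words)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    need <- if (dirs[a] == dirs[b]) 1L else 2L
    wa <- nchar(words[a]); wb <- nchar(words[b])
    ca <- strsplit(words[a], "")[[1]]
    for (orient in c("fwd", "rc")) {
      cb <- strsplit(if (orient == "fwd") words[b] else
        revcomp(words[b]), "")[[1]]
      for (o in seq(-(wb - 1L), wa - 1L)) {
        ov <- min(wa, o + wb) - max(0L, o)
        if (ov / min(wa, wb) <= 0.8) next
        ia <- (max(0L, o) + 1L):min(wa, o + wb)
        if (sum(ca[ia] != cb[ia - o]) >= need) next
        key <- sprintf("%d:%d:%d:%s", a, b, o, orient)
        if (!key %in% exempt) return(FALSE)
      }
    }
  }
  TRUE
}

# fixed 8-TF panel; consensus words derived from the seeded RNG, redrawn
# until the cross-word compatibility check passes
fixture_tf_panel <- function(composition) {
  exempt <- c("1:2:1:fwd", "2:1:-1:fwd", "3:4:1:fwd", "4:3:-1:fwd",
              "5:6:1:fwd", "6:5:-1:fwd")
  dirs <- c("up", "down", "up", "down", "up", "up", "down", "up")
  for (attempt in seq_len(200L)) {
    c1 <- rand_word(8, composition)
    c2 <- paste0(substr(c1, 2, 8), rand_word(1, composition))
    c3 <- rand_word(9, composition)
    c4 <- paste0(substr(c3, 2, 9), rand_word(1, composition))
    c5 <- rand_word(10, composition)
    c6 <- paste0(substr(c5, 2, 10), rand_word(1, composition))
    c7 <- paste0(substr(c1, 3, 8), rand_word(2, composition))
    c8 <- rand_word(6, composition)
    if (panel_words_ok(c(c1, c2, c3, c4, c5, c6, c7, c8), dirs, exempt)) break
    if (attempt == 200L) fail("could not draw a compatible consensus panel")
  }
  data.frame(
    tf_id = sprintf("TF%02d", 1:8),
    family = c("bZIP", "bZIP", "HD-ZIP", "HD-ZIP", "WRKY", "WRKY",
               "MYB", "AP2/ERF"),
    superclass = c("Basic domains", "Basic domains",
                   "Helix-Turn-Helix domains", "Helix-Turn-Helix domains",
                   "Beta-scaffold domains", "Beta-scaffold domains",
                   "Helix-Turn-Helix domains", "AP2/ERF domains"),
    direction = c("up", "down", "up", "down", "up", "up", "down", "up"),
    mode = c("activator", "activator", "activator", "activator",
             "suppressor", "suppressor", "activator", "suppressor"),
    effector_activity = c("weak_activator", "strong_activator",
                          "strong_activator", "weak_activator",
                          "repressor", "repressor", "unknown",
                          "strong_activator"),
    effector_strength = c(0.3, 0.9, 0.85, 0.25, -0.7, -0.6, NA, 0.8),
    consensus = c(c1, c2, c3, c4, c5, c6, c7, c8),
    width = c(8L, 8L, 9L, 9L, 10L, 10L, 8L, 6L),
    stringsAsFactors = FALSE
  )
}

# PFM with 85 counts on the consensus base and 5 on the others
consensus_pfm <- function(tf_id, word) {
  codes <- dna_codes(word)
  counts <- matrix(5, nrow = 4, ncol = length(codes),
                   dimnames = list(DNA_BASES, NULL))
  for (j in seq_along(codes)) counts[codes[j], j] <- 85
  pfm(tf_id, counts, source_dialect = "col")
}

#' Generate the synthetic test universe
#'
#' Emits a complete, seeded input set (genome FASTA, GFF3 annotation,
#' MEME motif file, per-TF BED peak sets tagged `col`/`colamp`, DEG, GO and
#' TF-metadata TSVs) together with a ground-truth manifest
#' (`manifest.json`) recording every planted site, peak, expected
#' regulator-target pair and expected/decoy interplay candidate, so each
#' pipeline stage has an oracle. Same seed, same bytes.
#'
#' @param config a [fixture_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with `dir`, `files` (named paths) and
#'   `manifest` (the parsed manifest list).
#' @export
generate_fixture <- function(config = fixture_config(), dir) {
  stopifnot(inherits(config, "fixture_config"))
  if (exists(".Random.seed", envir = .GlobalEnv)) {
    old_seed <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old_seed, envir = .GlobalEnv), add = TRUE)
  }
  set.seed(config$seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  peak_dir <- file.path(dir, "peaks")
  dir.create(peak_dir, showWarnings = FALSE)

  ## chromosomes as mutable character vectors
  chrom_names <- sprintf("chr%d", seq_len(config$n_chromosomes))
  chroms <- lapply(chrom_names, function(cn) {
    sample(DNA_BASES, config$chrom_length, replace = TRUE,
           prob = config$composition)
  })
  names(chroms) <- chrom_names

  ## gene layout: alternating strands, fixed spacing
  per_chrom <- ceiling(config$n_genes / config$n_chromosomes)
  genes <- data.frame(gene_id = sprintf("g%03d", seq_len(config$n_genes)),
                      chrom = chrom_names[((seq_len(config$n_genes) - 1L) %/%
                                             per_chrom) + 1L],
                      strand = rep_len(c("+", "-"), config$n_genes),
                      stringsAsFactors = FALSE)
  slot <- (seq_len(config$n_genes) - 1L) %% per_chrom
  genes$tss <- config$L + 500L + slot * config$spacing
  genes$start <- ifelse(genes$strand == "+", genes$tss,
                        pmax(1L, genes$tss - 499L))
  genes$end <- ifelse(genes$strand == "+",
                      pmin(config$chrom_length, genes$tss + 499L), genes$tss)
  # promoter genomic span, 0-based half-open
  genes$prom_start <- ifelse(genes$strand == "+",
                             genes$tss - 1L - config$L, genes$tss)
  genes$prom_end <- genes$prom_start + config$L

  ## TF panel and motifs
  tfs <- fixture_tf_panel(config$composition)
  pfms <- lapply(seq_len(nrow(tfs)),
                 function(i) consensus_pfm(tfs$tf_id[i], tfs$consensus[i]))

  ## gene pools
  nA <- ceiling(config$n_competition_clusters / 2)
  nB <- config$n_competition_clusters - nA
  down_genes <- genes$gene_id[seq_len(config$n_deg_down)]
  up_genes <- genes$gene_id[config$n_deg_down + seq_len(config$n_deg_up)]
  compA_genes <- down_genes[seq_len(nA)]
  dc_genes <- down_genes[nA + seq_len(config$n_decoy_concordant)]
  coop_genes <- down_genes[nA + config$n_decoy_concordant +
                             seq_len(config$n_cooperation_pairs)]
  compB_genes <- up_genes[seq_len(nB)]
  dl_genes <- up_genes[nB + seq_len(config$n_decoy_lowoverlap)]
  enriched_up <- up_genes[seq_len(config$n_enriched_up)]
  bg_enriched <- genes$gene_id[config$n_deg_down + config$n_deg_up +
                                 seq_len(config$n_enriched_bg)]
  enriched_genes <- c(down_genes, enriched_up, bg_enriched)
  special_genes <- c(compA_genes, dc_genes, coop_genes, compB_genes, dl_genes)
  free_enriched <- setdiff(c(down_genes, enriched_up), special_genes)
  pristine <- genes$gene_id[(config$n_genes - config$n_pristine + 1L):
                              config$n_genes]
  mid_pool <- setdiff(genes$gene_id,
                      c(enriched_genes, special_genes, pristine))
  if (length(free_enriched) < max(2L, config$n_planted_per_tf - 2L)) {
    fail("infeasible packing: too few enriched genes left for ordinary sites")
  }

  ## planting machinery ----------------------------------------------------
  gene_row <- function(g) genes[genes$gene_id == g, , drop = FALSE]
  occupied <- stats::setNames(vector("list", config$n_genes), genes$gene_id)
  margin <- 80L

  choose_offset <- function(g, len) {
    occ <- occupied[[g]]
    for (try in seq_len(500L)) {
      q <- sample.int(config$L - len + 1L, 1L) - 1L
      ok <- TRUE
      if (length(occ) > 0L) {
        for (iv in occ) {
          if (!(q >= iv[2] + margin || q + len <= iv[1] - margin)) {
            ok <- FALSE; break
          }
        }
      }
      if (ok) {
        occupied[[g]][[length(occupied[[g]]) + 1L]] <<- c(q, q + len)
        return(q)
      }
    }
    fail("infeasible packing: cannot place a %d bp unit in promoter of %s",
         len, g)
  }

  # write `text` along the gene at promoter offset q (0-based, 5'->3' along
  # the gene); returns a function mapping (unit offset d, width w) to the
  # 0-based half-open genomic span
  plant_text <- function(g, q, text) {
    gr <- gene_row(g)
    len <- nchar(text)
    if (gr$strand == "+") {
      gstart <- gr$prom_start + q
      chroms[[gr$chrom]][(gstart + 1L):(gstart + len)] <<-
        strsplit(text, "")[[1]]
      function(d, w) c(gstart + d, gstart + d + w)
    } else {
      gstart <- gr$prom_end - q - len
      chroms[[gr$chrom]][(gstart + 1L):(gstart + len)] <<-
        strsplit(revcomp(text), "")[[1]]
      function(d, w) c(gr$prom_end - q - d - w, gr$prom_end - q - d)
    }
  }

  sites <- list()
  record_site <- function(tf_i, g, span, strand, kind, in_col_peak) {
    gr <- gene_row(g)
    word <- tfs$consensus[tf_i]
    plus_word <- if ((gr$strand == "+") == (strand == "sense")) word else
      revcomp(word)
    sites[[length(sites) + 1L]] <<- data.frame(
      tf_id = tfs$tf_id[tf_i], gene_id = g, chrom = gr$chrom,
      start = span[1], end = span[2], strand = strand,
      plus_word = plus_word, kind = kind, in_col_peak = in_col_peak,
      stringsAsFactors = FALSE)
  }

  plant_single <- function(tf_i, g, strand, kind, in_col_peak) {
    w <- tfs$width[tf_i]
    word <- tfs$consensus[tf_i]
    text <- if (strand == "sense") word else revcomp(word)
    q <- choose_offset(g, w)
    span_of <- plant_text(g, q, text)
    record_site(tf_i, g, span_of(0L, w), strand, kind, in_col_peak)
  }

  # two 1-shifted (or 2-shifted) words sharing one locus
  plant_cluster <- function(tf_i, tf_j, g, shift, kind) {
    wi <- tfs$width[tf_i]; wj <- tfs$width[tf_j]
    text <- paste0(tfs$consensus[tf_i],
                   substr(tfs$consensus[tf_j], wj - shift + 1L, wj))
    q <- choose_offset(g, nchar(text))
    span_of <- plant_text(g, q, text)
    record_site(tf_i, g, span_of(0L, wi), "sense", kind, TRUE)
    record_site(tf_j, g, span_of(shift, wj), "sense", kind, TRUE)
  }

  plant_coop <- function(tf_i, tf_j, g, gap) {
    wi <- tfs$width[tf_i]; wj <- tfs$width[tf_j]
    filler <- rand_word(gap, config$composition)
    text <- paste0(tfs$consensus[tf_i], filler, tfs$consensus[tf_j])
    q <- choose_offset(g, nchar(text))
    span_of <- plant_text(g, q, text)
    record_site(tf_i, g, span_of(0L, wi), "sense", "cooperation", TRUE)
    record_site(tf_j, g, span_of(wi + gap, wj), "sense", "cooperation", TRUE)
  }

  ## special plantings
  for (g in compA_genes) plant_cluster(1L, 2L, g, 1L, "competition")
  for (g in compB_genes) plant_cluster(3L, 4L, g, 1L, "competition")
  for (g in dc_genes) plant_cluster(5L, 6L, g, 1L, "decoy_concordant")
  for (g in dl_genes) plant_cluster(1L, 7L, g, 2L, "decoy_lowoverlap")
  for (g in coop_genes) plant_coop(8L, 5L, g, 12L)

  ## ordinary planted sites, alternating sense/antisense: 2 per TF in
  ## enriched DEG genes (these become regulator-target pairs), the rest in
  ## the larger non-enriched mid pool
  n_enr <- min(2L, config$n_planted_per_tf, length(free_enriched))
  n_mid <- min(config$n_planted_per_tf - n_enr, length(mid_pool))
  for (tf_i in seq_len(nrow(tfs))) {
    gs <- c(sample(free_enriched, n_enr), sample(mid_pool, n_mid))
    for (si in seq_along(gs)) {
      plant_single(tf_i, gs[si], if (si %% 2L == 1L) "sense" else "antisense",
                   "regular", TRUE)
    }
  }

  ## off-peak decoy sites: found by the scanner, but covered only by a
  ## colamp peak, so a col-filtered run must drop them at localization
  for (tf_i in seq_len(nrow(tfs))) {
    if (config$n_offpeak_per_tf < 1L || length(mid_pool) == 0L) break
    gs <- sample(mid_pool, min(config$n_offpeak_per_tf, length(mid_pool)))
    for (g in gs) plant_single(tf_i, g, "sense", "offpeak_decoy", FALSE)
  }

  sites <- do.call(rbind, sites)
  rownames(sites) <- NULL

  ## peaks -----------------------------------------------------------------
  make_peak <- function(chrom, s, e) {
    wpk <- sample(150:300, 1L)
    lo <- max(0L, e - wpk)
    hi <- min(s, config$chrom_length - wpk)
    ps <- if (hi <= lo) lo else sample(lo:hi, 1L)
    c(ps, ps + wpk)
  }
  peak_rows <- list()
  add_peak <- function(tf_id, dialect, chrom, span) {
    peak_rows[[length(peak_rows) + 1L]] <<- data.frame(
      tf_id = tf_id, dialect = dialect, chrom = chrom,
      start = span[1], end = span[2],
      height = sample(10:999, 1L), stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    if (s$in_col_peak) {
      add_peak(s$tf_id, "col", s$chrom, make_peak(s$chrom, s$start, s$end))
    } else {
      add_peak(s$tf_id, "colamp", s$chrom, make_peak(s$chrom, s$start, s$end))
    }
  }
  for (tf_id in tfs$tf_id) {          # background peaks off the signal
    for (b in 1:2) {
      ps <- sample.int(config$chrom_length - 300L, 1L)
      add_peak(tf_id, "col", sample(chrom_names, 1L), c(ps, ps + sample(150:300, 1L)))
    }
    ps <- sample.int(config$chrom_length - 300L, 1L)
    add_peak(tf_id, "colamp", sample(chrom_names, 1L),
             c(ps, ps + sample(150:300, 1L)))
  }
  peaks <- do.call(rbind, peak_rows)

  ## DEG, GO, TF metadata --------------------------------------------------
  degs <- data.frame(
    gene_id = c(down_genes, up_genes),
    direction = c(rep("down", length(down_genes)),
                  rep("up", length(up_genes))),
    experiment = "exp1", stringsAsFactors = FALSE)

  go_rows <- list(data.frame(gene_id = enriched_genes, go_id = "GO:0000001",
                             term = "synthetic enriched process",
                             evidence = "IEA", stringsAsFactors = FALSE))
  other_genes <- setdiff(genes$gene_id, enriched_genes)
  blocks <- split(other_genes,
                  ceiling(seq_along(other_genes) /
                            max(1L, ceiling(length(other_genes) /
                                              max(1L, config$n_go_terms - 1L)))))
  ti <- 2L
  for (b in blocks) {
    if (ti > config$n_go_terms) break
    go_rows[[length(go_rows) + 1L]] <- data.frame(
      gene_id = b, go_id = sprintf("GO:%07d", ti),
      term = sprintf("synthetic process %d", ti),
      evidence = "IEA", stringsAsFactors = FALSE)
    ti <- ti + 1L
  }
  while (ti <= config$n_go_terms) {   # extra random terms
    go_rows[[length(go_rows) + 1L]] <- data.frame(
      gene_id = sample(genes$gene_id, 8L),
      go_id = sprintf("GO:%07d", ti),
      term = sprintf("synthetic process %d", ti),
      evidence = "IEA", stringsAsFactors = FALSE)
    ti <- ti + 1L
  }
  go_ann <- do.call(rbind, go_rows)

  ## expected outcomes -----------------------------------------------------
  expected_competition <- do.call(rbind, c(list(
    data.frame(gene_id = character(), tf_up = character(),
               tf_down = character(), overlap = numeric(),
               target_direction = character(), stringsAsFactors = FALSE)),
    lapply(compA_genes, function(g) data.frame(
      gene_id = g, tf_up = "TF01", tf_down = "TF02", overlap = 7 / 8,
      target_direction = "down", stringsAsFactors = FALSE)),
    lapply(compB_genes, function(g) data.frame(
      gene_id = g, tf_up = "TF03", tf_down = "TF04", overlap = 8 / 9,
      target_direction = "up", stringsAsFactors = FALSE))))
  expected_cooperation <- do.call(rbind, c(list(
    data.frame(gene_id = character(), tf_a = character(),
               tf_b = character(), gap = integer(),
               stringsAsFactors = FALSE)),
    lapply(coop_genes, function(g) data.frame(
      gene_id = g, tf_a = "TF08", tf_b = "TF05", gap = 12L,
      stringsAsFactors = FALSE))))
  decoy_clusters <- rbind(
    if (length(dc_genes) > 0L)
      data.frame(gene_id = dc_genes, tf_a = "TF05", tf_b = "TF06",
                 reason = "concordant_directions", stringsAsFactors = FALSE),
    if (length(dl_genes) > 0L)
      data.frame(gene_id = dl_genes, tf_a = "TF01", tf_b = "TF07",
                 reason = "overlap_below_threshold", stringsAsFactors = FALSE))
  in_pair <- sites$in_col_peak & sites$gene_id %in% enriched_genes &
    sites$gene_id %in% degs$gene_id
  expected_pairs <- unique(sites[in_pair, c("tf_id", "gene_id")])
  expected_pairs <- expected_pairs[order(expected_pairs$gene_id,
                                         expected_pairs$tf_id), ]
  rownames(expected_pairs) <- NULL

  ## write files -----------------------------------------------------------
  files <- list(
    genome = file.path(dir, "genome.fa"),
    annotation = file.path(dir, "genes.gff3"),
    motifs = file.path(dir, "motifs.meme"),
    peaks_dir = peak_dir,
    degs = file.path(dir, "degs.tsv"),
    go = file.path(dir, "go_annotations.tsv"),
    tf_meta = file.path(dir, "tf_metadata.tsv"),
    manifest = file.path(dir, "manifest.json"))

  dss <- Biostrings::DNAStringSet(vapply(chroms, paste, "", collapse = ""))
  names(dss) <- chrom_names
  Biostrings::writeXStringSet(dss, files$genome)

  gff <- c("##gff-version 3",
           sprintf("%s\tcompcis_fixture\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                   genes$chrom, genes$start, genes$end, genes$strand,
                   genes$gene_id))
  writeLines(gff, files$annotation)

  write_meme(pfms, files$motifs, background = config$composition)

  for (tf_id in tfs$tf_id) {
    for (dialect in c("col", "colamp")) {
      pk <- peaks[peaks$tf_id == tf_id & peaks$dialect == dialect, ,
                  drop = FALSE]
      if (nrow(pk) == 0L) next
      pk <- pk[order(pk$chrom, pk$start), ]
      writeLines(sprintf("%s\t%d\t%d\t%s_peak%d\t%d", pk$chrom, pk$start,
                         pk$end, tf_id, seq_len(nrow(pk)), pk$height),
                 file.path(peak_dir, sprintf("%s_%s.bed", tf_id, dialect)))
    }
  }

  write_tsv_file(degs, files$degs)
  write_tsv_file(go_ann, files$go)
  write_tsv_file(tfs[, c("tf_id", "family", "superclass", "direction",
                         "mode", "effector_activity", "effector_strength")],
                 files$tf_meta)

  manifest <- list(
    config = unclass(config),
    genes = genes,
    tfs = tfs,
    planted_sites = sites,
    peaks = peaks,
    expected_pairs = expected_pairs,
    expected_competition = expected_competition,
    expected_cooperation = expected_cooperation,
    decoy_clusters = decoy_clusters,
    enriched_terms = "GO:0000001",
    enriched_genes = enriched_genes,
    pristine_genes = pristine,
    deg_down = down_genes,
    deg_up = up_genes)
  jsonlite::write_json(manifest, files$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")

  invisible(list(dir = dir, files = files, manifest = manifest))
}

#' Read a fixture manifest back from disk
#' @param path path to `manifest.json`.
#' @return the manifest as a list of data.frames/vectors.
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Audit a generated fixture against its manifest
#'
#' Re-reads the emitted files and verifies that every planted word is
#' present at its recorded genomic coordinates (on the plus strand as
#' recorded), that every in-peak site is contained in a peak of its TF, and
#' that the designated GO terms are enriched in the DEG list at p <= 0.001
#' by direct hypergeometric recomputation.
#'
#' @param fixture the list returned by [generate_fixture()], or a directory
#'   path containing a generated fixture.
#' @return data.frame of failures (zero rows when the fixture is intact):
#'   columns `check`, `detail`.
#' @export
audit_fixture <- function(fixture) {
  if (is.character(fixture)) {
    dir <- fixture
    manifest <- read_manifest(file.path(dir, "manifest.json"))
    files <- list(genome = file.path(dir, "genome.fa"),
                  degs = file.path(dir, "degs.tsv"),
                  go = file.path(dir, "go_annotations.tsv"),
                  peaks_dir = file.path(dir, "peaks"))
  } else {
    manifest <- fixture$manifest
    files <- fixture$files
  }
  failures <- list()
  flag <- function(check, detail) {
    failures[[length(failures) + 1L]] <<- data.frame(
      check = check, detail = detail, stringsAsFactors = FALSE)
  }
  genome <- read_genome(files$genome)
  sites <- manifest$planted_sites
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    obs <- as.character(Biostrings::subseq(genome[[s$chrom]],
                                           start = s$start + 1L,
                                           end = s$end))
    if (!identical(obs, s$plus_word)) {
      flag("planted_word",
           sprintf("%s %s %s:[%d,%d) expected %s got %s", s$tf_id,
                   s$gene_id, s$chrom, s$start, s$end, s$plus_word, obs))
    }
  }
  peaks <- read_peak_dir(files$peaks_dir)
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    dialect <- if (s$in_col_peak) "col" else "colamp"
    pk <- peaks[peaks$tf_id == s$tf_id & peaks$dialect == dialect &
                  peaks$chrom == s$chrom, , drop = FALSE]
    contained <- any(pk$start <= s$start & s$end <= pk$end)
    if (!contained) {
      flag("site_in_peak", sprintf("%s %s [%d,%d) not inside any %s peak",
                                   s$tf_id, s$gene_id, s$start, s$end,
                                   dialect))
    }
  }
  degs <- read_tsv_file(files$degs)
  go_ann <- read_tsv_file(files$go)
  universe <- unique(go_ann$gene_id)
  deg_in <- intersect(unique(degs$gene_id), universe)
  for (term in manifest$enriched_terms) {
    genes_t <- unique(go_ann$gene_id[go_ann$go_id == term])
    K <- length(genes_t)
    k <- length(intersect(genes_t, deg_in))
    p <- stats::phyper(k - 1, K, length(universe) - K, length(deg_in),
                       lower.tail = FALSE)
    if (p > 0.001) {
      flag("enrichment", sprintf("%s: hypergeometric p=%.3g > 0.001", term, p))
    }
  }
  if (length(failures) == 0L) {
    return(data.frame(check = character(), detail = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, failures)
}

#' Match scan hits against planted sites
#'
#' A planted site is recovered when a hit of the same TF on the same gene
#' has the same genomic span and orientation.
#'
#' @param hits data.frame from [scan_promoters()].
#' @param planted the `planted_sites` table of a fixture manifest.
#' @return logical vector along `planted` rows.
#' @export
site_recovery <- function(hits, planted) {
  key_h <- paste(hits$tf_id, hits$gene_id, hits$chrom, hits$start, hits$end,
                 hits$strand)
  key_p <- paste(planted$tf_id, planted$gene_id, planted$chrom,
                 planted$start, planted$end, planted$strand)
  key_p %in% key_h
}
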