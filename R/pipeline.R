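#' Build a validated run configuration
#'
#' Collects all paths and thresholds of an end-to-end run. Defaults carry
#' the workflow's standard parameters: 1,000 bp 5'-regulatory regions, GO
#' enrichment threshold 0.001, binding-site overlap criterion "over 80 %",
#' top 2,000 peaks per set, and native-DNA ("col") peak sets only.
#'
#' @param genome,annotation,motifs,degs,go,tf_meta input file paths.
#' @param peaks_dir directory of `<TF>_<dialect>.bed` peak files.
#' @param out_dir output directory.
#' @param L promoter length; one of 500, 1000, 2000, 2500.
#' @param p_scan PWM cutoff calibration p-value (default 1e-4).
#' @param p_go GO enrichment threshold (default 0.001).
#' @param overlap_threshold competition overlap criterion (default 0.8).
#' @param coop_window cooperation proximity window in bp (default 50).
#' @param dialect_filter `"col"`, `"colamp"` or `NA`/`NULL` for all.
#' @param top_n_peaks peaks kept per set by height (default 2000).
#' @param min_peak_overlap minimum peak-promoter overlap in bp (default 1).
#' @param background `"promoters"` (strand-symmetrized promoter
#'   composition) or `"uniform"`.
#' @param adjust_go apply Benjamini-Hochberg before the GO threshold.
#' @return a validated `run_config` list.
#' @export
run_config <- function(genome, annotation, motifs, peaks_dir, degs, go,
                       tf_meta, out_dir,
                       L = 1000L, p_scan = 1e-4, p_go = 0.001,
                       overlap_threshold = 0.8, coop_window = 50L,
                       dialect_filter = "col", top_n_peaks = 2000L,
                       min_peak_overlap = 1L,
                       background = c("promoters", "uniform"),
                       adjust_go = FALSE) {
  cfg <- list(genome = genome, annotation = annotation, motifs = motifs,
              peaks_dir = peaks_dir, degs = degs, go = go,
              tf_meta = tf_meta, out_dir = out_dir,
              L = as.integer(L), p_scan = p_scan, p_go = p_go,
              overlap_threshold = overlap_threshold,
              coop_window = as.integer(coop_window),
              dialect_filter = if (is.null(dialect_filter) ||
                                   is.na(dialect_filter)) NULL else dialect_filter,
              top_n_peaks = as.integer(top_n_peaks),
              min_peak_overlap = as.integer(min_peak_overlap),
              background = match.arg(background),
              adjust_go = adjust_go)
  if (!cfg$L %in% c(500L, 1000L, 2000L, 2500L)) {
    fail("L must be one of 500, 1000, 2000, 2500 (got %d)", cfg$L)
  }
  for (p in c("p_scan", "p_go", "overlap_threshold")) {
    if (!is.numeric(cfg[[p]]) || cfg[[p]] <= 0 || cfg[[p]] >= 1) {
      fail("%s must be in (0, 1)", p)
    }
  }
  for (f in c("genome", "annotation", "motifs", "degs", "go", "tf_meta")) {
    if (!file.exists(cfg[[f]])) fail("%s file not found: %s", f, cfg[[f]])
  }
  if (!dir.exists(cfg$peaks_dir)) {
    fail("peaks directory not found: %s", cfg$peaks_dir)
  }
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; `overrides` (a named list,
#' e.g. from CLI flags) take precedence.
#'
#' @param path YAML file.
#' @param overrides named list of overriding values.
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  do.call(run_config, vals)
}

stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    fail("stage '%s' failed: %s", name, conditionMessage(e))
  })
  message(sprintf("[compcis] stage %-12s %6.2f s", name,
                  as.numeric(Sys.time() - t0, units = "secs")))
  res
}

#' Run the full workflow
#'
#' Promoter extraction, PWM scanning, GO enrichment, peak-to-promoter
#' linking with binding-site localization, output blocks 1 and 4, and
#' competition/cooperation candidate detection with mechanism
#' interpretation and a summary. All outputs are deterministic functions of
#' the inputs; a metadata file records every threshold and input checksum.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the in-memory stage results
#'   (`promoters`, `hits`, `enrichment`, `pairs`, `competition`,
#'   `cooperation`, `summary`) and `outputs` (named file paths).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  genome <- stage("genome", read_genome(config$genome))
  genes <- stage("annotation", read_annotation(config$annotation))
  promoters <- stage("promoters", extract_promoters(genes, genome, config$L))

  pfms <- stage("motifs", read_motifs(config$motifs))
  bg <- if (config$background == "promoters") {
    background_composition(promoters$seq)
  } else rep(0.25, 4)
  pwms <- lapply(pfms, pfm_to_pwm, background = bg)
  hits <- stage("scan",
                suppressWarnings(scan_promoters(pwms, promoters,
                                                config$p_scan)))

  degs <- read_tsv_file(config$degs)
  go_ann <- read_tsv_file(config$go)
  deg_list <- intersect(unique(degs$gene_id), unique(go_ann$gene_id))
  enr <- stage("enrich", enrich(deg_list, annotations = go_ann,
                                p_threshold = config$p_go,
                                adjust = config$adjust_go))
  gene_map <- genes_of_enriched_terms(enr, go_ann, deg_list)

  peaks <- stage("peaks", read_peak_dir(config$peaks_dir))
  peaks <- do.call(rbind, lapply(split(peaks, paste(peaks$tf_id,
                                                    peaks$dialect)),
                                 select_top_peaks, n = config$top_n_peaks))
  rownames(peaks) <- NULL
  regions <- stage("link", map_peaks_to_promoters(
    peaks, promoters, dialect_filter = config$dialect_filter,
    min_overlap = config$min_peak_overlap))
  sites <- localize_sites(hits, regions)
  tf_meta <- read_tsv_file(config$tf_meta)
  pairs <- build_pairs(tf_meta, gene_map, sites)

  comp <- stage("interplay", find_competition(pairs, tf_meta,
                                              config$overlap_threshold))
  dir_of <- stats::setNames(degs$direction, degs$gene_id)
  if (nrow(comp) > 0L) {
    comp$target_direction <- unname(dir_of[comp$gene_id])
    comp$mechanism <- vapply(seq_len(nrow(comp)), function(i) {
      interpret_mechanism(comp[i, ], tf_meta, comp$target_direction[i])
    }, character(1))
  } else {
    comp$target_direction <- character(0)
    comp$mechanism <- character(0)
  }
  coop <- find_cooperation(pairs, tf_meta, window = config$coop_window,
                           overlap_threshold = config$overlap_threshold)

  supp_tfs <- tf_meta$tf_id[tf_meta$mode == "suppressor"]
  supp_targets <- unique(pairs$pairs$gene_id[pairs$pairs$tf_id %in% supp_tfs])
  summ <- summarize_candidates(comp, length(supp_targets))

  outputs <- list(
    block1 = file.path(config$out_dir, "block1.tsv"),
    block4 = file.path(config$out_dir, "block4.tsv"),
    hits = file.path(config$out_dir, "hits.tsv"),
    enrichment = file.path(config$out_dir, "enrichment.tsv"),
    competition = file.path(config$out_dir, "competition_candidates.tsv"),
    cooperation = file.path(config$out_dir, "cooperation_candidates.tsv"),
    summary = file.path(config$out_dir, "summary.tsv"),
    metadata = file.path(config$out_dir, "run_metadata.json"))

  stage("output", {
    write_block1(pairs, outputs$block1)
    write_block4(pairs, outputs$block4)
    write_hits_tsv(hits, outputs$hits)
    write_enrichment_tsv(enr, outputs$enrichment)
    write_tsv_file(comp, outputs$competition)
    write_tsv_file(coop, outputs$cooperation)
    summary_df <- data.frame(
      metric = c("candidate_genes_down", "candidate_genes_up",
                 "candidate_genes_bidirectional", "candidate_genes_total",
                 "suppressor_regulated_genes",
                 "percent_of_suppressor_regulated"),
      value = c(summ$categories[["down"]], summ$categories[["up"]],
                summ$categories[["bidirectional"]], summ$total,
                length(supp_targets),
                summ$percent_of_suppressor_targets))
    write_tsv_file(summary_df, outputs$summary)
    inputs <- c(config$genome, config$annotation, config$motifs,
                config$degs, config$go, config$tf_meta)
    meta <- list(
      parameters = config[c("L", "p_scan", "p_go", "overlap_threshold",
                            "coop_window", "dialect_filter", "top_n_peaks",
                            "min_peak_overlap", "background", "adjust_go")],
      input_md5 = as.list(tools::md5sum(inputs)))
    jsonlite::write_json(meta, outputs$metadata, auto_unbox = TRUE,
                         pretty = TRUE, na = "null")
    NULL
  })

  invisible(list(promoters = promoters, hits = hits, enrichment = enr,
                 pairs = pairs, competition = comp, cooperation = coop,
                 summary = summ, outputs = outputs))
}
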