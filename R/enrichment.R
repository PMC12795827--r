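#' GO biological-process enrichment of a DEG list
#'
#' Hypergeometric over-representation test. For each GO term annotating at
#' least one universe gene, `p = P(X >= k)` where `X` follows a
#' hypergeometric distribution with `K` annotated genes in a universe of
#' `N`, drawing `n` DEGs, of which `k` are annotated. By default the
#' threshold is applied to raw p-values; Benjamini-Hochberg adjustment is
#' available behind `adjust`.
#'
#' @param deg_list character vector of DEG gene ids (must be a subset of the
#'   universe).
#' @param universe character vector of universe gene ids. `NULL` (default)
#'   uses all genes present in `annotations`.
#' @param annotations data.frame with columns `gene_id`, `go_id` and
#'   optionally `term`, `evidence`; duplicated (gene, GO) pairs are dropped.
#' @param p_threshold enrichment threshold (default 0.001).
#' @param adjust apply Benjamini-Hochberg correction before thresholding.
#' @return data.frame sorted by p ascending (ties by `go_id`): `go_id`,
#'   `term`, `k`, `K`, `n`, `N`, `p`, (`p_adj`,) `enriched`.
#' @export
#' @examples
#' ann <- data.frame(gene_id = paste0("g", 1:5), go_id = "GO:1",
#'                   term = "proc", evidence = "IEA")
#' ann <- rbind(ann, data.frame(gene_id = paste0("g", 1:20), go_id = "GO:2",
#'                              term = "other", evidence = "IEA"))
#' enrich(paste0("g", 1:5), paste0("g", 1:20), ann)
enrich <- function(deg_list, universe = NULL, annotations,
                   p_threshold = 0.001, adjust = FALSE) {
  if (is.null(universe)) universe <- unique(annotations$gene_id)
  universe <- unique(universe)
  if (length(universe) == 0L) fail("empty gene universe")
  deg_list <- unique(deg_list)
  missing <- setdiff(deg_list, universe)
  if (length(missing) > 0L) {
    fail("DEG(s) not in universe: %s", paste(missing, collapse = ", "))
  }
  ann <- annotations[annotations$gene_id %in% universe, , drop = FALSE]
  ann <- ann[!duplicated(ann[c("gene_id", "go_id")]), , drop = FALSE]
  if (nrow(ann) == 0L) fail("no annotations overlap the universe")
  N <- length(universe)
  n <- length(deg_list)
  terms <- split(ann$gene_id, ann$go_id)
  term_names <- if ("term" %in% names(ann)) {
    tapply(ann$term, ann$go_id, function(x) x[1])
  } else NULL
  go_ids <- names(terms)
  K <- lengths(terms)
  k <- vapply(terms, function(g) sum(g %in% deg_list), integer(1))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  res <- data.frame(
    go_id = go_ids,
    term = if (is.null(term_names)) NA_character_ else
      as.character(term_names[go_ids]),
    k = as.integer(k), K = as.integer(K), n = n, N = N,
    p = as.numeric(p),
    stringsAsFactors = FALSE
  )
  if (adjust) {
    res$p_adj <- stats::p.adjust(res$p, method = "BH")
    res$enriched <- res$p_adj <= p_threshold
  } else {
    res$enriched <- res$p <= p_threshold
  }
  res <- res[order(res$p, res$go_id), ]
  rownames(res) <- NULL
  res
}

#' DEGs annotated to enriched biological processes
#'
#' The sublist of DEGs associated with at least one enriched term, with the
#' (GO id, evidence) pairs that support each gene.
#'
#' @param results data.frame from [enrich()].
#' @param annotations the annotation table given to [enrich()].
#' @param deg_list the DEG list given to [enrich()].
#' @return data.frame with one row per (gene, enriched GO) pair: `gene_id`,
#'   `go_id`, `term`, `evidence`; zero rows if nothing is enriched.
#' @export
genes_of_enriched_terms <- function(results, annotations, deg_list) {
  enriched <- results$go_id[results$enriched]
  ann <- annotations[annotations$go_id %in% enriched &
                       annotations$gene_id %in% deg_list, , drop = FALSE]
  ann <- ann[!duplicated(ann[c("gene_id", "go_id")]), , drop = FALSE]
  keep <- intersect(c("gene_id", "go_id", "term", "evidence"), names(ann))
  out <- ann[order(ann$gene_id, ann$go_id), keep, drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write enrichment results as TSV
#' @param results data.frame from [enrich()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_enrichment_tsv <- function(results, path) write_tsv_file(results, path)
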