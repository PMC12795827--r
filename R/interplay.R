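#' Classify a regulator into the four network classes
#'
#' Combines a TF's own expression direction with its predicted mode of
#' regulation: up + activator = UA, up + suppressor = US, down + activator
#' = DA, down + suppressor = DS. UA/US form the stimulus-activated A
#' subnetwork, DA/DS the repressed R subnetwork. TFs whose own expression
#' is unchanged get no class (`NA`).
#'
#' @param direction `"up"`, `"down"` or `"unchanged"` (vectorized).
#' @param mode `"activator"` or `"suppressor"` (vectorized).
#' @return character vector of `"UA"`, `"US"`, `"DA"`, `"DS"` or `NA`.
#' @export
#' @examples
#' classify_tf("up", "activator")    # "UA"
#' classify_tf("down", "suppressor") # "DS"
classify_tf <- function(direction, mode) {
  n <- max(length(direction), length(mode))
  direction <- rep_len(direction, n); mode <- rep_len(mode, n)
  bad_d <- !direction %in% c("up", "down", "unchanged")
  bad_m <- !mode %in% c("activator", "suppressor")
  if (any(bad_d)) fail("invalid direction: %s",
                       paste(unique(direction[bad_d]), collapse = ", "))
  if (any(bad_m)) fail("invalid mode: %s",
                       paste(unique(mode[bad_m]), collapse = ", "))
  out <- ifelse(direction == "up",
                ifelse(mode == "activator", "UA", "US"),
                ifelse(mode == "activator", "DA", "DS"))
  unchanged <- direction == "unchanged"
  if (any(unchanged)) {
    message(sprintf("%d TF(s) with unchanged expression have no network class",
                    sum(unchanged)))
    out[unchanged] <- NA_character_
  }
  out
}

#' Subnetwork of a network class
#' @param class `"UA"`, `"US"`, `"DA"` or `"DS"` (vectorized).
#' @return `"A"` for UA/US, `"R"` for DA/DS, `NA` otherwise.
#' @export
subnetwork <- function(class) {
  ifelse(class %in% c("UA", "US"), "A",
         ifelse(class %in% c("DA", "DS"), "R", NA_character_))
}

#' Fraction of the shorter span covered by the overlap of two spans
#'
#' Spans are 0-based half-open `c(start, end)` on the same chromosome;
#' strand is ignored (competition concerns the DNA locus).
#'
#' @param span_a,span_b integer vectors `c(start, end)`.
#' @return overlap fraction in `[0, 1]`: intersection length divided by the
#'   shorter span length.
#' @export
#' @examples
#' overlap_fraction(c(100, 110), c(100, 110))  # 1
#' overlap_fraction(c(0, 9), c(2, 11))         # 7/9
overlap_fraction <- function(span_a, span_b) {
  la <- span_a[2] - span_a[1]; lb <- span_b[2] - span_b[1]
  if (la <= 0 || lb <= 0) fail("zero-length span in overlap_fraction")
  inter <- max(0, min(span_a[2], span_b[2]) - max(span_a[1], span_b[1]))
  inter / min(la, lb)
}

# pairwise overlap fractions for a site table (same chromosome assumed
# within one gene's promoter); returns matrix
site_overlap_matrix <- function(sites) {
  n <- nrow(sites)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && sites$chrom[i] == sites$chrom[j]) {
      f <- overlap_fraction(c(sites$start[i], sites$end[i]),
                            c(sites$start[j], sites$end[j]))
      m[i, j] <- f; m[j, i] <- f
    }
  }
  diag(m) <- 1
  m
}

# single-linkage components under the relation overlap > threshold
overlap_clusters <- function(sites, threshold) {
  n <- nrow(sites)
  comp <- seq_len(n)
  m <- site_overlap_matrix(sites)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (m[i, j] > threshold && comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  list(component = match(comp, unique(comp)), overlap = m)
}

tf_direction_map <- function(tf_records) {
  stats::setNames(tf_records$direction, tf_records$tf_id)
}

#' Detect candidate competitive regulation
#'
#' For each target gene, binding sites are clustered by single linkage
#' under the relation "overlap fraction of the shorter site > threshold".
#' A cluster is a competition candidate iff it holds sites of at least two
#' TFs whose own-expression directions include both up and down; every
#' opposite-direction TF pair whose sites overlap above the threshold is
#' reported. TFs with unknown/unchanged direction are excluded from
#' candidacy with a warning.
#'
#' @param pairs `reg_pairs` object from [build_pairs()].
#' @param tf_records TF metadata data.frame with `tf_id`, `direction`,
#'   optionally `family`, `superclass`, `mode`, `effector_activity`,
#'   `effector_strength`.
#' @param overlap_threshold strict lower bound on the overlap fraction
#'   (default 0.8, i.e. "over 80 %").
#' @return data.frame with one row per competing site pair: `gene_id`,
#'   `cluster`, `tf_a`, `tf_b`, `dir_a`, `dir_b`, site spans
#'   (`start_a`, `end_a`, `start_b`, `end_b`, 0-based half-open genomic),
#'   `overlap`, `families`, `superclasses`, `n_cluster_tfs`.
#' @export
find_competition <- function(pairs, tf_records, overlap_threshold = 0.8) {
  sites <- pairs$sites
  dir_map <- tf_direction_map(tf_records)
  fam_map <- stats::setNames(tf_records$family, tf_records$tf_id)
  sup_map <- if ("superclass" %in% names(tf_records)) {
    stats::setNames(tf_records$superclass, tf_records$tf_id)
  } else stats::setNames(rep(NA_character_, nrow(tf_records)),
                         tf_records$tf_id)
  no_dir <- setdiff(unique(sites$tf_id),
                    tf_records$tf_id[tf_records$direction %in% c("up", "down")])
  if (length(no_dir) > 0L) {
    warning(sprintf("TF(s) without up/down direction excluded from competition: %s",
                    paste(no_dir, collapse = ", ")))
    sites <- sites[!sites$tf_id %in% no_dir, , drop = FALSE]
  }
  out <- list()
  for (g in unique(sites$gene_id)) {
    sg <- sites[sites$gene_id == g, , drop = FALSE]
    if (nrow(sg) < 2L || length(unique(sg$tf_id)) < 2L) next
    cl <- overlap_clusters(sg, overlap_threshold)
    for (cid in unique(cl$component)) {
      idx <- which(cl$component == cid)
      if (length(idx) < 2L) next
      tfs <- unique(sg$tf_id[idx])
      dirs <- dir_map[tfs]
      if (!("up" %in% dirs && "down" %in% dirs)) next
      combs <- utils::combn(idx, 2)
      for (cc in seq_len(ncol(combs))) {
        i <- combs[1, cc]; j <- combs[2, cc]
        if (sg$tf_id[i] == sg$tf_id[j]) next
        if (cl$overlap[i, j] <= overlap_threshold) next
        di <- dir_map[[sg$tf_id[i]]]; dj <- dir_map[[sg$tf_id[j]]]
        if (di == dj) next
        # orient pair as (up TF, down TF)
        if (di == "down") { tmp <- i; i <- j; j <- tmp }
        out[[length(out) + 1L]] <- data.frame(
          gene_id = g,
          cluster = cid,
          tf_a = sg$tf_id[i], tf_b = sg$tf_id[j],
          dir_a = "up", dir_b = "down",
          start_a = sg$start[i], end_a = sg$end[i],
          start_b = sg$start[j], end_b = sg$end[j],
          overlap = cl$overlap[i, j],
          families = paste(sort(unique(fam_map[c(sg$tf_id[i], sg$tf_id[j])])),
                           collapse = ";"),
          superclasses = paste(sort(unique(sup_map[c(sg$tf_id[i],
                                                     sg$tf_id[j])])),
                               collapse = ";"),
          n_cluster_tfs = length(tfs),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(gene_id = character(), cluster = integer(),
                      tf_a = character(), tf_b = character(),
                      dir_a = character(), dir_b = character(),
                      start_a = integer(), end_a = integer(),
                      start_b = integer(), end_b = integer(),
                      overlap = numeric(), families = character(),
                      superclasses = character(), n_cluster_tfs = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$gene_id, res$tf_a, res$tf_b, res$start_a), ]
  rownames(res) <- NULL
  res
}

# discordance between predicted mode and measured effector activity
mode_activity_discordant <- function(mode, activity) {
  if (is.na(activity) || activity == "unknown") return(FALSE)
  (mode == "suppressor" && activity %in% c("strong_activator", "weak_activator")) ||
    (mode == "activator" && activity == "repressor")
}

#' Detect candidate cooperative regulation
#'
#' Binding-site pairs of two distinct TFs from the same subnetwork (both in
#' A = {UA, US} or both in R = {DA, DS}) whose spans do not satisfy the
#' competition overlap criterion, lie within `window` bp of each other, and
#' for which at least one TF's predicted mode disagrees with its measured
#' effector-domain activity (e.g. a predicted suppressor carrying an
#' activator-type effector domain, suggesting conversion by a partner).
#' This detector is an explicit extension of the competition logic; the
#' 50 bp default window is a package choice, not a literature constant.
#'
#' @inheritParams find_competition
#' @param window maximum gap in bp between the two spans (default 50).
#' @param overlap_threshold the competition overlap criterion the pair must
#'   NOT satisfy (default 0.8).
#' @return data.frame with one row per candidate site pair: `gene_id`,
#'   `tf_a`, `tf_b`, `class_a`, `class_b`, `subnetwork`, spans, `gap`,
#'   `activity_a`, `activity_b`, `discordant_tf`, `note`.
#' @export
find_cooperation <- function(pairs, tf_records, window = 50L,
                             overlap_threshold = 0.8) {
  sites <- pairs$sites
  rec <- tf_records
  rec$class <- classify_tf(rec$direction, rec$mode)
  rec$subnet <- subnetwork(rec$class)
  class_map <- stats::setNames(rec$class, rec$tf_id)
  sub_map <- stats::setNames(rec$subnet, rec$tf_id)
  mode_map <- stats::setNames(rec$mode, rec$tf_id)
  act_map <- if ("effector_activity" %in% names(rec)) {
    stats::setNames(rec$effector_activity, rec$tf_id)
  } else stats::setNames(rep("unknown", nrow(rec)), rec$tf_id)
  out <- list()
  for (g in unique(sites$gene_id)) {
    sg <- sites[sites$gene_id == g, , drop = FALSE]
    if (nrow(sg) < 2L) next
    combs <- utils::combn(nrow(sg), 2)
    for (cc in seq_len(ncol(combs))) {
      i <- combs[1, cc]; j <- combs[2, cc]
      ta <- sg$tf_id[i]; tb <- sg$tf_id[j]
      if (ta == tb) next
      sa <- sub_map[[ta]]; sb <- sub_map[[tb]]
      if (is.na(sa) || is.na(sb) || sa != sb) next
      frac <- overlap_fraction(c(sg$start[i], sg$end[i]),
                               c(sg$start[j], sg$end[j]))
      if (frac > overlap_threshold) next  # that pair is competition territory
      gap <- max(0L, max(sg$start[i], sg$start[j]) -
                   min(sg$end[i], sg$end[j]))
      if (gap > window) next
      disc_a <- mode_activity_discordant(mode_map[[ta]], act_map[[ta]])
      disc_b <- mode_activity_discordant(mode_map[[tb]], act_map[[tb]])
      if (!disc_a && !disc_b) next
      # order pair 5'->3' by genomic start
      if (sg$start[j] < sg$start[i]) {
        tmp <- i; i <- j; j <- tmp
        ta <- sg$tf_id[i]; tb <- sg$tf_id[j]
        tmpd <- disc_a; disc_a <- disc_b; disc_b <- tmpd
      }
      out[[length(out) + 1L]] <- data.frame(
        gene_id = g,
        tf_a = ta, tf_b = tb,
        class_a = class_map[[ta]], class_b = class_map[[tb]],
        subnetwork = sub_map[[ta]],
        start_a = sg$start[i], end_a = sg$end[i],
        start_b = sg$start[j], end_b = sg$end[j],
        gap = gap,
        activity_a = act_map[[ta]], activity_b = act_map[[tb]],
        discordant_tf = paste(c(ta, tb)[c(disc_a, disc_b)], collapse = ";"),
        note = "mode/effector discordance within one subnetwork",
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(gene_id = character(), tf_a = character(),
                      tf_b = character(), class_a = character(),
                      class_b = character(), subnetwork = character(),
                      start_a = integer(), end_a = integer(),
                      start_b = integer(), end_b = integer(),
                      gap = integer(), activity_a = character(),
                      activity_b = character(), discordant_tf = character(),
                      note = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$gene_id, res$tf_a, res$tf_b, res$start_a), ]
  rownames(res) <- NULL
  res
}

activity_strength <- function(tf_id, tf_records) {
  r <- tf_records[tf_records$tf_id == tf_id, , drop = FALSE]
  if (nrow(r) == 0L) return(NA_real_)
  if ("effector_strength" %in% names(r) && !is.na(r$effector_strength[1])) {
    return(as.numeric(r$effector_strength[1]))
  }
  act <- if ("effector_activity" %in% names(r)) r$effector_activity[1] else NA
  switch(as.character(act),
         strong_activator = 1, weak_activator = 0.4,
         bifunctional = 0.5, repressor = -1, NA_real_)
}

#' Interpret the mechanism of a competition candidate
#'
#' Competitive replacement logic: after the stimulus the up-regulated TF
#' displaces the down-regulated TF at the shared site. If the incoming TF is
#' the weaker activator and the target goes down, the observed suppression
#' is explained by replacement of a strong activator with a weaker one
#' (`"suppression_by_weak_activator_replacement"`); if the incoming TF is
#' the stronger activator and the target goes up, activation is explained
#' (`"activation_by_strong_activator_replacement"`). Candidates whose
#' activity ordering contradicts the target response are `"unexplained"`
#' (real examples of this exist, e.g. a displaced weak activator paired
#' with target suppression); candidates with no usable activity data are
#' `"insufficient_activity_data"`.
#'
#' @param candidate one row of [find_competition()] output.
#' @param tf_records TF metadata (see [find_competition()]).
#' @param target_direction DEG direction of the target gene (`"up"` or
#'   `"down"`).
#' @return mechanism label string.
#' @export
interpret_mechanism <- function(candidate, tf_records, target_direction) {
  s_up <- activity_strength(candidate$tf_a, tf_records)    # up-regulated TF
  s_down <- activity_strength(candidate$tf_b, tf_records)  # down-regulated TF
  if (is.na(s_up) && is.na(s_down)) return("insufficient_activity_data")
  if (is.na(s_up) || is.na(s_down)) return("insufficient_activity_data")
  if (s_up < s_down && target_direction == "down") {
    "suppression_by_weak_activator_replacement"
  } else if (s_up > s_down && target_direction == "up") {
    "activation_by_strong_activator_replacement"
  } else {
    "unexplained"
  }
}

#' Summarize competition candidates
#'
#' Counts candidate target genes by direction category (down-regulated,
#' up-regulated, bidirectional across experiments), their total, and the
#' total as a percentage (rounded to the nearest integer) of the number of
#' suppressor-regulated genes; plus per-family and per-superclass tallies
#' of the competing TF pairs.
#'
#' @param candidates data.frame with at least `gene_id` and
#'   `target_direction` (`"up"`/`"down"`; a gene appearing with both
#'   directions, e.g. across two experiments, counts as bidirectional).
#'   `families`/`superclasses` columns, if present, feed the tallies.
#' @param suppressor_target_total denominator: total number of genes
#'   regulated by suppressors. `NULL` or 0 omits the percentage.
#' @return list with `categories` (named counts: down, up, bidirectional),
#'   `total`, `percent_of_suppressor_targets` (integer or `NA`),
#'   `family_table` and `superclass_table`.
#' @export
summarize_candidates <- function(candidates, suppressor_target_total = NULL) {
  if (nrow(candidates) == 0L) {
    return(list(categories = c(down = 0L, up = 0L, bidirectional = 0L),
                total = 0L,
                percent_of_suppressor_targets = NA_integer_,
                family_table = table(character()),
                superclass_table = table(character())))
  }
  dirs <- split(candidates$target_direction, candidates$gene_id)
  cat_of <- vapply(dirs, function(d) {
    u <- unique(d[d %in% c("up", "down")])
    if (length(u) == 2L) "bidirectional" else if (length(u) == 1L) u else NA_character_
  }, character(1))
  categories <- c(down = sum(cat_of == "down", na.rm = TRUE),
                  up = sum(cat_of == "up", na.rm = TRUE),
                  bidirectional = sum(cat_of == "bidirectional", na.rm = TRUE))
  total <- sum(categories)
  pct <- if (is.null(suppressor_target_total) ||
             !is.finite(suppressor_target_total) ||
             suppressor_target_total <= 0) {
    NA_integer_
  } else {
    as.integer(round(100 * total / suppressor_target_total))
  }
  fam <- if ("families" %in% names(candidates)) {
    table(candidates$families)
  } else table(character())
  sup <- if ("superclasses" %in% names(candidates)) {
    table(candidates$superclasses)
  } else table(character())
  list(categories = categories, total = total,
       percent_of_suppressor_targets = pct,
       family_table = fam, superclass_table = sup)
}
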