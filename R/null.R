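#' @name richness_null
#' @title Richness-matched resampling null model
#' @description Tests whether the loss of network connectivity in
#'   hyperarid soils is an artifact of their lower richness: arid and
#'   margin samples are repeatedly rarefied to a low read depth (dropping
#'   their richness to the hyperarid level), the network is rebuilt on
#'   each replicate, per-sample statistics are averaged across
#'   replicates, and class medians are compared against the original
#'   (unmodified) hyperarid row.
NULL

#' Rarefy to a fixed (low) read depth
#'
#' Same contract as \code{\link{rarefy}} with the richness-null default
#' depth of 300 reads per sample.
#'
#' @param table an \code{\link{otu_table}}.
#' @param depth reads per sample (default 300).
#' @param seed RNG seed.
#' @return rarefied \code{\link{otu_table}}.
#' @export
rarefy_to_reads <- function(table, depth = 300, seed = NULL) {
  rarefy(table, depth = depth, seed = seed)
}

#' Run the richness-matched network null
#'
#' For each replicate, the arid and margin samples are rarefied to
#' \code{depth} reads (hyperarid samples are never modified), rare OTUs
#' are re-filtered on the modified table with the same rule as the main
#' pipeline, the co-occurrence network is rebuilt on the whole modified
#' table (reusing the original correlation threshold unless
#' \code{rethreshold = TRUE}), and per-sample induced-subgraph
#' statistics are computed for the modified samples.  Statistics are
#' then averaged per sample across replicates and summarized as the
#' per-class median of those averages, next to the original
#' (unmodified) hyperarid row.
#'
#' @param table the full \code{\link{otu_table}} (all classes).
#' @param meta metadata with \code{sample_id} and \code{aridity_class}.
#' @param threshold correlation cutoff for the rebuilt networks,
#'   normally the original network's threshold.
#' @param n_reps number of replicates (default 500).
#' @param depth rarefaction depth per replicate (default 300; see
#'   \code{\link{calibrate_null_depth}} for matching it to the
#'   hyperarid richness of a given dataset).
#' @param min_frac rare-OTU fraction rule, recomputed per replicate
#'   (default 1e-4).
#' @param q_cutoff FDR cutoff for edges (default 0.01).
#' @param seed RNG seed (the whole null is reproducible from it).
#' @param rethreshold if TRUE, re-run RMT threshold selection on every
#'   replicate instead of reusing \code{threshold}.
#' @param min_otus RMT minimum spectrum size (only with
#'   \code{rethreshold}).
#' @param original_stats optional per-sample statistics of the original
#'   (unmodified) network — typically
#'   \code{\link{sample_level_stats}} on the global network — from
#'   which the reference hyperarid row is taken, so that the comparison
#'   row matches the main class summary.  When NULL the original
#'   network is rebuilt internally.
#' @return list of class \code{richness_null} with \code{n_reps},
#'   \code{depth}, \code{per_sample} (rep-averaged statistics),
#'   \code{class_medians} (modified arid/margin rows),
#'   \code{original_hyperarid} (unmodified row),
#'   \code{reduced_richness} (median observed OTUs per modified class)
#'   and \code{hyperarid_richness} (median observed OTUs, original).
#' @export
run_richness_null <- function(table, meta, threshold,
                              n_reps = 500, depth = 300, min_frac = 1e-4,
                              q_cutoff = 0.01, seed = NULL,
                              rethreshold = FALSE, min_otus = 30,
                              original_stats = NULL) {
  cls <- meta$aridity_class[match(rownames(table), meta$sample_id)]
  if (any(is.na(cls))) stop("sample(s) missing an aridity class")
  for (need in c("arid", "margin"))
    if (!any(cls == need)) stop("class ", need, " has no samples")
  if (!is.null(seed)) set.seed(seed)

  fields <- c("size", "degree", "betweenness", "edge_count",
              "avg_path_length", "betweenness_centralization")
  modified <- which(cls %in% c("arid", "margin"))
  deep_enough <- rowSums(table)[modified] >= depth
  if (!all(deep_enough)) {
    for (target in c("arid", "margin"))
      if (!any(deep_enough[cls[modified] == target]))
        stop("class ", target, " loses all samples at depth ", depth)
    warning(sprintf("dropping %d modified sample(s) below %d reads",
                    sum(!deep_enough), depth))
    modified <- modified[deep_enough]
  }
  mod_ids <- rownames(table)[modified]
  mod_cls <- cls[modified]

  sums <- matrix(0, length(modified), length(fields),
                 dimnames = list(mod_ids, fields))
  rich_sums <- setNames(numeric(length(modified)), mod_ids)
  thr <- if (rethreshold) NULL else threshold
  for (rep_i in seq_len(n_reps)) {
    # the whole table is rarefied to even depth before refiltering and
    # rebuilding, exactly as in the main pipeline; only the modified
    # (arid/margin) samples' statistics are reported -- the hyperarid
    # reference row always comes from the unmodified network
    rt <- suppressWarnings(rarefy(table, depth = depth))
    ft <- filter_rare(rt, min_frac)
    net <- suppressWarnings(suppressMessages(
      build_cooccurrence(ft, min_frac = 0, threshold = thr,
                         q_cutoff = q_cutoff, min_otus = min_otus)))
    st <- suppressWarnings(sample_level_stats(net, ft))
    st <- st[match(mod_ids, st$sample_id), , drop = FALSE]
    sums <- sums + as.matrix(st[, fields])
    rich_sums <- rich_sums + rowSums(unclass(rt)[mod_ids, , drop = FALSE] > 0)
  }
  avg <- as.data.frame(sums / n_reps)
  avg_rich <- rich_sums / n_reps

  acc <- lapply(split(seq_along(modified), mod_cls), function(i)
    cbind(data.frame(sample_id = mod_ids[i], stringsAsFactors = FALSE),
          avg[i, , drop = FALSE]))
  class_medians <- do.call(rbind, lapply(names(acc), function(cl) {
    cbind(data.frame(class = cl, n_samples = nrow(acc[[cl]]),
                     stringsAsFactors = FALSE),
          as.data.frame(lapply(acc[[cl]][, fields], median)))
  }))

  hyper_ids <- rownames(table)[cls == "hyperarid"]
  if (is.null(original_stats) && length(hyper_ids) >= 2) {
    onet <- suppressWarnings(suppressMessages(
      build_cooccurrence(table, min_frac = min_frac, threshold = thr,
                         q_cutoff = q_cutoff, min_otus = min_otus)))
    original_stats <- suppressWarnings(
      sample_level_stats(onet, onet$table))
  }
  hyper_row <- NULL
  if (!is.null(original_stats)) {
    hs <- original_stats[original_stats$sample_id %in% hyper_ids, ,
                         drop = FALSE]
    if (nrow(hs))
      hyper_row <- cbind(data.frame(class = "hyperarid",
                                    n_samples = nrow(hs),
                                    stringsAsFactors = FALSE),
                         as.data.frame(lapply(hs[, fields], median)))
  }
  hyper_rich <- if (length(hyper_ids))
    median(rowSums(unclass(table[hyper_ids, , drop = FALSE]) > 0))
  else NA_real_

  structure(list(
    n_reps = n_reps, depth = depth,
    per_sample = acc,
    class_medians = class_medians,
    original_hyperarid = hyper_row,
    reduced_richness = vapply(split(avg_rich, mod_cls), median,
                              numeric(1)),
    hyperarid_richness = hyper_rich),
    class = "richness_null")
}

#' Calibrate the richness-matching rarefaction depth
#'
#' The richness null rarefies arid and margin samples so that their
#' observed richness matches the hyperarid level.  This helper finds the
#' read depth whose expected post-rarefaction richness (closed-form
#' hypergeometric expectation
#' \eqn{\sum_i [1 - C(N-n_i, d)/C(N, d)]}) across the modified classes
#' best matches the median observed richness of the unmodified
#' hyperarid samples.
#'
#' @param table the full \code{\link{otu_table}}.
#' @param classes aridity class per sample of \code{table} (same
#'   order).
#' @param depth_grid candidate depths (default a log-spaced grid from
#'   50 to 20000).
#' @return list with \code{depth}, \code{expected_richness} (at that
#'   depth, per modified class) and \code{target} (hyperarid median
#'   richness).
#' @export
calibrate_null_depth <- function(table, classes,
                                 depth_grid = round(exp(seq(log(50),
                                                            log(20000),
                                                            length.out = 40)))) {
  stopifnot(length(classes) == nrow(table))
  target <- median(rowSums(unclass(table)[classes == "hyperarid", ,
                                          drop = FALSE] > 0))
  mod <- unclass(table)[classes %in% c("arid", "margin"), , drop = FALSE]
  exp_rich <- function(counts, d) {
    n_tot <- sum(counts)
    if (n_tot < d) return(sum(counts > 0))
    pos <- counts[counts > 0]
    sum(1 - exp(lchoose(n_tot - pos, d) - lchoose(n_tot, d)))
  }
  med_rich <- vapply(depth_grid, function(d)
    median(apply(mod, 1, exp_rich, d = d)), numeric(1))
  best <- which.min(abs(med_rich - target))
  d <- depth_grid[best]
  cls_mod <- classes[classes %in% c("arid", "margin")]
  list(depth = d,
       expected_richness = vapply(split(seq_len(nrow(mod)), cls_mod),
                                  function(i) median(apply(
                                    mod[i, , drop = FALSE], 1, exp_rich,
                                    d = d)), numeric(1)),
       target = target)
}

#' Check that the null matched the hyperarid richness
#'
#' Compares the median observed-OTU counts of the reduced arid and margin
#' replicates against the original hyperarid median and flags each class
#' as matched when the ratio lies within \code{tolerance} of 1.
#'
#' @param null_result result of \code{\link{run_richness_null}}.
#' @param tolerance relative tolerance (default 0.2, i.e. 20\%).
#' @return data.frame with class, reduced and reference medians, ratio
#'   and \code{matched} flag.
#' @export
richness_check <- function(null_result, tolerance = 0.2) {
  ref <- null_result$hyperarid_richness
  if (!is.finite(ref) || ref <= 0)
    stop("no hyperarid reference richness available")
  red <- null_result$reduced_richness
  ratio <- red / ref
  data.frame(class = names(red),
             reduced_median_otus = unname(red),
             hyperarid_median_otus = ref,
             ratio = unname(ratio),
             matched = unname(abs(ratio - 1) <= tolerance),
             row.names = NULL, stringsAsFactors = FALSE)
}
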