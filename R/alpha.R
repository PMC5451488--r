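#' Rarefy an OTU table to even depth
#'
#' Subsamples each sample's reads without replacement to exactly
#' \code{depth}; samples with fewer reads are dropped with a warning.
#'
#' @param table an \code{\link{otu_table}}.
#' @param depth target reads per sample (>= 1).
#' @param seed integer RNG seed for reproducible subsampling.
#' @return rarefied \code{\link{otu_table}}.
#' @export
rarefy <- function(table, depth, seed = NULL) {
  if (!is.numeric(depth) || depth < 1) stop("depth must be >= 1")
  depth <- as.integer(depth)
  if (!is.null(seed)) set.seed(seed)
  tot <- rowSums(table)
  drop <- tot < depth
  if (any(drop)) {
    warning(sprintf("dropping %d sample(s) with fewer than %d reads",
                    sum(drop), depth))
    table <- table[!drop, , drop = FALSE]
    tot <- tot[!drop]
  }
  if (nrow(table) == 0) return(table)
  m <- unclass(table)
  out <- matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
  for (i in seq_len(nrow(m))) {
    if (tot[i] == depth) { out[i, ] <- m[i, ]; next }
    reads <- rep.int(seq_len(ncol(m)), m[i, ])
    picked <- sample(reads, depth, replace = FALSE)
    out[i, ] <- tabulate(picked, nbins = ncol(m))
  }
  otu_table(out)
}

#' Shannon diversity of a count vector
#'
#' \eqn{H = -\sum p_i \log_b p_i} over positive proportions.  Base 2
#' (bits) by default, the QIIME 1 convention.
#'
#' @param counts non-negative numeric vector with at least one positive
#'   entry.
#' @param base logarithm base (default 2).
#' @return Shannon index.
#' @export
shannon <- function(counts, base = 2) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("negative counts")
  tot <- sum(counts)
  if (tot == 0) stop("all-zero count vector")
  p <- counts[counts > 0] / tot
  -sum(p * log(p, base = base))
}

#' Simpson diversity (1 - dominance) of a count vector
#'
#' @param counts non-negative numeric vector with at least one positive
#'   entry.
#' @return \eqn{1 - \sum p_i^2}, in [0, 1].
#' @export
simpson <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("negative counts")
  tot <- sum(counts)
  if (tot == 0) stop("all-zero count vector")
  p <- counts / tot
  1 - sum(p^2)
}

#' Faith's phylogenetic diversity
#'
#' Sum of branch lengths of the minimal subtree connecting the observed
#' leaves to the root (rooted variant: the path to the root is included).
#'
#' @param otus character vector of observed leaf names.
#' @param tree rooted \code{ape::phylo} with branch lengths.
#' @return total branch length (>= 0); 0 for an empty set.
#' @export
faith_pd <- function(otus, tree) {
  otus <- unique(as.character(otus))
  if (length(otus) == 0) return(0)
  unknown <- setdiff(otus, tree$tip.label)
  if (length(unknown))
    stop("leaf name(s) not in tree: ",
         paste(head(unknown, 5), collapse = ", "))
  tr <- stats::reorder(tree, "postorder")
  n_nodes <- length(tr$tip.label) + tr$Nnode
  present <- logical(n_nodes)
  present[match(otus, tr$tip.label)] <- TRUE
  for (i in seq_len(nrow(tr$edge))) {
    if (present[tr$edge[i, 2]]) present[tr$edge[i, 1]] <- TRUE
  }
  sum(tr$edge.length[present[tr$edge[, 2]]])
}

#' Alpha-diversity table for every sample
#'
#' @param table an \code{\link{otu_table}}.
#' @param tree rooted phylogeny covering the table's OTUs.
#' @param shannon_base logarithm base for Shannon (default 2).
#' @return data.frame with columns \code{sample_id}, \code{pd},
#'   \code{shannon}, \code{simpson}, \code{observed_otus}.
#' @export
alpha_table <- function(table, tree, shannon_base = 2) {
  m <- unclass(table)
  data.frame(
    sample_id = rownames(m),
    pd = vapply(seq_len(nrow(m)), function(i)
      faith_pd(colnames(m)[m[i, ] > 0], tree), numeric(1)),
    shannon = apply(m, 1, shannon, base = shannon_base),
    simpson = apply(m, 1, simpson),
    observed_otus = rowSums(m > 0),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Diversity-environment correlation report
#'
#' Spearman correlation of each alpha metric against each numeric
#' environmental variable, with Benjamini-Hochberg q-values across the
#' whole family, plus a Welch t-test of richness by vegetation presence.
#'
#' @param alpha data.frame from \code{\link{alpha_table}}.
#' @param meta metadata data.frame matched on \code{sample_id}.
#' @param variables environmental variables to test (default the full
#'   numeric field set).
#' @param metrics alpha metrics to test (default pd, shannon, simpson,
#'   observed_otus).
#' @return list with \code{correlations} (metric, variable, rs, p, q, n)
#'   and \code{vegetation_t_test} (t statistic, p, group means).
#' @export
alpha_env_report <- function(alpha, meta,
                             variables = METADATA_NUMERIC_FIELDS,
                             metrics = c("pd", "shannon", "simpson",
                                         "observed_otus")) {
  if (nrow(alpha) < 3) stop("need at least 3 samples")
  meta <- meta[match(alpha$sample_id, meta$sample_id), , drop = FALSE]
  rows <- list()
  for (mname in metrics) {
    for (v in variables) {
      xv <- meta[[v]]
      if (is.null(xv) || sd(xv) == 0) next
      sp <- spearman(alpha[[mname]], xv)
      rows[[length(rows) + 1]] <-
        data.frame(metric = mname, variable = v,
                   rs = sp$rs, p = sp$p, n = sp$n)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)

  veg <- meta$vegetation_cover > 0
  if (min(table(veg)) < 2)
    stop("need >= 2 samples per vegetation group for the t-test")
  tt <- t.test(alpha$observed_otus[veg], alpha$observed_otus[!veg])
  list(correlations = out,
       vegetation_t_test = list(
         t = unname(tt$statistic), p = tt$p.value,
         mean_vegetated = unname(tt$estimate[1]),
         mean_unvegetated = unname(tt$estimate[2])))
}
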