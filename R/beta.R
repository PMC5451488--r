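#' @name beta_diversity
#' @title Phylogenetic beta diversity and environmental-driver statistics
#' @description UniFrac distances, principal-coordinate ordination, and the
#'   permutation statistics (Mantel, ANOSIM, exhaustive BEST/BioEnv subset
#'   search) used to relate community dissimilarity to soil climate.
NULL

# per-branch abundance accumulation: counts below each edge, per sample
branch_profile <- function(table, tree) {
  missing <- setdiff(colnames(table), tree$tip.label)
  if (length(missing))
    stop("OTU(s) missing from tree: ", paste(head(missing, 5), collapse = ", "))
  tr <- stats::reorder(tree, "postorder")
  n_tip <- length(tr$tip.label)
  n_nodes <- n_tip + tr$Nnode
  acc <- matrix(0, n_nodes, nrow(table))
  idx <- match(colnames(table), tr$tip.label)
  acc[idx, ] <- t(unclass(table))
  for (i in seq_len(nrow(tr$edge)))
    acc[tr$edge[i, 1], ] <- acc[tr$edge[i, 1], ] + acc[tr$edge[i, 2], ]
  list(lengths = tr$edge.length,
       abundance = acc[tr$edge[, 2], , drop = FALSE],
       sample_ids = rownames(table))
}

#' UniFrac distance matrix
#'
#' Unweighted UniFrac between two samples is the branch length unique to
#' either sample's observed leaf set divided by the branch length of their
#' union.  Weighted UniFrac is the normalized abundance-weighted variant:
#' \eqn{\sum_b L_b |p_{Ab} - p_{Bb}| / \sum_b L_b (p_{Ab} + p_{Bb})}, where
#' \eqn{p} are proportional leaf abundances summed below branch \eqn{b}.
#'
#' @param table an \code{\link{otu_table}} (ideally rarefied to even depth;
#'   unequal depths are allowed but logged).
#' @param tree rooted phylogeny covering the table's OTUs.
#' @param weighted logical; FALSE (default) for presence/absence UniFrac.
#' @return symmetric distance matrix with sample ids as dimnames.
#' @export
unifrac <- function(table, tree, weighted = FALSE) {
  tot <- rowSums(table)
  if (any(tot == 0)) stop("sample(s) with zero total reads")
  if (length(unique(tot)) > 1)
    message("note: samples are not at even depth (",
            min(tot), "-", max(tot), " reads)")
  bp <- branch_profile(table, tree)
  n <- nrow(table)
  d <- matrix(0, n, n, dimnames = list(bp$sample_ids, bp$sample_ids))
  if (weighted) {
    p <- sweep(bp$abundance, 2, tot, "/")
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      num <- sum(bp$lengths * abs(p[, i] - p[, j]))
      den <- sum(bp$lengths * (p[, i] + p[, j]))
      d[i, j] <- d[j, i] <- if (den > 0) num / den else 0
    }
  } else {
    pres <- bp$abundance > 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      uni <- sum(bp$lengths[xor(pres[, i], pres[, j])])
      tot_b <- sum(bp$lengths[pres[, i] | pres[, j]])
      d[i, j] <- d[j, i] <- if (tot_b > 0) uni / tot_b else 0
    }
  }
  d
}

check_distance_matrix <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm))
    stop("not a square matrix")
  if (max(abs(dm - t(dm))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(diag(dm) != 0)) stop("distance matrix has nonzero diagonal")
  if (any(dm < -1e-12)) stop("negative dissimilarities")
  invisible(dm)
}

#' Principal-coordinate analysis
#'
#' Classical metric ordination: eigendecomposition of the double-centred
#' Gram matrix of squared dissimilarities.  Axes are ordered by eigenvalue;
#' proportions of variance are taken over the positive eigenvalues and
#' negative eigenvalues are reported rather than dropped.
#'
#' @param dm symmetric dissimilarity matrix with zero diagonal.
#' @return list with \code{coordinates} (samples x axes, one axis per
#'   positive eigenvalue), \code{eigenvalues} (all, descending) and
#'   \code{proportions} (share of the positive-eigenvalue total per
#'   retained axis).
#' @export
pcoa <- function(dm) {
  check_distance_matrix(dm)
  n <- nrow(dm)
  d2 <- dm^2
  cc <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * cc %*% d2 %*% cc
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- which(e$values > tol)
  if (length(pos)) {
    coords <- e$vectors[, pos, drop = FALSE] %*%
      diag(sqrt(e$values[pos]), length(pos))
  } else {
    coords <- matrix(0, n, 1)  # degenerate: all dissimilarities zero
  }
  dimnames(coords) <- list(rownames(dm),
                           paste0("PC", seq_len(ncol(coords))))
  list(coordinates = coords,
       eigenvalues = e$values,
       proportions = if (length(pos)) e$values[pos] / sum(e$values[pos])
                     else numeric(0))
}

upper_vec <- function(dm) dm[upper.tri(dm)]

# spearman correlation of the upper triangles of two conformable matrices
triangle_cor <- function(dm1, dm2) {
  cor(rank(upper_vec(dm1)), rank(upper_vec(dm2)))
}

check_matching_ids <- function(dm1, dm2) {
  if (nrow(dm1) != nrow(dm2)) stop("distance matrices differ in size")
  if (!is.null(rownames(dm1)) && !is.null(rownames(dm2)) &&
      !identical(rownames(dm1), rownames(dm2)))
    stop("distance matrices have mismatched sample ids")
  invisible(TRUE)
}

#' Mantel test between two distance matrices
#'
#' Statistic: Spearman correlation of the upper-triangle entries.
#' Significance: one-sided (positive association) permutation test over
#' simultaneous row/column relabelings, with the add-one rule
#' \eqn{p = (\#\{r^* \ge r\} + 1)/(n_{perm} + 1)}.  For \eqn{n \le 7}
#' samples all \eqn{n!} relabelings are enumerated and the p-value is
#' exact.
#'
#' @param dm1,dm2 symmetric distance matrices over the same samples.
#' @param n_perm number of random permutations (default 9999).
#' @param seed RNG seed.
#' @return list with \code{r}, \code{p}, \code{n}, \code{n_perm} and
#'   \code{exact} (TRUE when fully enumerated).
#' @export
mantel <- function(dm1, dm2, n_perm = 9999, seed = NULL) {
  check_distance_matrix(dm1); check_distance_matrix(dm2)
  check_matching_ids(dm1, dm2)
  n <- nrow(dm1)
  if (n < 4) stop("need at least 4 samples")
  r_obs <- triangle_cor(dm1, dm2)
  v1 <- rank(upper_vec(dm1))
  eps <- 1e-12
  if (n <= 7) {
    perms <- all_permutations(n)
    null_r <- apply(perms, 1, function(p)
      cor(v1, rank(upper_vec(dm2[p, p]))))
    p_val <- mean(null_r >= r_obs - eps)
    exact <- TRUE
    n_used <- nrow(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    count <- 0L
    for (k in seq_len(n_perm)) {
      p <- sample.int(n)
      if (cor(v1, rank(upper_vec(dm2[p, p]))) >= r_obs - eps)
        count <- count + 1L
    }
    p_val <- (count + 1) / (n_perm + 1)
    exact <- FALSE
    n_used <- n_perm
  }
  list(r = r_obs, p = p_val, n = n, n_perm = n_used, exact = exact)
}

#' Analysis of similarity (ANOSIM)
#'
#' \eqn{R = (\bar r_B - \bar r_W) / (n(n-1)/4)} where \eqn{\bar r_B} and
#' \eqn{\bar r_W} are mean midranks of between- and within-group
#' dissimilarities.  One-sided permutation p-value as in
#' \code{\link{mantel}}; exact for \eqn{n \le 7}.
#'
#' @param dm symmetric distance matrix.
#' @param groups group labels, one per sample; every group needs >= 2
#'   members.
#' @param n_perm number of random permutations (default 999).
#' @param seed RNG seed.
#' @return list with \code{R}, \code{p}, \code{n}, \code{n_perm},
#'   \code{exact}.
#' @export
anosim <- function(dm, groups, n_perm = 999, seed = NULL) {
  check_distance_matrix(dm)
  groups <- as.character(groups)
  if (length(groups) != nrow(dm)) stop("one group label per sample required")
  if (length(unique(groups)) < 2) stop("need at least 2 groups")
  if (min(table(groups)) < 2) stop("singleton group(s) present")
  n <- nrow(dm)
  rk <- matrix(0, n, n)
  rk[upper.tri(rk)] <- rank(upper_vec(dm))
  rk <- rk + t(rk)
  stat <- function(g) {
    within <- outer(g, g, "==")[upper.tri(rk)]
    r <- rk[upper.tri(rk)]
    (mean(r[!within]) - mean(r[within])) / (n * (n - 1) / 4)
  }
  r_obs <- stat(groups)
  eps <- 1e-12
  if (n <= 7) {
    perms <- all_permutations(n)
    null_r <- apply(perms, 1, function(p) stat(groups[p]))
    p_val <- mean(null_r >= r_obs - eps)
    exact <- TRUE
    n_used <- nrow(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    count <- 0L
    for (k in seq_len(n_perm)) {
      if (stat(groups[sample.int(n)]) >= r_obs - eps) count <- count + 1L
    }
    p_val <- (count + 1) / (n_perm + 1)
    exact <- FALSE
    n_used <- n_perm
  }
  list(R = r_obs, p = p_val, n = n, n_perm = n_used, exact = exact)
}

#' Euclidean distance on standardized environmental variables
#'
#' Each variable is scaled to zero mean and unit variance across samples
#' before computing Euclidean distances (the BEST/BioEnv convention).
#'
#' @param meta metadata data.frame with a \code{sample_id} column.
#' @param variables character vector of numeric column names.
#' @return symmetric distance matrix with sample ids as dimnames.
#' @export
env_distance <- function(meta, variables) {
  if (length(variables) == 0) stop("no variables given")
  missing <- setdiff(variables, names(meta))
  if (length(missing))
    stop("variable(s) not in metadata: ", paste(missing, collapse = ", "))
  x <- as.matrix(meta[, variables, drop = FALSE])
  if (!is.numeric(x)) stop("non-numeric variable among: ",
                           paste(variables, collapse = ", "))
  sds <- apply(x, 2, sd)
  if (any(sds == 0))
    stop("constant variable(s): ",
         paste(variables[sds == 0], collapse = ", "))
  x <- scale(x)
  d <- as.matrix(dist(x))
  dimnames(d) <- list(meta$sample_id, meta$sample_id)
  d
}

#' Exhaustive BEST/BioEnv environmental-driver selection
#'
#' For every non-empty subset of the candidate variables, computes the
#' Spearman correlation between the community dissimilarity upper triangle
#' and the Euclidean distances of the standardized subset, and ranks all
#' subsets by correlation — the full ranked table behind a BEST analysis.
#'
#' @param dm community distance matrix.
#' @param meta metadata matched to \code{dm}'s samples.
#' @param variables candidate variables (at most 15: the search is
#'   exhaustive over \eqn{2^k - 1} subsets).
#' @param max_subset largest subset size to consider (default all).
#' @return data.frame with columns \code{variables} (comma-joined),
#'   \code{size} and \code{rs}, sorted by decreasing \code{rs}.
#' @export
best_bioenv <- function(dm, meta, variables, max_subset = length(variables)) {
  check_distance_matrix(dm)
  k <- length(variables)
  if (k == 0) stop("no variables given")
  if (k > 15)
    stop("exhaustive BEST over ", k, " variables is 2^", k,
         " subsets; cap the variable list at 15 or fewer")
  if (!is.null(rownames(dm)) && all(rownames(dm) %in% meta$sample_id))
    meta <- meta[match(rownames(dm), meta$sample_id), , drop = FALSE]
  comm <- rank(upper_vec(dm))
  rows <- vector("list", 2^k - 1)
  idx <- 0L
  for (size in seq_len(min(max_subset, k))) {
    for (subset in as.data.frame(combn(variables, size),
                                 stringsAsFactors = FALSE)) {
      ed <- env_distance(meta, subset)
      idx <- idx + 1L
      rows[[idx]] <- data.frame(
        variables = paste(subset, collapse = ", "),
        size = size,
        rs = cor(comm, rank(upper_vec(ed))))
    }
  }
  out <- do.call(rbind, rows[seq_len(idx)])
  out[order(-out$rs), , drop = FALSE]
}

#' Mantel report of UniFrac distance versus each environmental variable
#'
#' For each variable and each community matrix (weighted and unweighted
#' UniFrac), the Mantel correlation against that variable's standardized
#' Euclidean distances, with Benjamini-Hochberg q-values across the whole
#' family; also reports the Mantel correlation between the weighted and
#' unweighted matrices themselves.
#'
#' @param dm_unweighted,dm_weighted UniFrac distance matrices (either may
#'   be NULL to skip).
#' @param meta metadata matched to the matrices' samples.
#' @param variables environmental variables to test.
#' @param n_perm permutations per Mantel test (default 9999).
#' @param seed RNG seed.
#' @return list with \code{correlations} (variable, matrix, r, p, q) and
#'   \code{weighted_vs_unweighted} (Mantel result or NULL).
#' @export
env_mantel_report <- function(dm_unweighted, dm_weighted, meta, variables,
                              n_perm = 9999, seed = NULL) {
  mats <- list(unweighted = dm_unweighted, weighted = dm_weighted)
  mats <- mats[!vapply(mats, is.null, logical(1))]
  if (length(mats) == 0) stop("no distance matrix given")
  rows <- list()
  for (v in variables) {
    xv <- meta[[v]][match(rownames(mats[[1]]), meta$sample_id)]
    if (is.null(meta[[v]]) || sd(xv) == 0) {
      warning("skipping constant or missing variable: ", v)
      next
    }
    for (mn in names(mats)) {
      mt <- mantel(mats[[mn]], env_distance(
        meta[match(rownames(mats[[mn]]), meta$sample_id), , drop = FALSE], v),
        n_perm = n_perm, seed = seed)
      rows[[length(rows) + 1]] <-
        data.frame(variable = v, matrix = mn, r = mt$r, p = mt$p)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) out$q <- bh_fdr(out$p)
  wu <- if (length(mats) == 2)
    mantel(mats$unweighted, mats$weighted, n_perm = n_perm, seed = seed)
  list(correlations = out, weighted_vs_unweighted = wu)
}
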