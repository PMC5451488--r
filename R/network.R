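#' @name cooccurrence_network
#' @title Co-occurrence network inference and topology statistics
#' @description OTU co-occurrence networks are built from all-pairs
#'   Spearman correlations of relative abundances.  Edges are retained only
#'   when (i) the Benjamini-Hochberg q-value of the correlation passes the
#'   significance cutoff, (ii) the absolute correlation passes a cutoff
#'   chosen by the random-matrix-theory (RMT) spectral criterion, and
#'   (iii) network deconvolution assigns the pair a positive direct
#'   dependency (removing transitive correlations).  Topology statistics
#'   are computed per sample on induced subgraphs and aggregated by
#'   aridity class.
NULL

#' Reference correlation cutoffs from the Atacama field study
#'
#' The cutoffs the random-matrix-theory procedure yielded on the real
#' aridity-transect data: 0.81 for the global network and 0.82 / 0.92 /
#' 0.84 for the arid, margin and hyperarid subnetworks.  Used as
#' documented defaults when no data-driven threshold is requested.
#'
#' @format named numeric vector.
#' @export
ATACAMA_RMT_THRESHOLDS <- c(global = 0.81, arid = 0.82,
                            margin = 0.92, hyperarid = 0.84)

#' Remove rare OTUs
#'
#' Drops OTUs whose summed count is below \code{min_frac} of the table's
#' grand total (default 0.01\%); the sample set is unchanged.
#'
#' @param table an \code{\link{otu_table}}.
#' @param min_frac fraction of total reads below which an OTU is dropped
#'   (in [0, 1)).
#' @return filtered \code{\link{otu_table}}.
#' @export
filter_rare <- function(table, min_frac = 1e-4) {
  if (min_frac < 0 || min_frac >= 1) stop("min_frac must lie in [0, 1)")
  if (min_frac == 0) return(table)
  grand <- sum(as.numeric(table))
  if (grand == 0) stop("empty table")
  keep <- colSums(table) >= min_frac * grand
  table[, keep, drop = FALSE]
}

#' All-pairs Spearman correlation and p-value matrices
#'
#' Rank correlations (midrank ties) between every OTU pair, computed on
#' per-sample relative abundances.  P-values follow the
#' \code{\link{spearman}} contract: exhaustive permutation for small
#' sample numbers, t approximation otherwise.  Constant OTU vectors get
#' correlation 0 and p 1 with a note.
#'
#' @param table an \code{\link{otu_table}} with >= 4 samples.
#' @return list with symmetric matrices \code{r} (unit diagonal) and
#'   \code{p} (zero diagonal).
#' @export
spearman_matrix <- function(table) {
  n <- nrow(table)
  if (n < 4) stop("need at least 4 samples")
  ra <- relative_abundance(table)
  constant <- apply(ra, 2, function(x) length(unique(x)) == 1)
  if (any(constant))
    message("note: ", sum(constant),
            " constant OTU vector(s); correlations set to 0")
  rk <- apply(ra, 2, rank)
  # constant columns are handled explicitly below; silence cor's sd-zero
  # warning for them
  r <- suppressWarnings(cor(rk))
  if (n <= 8) {
    p <- matrix(0, ncol(ra), ncol(ra))
    for (i in seq_len(ncol(ra) - 1)) for (j in (i + 1):ncol(ra)) {
      if (constant[i] || constant[j]) { p[i, j] <- p[j, i] <- 1; next }
      sp <- spearman(ra[, i], ra[, j])
      p[i, j] <- p[j, i] <- sp$p
    }
  } else {
    rc <- r
    rc[] <- pmin(1 - 1e-15, pmax(-1 + 1e-15, r))
    tt <- rc * sqrt((n - 2) / (1 - rc^2))
    p <- 2 * pt(abs(tt), df = n - 2, lower.tail = FALSE)
  }
  r[constant, ] <- 0; r[, constant] <- 0
  p[constant, ] <- 1; p[, constant] <- 1
  diag(r) <- 1; diag(p) <- 0
  dimnames(r) <- dimnames(p) <- list(colnames(table), colnames(table))
  list(r = r, p = p)
}

#' Network deconvolution of a dependency matrix
#'
#' Separates direct from transitive dependencies.  The observed matrix
#' \eqn{G} (symmetric, zero diagonal) is modelled as the series
#' \eqn{G = D + D^2 + D^3 + \dots}; in the eigenbasis of \eqn{G} the
#' direct matrix has eigenvalues \eqn{\lambda_d = \lambda/(1+\lambda)}.
#' \eqn{G} is first scaled so that the largest transformed eigenvalue
#' magnitude equals \code{beta}, keeping the series convergent.
#'
#' @param g symmetric numeric matrix with zero diagonal (signed
#'   correlations allowed).
#' @param beta target magnitude of the largest direct eigenvalue, in
#'   (0, 1) (default 0.99).
#' @return symmetric matrix of direct dependencies (zero diagonal up to
#'   numerical error).
#' @export
deconvolve <- function(g, beta = 0.99) {
  if (!is.matrix(g) || nrow(g) != ncol(g)) stop("g must be square")
  if (max(abs(g - t(g))) > 1e-8) stop("g must be symmetric")
  if (beta <= 0 || beta >= 1) stop("beta must lie in (0, 1)")
  if (max(abs(diag(g))) > 1e-8) stop("g must have zero diagonal")
  e <- eigen((g + t(g)) / 2, symmetric = TRUE)
  lam <- e$values
  if (max(abs(lam)) < 1e-14) return(g * 0)
  # scaling alpha: |alpha*lam/(1 + alpha*lam)| <= beta for every eigenvalue,
  # with equality at the binding extreme
  lam_p <- max(lam, 0)
  lam_n <- max(-min(lam, 0), 0)
  cand <- c(if (lam_p > 0) beta / ((1 - beta) * lam_p),
            if (lam_n > 0) beta / ((1 + beta) * lam_n))
  alpha <- min(cand)
  lam_d <- alpha * lam / (1 + alpha * lam)
  d <- e$vectors %*% (lam_d * t(e$vectors))
  (d + t(d)) / 2
}

# nearest-neighbour spacing distribution of an eigenvalue spectrum after
# cubic-spline unfolding; chi-square goodness of fit against the Poisson
# law exp(-s) and the Wigner-Dyson (GOE) surmise (pi/2) s exp(-pi s^2 / 4)
nnsd_fit <- function(values, min_spacings = 20) {
  values <- sort(values)
  n <- length(values)
  ux <- unique(values)
  if (n < min_spacings + 1 || length(ux) < 5) return(NULL)
  # empirical cumulative spectral density, smoothed by a low-df cubic
  # spline: the unfolding must capture the secular density only, not
  # local fluctuations (which carry the spacing statistics)
  dfree <- max(4, min(10, floor(length(ux) / 5)))
  fs <- tryCatch(
    smooth.spline(values, seq_len(n) / n, df = dfree),
    error = function(e) NULL)
  if (is.null(fs)) return(NULL)
  unfolded <- n * predict(fs, values)$y
  s <- diff(unfolded)
  s[s < 0] <- 0
  if (mean(s) <= 0) return(NULL)
  s <- s / mean(s)
  edges <- c(seq(0, 2.5, by = 0.5), Inf)
  obs <- table(cut(s, edges, include.lowest = TRUE))
  p_pois <- diff(1 - exp(-edges))          # F(s) = 1 - exp(-s)
  p_goe <- diff(1 - exp(-pi * edges^2 / 4))  # F(s) = 1 - exp(-pi s^2/4)
  gof <- function(pr) {
    expd <- pr * length(s)
    stat <- sum((as.numeric(obs) - expd)^2 / pmax(expd, 1e-12))
    pchisq(stat, df = length(expd) - 1, lower.tail = FALSE)
  }
  list(n_spacings = length(s),
       p_poisson = gof(p_pois),
       p_goe = gof(p_goe))
}

#' Random-matrix-theory correlation threshold
#'
#' Scans a grid of candidate cutoffs.  At each cutoff the correlation
#' matrix is sparsified (entries with \eqn{|r|} below the cutoff zeroed),
#' isolated OTUs are removed, and the nearest-neighbour spacing
#' distribution (NNSD) of the remaining eigenvalue spectrum is computed
#' after cubic-spline unfolding.  The chosen threshold is the smallest
#' cutoff at which the NNSD is consistent with the Poisson law
#' (modular signal; chi-square p > \code{alpha}) while the Wigner-Dyson
#' (GOE, correlated noise) law is rejected.  If no cutoff qualifies the
#' grid maximum is returned with a warning.
#'
#' @param r symmetric correlation matrix (unit diagonal).
#' @param grid candidate cutoffs (default 0.50 to 0.99 by 0.01).
#' @param alpha significance level for the spectral tests (default 0.05).
#' @param min_otus smallest usable spectrum (default 30 OTUs).
#' @return list with \code{threshold}, \code{chosen} (FALSE when the
#'   fallback was used) and \code{scan} (per-cutoff diagnostics).
#' @export
rmt_threshold <- function(r, grid = seq(0.50, 0.99, by = 0.01),
                          alpha = 0.05, min_otus = 30) {
  if (!is.matrix(r) || nrow(r) != ncol(r)) stop("r must be square")
  if (max(abs(r - t(r))) > 1e-8) stop("r must be symmetric")
  if (nrow(r) < min_otus)
    stop("matrix too small for spectral thresholding (",
         nrow(r), " < ", min_otus, " OTUs); supply a fixed threshold")
  a <- abs(r); diag(a) <- 0
  scan <- list()
  for (t in grid) {
    keep_entry <- a >= t
    deg <- rowSums(keep_entry)
    nodes <- which(deg > 0)
    if (length(nodes) < min_otus) next
    sub <- r[nodes, nodes, drop = FALSE]
    sub[a[nodes, nodes] < t] <- 0
    diag(sub) <- 1
    ev <- eigen(sub, symmetric = TRUE, only.values = TRUE)$values
    fit <- nnsd_fit(ev)
    if (is.null(fit)) next
    scan[[length(scan) + 1]] <- data.frame(
      threshold = t, n_otus = length(nodes),
      p_poisson = fit$p_poisson, p_goe = fit$p_goe)
    if (fit$p_poisson > alpha && fit$p_goe <= alpha) {
      return(list(threshold = t, chosen = TRUE,
                  scan = do.call(rbind, scan)))
    }
  }
  warning("no cutoff reached the Poisson regime; returning grid maximum ",
          max(grid))
  list(threshold = max(grid), chosen = FALSE,
       scan = if (length(scan)) do.call(rbind, scan))
}

#' Assemble the co-occurrence network
#'
#' An OTU pair becomes an edge iff its BH q-value is at most
#' \code{q_cutoff}, its absolute Spearman correlation is at least
#' \code{threshold}, and its deconvolved direct weight is positive.
#' Isolated OTUs are excluded from the node set.
#'
#' @param r,p matrices from \code{\link{spearman_matrix}}.
#' @param d deconvolved direct-dependency matrix from
#'   \code{\link{deconvolve}}.
#' @param threshold correlation cutoff in (0, 1), typically from
#'   \code{\link{rmt_threshold}}.
#' @param q_cutoff FDR cutoff for edges (default 0.01).
#' @return a \code{cooccurrence_network}: list with \code{graph} (igraph),
#'   \code{edges} (otu_a, otu_b, rs, q, deconvolved, sign),
#'   \code{nodes}, \code{threshold_used}, \code{q_cutoff},
#'   \code{fraction_positive}.
#' @export
build_network <- function(r, p, d, threshold, q_cutoff = 0.01) {
  if (threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  stopifnot(identical(dim(r), dim(p)), identical(dim(r), dim(d)))
  ids <- colnames(r)
  ut <- upper.tri(r)
  q <- matrix(NA_real_, nrow(r), ncol(r))
  q[ut] <- bh_fdr(p[ut])
  keep <- ut & q <= q_cutoff & abs(r) >= threshold & d > 0
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(
    otu_a = ids[idx[, 1]], otu_b = ids[idx[, 2]],
    rs = r[keep], q = q[keep], deconvolved = d[keep],
    sign = ifelse(r[keep] >= 0, 1L, -1L),
    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  net <- list(graph = g,
              edges = edges,
              nodes = data.frame(otu = igraph::V(g)$name,
                                 degree = igraph::degree(g),
                                 betweenness = igraph::betweenness(g),
                                 row.names = NULL,
                                 stringsAsFactors = FALSE),
              threshold_used = threshold,
              q_cutoff = q_cutoff,
              fraction_positive = if (nrow(edges)) mean(edges$sign > 0)
                                  else NA_real_)
  class(net) <- "cooccurrence_network"
  net
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf(
    "co-occurrence network: %d nodes, %d edges (|rs| >= %.2f, q <= %g, %s positive)\n",
    nrow(x$nodes), nrow(x$edges), x$threshold_used, x$q_cutoff,
    ifelse(is.na(x$fraction_positive), "NA",
           sprintf("%.1f%%", 100 * x$fraction_positive))))
  invisible(x)
}

#' Mean soil relative humidity per network node
#'
#' For every node, the mean AvgSoilRH over the samples in which the OTU
#' was observed (count > 0) — the node colouring used for aridity-gradient
#' network figures.
#'
#' @param net a \code{cooccurrence_network}.
#' @param table the \code{\link{otu_table}} the network was built from.
#' @param meta metadata with \code{AvgSoilRH}, matched on sample ids.
#' @return the network with a \code{mean_rh} column added to
#'   \code{net$nodes}.
#' @export
node_environment <- function(net, table, meta) {
  absent <- setdiff(net$nodes$otu, colnames(table))
  if (length(absent))
    stop("node(s) absent from table: ",
         paste(head(absent, 5), collapse = ", "))
  rh <- meta$AvgSoilRH[match(rownames(table), meta$sample_id)]
  net$nodes$mean_rh <- vapply(net$nodes$otu, function(o) {
    present <- table[, o] > 0
    if (!any(present)) return(NA_real_)
    mean(rh[present])
  }, numeric(1))
  net
}

# graph-level statistics for one (sub)graph
graph_stats <- function(g) {
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  if (n == 0)
    return(data.frame(size = 0, degree = 0, betweenness = 0,
                      edge_count = 0, avg_path_length = 0,
                      betweenness_centralization = 0))
  apl <- if (m > 0) igraph::mean_distance(g, directed = FALSE,
                                          unconnected = TRUE) else 0
  centr <- if (n >= 3) {
    igraph::centr_betw(g, directed = FALSE)$centralization
  } else 0
  data.frame(
    size = n,
    degree = mean(igraph::degree(g)),
    betweenness = mean(igraph::betweenness(g)),
    edge_count = m,
    avg_path_length = if (is.finite(apl)) apl else 0,
    betweenness_centralization = centr)
}

#' Per-sample induced-subgraph network statistics
#'
#' For each sample, the network is restricted to the OTUs observed in that
#' sample (count > 0) and graph statistics are computed on the induced
#' subgraph: node count (size), mean degree, mean betweenness, edge count,
#' average shortest-path length over reachable pairs, and Freeman
#' betweenness centralization.
#'
#' @param net a \code{cooccurrence_network}.
#' @param table the \code{\link{otu_table}} (samples x OTUs).
#' @return data.frame with one row per sample.
#' @export
sample_level_stats <- function(net, table) {
  out <- lapply(rownames(table), function(s) {
    present <- colnames(table)[table[s, ] > 0]
    nodes <- intersect(net$nodes$otu, present)
    if (length(nodes) == 0)
      warning("empty induced subgraph for sample ", s)
    g <- igraph::induced_subgraph(net$graph, nodes)
    cbind(data.frame(sample_id = s, stringsAsFactors = FALSE),
          graph_stats(g))
  })
  do.call(rbind, out)
}

#' Aridity-class medians of per-sample network statistics
#'
#' @param stats data.frame from \code{\link{sample_level_stats}}.
#' @param classes aridity class per sample (matched by position or by a
#'   named vector on \code{sample_id}).
#' @return data.frame with one row per class (hyperarid, margin, arid
#'   order where present) and the median of each statistic.
#' @export
class_summary <- function(stats, classes) {
  if (!is.null(names(classes)))
    classes <- classes[stats$sample_id]
  if (length(classes) != nrow(stats))
    stop("one class per sample required")
  fields <- c("size", "degree", "betweenness", "edge_count",
              "avg_path_length", "betweenness_centralization")
  lv <- intersect(c("hyperarid", "margin", "arid"), unique(classes))
  missing_cls <- setdiff(c("hyperarid", "margin", "arid"), lv)
  if (length(missing_cls))
    warning("empty class(es) omitted: ", paste(missing_cls, collapse = ", "))
  rows <- lapply(lv, function(cl) {
    sub <- stats[classes == cl, fields, drop = FALSE]
    cbind(data.frame(class = cl, n_samples = nrow(sub),
                     stringsAsFactors = FALSE),
          as.data.frame(lapply(sub, median)))
  })
  do.call(rbind, rows)
}

#' Correlations between network metrics and soil relative humidity
#'
#' Node level: Spearman correlation of each node's mean soil RH with its
#' degree and betweenness.  Sample level: correlation of each sample's
#' AvgSoilRH with the induced-subgraph edge count and size.
#'
#' @param net a \code{cooccurrence_network} with node \code{mean_rh}
#'   (see \code{\link{node_environment}}).
#' @param sample_stats data.frame from \code{\link{sample_level_stats}}.
#' @param meta metadata with \code{AvgSoilRH}.
#' @return data.frame with columns \code{level}, \code{metric}, \code{rs},
#'   \code{p}, \code{n}; degenerate (constant) pairs are flagged with NA.
#' @export
node_metric_env_correlation <- function(net, sample_stats, meta) {
  if (is.null(net$nodes$mean_rh))
    stop("run node_environment() first to attach node mean_rh")
  rh_sample <- meta$AvgSoilRH[match(sample_stats$sample_id, meta$sample_id)]
  pairs <- list(
    list(level = "node", metric = "degree",
         x = net$nodes$mean_rh, y = net$nodes$degree),
    list(level = "node", metric = "betweenness",
         x = net$nodes$mean_rh, y = net$nodes$betweenness),
    list(level = "sample", metric = "edge_count",
         x = rh_sample, y = sample_stats$edge_count),
    list(level = "sample", metric = "size",
         x = rh_sample, y = sample_stats$size))
  rows <- lapply(pairs, function(pr) {
    res <- tryCatch(spearman(pr$x, pr$y),
                    error = function(e) list(rs = NA_real_, p = NA_real_,
                                             n = sum(complete.cases(pr$x, pr$y))))
    data.frame(level = pr$level, metric = pr$metric,
               rs = res$rs, p = res$p, n = res$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Full co-occurrence inference pipeline on an OTU table
#'
#' Runs rare-OTU filtering, the Spearman correlation matrix, network
#' deconvolution, RMT threshold selection (unless a fixed threshold is
#' supplied) and edge assembly; optionally attaches node mean soil RH.
#'
#' @param table an \code{\link{otu_table}}.
#' @param meta optional metadata (enables node \code{mean_rh}).
#' @param min_frac rare-OTU fraction cutoff (default 1e-4, i.e. 0.01\%).
#' @param q_cutoff FDR cutoff for edges (default 0.01).
#' @param threshold correlation cutoff.  The default 0.81 is the cutoff
#'   the random-matrix-theory procedure selected on the Atacama field
#'   data, kept as the reference default; pass NULL to select a cutoff
#'   from the data at hand with \code{\link{rmt_threshold}} instead.
#' @param deconvolve_beta scaling target for \code{\link{deconvolve}}.
#' @param rmt_grid candidate cutoff grid for \code{\link{rmt_threshold}}.
#' @param min_otus smallest spectrum for the RMT scan.
#' @return a \code{cooccurrence_network} with an extra
#'   \code{threshold_chosen_by_rmt} flag and the filtered table under
#'   \code{$table}.
#' @export
build_cooccurrence <- function(table, meta = NULL, min_frac = 1e-4,
                               q_cutoff = 0.01, threshold = 0.81,
                               deconvolve_beta = 0.99,
                               rmt_grid = seq(0.50, 0.99, by = 0.01),
                               min_otus = 30) {
  ft <- filter_rare(table, min_frac)
  sm <- spearman_matrix(ft)
  g <- sm$r; diag(g) <- 0
  d <- deconvolve(g, beta = deconvolve_beta)
  chosen_by_rmt <- FALSE
  if (is.null(threshold)) {
    rt <- rmt_threshold(sm$r, grid = rmt_grid, min_otus = min_otus)
    threshold <- rt$threshold
    chosen_by_rmt <- rt$chosen
  }
  net <- build_network(sm$r, sm$p, d, threshold = threshold,
                       q_cutoff = q_cutoff)
  net$threshold_chosen_by_rmt <- chosen_by_rmt
  net$table <- ft
  if (!is.null(meta)) net <- node_environment(net, ft, meta)
  net
}

#' Aridity-class subnetwork
#'
#' Re-runs the full co-occurrence pipeline on the samples of one aridity
#' class only, with its own RMT threshold.
#'
#' @param table an \code{\link{otu_table}}.
#' @param meta metadata with \code{aridity_class} and \code{sample_id}.
#' @param class one of "hyperarid", "margin", "arid".
#' @param ... further arguments to \code{\link{build_cooccurrence}}.
#' @return a \code{cooccurrence_network} for that class.
#' @export
class_subnetwork <- function(table, meta, class, ...) {
  ids <- meta$sample_id[meta$aridity_class == class]
  ids <- intersect(rownames(table), ids)
  if (length(ids) < 4)
    stop("fewer than 4 samples in class ", class)
  build_cooccurrence(table[ids, , drop = FALSE],
                     meta = meta[meta$sample_id %in% ids, , drop = FALSE],
                     ...)
}
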