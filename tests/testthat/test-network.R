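test_that("filter_rare applies the fraction-of-total rule", {
  tab <- otu_table(matrix(as.integer(c(1, 10, 100, 1000, 10000)), 1,
                          dimnames = list("s", paste0("o", 1:5))))
  # grand total 11,111; cut at 1e-4 is 1.11 reads -> only the singleton drops
  f <- filter_rare(tab, 1e-4)
  expect_equal(colnames(f), paste0("o", 2:5))
  expect_identical(unclass(filter_rare(tab, 0)), unclass(tab))
  expect_error(filter_rare(tab, 1), "min_frac")
})

test_that("spearman_matrix matches pairwise brute force", {
  tab <- toy_table()
  # duplicate and reversed columns
  m <- cbind(unclass(tab), E = unclass(tab)[, "A"],
             Frev = rev(unclass(tab)[, "A"]))
  tab2 <- otu_table(m)
  sm <- spearman_matrix(tab2)
  expect_equal(sm$r["A", "E"], 1)
  expect_equal(unname(diag(sm$r)), rep(1, 6))
  expect_equal(max(abs(sm$r - t(sm$r))), 0)
  # brute force every pair on relative abundances
  ra <- relative_abundance(tab2)
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(sm$r[i, j], cor(rank(ra[, i]), rank(ra[, j])),
                 tolerance = 1e-12)
  }
  # constant relative-abundance vectors are flagged and zeroed
  m3 <- matrix(10L, 5, 2, dimnames = list(paste0("S", 1:5),
                                          c("K1", "K2")))
  expect_message(sm3 <- suppressWarnings(spearman_matrix(otu_table(m3))),
                 "constant")
  expect_equal(sm3$r["K1", "K2"], 0)
  expect_equal(sm3$p["K1", "K2"], 1)
})

test_that("deconvolution separates direct from transitive dependencies", {
  # zero matrix is a fixed point
  z <- matrix(0, 4, 4)
  expect_equal(deconvolve(z), z)
  # 3-node chain: direct AB = BC = 0.9, transitive AC = 0.81
  g <- matrix(c(0, .9, .81,
                .9, 0, .9,
                .81, .9, 0), 3, 3)
  d <- deconvolve(g)
  expect_lt(d[1, 3], d[1, 2])
  expect_lt(d[1, 3], d[2, 3])
  # independent eigendecomposition confirms the transform
  e <- eigen(g, symmetric = TRUE)
  alpha <- min(0.99 / ((1 - 0.99) * max(e$values)),
               0.99 / ((1 + 0.99) * abs(min(e$values))))
  lam_d <- alpha * e$values / (1 + alpha * e$values)
  d_ref <- e$vectors %*% diag(lam_d) %*% t(e$vectors)
  expect_equal(d, (d_ref + t(d_ref)) / 2, tolerance = 1e-12)
  # symmetry on random symmetric inputs
  set.seed(16)
  for (k in 1:3) {
    a <- matrix(rnorm(36), 6)
    a <- (a + t(a)) / 2; diag(a) <- 0
    dd <- deconvolve(a)
    expect_lt(max(abs(dd - t(dd))), 1e-10)
  }
  expect_error(deconvolve(matrix(1:4, 2)), "symmetric")
})

test_that("deconvolution inverse transform recovers the scaled spectrum", {
  set.seed(17)
  a <- matrix(rnorm(49), 7)
  a <- (a + t(a)) / 2; diag(a) <- 0
  d <- deconvolve(a, beta = 0.9)
  lam_d <- eigen(d, symmetric = TRUE, only.values = TRUE)$values
  lam_rec <- sort(lam_d / (1 - lam_d))
  e <- eigen(a, symmetric = TRUE)
  alpha <- min(0.9 / ((1 - 0.9) * max(e$values)),
               0.9 / ((1 + 0.9) * abs(min(e$values))))
  expect_equal(lam_rec, sort(alpha * e$values), tolerance = 1e-8)
})

test_that("rmt_threshold finds the planted-block band and flags noise", {
  # planted blocks generated from data: within-block r ~ 0.9, noise below
  set.seed(18)
  n_samp <- 60
  blocks <- 3; per <- 40
  lat <- matrix(rnorm(blocks * n_samp), blocks)
  x <- matrix(rnorm(blocks * per * n_samp, sd = 0.35),
              blocks * per, n_samp) +
    lat[rep(1:blocks, each = per), ]
  r <- cor(t(x))
  ut <- upper.tri(r)
  same <- outer(rep(1:blocks, each = per), rep(1:blocks, each = per), "==")
  expect_gt(median(r[ut & same]), 0.85)
  expect_lt(quantile(abs(r[ut & !same]), 0.999), 0.5)
  res <- rmt_threshold(r)
  # the cutoff separates the planted band from the noise band
  expect_gte(res$threshold, 0.5)
  expect_lt(res$threshold, 0.9)
  expect_gt(median(r[ut & same]), res$threshold)
  expect_lt(quantile(abs(r[ut & !same]), 0.99), res$threshold)

  # pure noise: returned threshold exceeds the noise 95th percentile
  noise <- matrix(rnorm(60 * 40), 60, 40)
  rn <- cor(t(noise))
  resn <- suppressWarnings(rmt_threshold(rn))
  expect_gt(resn$threshold, quantile(abs(rn[upper.tri(rn)]), 0.95))

  expect_error(rmt_threshold(diag(5)), "fixed threshold")
})

test_that("build_network enforces all three retention rules", {
  ids <- paste0("o", 1:4)
  r <- diag(4); r[1, 2] <- r[2, 1] <- 0.95
  r[3, 4] <- r[4, 3] <- 0.9
  p <- matrix(0.5, 4, 4); diag(p) <- 0
  p[1, 2] <- p[2, 1] <- 1e-8
  p[3, 4] <- p[4, 3] <- 0.2   # high r but insignificant -> dropped
  d <- matrix(0.1, 4, 4); diag(d) <- 0
  dimnames(r) <- dimnames(p) <- dimnames(d) <- list(ids, ids)
  net <- build_network(r, p, d, threshold = 0.8)
  expect_equal(nrow(net$edges), 1)
  expect_setequal(c(net$edges$otu_a, net$edges$otu_b), c("o1", "o2"))
  expect_equal(nrow(net$nodes), 2)
  expect_true(all(abs(net$edges$rs) >= net$threshold_used))
  expect_true(all(net$edges$q <= net$q_cutoff))
  expect_true(all(net$edges$deconvolved > 0))
  # negative deconvolved weight removes the edge
  d2 <- d; d2[1, 2] <- d2[2, 1] <- -0.1
  expect_equal(nrow(build_network(r, p, d2, threshold = 0.8)$edges), 0)
  # threshold 1.0 gives an empty network on generic data
  expect_equal(nrow(build_network(r, p, d, threshold = 1)$edges), 0)
  expect_error(build_network(r, p, d, threshold = 0), "threshold")
})

test_that("node_environment averages AvgSoilRH over occupied samples", {
  tab <- otu_table(matrix(c(1L, 0L, 3L,
                            1L, 2L, 5L), 2, 3, byrow = FALSE,
                          dimnames = list(c("s1", "s2"),
                                          c("u", "v", "w"))))
  meta <- data.frame(sample_id = c("s1", "s2"), AvgSoilRH = c(10, 30))
  net <- list(nodes = data.frame(otu = c("u", "v", "w"),
                                 degree = 1:3, betweenness = 0,
                                 stringsAsFactors = FALSE))
  out <- node_environment(net, tab, meta)
  # u only in s1 (RH 10); v and w in both samples (mean 20)
  expect_equal(out$nodes$mean_rh, c(10, 20, 20))
  net$nodes$otu[1] <- "absent"
  expect_error(node_environment(net, tab, meta), "absent")
})

test_that("induced-subgraph statistics match known topologies", {
  # star on 5 nodes: centralization 1, path length 2(1 - 1/n)...
  star_edges <- data.frame(a = "h", b = paste0("s", 1:4))
  g_star <- igraph::graph_from_data_frame(star_edges, directed = FALSE)
  st <- aridnet:::graph_stats(g_star)
  expect_equal(st$betweenness_centralization, 1)
  expect_equal(st$size, 5)
  expect_equal(st$edge_count, 4)
  # complete K4: path length 1, centralization 0
  k4 <- igraph::make_full_graph(4)
  st4 <- aridnet:::graph_stats(k4)
  expect_equal(st4$avg_path_length, 1)
  expect_equal(st4$betweenness_centralization, 0)
  # path A-B-C: (1 + 1 + 2) / 3
  p3 <- igraph::make_graph(~ A - B - C)
  expect_equal(aridnet:::graph_stats(p3)$avg_path_length, 4 / 3)
})

test_that("path metrics agree with an exhaustive shortest-path oracle", {
  set.seed(19)
  n <- 7
  em <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  picked <- em[runif(nrow(em)) < 0.4, , drop = FALSE]
  g <- igraph::graph_from_edgelist(picked, directed = FALSE)
  g <- igraph::add_vertices(g, n - igraph::vcount(g))
  st <- aridnet:::graph_stats(g)
  d <- brute_shortest_paths(n, picked)
  finite <- d[upper.tri(d)][is.finite(d[upper.tri(d)]) &
                              d[upper.tri(d)] > 0]
  expect_equal(st$avg_path_length, mean(finite))
  expect_equal(st$degree, mean(table(factor(c(picked), levels = 1:n))))
})

test_that("class_summary takes per-class medians in Table order", {
  stats <- data.frame(sample_id = paste0("s", 1:6),
                      size = c(1, 2, 9, 4, 5, 6),
                      degree = 1, betweenness = 0,
                      edge_count = c(1, 2, 9, 1, 1, 1),
                      avg_path_length = 1,
                      betweenness_centralization = 0)
  cls <- c(rep("hyperarid", 3), rep("arid", 3))
  expect_warning(cs <- class_summary(stats, cls), "omitted")  # no margin
  expect_equal(cs$class, c("hyperarid", "arid"))
  expect_equal(cs$edge_count[cs$class == "hyperarid"], 2)
  expect_equal(names(cs)[3:8],
               c("size", "degree", "betweenness", "edge_count",
                 "avg_path_length", "betweenness_centralization"))
  # one sample per class: medians equal the sample values
  cs1 <- suppressWarnings(class_summary(stats[c(1, 4), ], cls[c(1, 4)]))
  expect_equal(cs1$size, stats$size[c(1, 4)])
})

test_that("every reported edge satisfies the retention invariants", {
  ds <- simulate_dataset(compact_gradient_design(2))
  net <- suppressMessages(build_cooccurrence(ds$table, ds$metadata))
  expect_true(all(abs(net$edges$rs) >= net$threshold_used))
  expect_true(all(net$edges$q <= net$q_cutoff))
  expect_true(all(net$edges$deconvolved > 0))
  expect_false(any(net$edges$otu_a == net$edges$otu_b))
  expect_true(is.finite(net$fraction_positive))
  # arid subnetwork denser than hyperarid subnetwork
  arid <- suppressMessages(suppressWarnings(
    class_subnetwork(ds$table, ds$metadata, "arid")))
  hyper <- suppressMessages(suppressWarnings(
    class_subnetwork(ds$table, ds$metadata, "hyperarid")))
  expect_gt(nrow(arid$edges), nrow(hyper$edges))
  expect_error(class_subnetwork(ds$table, ds$metadata[1:3, ], "arid"),
               "fewer than 4")
})
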