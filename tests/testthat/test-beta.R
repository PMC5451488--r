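test_that("unweighted UniFrac matches the per-branch oracle", {
  tr <- balanced4()
  tab <- otu_table(matrix(c(5L, 5L, 0L, 0L,   # {A,B}
                            3L, 0L, 7L, 0L,   # {A,C}
                            5L, 5L, 0L, 0L),  # {A,B} again
                          3, 4, byrow = TRUE,
                          dimnames = list(c("s1", "s2", "s3"),
                                          c("A", "B", "C", "D"))))
  d <- unifrac(tab, tr, weighted = FALSE)
  # {A,B} vs {A,C}: 6 branches, unique = B,C,(CD-stem) = 3; union = 5
  expect_equal(d["s1", "s2"], 3 / 5)
  expect_equal(d["s1", "s2"], brute_unifrac(c("A", "B"), c("A", "C"), tr))
  # identical samples -> 0
  expect_equal(d["s1", "s3"], 0)
  # disjoint leaves of a star tree -> 1
  st <- star_tree(c("A", "B", "C", "D"))
  tab2 <- otu_table(matrix(c(1L, 1L, 0L, 0L,
                             0L, 0L, 1L, 1L), 2, 4, byrow = TRUE,
                           dimnames = list(c("x", "y"),
                                           c("A", "B", "C", "D"))))
  expect_equal(unifrac(tab2, st)["x", "y"], 1)
  # random presence sets against the oracle
  set.seed(6)
  tr8 <- ape::rtree(6)
  m <- matrix(rbinom(24, 1, 0.6), 4, 6,
              dimnames = list(paste0("s", 1:4), tr8$tip.label))
  m[rowSums(m) == 0, 1] <- 1
  du <- unifrac(otu_table(m), tr8)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(du[i, j],
                 brute_unifrac(colnames(m)[m[i, ] > 0],
                               colnames(m)[m[j, ] > 0], tr8),
                 tolerance = 1e-12)
  }
  expect_true(all(du >= 0 & du <= 1))
})

test_that("weighted UniFrac follows the normalized abundance form", {
  tr <- balanced4()
  tab <- otu_table(matrix(c(10L, 0L, 0L, 0L,
                            0L, 0L, 10L, 0L), 2, 4, byrow = TRUE,
                          dimnames = list(c("s1", "s2"),
                                          c("A", "B", "C", "D"))))
  # all mass on A vs all on C: every branch fully unshared -> 1
  expect_equal(unifrac(tab, tr, weighted = TRUE)["s1", "s2"], 1)
  # hand computation for a mixed case
  tab2 <- otu_table(matrix(c(5L, 5L, 0L, 0L,
                             0L, 5L, 5L, 0L), 2, 4, byrow = TRUE,
                           dimnames = list(c("s1", "s2"),
                                           c("A", "B", "C", "D"))))
  # branches (unit length): A, B, C, D, AB-stem, CD-stem
  pa <- c(A = .5, B = .5, C = 0, D = 0, AB = 1, CD = 0)
  pb <- c(A = 0, B = .5, C = .5, D = 0, AB = .5, CD = .5)
  expect_equal(unifrac(tab2, tr, weighted = TRUE)["s1", "s2"],
               sum(abs(pa - pb)) / sum(pa + pb))
})

test_that("pcoa recovers planted geometry and reports eigenvalues", {
  # points on a line: PC1 explains everything
  x <- c(0, 1, 3, 7)
  dm <- as.matrix(dist(x))
  ord <- pcoa(dm)
  expect_equal(ord$proportions[1], 1)
  expect_equal(unname(abs(diff(sort(ord$coordinates[, 1])))),
               abs(diff(sort(x))), tolerance = 1e-8)
  # all-zero distances -> zero coordinates
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_true(all(pcoa(z)$coordinates == 0))
  # 2-D round trip: recovered coordinates reproduce the input distances
  set.seed(7)
  pts <- matrix(rnorm(10), 5, 2)
  dm2 <- as.matrix(dist(pts))
  rec <- pcoa(dm2)$coordinates
  expect_equal(as.matrix(dist(rec)), dm2, tolerance = 1e-8,
               ignore_attr = TRUE)
  # cross-check against classical MDS
  ref <- cmdscale(dm2, k = 2)
  expect_equal(abs(cor(rec[, 1], ref[, 1])), 1, tolerance = 1e-8)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("mantel is exact under enumeration and matches vegan at scale", {
  set.seed(9)
  x <- rnorm(5)
  d1 <- as.matrix(dist(x))
  expect_equal(mantel(d1, d1)$r, 1)
  d2 <- as.matrix(dist(rnorm(5)))
  res <- mantel(d1, d2)
  expect_true(res$exact)
  # enumeration oracle over all 120 relabelings
  perms <- gtools_permutations(5)
  v1 <- rank(d1[upper.tri(d1)])
  null_r <- apply(perms, 1, function(p)
    cor(v1, rank(d2[p, p][upper.tri(d2)])))
  expect_equal(res$p, mean(null_r >= res$r - 1e-12))

  skip_if_not_installed("vegan")
  set.seed(10)
  a <- as.matrix(dist(rnorm(20)))
  b <- as.matrix(dist(rnorm(20)))
  ours <- mantel(a, b, n_perm = 999, seed = 1)
  ref <- vegan::mantel(as.dist(a), as.dist(b), method = "spearman",
                       permutations = 999)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p, ref$signif, tolerance = 0.05)
})

test_that("anosim matches brute-force ranks and vegan", {
  # perfectly separated groups -> R = 1
  pts <- c(0, 0.1, 0.2, 10, 10.1, 10.2)
  dm <- as.matrix(dist(pts))
  g <- rep(c("a", "b"), each = 3)
  res <- anosim(dm, g)
  expect_equal(res$R, 1)
  # brute-force rank computation for a mixed case
  set.seed(11)
  pts2 <- rnorm(6)
  dm2 <- as.matrix(dist(pts2))
  res2 <- anosim(dm2, g)
  rk <- matrix(0, 6, 6)
  rk[upper.tri(rk)] <- rank(dm2[upper.tri(dm2)])
  rk <- rk + t(rk)
  within <- outer(g, g, "==")[upper.tri(rk)]
  r_brute <- (mean(rk[upper.tri(rk)][!within]) -
                mean(rk[upper.tri(rk)][within])) / (6 * 5 / 4)
  expect_equal(res2$R, r_brute)
  expect_true(res2$exact)
  expect_error(anosim(dm, c("a", rep("b", 5))), "singleton")

  skip_if_not_installed("vegan")
  set.seed(12)
  pts3 <- rnorm(14)
  dm3 <- as.matrix(dist(pts3))
  g3 <- rep(c("a", "b"), 7)
  ref <- vegan::anosim(as.dist(dm3), g3, permutations = 99)
  expect_equal(anosim(dm3, g3, n_perm = 99, seed = 1)$R,
               unname(ref$statistic), tolerance = 1e-12)
})

test_that("env_distance standardizes before Euclidean distance", {
  m <- toy_metadata(4)
  m$elevation <- c(100, 200, 300, 400)
  m$pH <- c(7, 8, 7.5, 7.2)
  # one variable: distance = difference in sd units
  m2 <- m[1:2, ]
  m2$elevation <- c(0, 1)       # sd of the pair is 1/sqrt(2)
  d2 <- env_distance(m2, "elevation")
  expect_equal(d2[1, 2], 1 / sd(c(0, 1)))
  # duplicated variable scales distances by sqrt(2)
  m$elev2 <- m$elevation
  d1 <- env_distance(m, "elevation")
  dd <- env_distance(m, c("elevation", "elev2"))
  expect_equal(dd, d1 * sqrt(2))
  # hand-computed 2-variable case
  z <- scale(cbind(m$elevation, m$pH))
  expect_equal(env_distance(m, c("elevation", "pH"))[1, 3],
               sqrt(sum((z[1, ] - z[3, ])^2)))
  m$const <- 1
  expect_error(env_distance(m, "const"), "constant")
})

test_that("best_bioenv ranks the generating subset first", {
  m <- toy_metadata(8)
  set.seed(13)
  m$elevation <- rnorm(8); m$pH <- rnorm(8); m$EC <- rnorm(8)
  dm <- env_distance(m, "elevation")
  res <- best_bioenv(dm, m, c("elevation", "pH", "EC"))
  expect_equal(nrow(res), 2^3 - 1)
  expect_equal(res$variables[1], "elevation")
  expect_equal(res$rs[1], 1)
  expect_true(all(res$rs <= 1))
  expect_true(all(diff(res$rs) <= 1e-12))
  # subset-size column mirrors the reported layout
  expect_equal(res$size[1], 1)
  expect_error(best_bioenv(dm, m, paste0("v", 1:16)), "15")
})

test_that("best_bioenv agrees with vegan::bioenv on the winner", {
  skip_if_not_installed("vegan")
  set.seed(14)
  n <- 10
  m <- toy_metadata(n)
  m$elevation <- rnorm(n); m$pH <- rnorm(n); m$EC <- rnorm(n)
  comm_x <- m$elevation + 0.3 * m$pH + rnorm(n, 0, 0.1)
  dm <- as.matrix(dist(scale(comm_x)))
  dimnames(dm) <- list(m$sample_id, m$sample_id)
  ours <- best_bioenv(dm, m, c("elevation", "pH", "EC"))
  ref <- vegan::bioenv(as.dist(dm),
                       data.frame(elevation = m$elevation, pH = m$pH,
                                  EC = m$EC))
  ref_best <- max(vapply(ref$models, function(x) x$est, numeric(1)))
  expect_equal(ours$rs[1], ref_best, tolerance = 1e-10)
})

test_that("env_mantel_report composes mantel with BH and flags constants", {
  ds <- simulate_dataset(gradient_design(
    n_sites = 5, pits_per_site = 2, n_otus = 60, n_blocks = 2,
    block_size_range = c(5, 6), seed = 15))
  rt <- suppressWarnings(rarefy(ds$table, 5000, seed = 1))
  du <- unifrac(rt, ds$tree)
  meta <- ds$metadata[match(rownames(du), ds$metadata$sample_id), ]
  meta$const <- 1
  expect_warning(
    rep <- env_mantel_report(du, NULL, meta,
                             c("AvgSoilRH", "pH", "const"),
                             n_perm = 99, seed = 1),
    "constant")
  expect_equal(rep$correlations$q, bh_fdr(rep$correlations$p))
  expect_null(rep$weighted_vs_unweighted)
  # the gradient driver beats the non-gradient soil variable
  rh_r <- rep$correlations$r[rep$correlations$variable == "AvgSoilRH"]
  ph_r <- rep$correlations$r[rep$correlations$variable == "pH"]
  expect_gt(rh_r, ph_r)
})
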