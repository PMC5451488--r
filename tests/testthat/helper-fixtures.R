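# shared fixtures: tiny trees, tables and brute-force oracles

# rooted 4-leaf balanced tree with unit branches: ((A:1,B:1):1,(C:1,D:1):1)
balanced4 <- function() {
  ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
}

# star tree over n leaves with unit branches
star_tree <- function(labels) {
  ape::read.tree(text = paste0(
    "(", paste0(labels, ":1", collapse = ","), ");"))
}

# brute-force Faith's PD: union of the branch sets on each observed
# leaf's root path, summed (per-branch membership oracle)
brute_pd <- function(otus, tree) {
  if (length(otus) == 0) return(0)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1
  edges <- numeric(0)
  for (leaf in match(otus, tree$tip.label)) {
    node <- leaf
    while (node != root) {
      e <- which(tree$edge[, 2] == node)
      edges <- union(edges, e)
      node <- tree$edge[e, 1]
    }
  }
  sum(tree$edge.length[edges])
}

# brute-force unweighted UniFrac: per-branch unique/union tally over the
# root paths of the two leaf sets
brute_unifrac <- function(set_a, set_b, tree) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1
  branch_set <- function(otus) {
    edges <- integer(0)
    for (leaf in match(otus, tree$tip.label)) {
      node <- leaf
      while (node != root) {
        e <- which(tree$edge[, 2] == node)
        edges <- union(edges, e)
        node <- tree$edge[e, 1]
      }
    }
    edges
  }
  ea <- branch_set(set_a); eb <- branch_set(set_b)
  uniq <- union(setdiff(ea, eb), setdiff(eb, ea))
  sum(tree$edge.length[uniq]) / sum(tree$edge.length[union(ea, eb)])
}

# exhaustive Spearman permutation null: all orderings of y
brute_spearman_null <- function(x, y) {
  perms <- gtools_permutations(length(y))
  apply(perms, 1, function(p) cor(rank(x), rank(y[p])))
}

# all permutations of 1..n (small n), plain recursion
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

# brute-force all-pairs shortest path lengths for an undirected graph
# given as an edge list over 1..n (Inf where unreachable)
brute_shortest_paths <- function(n, edges) {
  d <- matrix(Inf, n, n); diag(d) <- 0
  if (nrow(edges)) for (i in seq_len(nrow(edges))) {
    d[edges[i, 1], edges[i, 2]] <- 1
    d[edges[i, 2], edges[i, 1]] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# small deterministic count table (samples x OTUs)
toy_table <- function() {
  m <- matrix(c(10, 0, 5, 3,
                2, 8, 0, 6,
                7, 1, 9, 0,
                4, 4, 4, 4,
                0, 6, 2, 9), nrow = 5, byrow = TRUE)
  otu_table(m, sample_ids = paste0("S", 1:5),
            otu_ids = c("A", "B", "C", "D"))
}

# minimal valid metadata record(s)
toy_metadata <- function(n = 1) {
  data.frame(
    sample_id = paste0("S", seq_len(n)), site_id = "SITE01",
    elevation = 1000, pH = 7.8, EC = 1.2, SOC = 0.5,
    AvgSoilRH = seq(10, 70, length.out = n),
    HighSoilRH = pmin(100, seq(10, 70, length.out = n) + 10),
    LowSoilRH = pmax(0, seq(10, 70, length.out = n) - 10),
    PercSoilRH100 = 5, AvgSoilT = 15, HighSoilT = 25, LowSoilT = 5,
    vegetation_cover = 0, shallow_nitrate = 2, shallow_sulfate = 50,
    salar_override = FALSE, stringsAsFactors = FALSE)
}
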