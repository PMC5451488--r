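# aridnet

Soil microbiomes along aridity gradients lose taxa and — more subtly —
lose *connectivity*: in extremely dry soils, co-occurrence networks of
bacteria and archaea break down from one cohesive web into weakly
bridged islands. `aridnet` is an R package for quantifying both
effects from standard amplicon-survey inputs: an OTU count table
(samples × OTUs), a rooted phylogeny, a taxonomy table, and per-sample
soil-climate metadata whose key variable is average soil relative
humidity (AvgSoilRH). It is aimed at microbial ecologists analysing
desert or drought-gradient soil surveys.

## What it computes

- **Aridity classes.** Samples are classified as *hyperarid* (shallow
  nitrate > 20 or sulfate > 500 µmol g⁻¹ dry soil, no vegetation),
  *arid* (vegetation present) or *margin* (neither), with an explicit
  override for salt accumulations of hydrologic origin.
- **Alpha diversity.** Faith's phylogenetic diversity
  PD = Σ branch lengths of the minimal rooted subtree spanning a
  sample's taxa, Shannon H = −Σ pᵢ log₂ pᵢ, Simpson 1 − Σ pᵢ², and
  rarefaction by subsampling without replacement; Spearman rank
  correlations (r_s) of each metric against each soil variable with
  Benjamini–Hochberg q-values.
- **Beta diversity.** Unweighted and normalized weighted UniFrac,
  principal-coordinate analysis, Mantel and ANOSIM permutation tests
  (one-sided, exact by enumeration for small n), and an exhaustive
  BEST/BioEnv search ranking every subset of environmental variables
  by how well its scaled Euclidean distances rank-correlate with
  community dissimilarity.
- **Co-occurrence networks.** All-pairs Spearman correlations of OTU
  relative abundances; edges retained only when the BH-adjusted
  p-value is ≤ 0.01, |r_s| exceeds a correlation cutoff (reference
  default 0.81, from random-matrix-theory thresholding of the original
  field data; a data-driven RMT scan is available), and network
  deconvolution — eigenvalue shrinkage λ → λ/(1+λ) separating direct
  from transitive dependencies — assigns the pair a positive direct
  weight. Per-sample induced-subgraph statistics (size, degree,
  betweenness, edge count, average path length over reachable pairs,
  Freeman betweenness centralization) are summarized as medians per
  aridity class.
- **Richness-matched null.** To test whether hyperarid connectivity
  loss is just a richness artifact, arid and margin samples are
  repeatedly rarefied to a depth at which their richness matches the
  hyperarid level, networks are rebuilt each time, and the modified
  class medians are compared against the unmodified hyperarid row.
- **Taxon gradients.** Counts collapsed to any rank, per-taxon r_s
  against AvgSoilRH with flags for strong gradients (|r_s| > 0.6,
  q < 0.02), a row-normalized heat-map matrix, and a report on
  nitrogen-cycling guild genera.
- **Synthetic gradient generator.** `simulate_dataset()` builds
  aridity-gradient communities with planted co-occurrence blocks and
  full ground truth, so every stage above is testable without field
  data.

## Worked example

```r
library(aridnet)

ds  <- simulate_dataset(gradient_design(seed = 1))
ds$table
#> OTU table: 48 samples x 1500 OTUs, 2,058,887 total reads

rs <- spearman(observed_otus(ds$table), ds$metadata$AvgSoilRH)
sprintf("rs(observed OTUs, AvgSoilRH) = %.2f (p = %.2g)", rs$rs, rs$p)
#> "rs(observed OTUs, AvgSoilRH) = 0.87 (p = 8.4e-16)"

net <- build_cooccurrence(ds$table, ds$metadata)
net
#> co-occurrence network: 278 nodes, 1272 edges (|rs| >= 0.81, q <= 0.01, 100.0% positive)

ep <- edge_precision(net, ds$truth)
sprintf("planted-edge precision = %.1f%% over %d edges",
        100 * ep$precision, ep$n_edges)
#> "planted-edge precision = 93.0% over 1272 edges"

stats <- sample_level_stats(net, net$table)
cls   <- setNames(ds$metadata$aridity_class, ds$metadata$sample_id)
class_summary(stats, cls)
#>       class n_samples  size degree betweenness edge_count avg_path_length
#> 1 hyperarid        12  41.5   2.92        8.55         66            2.34
#> 2    margin        15  97.0   3.94       10.52        205            2.29
#> 3      arid        21 166.0   9.83       31.35        779            2.60
#>   betweenness_centralization
#> 1                     0.0352
#> 2                     0.0188
#> 3                     0.0473
```

Reading the output: richness tracks soil humidity strongly
(r_s = 0.87); the network's edges are overwhelmingly positive
co-occurrences and 93% of them join members of the same planted guild;
and the per-class medians reproduce the field pattern of shrinking,
sparser networks toward hyperaridity (size 166 → 41.5, edge count
779 → 66), with the size-normalized island signature (higher
centralization in the hyperarid class) emerging clearly in the pooled
replicate analysis described in the methods vignette.

A single-config run of every stage, writing plain-text artifacts plus
a checksum manifest:

```r
run_pipeline(pipeline_config(out_dir = "out", seed = 1))
```

or from a shell, `Rscript inst/cli/aridnet.R all --seed 1 --out-dir out`.

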