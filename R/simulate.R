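#' @name synthetic_community
#' @title Synthetic aridity-gradient community generator
#' @description Generates datasets with the statistical structure the
#'   downstream analysis assumes: a monotone soil-relative-humidity (RH)
#'   gradient across sites with triplicate pits, declining richness
#'   toward the dry end, planted co-occurrence blocks (groups of OTUs
#'   sharing a latent log-normal factor) whose correlation strength
#'   tracks their RH niche, phylum-level monotone abundance responses,
#'   and a rooted phylogeny in which phyla form clades.  Ground truth
#'   (block membership, niches, phylum effects) is returned alongside
#'   the data so recovery can be measured.
NULL

# phylum model: relative OTU share and signed monotone RH response
SYNTH_PHYLA <- data.frame(
  phylum = c("Actinobacteria", "Proteobacteria", "Chloroflexi",
             "Acidobacteria", "Gemmatimonadetes", "Planctomycetes",
             "Verrucomicrobia", "Bacteroidetes", "Firmicutes",
             "Cyanobacteria", "Nitrospirae", "Crenarchaeota",
             "Euryarchaeota"),
  domain = c(rep("Bacteria", 11), "Archaea", "Archaea"),
  weight = c(0.30, 0.15, 0.08, 0.08, 0.06, 0.06,
             0.05, 0.05, 0.05, 0.04, 0.03, 0.03, 0.02),
  effect = c(-1, 1, 0, 1, 0, 1, 1, 0, 0, 0, 1, 1, 1),
  stringsAsFactors = FALSE)

# genus labels planted inside suitable phyla so the nitrogen-guild report
# has material to find; nitrifier genera Nitrobacter/Nitrosomonas/
# Nitrosospira are deliberately never assigned (the "not detected" case)
SYNTH_GENERA <- data.frame(
  genus = c("Bradyrhizobium", "Mesorhizobium", "Rhizobium",
            "Sinorhizobium", "Azospirillum", "Nitrospira",
            "Nitrososphaera", "Frankia"),
  phylum = c("Proteobacteria", "Proteobacteria", "Proteobacteria",
             "Proteobacteria", "Proteobacteria", "Nitrospirae",
             "Crenarchaeota", "Actinobacteria"),
  n_otus = c(3L, 2L, 1L, 1L, 1L, 2L, 3L, 2L),
  stringsAsFactors = FALSE)

#' Gradient simulation design
#'
#' Collects and validates every knob of the generator.
#'
#' @param n_sites number of sites along the gradient (>= 3 so all three
#'   aridity classes are populated; default 16).
#' @param pits_per_site soil pits (replicate samples) per site
#'   (default 3).
#' @param rh_range low/high AvgSoilRH across sites, percent, strictly
#'   inside [0, 100] (default c(2, 78)).
#' @param n_otus number of OTUs (default 1500).
#' @param n_blocks number of planted co-occurrence blocks (default 12).
#' @param block_size_range OTUs per block, graded from the driest to the
#'   wettest block niche (default c(14, 40); blocks are disjoint), so
#'   wet-end guilds are larger.
#' @param block_rh_niches per-block RH optimum; the default places
#'   blocks with density increasing toward the wet end, so block
#'   activity tracks RH.
#' @param block_rho design expectation for within-block rank correlation
#'   at full factor strength (default 0.85).
#' @param density_range multiplier range of block factor strength from
#'   the driest to the wettest block niche (default c(0.6, 1)); makes
#'   planted connectivity increase with RH.
#' @param block_bandwidth_range within-block correlation bandwidth,
#'   graded from the driest to the wettest block niche (default
#'   c(1.6, 4.2)).  Members of a block are ordered along a latent guild
#'   axis and correlate with neighbours within roughly this many
#'   positions, so dry-end blocks form stringy chains (the island
#'   topology) while wet-end blocks are densely connected.
#' @param member_detect detection probability range for members of an
#'   active block, graded from the driest to the wettest block niche
#'   (default c(0.6, 0.95)); independent across members, so dry-end
#'   blocks have thinner co-presence and hence weaker recoverable
#'   connectivity.
#' @param block_act_floor activation probability of a block in samples
#'   wetter than its niche (default 0.35): dry-adapted guilds persist
#'   at reduced rates in moister soils, so block absence patterns alone
#'   cannot dominate member correlations, while blocks never extend to
#'   soils drier than their niche.
#' @param member_abund_meanlog log-normal mean of block-member baseline
#'   abundances (default 1.5; sd fixed at 1), keeping guild members
#'   abundant enough to be measurable after deep rarefaction.
#' @param niche_sd base Gaussian kernel width (percent RH) for
#'   background OTUs (default 18; the dry-tolerant generalist phylum
#'   uses 1.4x of it).
#' @param block_niche_sd kernel width for block members (default 10).
#' @param otu_noise_sd log-normal sd of per-OTU per-sample idiosyncratic
#'   noise for background OTUs (default 1.3).
#' @param abundance_sdlog log-normal sd of per-OTU baseline abundances
#'   (default 2, a long-tailed community).
#' @param occupancy_max upper bound of the abundance-occupancy floor:
#'   the most abundant background OTUs keep at least this fraction of
#'   their peak expected abundance everywhere (default 0.25), making
#'   them prevalent generalists, while rare OTUs remain narrow
#'   specialists.
#' @param bg_occupancy_range multiplier range of background occupancy
#'   probability from the dry to the wet end of the gradient (default
#'   c(0.6, 1)), thinning detectable background richness toward
#'   aridity.
#' @param depth_meanlog,depth_sdlog log-normal sequencing-depth
#'   parameters (defaults log(40000) and 0.25).
#' @param env_noise_sd within-site environmental noise sd, percent RH
#'   (default 1.5).
#' @param veg_rh_cutoff AvgSoilRH above which vegetation is present
#'   (default 45).
#' @param salt_rh_cutoff AvgSoilRH below which shallow salts accumulate
#'   (default 20).
#' @param seed integer RNG seed (default 1).
#' @return validated list of class \code{gradient_design}.
#' @export
gradient_design <- function(n_sites = 16, pits_per_site = 3,
                            rh_range = c(2, 78), n_otus = 1500,
                            n_blocks = 12, block_size_range = c(14, 40),
                            block_rh_niches = NULL, block_rho = 0.95,
                            density_range = c(0.65, 1),
                            block_bandwidth_range = c(1.6, 4.2),
                            member_detect = c(0.85, 0.95),
                            block_act_floor = 0.35,
                            member_abund_meanlog = 1.5,
                            niche_sd = 18, block_niche_sd = 10,
                            otu_noise_sd = 1.3, abundance_sdlog = 2,
                            occupancy_max = 0.35,
                            bg_occupancy_range = c(0.6, 1),
                            depth_meanlog = log(40000),
                            depth_sdlog = 0.25,
                            env_noise_sd = 1.5,
                            veg_rh_cutoff = 45, salt_rh_cutoff = 20,
                            seed = 1) {
  d <- list(n_sites = as.integer(n_sites),
            pits_per_site = as.integer(pits_per_site),
            rh_range = as.numeric(rh_range), n_otus = as.integer(n_otus),
            n_blocks = as.integer(n_blocks),
            block_size_range = as.integer(round(block_size_range)),
            block_rh_niches = block_rh_niches, block_rho = block_rho,
            density_range = as.numeric(density_range),
            block_bandwidth_range = as.numeric(block_bandwidth_range),
            member_detect = as.numeric(member_detect),
            block_act_floor = block_act_floor,
            member_abund_meanlog = member_abund_meanlog,
            niche_sd = niche_sd, block_niche_sd = block_niche_sd,
            otu_noise_sd = otu_noise_sd,
            abundance_sdlog = abundance_sdlog,
            occupancy_max = occupancy_max,
            bg_occupancy_range = as.numeric(bg_occupancy_range),
            depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
            env_noise_sd = env_noise_sd,
            veg_rh_cutoff = veg_rh_cutoff,
            salt_rh_cutoff = salt_rh_cutoff,
            seed = as.integer(seed))
  if (d$n_sites < 3) stop("invalid design: n_sites must be >= 3")
  if (d$pits_per_site < 1) stop("invalid design: pits_per_site must be >= 1")
  if (length(d$rh_range) != 2 || d$rh_range[1] >= d$rh_range[2] ||
      d$rh_range[1] <= 0 || d$rh_range[2] >= 100)
    stop("invalid design: rh_range must be strictly inside (0, 100)")
  if (d$n_otus < 2) stop("invalid design: n_otus must be >= 2")
  if (d$n_blocks < 0) stop("invalid design: n_blocks must be >= 0")
  if (is.null(d$block_rh_niches) && d$n_blocks > 0) {
    # density of block niches increases toward the wet end, while the
    # driest blocks still sit inside the hyperarid RH range
    q <- (seq_len(d$n_blocks) / (d$n_blocks + 1))^0.7
    d$block_rh_niches <- d$rh_range[1] + diff(d$rh_range) * q
  }
  if (d$n_blocks > 0) {
    if (length(d$block_rh_niches) != d$n_blocks)
      stop("invalid design: block_rh_niches must have one value per block")
    if (any(d$block_rh_niches < d$rh_range[1] |
            d$block_rh_niches > d$rh_range[2]))
      stop("invalid design: block_rh_niches outside rh_range")
    if (length(d$block_size_range) == 1)
      d$block_size_range <- rep(d$block_size_range, 2)
    rel <- (d$block_rh_niches - d$rh_range[1]) / diff(d$rh_range)
    d$block_sizes <- as.integer(round(d$block_size_range[1] +
                                        diff(d$block_size_range) * rel))
    if (any(d$block_sizes < 2))
      stop("invalid design: block_size_range gives blocks of < 2 OTUs")
    if (sum(d$block_sizes) > d$n_otus)
      stop("invalid design: planted blocks need ", sum(d$block_sizes),
           " OTUs but n_otus is ", d$n_otus,
           " (blocks must be disjoint)")
  }
  if (d$block_rho <= 0 || d$block_rho >= 1)
    stop("invalid design: block_rho must lie in (0, 1)")
  if (length(d$member_detect) == 1)
    d$member_detect <- rep(d$member_detect, 2)
  if (any(d$member_detect <= 0 | d$member_detect > 1))
    stop("invalid design: member_detect must lie in (0, 1]")
  if (d$env_noise_sd < 0) stop("invalid design: env_noise_sd must be >= 0")
  class(d) <- "gradient_design"
  d
}

#' Simulate per-sample environmental metadata
#'
#' Site-mean AvgSoilRH is linear across the site index (plus within-site
#' noise); elevation rises along the gradient while temperature falls;
#' vegetation is present only above an RH cutoff and shallow salts
#' (nitrate/sulfate) accumulate only below one — mirroring the field
#' pattern the aridity classification keys on.
#'
#' @param design a \code{\link{gradient_design}}.
#' @return metadata data.frame, one row per pit, with the derived
#'   \code{aridity_class} attached.
#' @export
simulate_environment <- function(design) {
  stopifnot(inherits(design, "gradient_design"))
  set.seed(design$seed + 1L)
  ns <- design$n_sites; np <- design$pits_per_site
  site_idx <- rep(seq_len(ns), each = np)
  site_frac <- (site_idx - 1) / (ns - 1)
  site_rh <- design$rh_range[1] + diff(design$rh_range) * site_frac
  nz <- function(sd) rnorm(ns * np, 0, sd)
  s <- design$env_noise_sd
  rh <- pmin(99, pmax(0.5, site_rh + nz(s)))
  elevation <- 900 + 3300 * site_frac + nz(20 * s)
  avg_t <- 26 - 18 * (elevation - 900) / 3300 + nz(0.3 * s)
  veg <- ifelse(site_rh > design$veg_rh_cutoff,
                1.5 * (site_rh - design$veg_rh_cutoff), 0)
  salty <- site_rh < design$salt_rh_cutoff
  meta <- data.frame(
    sample_id = sprintf("SITE%02d.P%d", site_idx, rep(seq_len(np), ns)),
    site_id = sprintf("SITE%02d", site_idx),
    elevation = elevation,
    pH = 7.9 + nz(0.15 * s),
    EC = pmax(0.05, 8 * exp(-rh / 12) + 0.2 + nz(0.05 * s)),
    SOC = pmax(0.1, 0.17 + 16 * (rh / 100)^2 + nz(0.2 * s)),
    AvgSoilRH = rh,
    HighSoilRH = pmin(100, rh * 1.15 + 8),
    LowSoilRH = pmax(0, rh * 0.6 - 0.5),
    PercSoilRH100 = pmax(0, rh - 30) * 0.6,
    AvgSoilT = avg_t,
    HighSoilT = avg_t + 9,
    LowSoilT = avg_t - 9,
    vegetation_cover = veg,
    shallow_nitrate = ifelse(salty, 35, 2) + pmax(0, nz(0.5 * s)),
    shallow_sulfate = ifelse(salty, 800, 50) + pmax(0, nz(10 * s)),
    salar_override = FALSE,
    stringsAsFactors = FALSE)
  meta$aridity_class <- classify_aridity(meta)
  meta
}

# deterministic OTU bookkeeping shared by tree, taxonomy and counts:
# phylum labels, genus labels, block membership and RH niches
otu_assignment <- function(design) {
  set.seed(design$seed + 2L)
  n <- design$n_otus
  otu_ids <- sprintf("OTU%04d", seq_len(n))
  phylum <- sample(SYNTH_PHYLA$phylum, n, replace = TRUE,
                   prob = SYNTH_PHYLA$weight)
  effect <- SYNTH_PHYLA$effect[match(phylum, SYNTH_PHYLA$phylum)]
  lo <- design$rh_range[1]; hi <- design$rh_range[2]
  u <- runif(n)
  # positive responders crowd the wet end (density ~ u^0.3 transform);
  # the negative responder (Actinobacteria-like) is a generalist whose
  # relative share rises toward the dry end as everything else drops out;
  # neutral phyla are uniform
  niche <- ifelse(effect > 0, lo + (hi - lo) * u^0.3, lo + (hi - lo) * u)
  block <- rep(NA_integer_, n)
  block_pos <- rep(NA_real_, n)
  if (design$n_blocks > 0) {
    sizes <- design$block_sizes
    members <- sample.int(n, sum(sizes))
    block[members] <- rep(seq_len(design$n_blocks), times = sizes)
    block_pos[members] <- unlist(lapply(sizes, seq_len))
    niche[members] <- design$block_rh_niches[block[members]]
  }
  # kernel widths: the negative (dry-tolerant) phylum is the broadest
  # generalist; everything else shares the base width; block members use
  # the block width
  kernel_sd <- ifelse(effect < 0, 1.4, 1) * design$niche_sd
  kernel_sd[!is.na(block)] <- design$block_niche_sd
  genus <- rep("", n)
  for (k in seq_len(nrow(SYNTH_GENERA))) {
    pool <- which(phylum == SYNTH_GENERA$phylum[k] & genus == "" &
                  is.na(block))
    take <- head(pool, SYNTH_GENERA$n_otus[k])
    genus[take] <- SYNTH_GENERA$genus[k]
  }
  list(otu_ids = otu_ids, phylum = phylum, effect = effect,
       niche = niche, kernel_sd = kernel_sd, block = block,
       block_pos = block_pos, genus = genus)
}

# random binary subtree over a set of leaf ids, as a newick fragment
rand_clade <- function(ids, depth_scale) {
  if (length(ids) == 1)
    return(sprintf("%s:%.6f", ids, runif(1, 0.02, 0.12) * depth_scale))
  split <- rbinom(length(ids), 1, 0.5)
  if (all(split == 1) || all(split == 0))
    split[sample.int(length(ids), 1)] <- 1 - split[1]
  left <- rand_clade(ids[split == 1], depth_scale)
  right <- rand_clade(ids[split == 0], depth_scale)
  sprintf("(%s,%s):%.6f", left, right, runif(1, 0.02, 0.12) * depth_scale)
}

#' Simulate the phylogeny
#'
#' A rooted, strictly binary tree with one leaf per OTU and positive
#' branch lengths; leaves of the same phylum form clades.
#'
#' @param design a \code{\link{gradient_design}} with \code{n_otus >= 2}.
#' @return an \code{ape::phylo}.
#' @export
simulate_tree <- function(design) {
  stopifnot(inherits(design, "gradient_design"))
  if (design$n_otus < 2) stop("n_otus must be >= 2")
  asg <- otu_assignment(design)
  set.seed(design$seed + 3L)
  groups <- split(asg$otu_ids, asg$phylum)
  clades <- vapply(groups, rand_clade, character(1), depth_scale = 1)
  # join the phylum clades pairwise into a binary backbone
  while (length(clades) > 1) {
    merged <- sprintf("(%s,%s):%.6f", clades[1], clades[2],
                      runif(1, 0.05, 0.2))
    clades <- c(merged, clades[-(1:2)])
  }
  txt <- sub(":[0-9.]+$", "", clades[[1]])  # no branch above the root
  tree <- ape::read.tree(text = paste0(txt, ";"))
  tree
}

#' Simulate the OTU count table
#'
#' Each OTU's expected relative abundance in a sample is a Gaussian
#' kernel of the distance between the sample's AvgSoilRH and the OTU's
#' RH niche, times a per-OTU baseline, a per-sample block latent factor
#' (shared by all members of a planted block, with strength increasing
#' with the block's RH niche) and idiosyncratic log-normal noise.
#' Counts are multinomial draws at a log-normal sequencing depth.
#'
#' @param design a \code{\link{gradient_design}}.
#' @param metadata data.frame from \code{\link{simulate_environment}}.
#' @return list with \code{table} (an \code{\link{otu_table}}) and
#'   \code{truth} (ground truth: block membership, niches, phylum
#'   effects, per-sample latent gradient).
#' @export
simulate_counts <- function(design, metadata) {
  stopifnot(inherits(design, "gradient_design"))
  if (!is.data.frame(metadata) || !"AvgSoilRH" %in% names(metadata))
    stop("metadata must come from simulate_environment()")
  if (nrow(metadata) != design$n_sites * design$pits_per_site)
    stop("metadata rows do not match the design's site x pit layout")
  asg <- otu_assignment(design)
  set.seed(design$seed + 4L)
  n_otu <- design$n_otus
  n_smp <- nrow(metadata)
  rh <- metadata$AvgSoilRH
  kw <- asg$kernel_sd
  member <- !is.na(asg$block)
  base <- rlnorm(n_otu, 0, design$abundance_sdlog)
  # block members are moderately abundant guild organisms
  base[member] <- rlnorm(sum(member), design$member_abund_meanlog, 1)
  # abundance-occupancy relationship: abundant background OTUs are
  # prevalent generalists (a floor keeps them detectable everywhere),
  # rare ones are narrow specialists that drive the richness gradient
  prank <- rank(base) / n_otu
  floor_c <- design$occupancy_max * prank^3
  floor_c[member] <- 0
  kern <- exp(-outer(asg$niche, rh, "-")^2 / (2 * kw^2))
  loge <- log(base * (floor_c + (1 - floor_c) * kern))

  # occupancy is patchy at the pit (sample) level: every background OTU
  # draws its own presence pattern with probability set by its niche
  # kernel, so same-niche OTUs are not forced into aligned absence
  # patterns; a planted block draws ONE pattern that all of its members
  # share, so more blocks are active in wetter samples and block
  # co-occurrence stands out against the patchy background
  # a smooth occupancy gradient thins background presence toward the dry
  # end on top of each OTU's niche kernel, emulating the field's decline
  # in detectable richness with aridity
  m_rh <- design$bg_occupancy_range[1] +
    diff(design$bg_occupancy_range) *
    (rh - design$rh_range[1]) / diff(design$rh_range)
  p_occ <- sqrt(sweep(kern, 1, floor_c, function(k, f) f + (1 - f) * k)) *
    rep(pmin(1, pmax(0.05, m_rh)), each = n_otu)
  occ <- matrix(rbinom(length(p_occ), 1, p_occ), nrow(p_occ))
  # relative position of each block niche along the gradient, reused by
  # activation, detection and factor strength
  rel <- if (design$n_blocks > 0)
    (design$block_rh_niches - design$rh_range[1]) / diff(design$rh_range)
  if (design$n_blocks > 0) {
    # activation is asymmetric in RH: a block is reliably active near
    # its niche, persists at a reduced rate in soils wetter than its
    # niche (water is the limiting factor, not its absence), and
    # vanishes toward the dry side
    p_act <- exp(-outer(design$block_rh_niches, rh, "-")^2 /
                   (2 * design$block_niche_sd^2))^0.5
    wet_side <- outer(design$block_rh_niches, rh, function(nb, r) r > nb)
    p_act[wet_side] <- pmax(p_act[wet_side], design$block_act_floor)
    act <- matrix(rbinom(length(p_act), 1, p_act), nrow(p_act))
    # members of an active block are each detected independently, so a
    # block's absence pattern alone cannot make its members correlate;
    # detectability rises with the block's RH niche (dry-end stress
    # thins co-presence), which is what grades connectivity by aridity
    p_det <- design$member_detect[1] +
      diff(design$member_detect) * rel[asg$block[member]]
    occ[member, ] <- act[asg$block[member], , drop = FALSE] *
      matrix(rbinom(sum(member) * n_smp, 1, rep(p_det, n_smp)),
             sum(member), n_smp)
    loge[member, ] <- log(base[member])  # abundance set by the factor
  }
  loge <- loge + log(occ)

  # banded within-block latent structure: members are ordered along a
  # latent guild axis and share sub-factors with neighbours within the
  # block's bandwidth.  Factor strength and bandwidth both rise with the
  # block's RH niche, so dry-end blocks resolve into stringy, weakly
  # connected chains (island topology) and wet-end blocks into dense,
  # cohesive modules
  if (design$n_blocks > 0) {
    strength <- design$density_range[1] +
      diff(design$density_range) * rel
    s_max <- 1.8
    s_b <- s_max * strength
    w_b <- design$block_bandwidth_range[1] +
      diff(design$block_bandwidth_range) * rel
    # member noise chosen so near-neighbour pairs of the strongest
    # blocks reach the design correlation floor:
    # rho = s^2 / (s^2 + sigma^2)
    sigma_m <- s_max * sqrt(1 / design$block_rho - 1)
    for (b in seq_len(design$n_blocks)) {
      idx <- which(asg$block == b)
      k <- length(idx)
      if (k == 0) next
      zeta <- matrix(rnorm(k * n_smp), k, n_smp)
      wts <- exp(-outer(asg$block_pos[idx], seq_len(k), "-")^2 /
                   (2 * w_b[b]^2))
      wts <- wts / sqrt(rowSums(wts^2))
      loge[idx, ] <- loge[idx, ] + s_b[b] * (wts %*% zeta)
    }
    noise_sd <- ifelse(member, sigma_m, design$otu_noise_sd)
  } else {
    noise_sd <- rep(design$otu_noise_sd, n_otu)
  }
  loge <- loge + matrix(rnorm(n_otu * n_smp), n_otu, n_smp) * noise_sd
  e <- exp(loge)
  p <- sweep(e, 2, colSums(e), "/")
  depth <- pmax(1, round(rlnorm(n_smp, design$depth_meanlog,
                                design$depth_sdlog)))
  counts <- vapply(seq_len(n_smp), function(j)
    rmultinom(1, depth[j], p[, j])[, 1], integer(n_otu))
  table <- otu_table(t(counts), sample_ids = metadata$sample_id,
                     otu_ids = asg$otu_ids)
  truth <- list(
    block_membership = setNames(asg$block, asg$otu_ids),
    otu_rh_niche = setNames(asg$niche, asg$otu_ids),
    phylum = setNames(asg$phylum, asg$otu_ids),
    phylum_effect = setNames(SYNTH_PHYLA$effect, SYNTH_PHYLA$phylum),
    block_rh_niches = design$block_rh_niches,
    sample_gradient = setNames(rh, metadata$sample_id))
  list(table = table, truth = truth)
}

#' Simulate the taxonomy table
#'
#' @param design a \code{\link{gradient_design}}.
#' @return taxonomy data.frame (otu_id plus the six ranks; class, order
#'   and family are empty placeholders).
#' @export
simulate_taxonomy <- function(design) {
  asg <- otu_assignment(design)
  data.frame(otu_id = asg$otu_ids,
             domain = SYNTH_PHYLA$domain[match(asg$phylum,
                                               SYNTH_PHYLA$phylum)],
             phylum = asg$phylum,
             class = "", order = "", family = "",
             genus = asg$genus,
             stringsAsFactors = FALSE)
}

#' Compact gradient design for fast validation runs
#'
#' A reduced version of the default study design (10 sites x 3 pits =
#' 30 samples, 150 OTUs, 9 planted blocks with niches centred inside
#' the three aridity classes) used to exercise the class-level network
#' topology comparison and the richness-matched null at desk scale.
#' Background occupancy is flatter than in the full design so that the
#' hyperarid richness level corresponds to a workable richness-matching
#' depth; the planted block structure keeps the full design's graded
#' bandwidth, activation and detection.
#'
#' @param seed integer RNG seed.
#' @return a \code{\link{gradient_design}}.
#' @export
compact_gradient_design <- function(seed = 1) {
  gradient_design(
    n_sites = 10, pits_per_site = 3, n_otus = 150, n_blocks = 9,
    block_size_range = c(17, 14), block_niche_sd = 8,
    block_rh_niches = c(8, 16, 26, 33, 40, 52, 60, 68, 75),
    block_bandwidth_range = c(1.3, 3.8), member_abund_meanlog = 2,
    bg_occupancy_range = c(0.95, 1), occupancy_max = 0.6,
    niche_sd = 32, density_range = c(0.85, 1), block_rho = 0.93,
    seed = seed)
}

#' Simulate a complete dataset
#'
#' Runs \code{\link{simulate_environment}}, \code{\link{simulate_tree}},
#' \code{\link{simulate_counts}} and \code{\link{simulate_taxonomy}} with
#' one design, so that every output is a pure function of
#' (design, seed).
#'
#' @param design a \code{\link{gradient_design}} (default the standard
#'   design).
#' @return list with \code{table}, \code{metadata}, \code{taxonomy},
#'   \code{tree}, \code{truth}.
#' @export
simulate_dataset <- function(design = gradient_design()) {
  metadata <- simulate_environment(design)
  tree <- simulate_tree(design)
  cnt <- simulate_counts(design, metadata)
  list(table = cnt$table, metadata = metadata,
       taxonomy = simulate_taxonomy(design), tree = tree,
       truth = cnt$truth)
}

#' Precision of network edges against planted blocks
#'
#' Fraction of a network's edges joining two OTUs of the same planted
#' block — the generator's parameter-recovery metric.
#'
#' @param net a \code{cooccurrence_network}.
#' @param truth ground truth from \code{\link{simulate_counts}}.
#' @return list with \code{precision}, \code{n_edges},
#'   \code{n_within_block}.
#' @export
edge_precision <- function(net, truth) {
  bm <- truth$block_membership
  a <- bm[net$edges$otu_a]
  b <- bm[net$edges$otu_b]
  within <- !is.na(a) & !is.na(b) & a == b
  list(precision = if (nrow(net$edges)) mean(within) else NA_real_,
       n_edges = nrow(net$edges),
       n_within_block = sum(within))
}
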