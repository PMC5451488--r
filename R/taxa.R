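#' @name taxa_gradients
#' @title Taxon-level abundance gradients along soil relative humidity
#' @description Collapses OTU counts to a taxonomic rank, correlates each
#'   taxon's relative abundance with soil climate, builds the
#'   row-normalized gradient heat-map matrix, and reports the
#'   nitrogen-cycling guild genera.
NULL

# genera commonly associated with N2 fixation or nitrification; the
# default guild list used by nitrogen_guild_report (config-supplied lists
# override it)
NITROGEN_GUILD_GENERA <- c(
  "Bradyrhizobium", "Mesorhizobium", "Nitrososphaera", "Nitrospira",
  "Frankia", "Sinorhizobium", "Rhizobium", "Azospirillum",
  "Nitrobacter", "Nitrosomonas", "Nitrosospira")

#' Collapse an OTU table to a taxonomic rank
#'
#' Counts are summed per rank label (OTUs without an assignment pool into
#' \code{"Unassigned"}) and converted to per-sample fractions.
#'
#' @param table an \code{\link{otu_table}}.
#' @param taxonomy taxonomy data.frame (see \code{\link{read_taxonomy}}).
#' @param rank one of domain, phylum, class, order, family, genus.
#' @return matrix of relative abundances, samples x taxa (each row sums
#'   to 1).
#' @export
collapse_taxonomy <- function(table, taxonomy, rank = "phylum") {
  if (!rank %in% TAXONOMY_RANKS)
    stop("unknown rank: ", rank, " (use one of ",
         paste(TAXONOMY_RANKS, collapse = ", "), ")")
  labels <- taxonomy[[rank]][match(colnames(table), taxonomy$otu_id)]
  labels[is.na(labels) | labels == ""] <- "Unassigned"
  m <- unclass(table)
  agg <- t(rowsum(t(m), group = labels))
  sweep(agg, 1, rowSums(agg), "/")
}

#' Taxon-abundance correlations with an environmental variable
#'
#' Spearman correlation of each taxon's relative abundance against the
#' variable, with Benjamini-Hochberg q-values across the rank family.
#' Flags taxa passing the strong-gradient rule (|rs| above
#' \code{rs_flag}, q below \code{q_flag}).  Taxa absent everywhere are
#' excluded with a note.
#'
#' @param collapsed relative-abundance matrix from
#'   \code{\link{collapse_taxonomy}}.
#' @param meta metadata matched on sample ids.
#' @param variable environmental variable (default \code{AvgSoilRH}).
#' @param rs_flag,q_flag flagging cutoffs (defaults 0.6 and 0.02).
#' @return data.frame with taxon, rs, p, q, detected_samples, max_ra and
#'   \code{flagged}.
#' @export
taxon_env_correlation <- function(collapsed, meta, variable = "AvgSoilRH",
                                  rs_flag = 0.6, q_flag = 0.02) {
  if (nrow(collapsed) < 3) stop("need at least 3 samples")
  xv <- meta[[variable]][match(rownames(collapsed), meta$sample_id)]
  if (is.null(meta[[variable]])) stop("variable not in metadata: ", variable)
  absent <- colSums(collapsed) == 0
  if (any(absent))
    message("note: excluding ", sum(absent), " taxa absent everywhere")
  taxa <- colnames(collapsed)[!absent]
  rows <- lapply(taxa, function(tx) {
    ra <- collapsed[, tx]
    res <- tryCatch(spearman(ra, xv),
                    error = function(e) list(rs = NA_real_, p = NA_real_,
                                             n = length(ra)))
    data.frame(taxon = tx, rs = res$rs, p = res$p,
               detected_samples = sum(ra > 0), max_ra = max(ra),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out$flagged <- !is.na(out$rs) & abs(out$rs) > rs_flag &
    !is.na(out$q) & out$q < q_flag
  out[order(-out$rs), , drop = FALSE]
}

#' Gradient heat-map matrix
#'
#' Rows are the flagged taxa whose maximum per-sample relative abundance
#' exceeds \code{min_site_ra}, ordered by decreasing correlation
#' strength; columns are samples ordered by increasing AvgSoilRH; each
#' row is divided by its maximum so the row maximum is exactly 1.
#'
#' @param gradients data.frame from \code{\link{taxon_env_correlation}}.
#' @param collapsed relative-abundance matrix the gradients were
#'   computed from.
#' @param meta metadata with \code{AvgSoilRH}.
#' @param min_site_ra minimum maximum-site relative abundance for a row
#'   (default 0.001, i.e. 0.1\%).
#' @return matrix (taxa x samples) with attribute \code{row_rs}; empty
#'   with a warning when nothing passes.
#' @export
heatmap_matrix <- function(gradients, collapsed, meta,
                           min_site_ra = 0.001) {
  keep <- gradients$flagged & gradients$max_ra > min_site_ra
  if (!any(keep)) {
    warning("no taxon passes the heat-map filters")
    return(matrix(numeric(0), 0, nrow(collapsed)))
  }
  sel <- gradients[keep, , drop = FALSE]
  sel <- sel[order(-sel$rs), , drop = FALSE]
  rh <- meta$AvgSoilRH[match(rownames(collapsed), meta$sample_id)]
  ord <- order(rh)
  m <- t(collapsed[ord, sel$taxon, drop = FALSE])
  m <- m / apply(m, 1, max)
  attr(m, "row_rs") <- setNames(sel$rs, sel$taxon)
  m
}

#' Nitrogen-cycling guild report
#'
#' For each guild genus: the number of samples in which it was detected,
#' its relative-abundance range, and its Spearman correlation (with BH
#' q across the guild) against AvgSoilRH.  Genera never observed are
#' reported as not detected.
#'
#' @param table an \code{\link{otu_table}}.
#' @param taxonomy taxonomy data.frame.
#' @param meta metadata with \code{AvgSoilRH}.
#' @param guild_genera character vector of genera (default the built-in
#'   N-fixer/nitrifier list).
#' @return data.frame with genus, detected_samples, ra_min, ra_max,
#'   ra_range (formatted), rs, p, q, detected.
#' @export
nitrogen_guild_report <- function(table, taxonomy, meta,
                                  guild_genera = NITROGEN_GUILD_GENERA) {
  if (length(guild_genera) == 0) stop("empty guild list")
  genus_ra <- collapse_taxonomy(table, taxonomy, rank = "genus")
  rh <- meta$AvgSoilRH[match(rownames(genus_ra), meta$sample_id)]
  rows <- lapply(guild_genera, function(g) {
    if (!g %in% colnames(genus_ra)) {
      return(data.frame(genus = g, detected_samples = 0L,
                        ra_min = 0, ra_max = 0,
                        ra_range = "not detected",
                        rs = NA_real_, p = NA_real_,
                        detected = FALSE, stringsAsFactors = FALSE))
    }
    ra <- genus_ra[, g]
    res <- tryCatch(spearman(ra, rh),
                    error = function(e) list(rs = NA_real_, p = NA_real_))
    data.frame(
      genus = g, detected_samples = sum(ra > 0),
      ra_min = min(ra), ra_max = max(ra),
      ra_range = if (any(ra > 0))
        sprintf("%.2g%% to %.2g%% RA", 100 * min(ra), 100 * max(ra))
      else "not detected",
      rs = res$rs, p = res$p, detected = any(ra > 0),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- bh_fdr(out$p[ok])
  out
}
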