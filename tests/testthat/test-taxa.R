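toy_taxonomy <- function() {
  data.frame(otu_id = c("A", "B", "C", "D"),
             domain = "Bacteria",
             phylum = c("P1", "P1", "P2", ""),
             class = "", order = "", family = "",
             genus = c("G1", "", "G2", ""),
             stringsAsFactors = FALSE)
}

test_that("collapse_taxonomy conserves counts and normalizes rows", {
  tab <- toy_table()
  coll <- collapse_taxonomy(tab, toy_taxonomy(), "phylum")
  expect_true(all(abs(rowSums(coll) - 1) < 1e-12))
  # conservation: collapsed fractions times totals reproduce group sums
  m <- unclass(tab)
  expect_equal(coll[, "P1"] * rowSums(m), m[, "A"] + m[, "B"],
               ignore_attr = TRUE)
  expect_equal(colnames(coll)[order(colnames(coll))],
               c("P1", "P2", "Unassigned"))
  # single-phylum table: RA 1 everywhere
  tax1 <- toy_taxonomy(); tax1$phylum <- "P1"
  coll1 <- collapse_taxonomy(tab, tax1, "phylum")
  expect_true(all(coll1[, "P1"] == 1))
  # explicit two-phylum arithmetic
  tab2 <- otu_table(matrix(c(30L, 70L), 1, 2,
                           dimnames = list("s", c("A", "C"))))
  coll2 <- collapse_taxonomy(tab2, toy_taxonomy(), "phylum")
  expect_equal(unname(coll2[1, c("P1", "P2")]), c(0.3, 0.7))
  expect_error(collapse_taxonomy(tab, toy_taxonomy(), "species"),
               "unknown rank")
})

test_that("taxon_env_correlation flags strong monotone gradients", {
  ra <- matrix(c(seq(0.1, 0.6, length.out = 6),    # increasing with RH
                 seq(0.7, 0.2, length.out = 6),    # decreasing
                 rep(0, 6)), 6, 3,
               dimnames = list(paste0("s", 1:6), c("up", "down", "gone")))
  ra <- cbind(ra, filler = 1 - rowSums(ra))
  ra[, "filler"] <- ra[, "filler"] + c(0.01, -0.01, 0, 0.02, -0.02, 0)
  ra[, "up"] <- ra[, "up"] - c(0.01, -0.01, 0, 0.02, -0.02, 0)
  meta <- data.frame(sample_id = paste0("s", 1:6),
                     AvgSoilRH = seq(5, 70, length.out = 6))
  expect_message(res <- taxon_env_correlation(ra, meta), "absent")
  expect_false("gone" %in% res$taxon)
  expect_equal(res$rs[res$taxon == "up"], 1)
  expect_equal(res$rs[res$taxon == "down"], -1)
  expect_true(res$flagged[res$taxon == "up"])
  expect_true(all(res$q >= res$p - 1e-12))
  # rows are sorted by decreasing correlation
  expect_true(all(diff(res$rs) <= 1e-12))
})

test_that("the planted negative phylum comes out negative", {
  ds <- simulate_dataset(gradient_design(seed = 7))
  coll <- collapse_taxonomy(ds$table, ds$taxonomy, "phylum")
  res <- suppressMessages(taxon_env_correlation(coll, ds$metadata))
  expect_lt(res$rs[res$taxon == "Actinobacteria"], 0)
  # at least one positive responder is flagged as a strong gradient
  pos <- c("Proteobacteria", "Acidobacteria", "Planctomycetes",
           "Verrucomicrobia", "Nitrospirae")
  expect_true(any(res$flagged[res$taxon %in% pos]))
})

test_that("heatmap_matrix normalizes rows and orders by correlation", {
  ra <- matrix(c(seq(0.1, 0.5, length.out = 5),
                 seq(0.5, 0.3, length.out = 5),
                 rep(4e-4, 5)), 5, 3,
               dimnames = list(paste0("s", 1:5),
                               c("strong", "weak", "tiny")))
  ra <- cbind(ra, filler = 1 - rowSums(ra))
  meta <- data.frame(sample_id = paste0("s", 1:5),
                     AvgSoilRH = c(30, 10, 50, 20, 60))
  grads <- suppressMessages(taxon_env_correlation(ra, meta))
  grads$flagged[grads$taxon %in% c("strong", "weak", "tiny")] <- TRUE
  hm <- heatmap_matrix(grads, ra, meta)
  # the 0.04% taxon is excluded at the 0.1% default floor
  expect_false("tiny" %in% rownames(hm))
  expect_true(all(apply(hm, 1, max) == 1))
  # columns follow increasing AvgSoilRH
  expect_equal(colnames(hm),
               meta$sample_id[order(meta$AvgSoilRH)])
  # rows sorted by decreasing rs, independently recomputed
  rs_direct <- apply(ra[, rownames(hm), drop = FALSE], 2, function(v)
    cor(rank(v), rank(meta$AvgSoilRH)))
  expect_equal(rownames(hm),
               names(sort(rs_direct, decreasing = TRUE)))
  none <- grads; none$flagged <- FALSE
  expect_warning(hm0 <- heatmap_matrix(none, ra, meta), "no taxon")
  expect_equal(nrow(hm0), 0)
})

test_that("nitrogen_guild_report covers detected and undetected genera", {
  tab <- otu_table(matrix(as.integer(c(10, 20, 30, 40,
                                       90, 80, 70, 60)), 4, 2,
                          dimnames = list(paste0("s", 1:4),
                                          c("A", "B"))))
  tax <- data.frame(otu_id = c("A", "B"), domain = "Bacteria",
                    phylum = c("Proteobacteria", "Actinobacteria"),
                    class = "", order = "", family = "",
                    genus = c("Bradyrhizobium", ""),
                    stringsAsFactors = FALSE)
  meta <- data.frame(sample_id = paste0("s", 1:4),
                     AvgSoilRH = c(10, 25, 45, 70))
  rep <- nitrogen_guild_report(tab, tax, meta)
  brady <- rep[rep$genus == "Bradyrhizobium", ]
  expect_equal(brady$detected_samples, 4)
  expect_equal(brady$rs, 1)   # RA strictly increasing with RH
  # min/max oracle for the printed range
  ra <- unclass(tab)[, "A"] / rowSums(tab)
  expect_equal(brady$ra_min, min(ra))
  expect_equal(brady$ra_max, max(ra))
  expect_match(brady$ra_range, "% to .*% RA")
  # the never-assigned nitrifiers come back "not detected"
  nitro <- rep[rep$genus %in% c("Nitrobacter", "Nitrosomonas",
                                "Nitrosospira"), ]
  expect_true(all(!nitro$detected))
  expect_true(all(nitro$ra_range == "not detected"))
  expect_equal(nrow(rep), length(aridnet:::NITROGEN_GUILD_GENERA))
  expect_error(nitrogen_guild_report(tab, tax, meta,
                                     guild_genera = character(0)),
               "empty")
})
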