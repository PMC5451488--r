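#' @name pipeline_cli
#' @title End-to-end pipeline orchestration
#' @description One declarative config drives every stage: simulate (or
#'   load) a dataset, validate and classify it, then run the alpha, beta,
#'   network, richness-null and taxon-gradient stages, writing plain-text
#'   artifacts plus a manifest with checksums.  Identical config and seed
#'   give identical checksums.
NULL

#' Pipeline configuration
#'
#' @param input optional list of paths (\code{otu}, \code{metadata},
#'   \code{taxonomy}, \code{tree}); when NULL a synthetic dataset is
#'   simulated from \code{design}.
#' @param design \code{\link{gradient_design}} for simulation.
#' @param out_dir output directory.
#' @param seed master seed; stage seeds are derived from it.
#' @param retention_min_reads per-sample read retention threshold
#'   (default 16660).
#' @param beta_rarefy_depth rarefaction depth for UniFrac
#'   (default 17212).
#' @param rare_min_frac rare-OTU fraction cutoff (default 1e-4).
#' @param q_cutoff edge FDR cutoff (default 0.01).
#' @param null_depth,null_reps richness-null depth and replicates
#'   (defaults 300 and 500).
#' @param n_perm_mantel,n_perm_anosim permutation counts (defaults 9999
#'   and 999).
#' @param best_variables variables for the BEST search (default a
#'   10-variable climate set).
#' @param stages which stages to run (subset of alpha, beta, network,
#'   null, taxa).
#' @return validated config list.
#' @export
pipeline_config <- function(input = NULL, design = gradient_design(),
                            out_dir = "aridnet_out", seed = 1,
                            retention_min_reads = 16660,
                            beta_rarefy_depth = 17212,
                            rare_min_frac = 1e-4, q_cutoff = 0.01,
                            null_depth = 300, null_reps = 500,
                            n_perm_mantel = 9999, n_perm_anosim = 999,
                            best_variables = c("elevation", "EC",
                              "AvgSoilRH", "HighSoilRH", "LowSoilRH",
                              "PercSoilRH100", "AvgSoilT", "HighSoilT",
                              "LowSoilT", "pH"),
                            stages = c("alpha", "beta", "network",
                                       "null", "taxa")) {
  cfg <- as.list(environment())
  stopifnot(cfg$rare_min_frac >= 0, cfg$rare_min_frac < 1,
            cfg$q_cutoff > 0, cfg$q_cutoff <= 1,
            cfg$beta_rarefy_depth >= 1, cfg$null_depth >= 1,
            cfg$null_reps >= 1)
  cfg$stages <- match.arg(stages, c("alpha", "beta", "network", "null",
                                    "taxa"), several.ok = TRUE)
  cfg
}

#' Load a pipeline config from a YAML file
#'
#' Keys mirror the arguments of \code{\link{pipeline_config}}; a
#' \code{design:} block holds \code{\link{gradient_design}} arguments.
#'
#' @param path YAML file.
#' @param overrides named list applied on top of the file
#'   (\code{--set key=value} support).
#' @return config list.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  raw <- utils::modifyList(raw, overrides)
  if (!is.null(raw$design)) raw$design <- do.call(gradient_design, raw$design)
  do.call(pipeline_config, raw)
}

config_hash <- function(cfg) {
  flat <- cfg[setdiff(names(cfg), "out_dir")]
  txt <- jsonlite::toJSON(flat, auto_unbox = TRUE, force = TRUE,
                          digits = NA)
  # small stable fingerprint without extra dependencies
  sum(utf8ToInt(as.character(txt)) *
        (seq_len(nchar(as.character(txt))) %% 251 + 1)) %% 1e8
}

write_output <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# aridnet %s seed=%d config=%s",
                     as.character(utils::packageVersion("aridnet")),
                     cfg$seed, format(config_hash(cfg), scientific = FALSE)),
             con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_matrix_output <- function(m, path, cfg) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  write_output(df, path, cfg)
}

#' Run the full pipeline
#'
#' @param cfg config from \code{\link{pipeline_config}}.
#' @return (invisibly) the manifest: a list of outputs with md5
#'   checksums, also written to \code{manifest.json} in
#'   \code{cfg$out_dir}.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  stage <- "input"
  result <- tryCatch({
    if (is.null(cfg$input)) {
      design <- cfg$design
      design$seed <- as.integer(cfg$seed)
      ds <- simulate_dataset(design)
      files <- c(files, write_dataset(ds, cfg$out_dir))
    } else {
      ds <- load_dataset(cfg$input$otu, cfg$input$metadata,
                         cfg$input$taxonomy, cfg$input$tree,
                         min_reads = cfg$retention_min_reads)
    }
    stage <- "classify"
    ds$metadata$aridity_class <- classify_aridity(ds$metadata)
    cls <- setNames(ds$metadata$aridity_class, ds$metadata$sample_id)

    alpha <- NULL
    if ("alpha" %in% cfg$stages || "null" %in% cfg$stages) {
      stage <- "alpha"
      alpha <- alpha_table(ds$table, ds$tree)
      rep_a <- alpha_env_report(alpha, ds$metadata)
      files <- c(files, alpha = write_output(
        alpha, file.path(cfg$out_dir, "alpha.tsv"), cfg))
      files <- c(files, alpha_env = write_output(
        rep_a$correlations, file.path(cfg$out_dir, "alpha_env.tsv"), cfg))
    }

    if ("beta" %in% cfg$stages) {
      stage <- "beta"
      rt <- suppressWarnings(rarefy(ds$table, cfg$beta_rarefy_depth,
                                    seed = cfg$seed + 11L))
      du <- unifrac(rt, ds$tree, weighted = FALSE)
      dw <- unifrac(rt, ds$tree, weighted = TRUE)
      ord <- pcoa(du)
      meta_b <- ds$metadata[match(rownames(du), ds$metadata$sample_id), ]
      mrep <- env_mantel_report(du, dw, meta_b, cfg$best_variables,
                                n_perm = cfg$n_perm_mantel,
                                seed = cfg$seed + 12L)
      an <- anosim(du, meta_b$vegetation_cover > 0,
                   n_perm = cfg$n_perm_anosim, seed = cfg$seed + 13L)
      best <- best_bioenv(du, meta_b, cfg$best_variables)
      files <- c(files,
        unifrac_unweighted = write_matrix_output(
          du, file.path(cfg$out_dir, "unifrac_unweighted.tsv"), cfg),
        unifrac_weighted = write_matrix_output(
          dw, file.path(cfg$out_dir, "unifrac_weighted.tsv"), cfg),
        pcoa_coords = write_matrix_output(
          ord$coordinates, file.path(cfg$out_dir, "pcoa_coords.tsv"), cfg),
        mantel_report = write_output(
          mrep$correlations, file.path(cfg$out_dir, "mantel_report.tsv"),
          cfg),
        anosim = write_output(
          data.frame(grouping = "vegetation_present", R = an$R, p = an$p),
          file.path(cfg$out_dir, "anosim.tsv"), cfg),
        best = write_output(
          best, file.path(cfg$out_dir, "best.tsv"), cfg))
    }

    net <- NULL; class_nets <- list()
    if ("network" %in% cfg$stages || "null" %in% cfg$stages) {
      stage <- "network"
      net <- suppressMessages(build_cooccurrence(
        ds$table, ds$metadata, min_frac = cfg$rare_min_frac,
        q_cutoff = cfg$q_cutoff))
      stats <- suppressWarnings(sample_level_stats(net, net$table))
      summ <- class_summary(stats, cls)
      metr <- node_metric_env_correlation(net, stats, ds$metadata)
      for (cl in intersect(c("arid", "margin", "hyperarid"),
                           unique(cls))) {
        class_nets[[cl]] <- tryCatch(
          suppressMessages(class_subnetwork(
            ds$table, ds$metadata, cl, min_frac = cfg$rare_min_frac,
            q_cutoff = cfg$q_cutoff)),
          error = function(e) NULL)
      }
      thresholds <- c(global = net$threshold_used,
                      vapply(class_nets, function(x)
                        if (is.null(x)) NA_real_ else x$threshold_used,
                        numeric(1)))
      files <- c(files,
        edges = write_output(net$edges,
          file.path(cfg$out_dir, "edges.tsv"), cfg),
        nodes = write_output(net$nodes,
          file.path(cfg$out_dir, "nodes.tsv"), cfg),
        sample_stats = write_output(stats,
          file.path(cfg$out_dir, "sample_stats.tsv"), cfg),
        class_summary = write_output(summ,
          file.path(cfg$out_dir, "class_summary.tsv"), cfg),
        node_metric_env = write_output(metr,
          file.path(cfg$out_dir, "node_metric_env.tsv"), cfg))
      report <- list(seed = cfg$seed,
                     thresholds = as.list(thresholds),
                     threshold_chosen_by_rmt = net$threshold_chosen_by_rmt,
                     fraction_positive = net$fraction_positive,
                     n_nodes = nrow(net$nodes), n_edges = nrow(net$edges))
      jsonlite::write_json(report,
                           file.path(cfg$out_dir, "network_report.json"),
                           auto_unbox = TRUE, digits = NA)
      files <- c(files, network_report =
                   file.path(cfg$out_dir, "network_report.json"))
    }

    if ("null" %in% cfg$stages) {
      stage <- "null"
      nres <- run_richness_null(ds$table, ds$metadata,
                                threshold = net$threshold_used,
                                n_reps = cfg$null_reps,
                                depth = cfg$null_depth,
                                min_frac = cfg$rare_min_frac,
                                q_cutoff = cfg$q_cutoff,
                                seed = cfg$seed + 21L,
                                original_stats = stats)
      null_tab <- rbind(nres$class_medians, nres$original_hyperarid)
      files <- c(files, null_summary = write_output(
        null_tab, file.path(cfg$out_dir, "null_summary.tsv"), cfg))
    }

    if ("taxa" %in% cfg$stages) {
      stage <- "taxa"
      coll <- collapse_taxonomy(ds$table, ds$taxonomy, "phylum")
      grads <- suppressMessages(
        taxon_env_correlation(coll, ds$metadata))
      hm <- suppressWarnings(heatmap_matrix(grads, coll, ds$metadata))
      guilds <- nitrogen_guild_report(ds$table, ds$taxonomy, ds$metadata)
      files <- c(files,
        taxa_gradients = write_output(grads,
          file.path(cfg$out_dir, "taxa_gradients.tsv"), cfg),
        nitrogen_guilds = write_output(guilds,
          file.path(cfg$out_dir, "nitrogen_guilds.tsv"), cfg))
      if (nrow(hm) > 0)
        files <- c(files, heatmap = write_matrix_output(
          hm, file.path(cfg$out_dir, "heatmap.tsv"), cfg))
    }

    manifest <- list(
      package = "aridnet",
      version = as.character(utils::packageVersion("aridnet")),
      seed = cfg$seed,
      config_hash = format(config_hash(cfg), scientific = FALSE),
      outputs = lapply(files, function(f)
        list(path = f, md5 = unname(tools::md5sum(f)))))
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(result)
}
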