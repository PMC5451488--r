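#' @name core_io
#' @title Reading, writing and validating gradient datasets
#' @description Plain-text formats used throughout: a TSV OTU table with
#'   OTUs as rows (first column \code{#OTU ID}, the common amplicon
#'   convention; transposed to samples x OTUs in memory), a TSV metadata
#'   table with one row per soil pit, a two-column TSV taxonomy of
#'   semicolon-delimited rank lineages, and a newick tree with branch
#'   lengths.
NULL

# metadata columns required for classification and the environment reports
METADATA_NUMERIC_FIELDS <- c(
  "elevation", "pH", "EC", "SOC",
  "AvgSoilRH", "HighSoilRH", "LowSoilRH", "PercSoilRH100",
  "AvgSoilT", "HighSoilT", "LowSoilT",
  "vegetation_cover", "shallow_nitrate", "shallow_sulfate")

TAXONOMY_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

#' Read an OTU table from TSV (OTUs as rows)
#'
#' @param path file path; the first column holds OTU ids (conventionally
#'   headed \code{#OTU ID}), remaining columns are samples.
#' @return an \code{\link{otu_table}} (samples x OTUs).
#' @export
read_otu_table <- function(path) {
  if (!file.exists(path)) stop("OTU table not found: ", path)
  df <- read.delim(path, check.names = FALSE, comment.char = "",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("OTU table has no sample columns: ", path)
  otu_ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric counts in ", path)
  otu_table(t(m), sample_ids = colnames(df)[-1], otu_ids = otu_ids)
}

#' Write an OTU table as TSV (OTUs as rows)
#'
#' @param table an \code{\link{otu_table}}.
#' @param path output file.
#' @export
write_otu_table <- function(table, path) {
  df <- data.frame(`#OTU ID` = colnames(table), t(unclass(table)),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample environmental metadata
#'
#' Expects a header row naming at least \code{sample_id} plus the soil
#' climate and chemistry fields (elevation, pH, EC, SOC, the soil RH and
#' temperature summaries, vegetation cover and shallow nitrate/sulfate).
#' A logical \code{salar_override} column marks sites whose salts are of
#' hydrologic rather than climatic origin; absent, it defaults to FALSE.
#'
#' @param path TSV file.
#' @return data.frame with one row per sample.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  df <- read.delim(path, check.names = TRUE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df))
    stop("metadata lacks a sample_id column: ", path)
  missing <- setdiff(METADATA_NUMERIC_FIELDS, names(df))
  if (length(missing))
    stop("metadata lacks field(s): ", paste(missing, collapse = ", "),
         " in ", path)
  if (!"salar_override" %in% names(df)) df$salar_override <- FALSE
  df$salar_override <- as.logical(df$salar_override)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in ", path)
  validate_metadata(df)
  df
}

validate_metadata <- function(meta) {
  rh <- c("AvgSoilRH", "HighSoilRH", "LowSoilRH", "PercSoilRH100")
  for (f in rh) {
    bad <- which(meta[[f]] < 0 | meta[[f]] > 100)
    if (length(bad))
      stop(sprintf("%s outside [0,100] for sample(s) %s", f,
                   paste(meta$sample_id[bad], collapse = ", ")))
  }
  if (any(meta$LowSoilRH > meta$AvgSoilRH | meta$AvgSoilRH > meta$HighSoilRH))
    stop("RH ordering violated: need LowSoilRH <= AvgSoilRH <= HighSoilRH")
  if (any(meta$LowSoilT > meta$AvgSoilT | meta$AvgSoilT > meta$HighSoilT))
    stop("temperature ordering violated")
  invisible(meta)
}

#' Write metadata TSV
#' @param meta metadata data.frame.
#' @param path output file.
#' @export
write_metadata <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy table
#'
#' Two-column TSV: OTU id, then a semicolon-delimited lineage string
#' (\code{k__...;p__...;c__...;o__...;f__...;g__...}).  Missing ranks are
#' kept as empty placeholders.
#'
#' @param path TSV file (header optional; detected from the first line).
#' @return data.frame with columns \code{otu_id} and the six ranks.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("taxonomy file not found: ", path)
  first <- readLines(path, n = 1)
  has_header <- grepl("taxonomy|lineage", tolower(first))
  df <- read.delim(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("taxonomy must have two columns: ", path)
  parse_lineages(as.character(df[[1]]), as.character(df[[2]]))
}

parse_lineages <- function(otu_ids, lineages) {
  if (anyDuplicated(otu_ids)) stop("duplicate OTU ids in taxonomy")
  parts <- strsplit(lineages, ";", fixed = TRUE)
  ranks <- vapply(seq_along(TAXONOMY_RANKS), function(i) {
    vapply(parts, function(p) {
      v <- if (length(p) >= i) trimws(p[[i]]) else ""
      sub("^[a-z]__", "", v)
    }, character(1))
  }, character(length(otu_ids)))
  ranks <- matrix(ranks, nrow = length(otu_ids))
  colnames(ranks) <- TAXONOMY_RANKS
  data.frame(otu_id = otu_ids, ranks, stringsAsFactors = FALSE)
}

#' Write a taxonomy table
#' @param taxonomy data.frame from \code{\link{read_taxonomy}}.
#' @param path output file.
#' @export
write_taxonomy <- function(taxonomy, path) {
  prefixes <- c("k__", "p__", "c__", "o__", "f__", "g__")
  lineage <- apply(taxonomy[, TAXONOMY_RANKS], 1, function(r)
    paste0(prefixes, r, collapse = ";"))
  write.table(data.frame(otu_id = taxonomy$otu_id, taxonomy = lineage),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted newick tree
#' @param path newick file.
#' @return an \code{ape::phylo} object; errors if unrooted or lacking
#'   branch lengths.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick tree: ", path)
  if (!ape::is.rooted(tree)) stop("tree is not rooted: ", path)
  if (is.null(tree$edge.length)) stop("tree lacks branch lengths: ", path)
  if (any(tree$edge.length < 0)) stop("negative branch lengths: ", path)
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf names: ", path)
  tree
}

#' Load and cross-validate a full dataset
#'
#' Reads counts, metadata, taxonomy and tree; drops samples whose total
#' reads fall below the retention threshold, and OTUs absent from the tree
#' (both with warnings); intersects sample ids with the metadata.
#'
#' @param otu_path,metadata_path,taxonomy_path,tree_path file paths.
#' @param min_reads per-sample read-retention threshold (default 16660, the
#'   study's cutoff for keeping a sample).
#' @return list with elements \code{table}, \code{metadata},
#'   \code{taxonomy}, \code{tree}.
#' @export
load_dataset <- function(otu_path, metadata_path, taxonomy_path, tree_path,
                         min_reads = 16660) {
  table <- read_otu_table(otu_path)
  meta <- read_metadata(metadata_path)
  taxonomy <- read_taxonomy(taxonomy_path)
  tree <- read_tree(tree_path)

  low <- rowSums(table) < min_reads
  if (any(low)) {
    warning(sprintf("dropping %d sample(s) below %d reads: %s",
                    sum(low), min_reads,
                    paste(rownames(table)[low], collapse = ", ")))
    table <- table[!low, , drop = FALSE]
  }
  off_tree <- !(colnames(table) %in% tree$tip.label)
  if (any(off_tree)) {
    warning(sprintf("dropping %d OTU(s) absent from the tree", sum(off_tree)))
    table <- table[, !off_tree, drop = FALSE]
  }
  common <- intersect(rownames(table), meta$sample_id)
  if (nrow(table) > 0 && length(common) < nrow(table))
    warning("sample(s) missing from metadata dropped: ",
            paste(setdiff(rownames(table), common), collapse = ", "))
  table <- table[common, , drop = FALSE]
  meta <- meta[match(common, meta$sample_id), , drop = FALSE]
  meta$aridity_class <- classify_aridity(meta)
  list(table = table, metadata = meta, taxonomy = taxonomy, tree = tree)
}

#' Write a full dataset to a directory
#'
#' Inverse of \code{\link{load_dataset}}: writes \code{otu_table.tsv},
#' \code{metadata.tsv}, \code{taxonomy.tsv} and \code{tree.nwk}.
#'
#' @param dataset list with \code{table}, \code{metadata}, \code{taxonomy},
#'   \code{tree} (and optionally \code{truth}, serialized as JSON).
#' @param dir output directory, created if needed.
#' @return named vector of the files written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    otu_table = file.path(dir, "otu_table.tsv"),
    metadata  = file.path(dir, "metadata.tsv"),
    taxonomy  = file.path(dir, "taxonomy.tsv"),
    tree      = file.path(dir, "tree.nwk"))
  write_otu_table(dataset$table, paths[["otu_table"]])
  write_metadata(dataset$metadata, paths[["metadata"]])
  write_taxonomy(dataset$taxonomy, paths[["taxonomy"]])
  ape::write.tree(dataset$tree, paths[["tree"]])
  if (!is.null(dataset$truth)) {
    paths <- c(paths, truth = file.path(dir, "truth.json"))
    jsonlite::write_json(dataset$truth, paths[["truth"]],
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(paths)
}

#' Classify samples into aridity classes
#'
#' Vegetated samples are \code{arid}; unvegetated samples with shallow salt
#' accumulation (nitrate or sulfate above cutoff) are \code{hyperarid}
#' unless their salts are flagged as hydrologic in origin
#' (\code{salar_override}); everything else is \code{margin}.
#'
#' @param meta metadata data.frame (one or more rows).
#' @param nitrate_cut shallow-nitrate cutoff, umol per g dry soil
#'   (default 20).
#' @param sulfate_cut shallow-sulfate cutoff, umol per g dry soil
#'   (default 500).
#' @return character vector of classes, one per row:
#'   \code{"hyperarid"}, \code{"margin"} or \code{"arid"}.
#' @export
classify_aridity <- function(meta, nitrate_cut = 20, sulfate_cut = 500) {
  req <- c("vegetation_cover", "shallow_nitrate", "shallow_sulfate",
           "salar_override")
  missing <- setdiff(req, names(meta))
  if (length(missing))
    stop("metadata lacks field(s): ", paste(missing, collapse = ", "))
  if (any(is.na(meta[req])))
    stop("missing values in classification fields")
  salty <- (meta$shallow_nitrate > nitrate_cut |
            meta$shallow_sulfate > sulfate_cut) & !meta$salar_override
  ifelse(meta$vegetation_cover > 0, "arid",
         ifelse(salty, "hyperarid", "margin"))
}

#' One-line dataset summary
#'
#' @param dataset list as returned by \code{\link{load_dataset}}.
#' @return (invisibly) a list of the summary counts; prints them.
#' @export
dataset_summary <- function(dataset) {
  cls <- table(factor(dataset$metadata$aridity_class,
                      levels = c("hyperarid", "margin", "arid")))
  out <- list(n_samples = nrow(dataset$table),
              n_otus = ncol(dataset$table),
              class_counts = as.list(cls))
  cat(sprintf("%d samples, %d OTUs | hyperarid %d, margin %d, arid %d\n",
              out$n_samples, out$n_otus,
              cls[["hyperarid"]], cls[["margin"]], cls[["arid"]]))
  invisible(out)
}
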