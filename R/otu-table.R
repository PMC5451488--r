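#' Construct an OTU count table
#'
#' The pipeline's central object: a samples x OTUs matrix of non-negative
#' integer read counts with unique sample and OTU identifiers.
#'
#' @param counts numeric matrix (samples in rows, OTUs in columns) of
#'   non-negative integers, or anything coercible to one.
#' @param sample_ids,otu_ids optional identifier vectors; defaults come from
#'   \code{dimnames(counts)}.
#' @return an object of class \code{otu_table} (an integer matrix with
#'   dimnames).
#' @export
otu_table <- function(counts, sample_ids = rownames(counts),
                      otu_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(counts)))
  if (is.null(otu_ids)) otu_ids <- paste0("OTU", seq_len(ncol(counts)))
  sample_ids <- as.character(sample_ids)
  otu_ids <- as.character(otu_ids)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (anyDuplicated(otu_ids)) stop("duplicate OTU ids")
  if (length(sample_ids) != nrow(counts) || length(otu_ids) != ncol(counts))
    stop("id lengths do not match count matrix dimensions")
  if (any(is.na(counts))) stop("counts contain NA")
  if (any(counts < 0)) stop("negative counts")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integers")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(sample_ids, otu_ids)
  structure(counts, class = c("otu_table", class(counts)))
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d samples x %d OTUs, %s total reads\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  invisible(x)
}

# keep class through subsetting when the result is still a matrix
#' @export
`[.otu_table` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) class(out) <- c("otu_table", "matrix", "array")
  out
}

#' Per-sample relative abundances
#'
#' @param table an \code{\link{otu_table}}.
#' @return numeric matrix of the same shape whose rows sum to 1.
#' @export
relative_abundance <- function(table) {
  tot <- rowSums(table)
  if (any(tot == 0)) stop("sample(s) with zero total reads")
  unclass(table) / tot
}

#' Observed richness (OTUs with positive count) per sample
#'
#' @param table an \code{\link{otu_table}}.
#' @return named integer vector.
#' @export
observed_otus <- function(table) {
  rowSums(unclass(table) > 0)
}
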