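#' Spearman rank correlation with small-sample exact p-values
#'
#' Rank correlation with midrank tie handling.  For small samples the
#' p-value is computed by exhaustive enumeration of all orderings of one
#' vector; for larger samples the usual t approximation on
#' \eqn{t = r_s \sqrt{(n-2)/(1-r_s^2)}} is used.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @param alternative "two.sided" (default), "greater" or "less".
#' @param exact_n largest sample size for which the permutation null is
#'   enumerated exhaustively (default 8, i.e. up to 40,320 orderings).
#' @return list with elements \code{rs}, \code{p} and \code{n}.
#' @examples
#' spearman(1:6, c(2, 1, 4, 3, 6, 5))
#' @export
spearman <- function(x, y, alternative = c("two.sided", "greater", "less"),
                     exact_n = 8L) {
  alternative <- match.arg(alternative)
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y))
    stop("x and y must have equal length")
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: constant vector")
  rx <- rank(x); ry <- rank(y)
  rs <- cor(rx, ry)
  if (n <= exact_n) {
    perms <- all_permutations(n)
    # correlation of rx with every reordering of ry; cor is linear in the
    # permuted vector so the null can be evaluated with one matrix product
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    null_rs <- as.vector(matrix(ryc[perms], nrow(perms), n) %*% rxc) / denom
    eps <- 1e-12
    p <- switch(alternative,
      two.sided = mean(abs(null_rs) >= abs(rs) - eps),
      greater   = mean(null_rs >= rs - eps),
      less      = mean(null_rs <= rs + eps))
  } else {
    p <- spearman_t_pvalue(rs, n, alternative)
  }
  list(rs = rs, p = p, n = n)
}

# t-approximation p-value for a Spearman correlation
spearman_t_pvalue <- function(rs, n, alternative = "two.sided") {
  rs <- min(1, max(-1, rs))
  if (abs(rs) == 1) {
    tt <- sign(rs) * Inf
  } else {
    tt <- rs * sqrt((n - 2) / (1 - rs^2))
  }
  switch(alternative,
    two.sided = 2 * pt(abs(tt), df = n - 2, lower.tail = FALSE),
    greater   = pt(tt, df = n - 2, lower.tail = FALSE),
    less      = pt(tt, df = n - 2))
}

# all n! permutations of 1..n as a matrix (n! rows); recursive insertion
all_permutations <- function(n) {
  if (n > 9L) stop("refusing to enumerate more than 9! permutations")
  p <- matrix(1L, 1L, 1L)
  for (k in 2L:n) {
    m <- nrow(p)
    out <- matrix(0L, m * k, k)
    for (pos in seq_len(k)) {
      rows <- (pos - 1L) * m + seq_len(m)
      if (pos > 1L) out[rows, seq_len(pos - 1L)] <- p[, seq_len(pos - 1L)]
      out[rows, pos] <- k
      if (pos < k) out[rows, (pos + 1L):k] <- p[, pos:(k - 1L), drop = FALSE]
    }
    p <- out
  }
  p
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values (q-values) controlling the FDR.  Thin
#' validating wrapper over \code{stats::p.adjust(method = "BH")}.
#'
#' @param p numeric vector of p-values in [0, 1]; NAs preserved.
#' @return vector of q-values in the input order.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Percent decrease between two values
#'
#' \code{100 * (high - low) / high}; used to express diversity loss between
#' gradient extremes.
#'
#' @param high,low numeric scalars, \code{high} > 0.
#' @return percent decrease (positive when \code{low < high}).
#' @export
percent_decrease <- function(high, low) {
  stopifnot(is.numeric(high), is.numeric(low), high > 0)
  100 * (high - low) / high
}
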