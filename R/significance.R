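# Permutation null for HRR values. Shuffling each probeset's values
# independently across arrays destroys all inter-gene correlation while
# preserving each gene's marginal distribution; the HRR matrix of each
# permuted compendium contributes all of its pairwise values to a pooled
# empirical null. Small HRR = strong co-expression, so significance is a
# left-tail test.

#' Null distribution of HRR values by permutation
#'
#' @param x Expression matrix, probesets x arrays.
#' @param n_permutations Number of independent permutations (default 100).
#' @param seed Integer seed; the result is a deterministic function of it.
#' @param block_size Passed to the rank computation.
#' @return An object of class `null_hrr`: list with `n`, `n_permutations`,
#'   `counts` (integer histogram over HRR values 1..n-1, pooled over all
#'   permutations and pairs) and `total`.
#' @export
permutation_null <- function(x, n_permutations = 100L, seed = NULL,
                             block_size = 1024L) {
  validate_expression(x)
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  n <- nrow(x)
  m <- ncol(x)
  counts <- numeric(n - 1L)
  with_seed(seed, {
    for (p in seq_len(n_permutations)) {
      xp <- x
      for (i in seq_len(n)) xp[i, ] <- xp[i, sample.int(m)]
      rk <- rank_matrix_blocked(xp, block_size = block_size)
      h <- hrr_matrix(rk)
      counts <- counts + tabulate(h[upper.tri(h)], nbins = n - 1L)
    }
  })
  structure(list(n = n, n_permutations = n_permutations,
                 counts = counts, total = sum(counts)),
            class = "null_hrr")
}

#' @export
print.null_hrr <- function(x, ...) {
  cat(sprintf("null_hrr: %d genes, %d permutations, %s pooled HRR values\n",
              x$n, x$n_permutations, format(x$total, big.mark = ",")))
  for (a in c(0.01, 0.05)) {
    cat(sprintf("  cutoff at alpha = %.2f: HRR <= %d\n", a, cutoff_at(x, a)))
  }
  invisible(x)
}

#' HRR cutoff at a significance level
#'
#' The largest integer `h` such that the empirical null probability
#' `P(HRR <= h)` is still below `alpha`. Non-decreasing in `alpha`;
#' `alpha = 1` returns `n - 1` (everything passes).
#'
#' @param dist A `null_hrr` object.
#' @param alpha Significance level in (0, 1].
#' @return Integer cutoff (0 when even HRR = 1 is too frequent).
#' @export
cutoff_at <- function(dist, alpha) {
  stopifnot(inherits(dist, "null_hrr"))
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (alpha == 1) return(dist$n - 1L)  # everything passes at alpha = 1
  cdf <- cumsum(dist$counts) / dist$total
  below <- which(cdf < alpha)
  if (!length(below)) 0L else max(below)
}

#' Empirical p-value of an observed HRR value
#'
#' Left-tail permutation p with add-one correction:
#' `p = (#\{null HRR <= h\} + 1) / (total + 1)`, so p is never exactly zero.
#'
#' @param dist A `null_hrr` object.
#' @param h Integer HRR value in `[1, n - 1]` (vectorised).
#' @return Empirical p-value(s), monotone non-decreasing in `h`.
#' @export
hrr_pvalue <- function(dist, h) {
  stopifnot(inherits(dist, "null_hrr"))
  if (any(h < 1L | h > dist$n - 1L)) stop("h out of range [1, n - 1]")
  cum <- cumsum(dist$counts)
  (cum[h] + 1) / (dist$total + 1)
}

#' Write a significance report and null histogram
#'
#' @param dist A `null_hrr` object.
#' @param path Report TSV path (cutoffs per alpha); the pooled histogram is
#'   written next to it as `<path>.hist.tsv`.
#' @param alpha Significance levels to report.
#' @export
write_significance_report <- function(dist, path, alpha = c(0.01, 0.05)) {
  rep <- data.frame(n = dist$n, n_permutations = dist$n_permutations,
                    alpha = alpha,
                    hrr_cutoff = vapply(alpha, function(a) cutoff_at(dist, a), 0L))
  utils::write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  hist_df <- data.frame(hrr = seq_along(dist$counts), count = dist$counts)
  utils::write.table(hist_df, paste0(path, ".hist.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# run an expression with a temporary RNG state; NULL seed = use current stream
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
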