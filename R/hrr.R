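# Core HRR machinery. rank matrices are stored column-wise: rank[j, i] is the
# rank of gene j in gene i's co-expression ordering (1 = most strongly
# co-expressed, self excluded). Column-wise storage keeps the block fill and
# the per-guide reads contiguous.

#' Pearson correlation matrix over arrays
#'
#' Textbook Pearson correlation between every pair of probesets, computed as
#' the cross-product of row-standardized expression (identical to
#' `stats::cor` on the transposed matrix). Probesets with zero variance are
#' rejected: their correlation is undefined and silently propagating NaN
#' would corrupt the rank transform.
#'
#' @param x Expression matrix, probesets x arrays (>= 3 arrays).
#' @return Symmetric numeric matrix of correlations with unit diagonal.
#' @export
pearson_correlation <- function(x) {
  z <- std_rows(x)
  r <- tcrossprod(z)
  r[r > 1] <- 1
  r[r < -1] <- -1
  r <- (r + t(r)) / 2          # enforce exact symmetry against FP noise
  diag(r) <- 1
  r
}

# rows scaled so tcrossprod() yields Pearson r
#' @keywords internal
std_rows <- function(x) {
  validate_expression(x)
  ctr <- x - rowMeans(x)
  ss <- sqrt(rowSums(ctr^2))
  zv <- ss == 0
  if (any(zv)) {
    stop("zero-variance probeset(s): ",
         paste(utils::head(rownames(x)[zv], 10L), collapse = ", "),
         if (sum(zv) > 10L) sprintf(" (and %d more)", sum(zv) - 10L) else "")
  }
  ctr / ss
}

# lexicographic rank of each identifier, C-locale, used for all tie-breaks
#' @keywords internal
id_order_rank <- function(ids) {
  match(ids, sort(ids, method = "radix"))
}

#' Transform a correlation matrix into per-gene co-expression ranks
#'
#' For each gene A the remaining genes are ordered by decreasing r(A, .) and
#' assigned ranks 1..n-1 (rank 1 = most strongly co-expressed partner). Ties
#' are broken by ascending probeset identifier so results are deterministic.
#'
#' @param corr Symmetric correlation matrix with dimnames.
#' @return Integer matrix `R` where `R[j, i]` is the rank of gene j in gene
#'   i's list; the (unused) diagonal is 0.
#' @export
correlation_ranks <- function(corr) {
  ids <- rownames(corr)
  if (is.null(ids)) stop("correlation matrix needs probeset dimnames")
  n <- nrow(corr)
  idr <- id_order_rank(ids)
  out <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    out[, i] <- rank_one_column(corr[, i], i, idr)
  }
  out
}

# ranks of a single gene's correlation vector; self gets 0
#' @keywords internal
rank_one_column <- function(v, self, idr) {
  v[self] <- -Inf
  ord <- order(-v, idr, method = "radix")
  rnk <- integer(length(v))
  rnk[ord] <- seq_along(v)
  rnk[self] <- 0L
  rnk
}

# Fill the full rank matrix from expression in row blocks so the dense
# double-precision correlation matrix is never materialized; block size does
# not change results (regression-tested).
#' @keywords internal
rank_matrix_blocked <- function(x, block_size = 1024L) {
  z <- std_rows(x)
  n <- nrow(z)
  ids <- rownames(z)
  idr <- id_order_rank(ids)
  out <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (start in seq(1L, n, by = block_size)) {
    idx <- start:min(start + block_size - 1L, n)
    cb <- tcrossprod(z[idx, , drop = FALSE], z)   # block x n correlations
    for (bi in seq_along(idx)) {
      i <- idx[bi]
      out[, i] <- rank_one_column(cb[bi, ], i, idr)
    }
  }
  out
}

#' Highest reciprocal rank matrix from a rank matrix
#'
#' `HRR(A, B) = max(rank(A, B), rank(B, A))`: a gene pair scores well (low)
#' only when each gene ranks the other highly, making the index robust to
#' hub genes that rank highly against everything.
#'
#' @param ranks Integer rank matrix from [correlation_ranks()].
#' @return Symmetric integer matrix of HRR values (diagonal 0).
#' @export
hrr_matrix <- function(ranks) {
  h <- pmax(ranks, t(ranks))
  dimnames(h) <- dimnames(ranks)
  h
}

#' Build an HRR co-expression network
#'
#' Runs the full chain correlation -> per-gene ranks -> HRR on a (sub-)
#' compendium. Computation is blocked over rows so memory stays bounded by
#' the integer rank/HRR matrices plus one block of correlations.
#'
#' @param x Expression matrix, probesets x arrays.
#' @param block_size Number of probesets correlated per block.
#' @return An object of class `hrr_network`: list with `probeset_ids`,
#'   `hrr` (symmetric integer matrix) and `rank` (integer matrix,
#'   `rank[j, i]` = rank of j in i's list).
#' @export
hrr_network <- function(x, block_size = 1024L) {
  rk <- rank_matrix_blocked(x, block_size = block_size)
  structure(list(probeset_ids = rownames(rk), hrr = hrr_matrix(rk), rank = rk),
            class = "hrr_network")
}

#' @export
print.hrr_network <- function(x, ...) {
  n <- length(x$probeset_ids)
  off <- x$hrr[upper.tri(x$hrr)]
  cat(sprintf("hrr_network: %d probesets, HRR range [%d, %d], %d mutual-best pairs\n",
              n, min(off), max(off), sum(off == 1L)))
  invisible(x)
}

#' Edge weight for an HRR cutoff
#'
#' The five weights used in the source methodology are returned verbatim for
#' cutoffs 10, 20, 30, 40 and 50; they follow the closed form
#' `w = 1 / (cutoff - 5)`, which is used for any other cutoff above 5.
#' Cutoffs of 5 or less (where the reciprocal form is undefined or negative)
#' get unit weight.
#'
#' @param cutoff Positive integer HRR cutoff.
#' @return A single positive weight.
#' @export
hrr_weight <- function(cutoff) {
  printed <- c(`10` = 0.2, `20` = 0.067, `30` = 0.04, `40` = 0.028, `50` = 0.022)
  key <- as.character(cutoff)
  if (key %in% names(printed)) return(unname(printed[key]))
  if (cutoff > 5) 1 / (cutoff - 5) else 1
}

#' Threshold an HRR network into a weighted edge list
#'
#' Retains every unordered pair with `HRR <= cutoff`; all retained edges in a
#' given network carry the single weight [hrr_weight()] of that cutoff.
#' Nodes left without any edge are excluded from the list but reported in
#' the `excluded` attribute.
#'
#' @param net An `hrr_network`.
#' @param cutoff Integer cutoff in `[2, n - 1]`.
#' @return A data.frame of class `hrr_edges` with columns `probeset_a`,
#'   `probeset_b` (lexicographically ordered within each pair), `hrr`,
#'   `weight`; attributes `cutoff`, `weight`, `nodes` (all network nodes)
#'   and `excluded` (nodes with no retained edge).
#' @export
threshold_network <- function(net, cutoff) {
  stopifnot(inherits(net, "hrr_network"))
  n <- length(net$probeset_ids)
  if (cutoff < 2 || cutoff > n - 1)
    stop(sprintf("cutoff must lie in [2, %d]", n - 1))
  h <- net$hrr
  ut <- upper.tri(h)
  sel <- which(ut & h <= cutoff, arr.ind = TRUE)
  ids <- net$probeset_ids
  a <- ids[sel[, 1L]]
  b <- ids[sel[, 2L]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  w <- hrr_weight(cutoff)
  ord <- order(a, b, method = "radix")
  edges <- data.frame(probeset_a = a[ord], probeset_b = b[ord],
                      hrr = h[sel][ord], weight = w, stringsAsFactors = FALSE)
  structure(edges, class = c("hrr_edges", "data.frame"),
            cutoff = cutoff, weight = w, nodes = ids,
            excluded = setdiff(ids, unique(c(a, b))))
}

#' @export
print.hrr_edges <- function(x, ...) {
  cat(sprintf("hrr_edges: %d edges at HRR <= %d (weight %g), %d/%d nodes connected\n",
              nrow(x), attr(x, "cutoff"), attr(x, "weight"),
              length(attr(x, "nodes")) - length(attr(x, "excluded")),
              length(attr(x, "nodes"))))
  NextMethod()
}

#' Write a weighted edge list as TSV
#' @param edges An `hrr_edges` data.frame.
#' @param path Output path.
#' @export
write_edges <- function(edges, path) {
  utils::write.table(as.data.frame(edges), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a thresholded network as GraphML
#'
#' Edge attributes `hrr` and `weight` are carried over.
#'
#' @param edges An `hrr_edges` data.frame.
#' @param path Output path (.graphml).
#' @export
export_graphml <- function(edges, path) {
  g <- igraph::graph_from_data_frame(as.data.frame(edges), directed = FALSE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

# ---- guide (seed) gene clusters --------------------------------------------

#' Guide-gene co-expression clusters
#'
#' Treats every gene as a seed/guide and collects the `k` genes with the
#' smallest HRR to it (its most mutually co-expressed partners), yielding
#' exactly one (possibly overlapping) cluster per probeset. Ties at the k-th
#' position are broken by ascending HRR, then the guide's own rank of the
#' candidate, then probeset identifier. When fewer than `k` partners exist
#' the cluster holds all `n - 1`.
#'
#' Given an expression matrix, the computation is streamed over guide blocks
#' so only the integer rank matrix is ever held in full — this is what makes
#' array-genome-scale inputs (tens of thousands of probesets) feasible.
#'
#' @param x An `hrr_network` or an expression matrix (probesets x arrays).
#' @param k Cluster width (default 100, the top-100-HRR rule).
#' @param block_size Probesets correlated per slab when streaming.
#' @param engine `"store"` streams correlation slabs through a compact
#'   16-bit rank store (the genome-scale path; requires an expression
#'   matrix), `"dense"` works off full integer rank matrices in R. The
#'   default picks `"store"` for a matrix and `"dense"` for an
#'   `hrr_network`; both produce identical clusters.
#' @return An object of class `guide_clusters`: list with `probeset_ids`,
#'   `k`, `members` (k x n integer index matrix) and `hrr` (matching HRR
#'   values).
#' @export
guide_clusters <- function(x, k = 100L, block_size = 1024L,
                           engine = c("auto", "store", "dense")) {
  engine <- match.arg(engine)
  if (k < 1L) stop("k must be >= 1")
  k <- as.integer(k)
  if (engine == "auto") engine <- if (inherits(x, "hrr_network")) "dense" else "store"
  if (engine == "store") {
    if (inherits(x, "hrr_network"))
      stop("engine = \"store\" needs the expression matrix, not a built network")
    return(guide_clusters_store(x, k, block_size))
  }
  rk <- if (inherits(x, "hrr_network")) x$rank
        else rank_matrix_blocked(x, block_size = block_size)
  ids <- rownames(rk)
  n <- nrow(rk)
  idr <- id_order_rank(ids)
  kk <- min(k, n - 1L)
  members <- matrix(NA_integer_, kk, n)
  hrrv <- matrix(NA_integer_, kk, n)
  for (start in seq(1L, n, by = block_size)) {
    idx <- start:min(start + block_size - 1L, n)
    # HRR rows for this guide block: pmax of the guides' columns and rows
    hb <- pmax(rk[, idx, drop = FALSE], t(rk[idx, , drop = FALSE]))
    for (bi in seq_along(idx)) {
      g <- idx[bi]
      hv <- hb[, bi]
      top <- top_k_partners(hv, rk[, g], g, kk, idr)
      members[, bi + start - 1L] <- top
      hrrv[, bi + start - 1L] <- hv[top]
    }
  }
  structure(list(probeset_ids = ids, k = k, members = members, hrr = hrrv),
            class = "guide_clusters")
}

# streaming path: correlation slabs (R BLAS) -> uint16 rank store (C++) ->
# tiled top-k; peak memory ~ 2 n^2 bytes instead of two full integer
# matrices plus copies
#' @keywords internal
guide_clusters_store <- function(x, k, block_size) {
  z <- std_rows(x)
  ids <- rownames(z)
  n <- nrow(z)
  idr <- id_order_rank(ids)
  store <- rank_store_create(n)
  for (start in seq(1L, n, by = block_size)) {
    idx <- start:min(start + block_size - 1L, n)
    cb <- tcrossprod(z[idx, , drop = FALSE], z)
    rank_store_fill(store, cb, idx, idr)
  }
  res <- rank_store_topk(store, k, idr)
  structure(list(probeset_ids = ids, k = k, members = res$members,
                 hrr = res$hrr),
            class = "guide_clusters")
}

# deterministic top-k selection for one guide
#' @keywords internal
top_k_partners <- function(hv, guide_rank, self, kk, idr) {
  n <- length(hv)
  hv[self] <- n   # larger than any attainable HRR (n - 1), so never selected
  if (n - 1L <= kk) {
    cand <- seq_len(n)[-self]
  } else {
    thr <- sort.int(hv, partial = kk)[kk]
    cand <- which(hv <= thr)
  }
  ord <- order(hv[cand], guide_rank[cand], idr[cand], method = "radix")
  cand[ord][seq_len(kk)]
}

#' @export
print.guide_clusters <- function(x, ...) {
  cat(sprintf("guide_clusters: %d clusters (one per probeset), k = %d, width %d\n",
              length(x$probeset_ids), x$k, nrow(x$members)))
  invisible(x)
}

#' Members of one guide cluster
#'
#' @param gc A `guide_clusters` object.
#' @param guide Probeset identifier of the guide.
#' @return data.frame (probeset_id, hrr) sorted by ascending HRR.
#' @export
guide_cluster <- function(gc, guide) {
  j <- match(guide, gc$probeset_ids)
  if (is.na(j)) stop("unknown guide: ", guide)
  keep <- !is.na(gc$members[, j])
  data.frame(probeset_id = gc$probeset_ids[gc$members[keep, j]],
             hrr = gc$hrr[keep, j], stringsAsFactors = FALSE)
}

#' Convert a clustering object to a plain list of member vectors
#' @param x A clustering-like object.
#' @param ... Method arguments.
#' @export
as_cluster_list <- function(x, ...) UseMethod("as_cluster_list")

#' @rdname as_cluster_list
#' @param include_guide Include the guide gene itself in its cluster (the
#'   guide's function is part of the cluster's function).
#' @export
as_cluster_list.guide_clusters <- function(x, include_guide = TRUE, ...) {
  out <- lapply(seq_along(x$probeset_ids), function(j) {
    keep <- !is.na(x$members[, j])
    mem <- x$probeset_ids[x$members[keep, j]]
    if (include_guide) c(x$probeset_ids[j], mem) else mem
  })
  names(out) <- x$probeset_ids
  out
}

#' Write guide clusters as a long TSV (guide, probeset_id, hrr)
#' @param gc A `guide_clusters` object.
#' @param path Output path.
#' @param guides Optional subset of guide ids to write.
#' @export
write_guide_clusters <- function(gc, path, guides = NULL) {
  if (is.null(guides)) guides <- gc$probeset_ids
  rows <- lapply(guides, function(g) {
    d <- guide_cluster(gc, g)
    cbind(guide = g, d)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
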