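# Markov Cluster Algorithm on the weighted, thresholded HRR network.
# Flow simulation on a column-stochastic matrix: expansion (matrix power)
# spreads flow along walks, inflation (entrywise power + renormalization)
# strengthens strong currents and starves weak ones, until the process
# converges to a (near) idempotent matrix whose connected structure encodes
# the clusters.

#' Markov clustering of a weighted edge list
#'
#' @param edges An `hrr_edges` data.frame, or any data.frame whose first two
#'   columns are node identifiers and which has a `weight` column. Weights
#'   must be positive; the graph is treated as undirected.
#' @param inflation Inflation exponent `I` (granularity knob; the sweep grid
#'   of the methodology is 1.1-2.0).
#' @param expansion Expansion power `e` (default 2).
#' @param self_loop_weight Loop weight added to every node before
#'   normalization. The default `"max"` gives each node a loop equal to the
#'   largest edge weight in its column (the behaviour of the reference MCL
#'   program), which makes the clustering invariant to the uniform weight
#'   attached by the cutoff-to-weight mapping; a single number fixes the
#'   loop weight instead.
#' @param pruning_threshold Entries below this are dropped (then columns
#'   renormalized) to keep the matrix sparse.
#' @param max_iterations Iteration cap; non-convergence is a warning and the
#'   last iterate is interpreted.
#' @param convergence_tol Convergence when the max absolute entrywise change
#'   between successive iterates falls below this.
#' @param min_size Clusters smaller than this are moved to `unassigned`
#'   (biologically meaningless micro-clusters are discarded; default 3).
#' @return An object of class `mcl_clustering`: list with `clusters` (named
#'   list of member id vectors, ids "1", "2", ... by decreasing size),
#'   `unassigned` (size-filtered or never-connected probesets), `params`,
#'   `iterations`, `converged` and `max_colsum_dev` (worst deviation of any
#'   column sum from 1 observed after a normalization step).
#' @export
mcl <- function(edges, inflation = 1.2, expansion = 2L,
                self_loop_weight = "max", pruning_threshold = 1e-5,
                max_iterations = 100L, convergence_tol = 1e-8,
                min_size = 3L) {
  ed <- as.data.frame(edges)
  if (!nrow(ed)) stop("empty edge list")
  wcol <- if ("weight" %in% colnames(ed)) ed$weight else ed[[3L]]
  if (any(wcol <= 0)) stop("edge weights must be positive")
  if (inflation < 1) stop("inflation must be >= 1")
  a <- as.character(ed[[1L]]); b <- as.character(ed[[2L]])
  nodes <- sort(unique(c(a, b)), method = "radix")
  universe <- attr(edges, "nodes")
  if (is.null(universe)) universe <- nodes
  n <- length(nodes)
  ii <- match(a, nodes); jj <- match(b, nodes)
  loops <- if (identical(self_loop_weight, "max")) {
    vapply(seq_len(n), function(v) max(wcol[ii == v | jj == v]), 0)
  } else {
    if (!is.numeric(self_loop_weight) || self_loop_weight <= 0)
      stop("self_loop_weight must be \"max\" or a positive number")
    rep(self_loop_weight, n)
  }
  m <- Matrix::sparseMatrix(i = c(ii, jj, seq_len(n)),
                            j = c(jj, ii, seq_len(n)),
                            x = c(wcol, wcol, loops),
                            dims = c(n, n))
  normalize <- function(m) {
    cs <- Matrix::colSums(m)
    if (any(cs == 0)) stop("column with zero mass during normalization")
    m %*% Matrix::Diagonal(n, 1 / cs)
  }
  m <- normalize(m)
  max_dev <- max(abs(Matrix::colSums(m) - 1))
  converged <- FALSE
  iter <- 0L
  while (iter < max_iterations) {
    iter <- iter + 1L
    prev <- m
    for (e in seq_len(expansion - 1L)) m <- m %*% prev  # e-th power of prev
    m <- inflate(m, inflation)
    m <- normalize(m)
    m <- Matrix::drop0(prune_small(m, pruning_threshold))
    m <- normalize(m)
    max_dev <- max(max_dev, abs(Matrix::colSums(m) - 1))
    if (max(abs(m - prev)) < convergence_tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge in ", max_iterations,
            " iterations; interpreting last iterate")
  comp <- limit_components(m, nodes)
  build_clustering(comp, universe, min_size,
                   params = list(method = "mcl", inflation = inflation,
                                 expansion = expansion,
                                 self_loop_weight = self_loop_weight,
                                 pruning_threshold = pruning_threshold,
                                 max_iterations = max_iterations,
                                 convergence_tol = convergence_tol,
                                 min_size = min_size),
                   iterations = iter, converged = converged,
                   max_colsum_dev = max_dev)
}

#' @keywords internal
inflate <- function(m, inflation) {
  m@x <- m@x^inflation
  m
}

#' @keywords internal
prune_small <- function(m, thr) {
  m@x[m@x < thr] <- 0
  m
}

# clusters = weakly connected components of the limit matrix's nonzero
# structure; a node that flows to attractors of several systems links them,
# so components yield a disjoint partition of the network nodes
#' @keywords internal
limit_components <- function(m, nodes) {
  g <- igraph::graph_from_adjacency_matrix(m, mode = "max", weighted = TRUE,
                                           diag = TRUE)
  cm <- igraph::components(g, mode = "weak")$membership
  split(nodes, cm)
}

#' @keywords internal
build_clustering <- function(comp, universe, min_size, params,
                             iterations = NA_integer_, converged = NA,
                             max_colsum_dev = NA_real_) {
  comp <- lapply(comp, function(v) sort(v, method = "radix"))
  sizes <- lengths(comp)
  first <- vapply(comp, `[`, "", 1L)
  ord <- order(-sizes, first, method = "radix")
  comp <- comp[ord]
  keep <- lengths(comp) >= min_size
  clusters <- comp[keep]
  names(clusters) <- as.character(seq_along(clusters))
  unassigned <- sort(c(unlist(comp[!keep], use.names = FALSE),
                       setdiff(universe, unlist(comp, use.names = FALSE))),
                     method = "radix")
  structure(list(clusters = clusters, unassigned = unassigned, params = params,
                 iterations = iterations, converged = converged,
                 max_colsum_dev = max_colsum_dev),
            class = "mcl_clustering")
}

#' @export
print.mcl_clustering <- function(x, ...) {
  sz <- lengths(x$clusters)
  cat(sprintf("mcl_clustering (%s): %d clusters of >= %d members (sizes %s), %d unassigned\n",
              paste(names(x$params)[2], "=", x$params$inflation),
              length(x$clusters), x$params$min_size,
              if (length(sz)) paste0(min(sz), "-", max(sz)) else "-",
              length(x$unassigned)))
  invisible(x)
}

#' @rdname as_cluster_list
#' @export
as_cluster_list.mcl_clustering <- function(x, ...) x$clusters

#' Write cluster membership as TSV (cluster_id, probeset_id)
#' @param clustering An `mcl_clustering`.
#' @param path Output path.
#' @export
write_clusters <- function(clustering, path) {
  cl <- as_cluster_list(clustering)
  df <- data.frame(cluster_id = rep(names(cl), lengths(cl)),
                   probeset_id = unlist(cl, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read cluster membership from TSV (cluster_id, probeset_id)
#' @param path Input path.
#' @return A named list of member vectors.
#' @export
read_clusters <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  split(df[[2L]], df[[1L]])
}

#' Sweep the MCL inflation parameter and score each solution
#'
#' Runs [mcl()] for every inflation value of the grid and scores each
#' clustering by GO-enrichment specificity / sensitivity / F-measure,
#' mirroring the parameter-selection procedure of the methodology.
#'
#' @param edges Weighted edge list (see [mcl()]).
#' @param inflation_grid Inflation values (default the 1.1-2.0 grid in 0.1
#'   steps).
#' @param annotations An `annotation_set`.
#' @param background Probeset universe for enrichment (defaults to the edge
#'   list's node universe).
#' @param ... Further arguments to [mcl()] and [clustering_performance()].
#' @return List with `performance` (data.frame: inflation, n_clusters,
#'   specificity, sensitivity, f_measure; sorted by decreasing F),
#'   `clusterings` (named list of `mcl_clustering`), `best_inflation`.
#' @export
sweep_inflation <- function(edges, inflation_grid = seq(1.1, 2.0, by = 0.1),
                            annotations, background = NULL, ...) {
  if (!length(inflation_grid)) stop("empty inflation grid")
  if (is.null(background)) background <- attr(edges, "nodes")
  dots <- list(...)
  mcl_args <- dots[names(dots) %in% names(formals(mcl))]
  perf_args <- dots[names(dots) %in% setdiff(names(formals(clustering_performance)),
                                             c("clusters", "annotations", "background"))]
  rows <- list(); clusterings <- list()
  for (inf in inflation_grid) {
    cl <- do.call(mcl, c(list(edges = edges, inflation = inf), mcl_args))
    perf <- do.call(clustering_performance,
                    c(list(clusters = cl, annotations = annotations,
                           background = background), perf_args))
    key <- format(inf, nsmall = 1)
    clusterings[[key]] <- cl
    rows[[key]] <- data.frame(inflation = inf,
                              n_clusters = length(cl$clusters),
                              specificity = perf$specificity,
                              sensitivity = perf$sensitivity,
                              f_measure = perf$f_measure)
  }
  perf <- do.call(rbind, rows)
  rownames(perf) <- NULL
  perf <- perf[order(-perf$f_measure, perf$inflation), , drop = FALSE]
  list(performance = perf, clusterings = clusterings,
       best_inflation = perf$inflation[1L])
}

#' Inter-cluster connectivity scores
#'
#' `score(A, B)` = (number of network edges with one endpoint in each
#' cluster) / (|A| x |B|), i.e. the density of the bipartite edge set
#' between the two clusters. Pairs with score strictly greater than
#' `threshold` are flagged connected.
#'
#' @param clustering An `mcl_clustering` (or named list of member vectors).
#' @param edges Weighted edge list over the same node universe.
#' @param threshold Connectivity threshold (default 0.03).
#' @return data.frame of class `connectivity_report`: cluster_a, cluster_b,
#'   n_edges, score, connected — one row per unordered cluster pair with at
#'   least the zero score omitted pairs included (all pairs reported).
#' @export
cluster_connectivity <- function(clustering, edges, threshold = 0.03) {
  cl <- if (inherits(clustering, "mcl_clustering")) as_cluster_list(clustering)
        else clustering
  empt <- lengths(cl) == 0L
  if (any(empt)) {
    warning("excluding empty cluster(s): ", paste(names(cl)[empt], collapse = ", "))
    cl <- cl[!empt]
  }
  if (length(cl) < 2L) {
    out <- data.frame(cluster_a = character(0), cluster_b = character(0),
                      n_edges = integer(0), score = numeric(0),
                      connected = logical(0))
    return(structure(out, class = c("connectivity_report", "data.frame"),
                     threshold = threshold))
  }
  ed <- as.data.frame(edges)
  memb <- stats::setNames(rep(names(cl), lengths(cl)),
                          unlist(cl, use.names = FALSE))
  ca <- memb[as.character(ed[[1L]])]
  cb <- memb[as.character(ed[[2L]])]
  ids <- names(cl)
  idx_pairs <- utils::combn(length(ids), 2L)
  cnt <- stats::setNames(integer(ncol(idx_pairs)),
                         paste(idx_pairs[1L, ], idx_pairs[2L, ], sep = "\r"))
  ia <- match(ca, ids); ib <- match(cb, ids)
  inter <- !is.na(ia) & !is.na(ib) & ia != ib
  if (any(inter)) {
    lo <- pmin(ia[inter], ib[inter]); hi <- pmax(ia[inter], ib[inter])
    tb <- table(paste(lo, hi, sep = "\r"))
    cnt[names(tb)] <- as.integer(tb)
  }
  sizes <- lengths(cl)
  pairs <- rbind(ids[idx_pairs[1L, ]], ids[idx_pairs[2L, ]])
  score <- cnt / (sizes[idx_pairs[1L, ]] * sizes[idx_pairs[2L, ]])
  out <- data.frame(cluster_a = pairs[1L, ], cluster_b = pairs[2L, ],
                    n_edges = unname(cnt), score = unname(score),
                    connected = unname(score > threshold),
                    stringsAsFactors = FALSE)
  structure(out, class = c("connectivity_report", "data.frame"),
            threshold = threshold)
}
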