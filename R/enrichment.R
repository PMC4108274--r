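# GO over-representation per cluster. For every term with at least one
# annotated cluster member, the upper-tail hypergeometric probability of
# seeing that many (or more) annotated genes among the cluster's draws from
# the background universe. BH adjustment is applied within each
# cluster x namespace family (BP, MF and CC are corrected separately); a
# term is called significant when FDR < 0.05 AND it covers >= 2 cluster
# genes — a single gene cannot witness a shared function.

#' Hypergeometric GO enrichment of gene clusters
#'
#' @param clusters A clustering object with an [as_cluster_list()] method, or
#'   a (named) list of probeset-id vectors, or a single character vector.
#' @param annotations An `annotation_set`.
#' @param background Character vector: all probesets of the compendium the
#'   clusters were drawn from. Every cluster must be contained in it.
#' @param universe `"annotated"` (default) restricts the sampling universe to
#'   background probesets carrying at least one annotation in the tested
#'   namespace — unannotatable genes cannot be drawn as successes and would
#'   only deflate p. `"all"` uses the full background.
#' @param fdr_threshold Significance level on the BH-adjusted p (default 0.05).
#' @param min_genes Minimum annotated cluster members for significance
#'   (default 2).
#' @return data.frame of class `enrichment_result`: cluster_id, term_id,
#'   namespace, n_in_cluster, n_in_background, cluster_size, background_size,
#'   p, fdr, significant, description.
#' @export
hypergeom_enrich <- function(clusters, annotations, background,
                             universe = c("annotated", "all"),
                             fdr_threshold = 0.05, min_genes = 2L) {
  universe <- match.arg(universe)
  cl <- normalize_clusters(clusters)
  stopifnot(inherits(annotations, "annotation_set"))
  allmem <- unique(unlist(cl, use.names = FALSE))
  if (!all(allmem %in% background))
    stop("cluster member(s) outside the background universe: ",
         paste(utils::head(setdiff(allmem, background), 5L), collapse = ", "))
  assoc <- annotations$associations
  assoc <- assoc[assoc$probeset_id %in% background, , drop = FALSE]
  rows <- list()
  for (ns in intersect(c("BP", "MF", "CC"), unique(assoc$namespace))) {
    a_ns <- assoc[assoc$namespace == ns, , drop = FALSE]
    uni <- if (universe == "annotated") unique(a_ns$probeset_id) else background
    big_n <- length(uni)
    if (!big_n) next
    term_genes <- split(a_ns$probeset_id, a_ns$term_id)
    n_bg <- lengths(term_genes)
    for (ci in names(cl)) {
      memb <- intersect(cl[[ci]], uni)
      draws <- length(memb)
      if (!draws) next
      hits <- vapply(term_genes, function(g) sum(memb %in% g), 0L)
      tested <- hits >= 1L
      if (!any(tested)) next
      p <- stats::phyper(hits[tested] - 1L, n_bg[tested],
                         big_n - n_bg[tested], draws, lower.tail = FALSE)
      fdr <- stats::p.adjust(p, method = "BH")
      rows[[length(rows) + 1L]] <- data.frame(
        cluster_id = ci, term_id = names(term_genes)[tested], namespace = ns,
        n_in_cluster = unname(hits[tested]), n_in_background = unname(n_bg[tested]),
        cluster_size = draws, background_size = big_n,
        p = unname(p), fdr = unname(fdr),
        significant = unname(fdr < fdr_threshold & hits[tested] >= min_genes),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster_id = character(0), term_id = character(0),
               namespace = character(0), n_in_cluster = integer(0),
               n_in_background = integer(0), cluster_size = integer(0),
               background_size = integer(0), p = numeric(0), fdr = numeric(0),
               significant = logical(0), stringsAsFactors = FALSE)
  desc <- annotations$term_names[out$term_id]
  out$description <- ifelse(is.na(desc), "", unname(desc))
  out <- out[order(out$cluster_id, out$namespace, out$p, out$term_id,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_result", "data.frame"),
            fdr_threshold = fdr_threshold, min_genes = min_genes,
            universe = universe)
}

#' @keywords internal
normalize_clusters <- function(clusters) {
  cl <- if (is.character(clusters)) list(cluster_1 = clusters)
        else if (is.list(clusters) && !is.object(clusters)) clusters
        else as_cluster_list(clusters)
  if (is.null(names(cl)) || any(names(cl) == ""))
    names(cl) <- as.character(seq_along(cl))
  cl
}

#' GO enrichment of guide-gene clusters
#'
#' [hypergeom_enrich()] applied to every guide cluster, with the guide gene
#' included as a member of its own cluster (its function is part of the
#' cluster's function).
#'
#' @param gc A `guide_clusters` object.
#' @param annotations An `annotation_set`.
#' @param background Compendium probeset universe.
#' @param guides Optional subset of guides to test (identifiers); default all.
#' @param ... Passed to [hypergeom_enrich()].
#' @export
guide_enrichment <- function(gc, annotations, background, guides = NULL, ...) {
  stopifnot(inherits(gc, "guide_clusters"))
  cl <- as_cluster_list(gc, include_guide = TRUE)
  if (!is.null(guides)) {
    bad <- setdiff(guides, names(cl))
    if (length(bad)) stop("unknown guide(s): ", paste(bad, collapse = ", "))
    cl <- cl[guides]
  }
  hypergeom_enrich(cl, annotations, background, ...)
}

#' Enrichment-based clustering performance
#'
#' Specificity = fraction of clusters enriched with at least one annotation
#' at FDR < 0.05 (with >= 2 genes); sensitivity = fraction of annotations
#' enriched in at least one cluster under the same rule; F-measure =
#' 2 x Spec x Sens / (Spec + Sens), with 0 when both components are 0. The
#' sensitivity denominator counts the distinct terms annotating at least one
#' background gene in the tested namespaces.
#'
#' @param clusters Clustering object or list of member vectors.
#' @param annotations An `annotation_set`.
#' @param background Compendium probeset universe.
#' @param ... Passed to [hypergeom_enrich()].
#' @return List of class `performance_report`: n_clusters, n_annotations,
#'   specificity, sensitivity, f_measure, plus the underlying
#'   `enrichment_result`.
#' @export
clustering_performance <- function(clusters, annotations, background, ...) {
  cl <- normalize_clusters(clusters)
  if (!length(cl)) stop("no retained clusters to evaluate")
  assoc <- annotations$associations
  assoc <- assoc[assoc$probeset_id %in% background, , drop = FALSE]
  if (!nrow(assoc)) stop("no annotated probesets in the background")
  enr <- hypergeom_enrich(cl, annotations, background, ...)
  sig <- enr[enr$significant, , drop = FALSE]
  spec <- length(unique(sig$cluster_id)) / length(cl)
  n_ann <- length(unique(assoc$term_id))
  sens <- length(unique(sig$term_id)) / n_ann
  f <- if (spec + sens == 0) 0 else 2 * spec * sens / (spec + sens)
  structure(list(n_clusters = length(cl), n_annotations = n_ann,
                 specificity = spec, sensitivity = sens, f_measure = f,
                 enrichment = enr),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf(paste0("clustering performance: %d clusters, %d annotations\n",
                     "  specificity %.3f  sensitivity %.3f  F %.3f\n"),
              x$n_clusters, x$n_annotations,
              x$specificity, x$sensitivity, x$f_measure))
  invisible(x)
}

#' Write an enrichment table as TSV
#'
#' Columns mirror the standard per-cluster GO report: cluster, GO ID, GO
#' type, counts in input and background, p, FDR, description.
#'
#' @param enr An `enrichment_result`.
#' @param path Output path.
#' @param significant_only Keep only significant rows.
#' @export
write_enrichment <- function(enr, path, significant_only = FALSE) {
  df <- as.data.frame(enr)
  if (significant_only) df <- df[df$significant, , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
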