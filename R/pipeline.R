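# End-to-end driver: compendium -> condition subsets -> HRR network ->
# permutation significance -> guide + MCL clusters -> enrichment ->
# ESI/cESI, with every stage also callable standalone on the written
# intermediates (no hidden state). A JSON run manifest records input
# digests, all parameters and the seed, which is sufficient to re-execute
# the run bit-identically.

#' Validate a pipeline configuration
#'
#' @param config A list (e.g. parsed from YAML).
#' @return The config with defaults filled in; errors on unknown or
#'   ill-typed keys before any computation.
#' @export
validate_config <- function(config) {
  defaults <- list(version = 1L, expression = NULL, metadata = NULL,
                   annotations = NULL, obo = NULL, propagate = FALSE,
                   exclude = character(0),
                   conditions = list(global = list()),
                   k = 100L, cutoff = 30L,
                   inflation = 1.2, n_permutations = 100L,
                   alpha = c(0.01, 0.05), min_size = 3L,
                   universe = "annotated", cesi_group = "organ",
                   write_guide = FALSE, seed = 1L)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$expression)) stop("config requires 'expression'")
  for (key in c("k", "cutoff", "n_permutations", "min_size", "seed")) {
    if (!is.numeric(cfg[[key]]) || length(cfg[[key]]) != 1L || cfg[[key]] < 0)
      stop("config key '", key, "' must be a single non-negative number")
    cfg[[key]] <- as.integer(cfg[[key]])
  }
  if (!is.numeric(cfg$inflation) || any(cfg$inflation < 1))
    stop("config key 'inflation' must be numeric value(s) >= 1")
  if (!cfg$universe %in% c("annotated", "all"))
    stop("config key 'universe' must be 'annotated' or 'all'")
  if (!is.list(cfg$conditions) || is.null(names(cfg$conditions)))
    stop("config key 'conditions' must be a named mapping")
  cfg
}

#' Run the full co-expression pipeline
#'
#' @param config Path to a YAML configuration file, or an equivalent list.
#'   Keys: `expression` (TSV path, required), `metadata`, `annotations`,
#'   `obo`, `propagate`, `exclude`, `conditions` (named list of metadata
#'   selectors; `global: {}` analyses all arrays), `k`, `cutoff`,
#'   `inflation` (scalar, or vector to sweep), `n_permutations` (0 skips the
#'   permutation stage), `alpha`, `min_size`, `universe`, `cesi_group`,
#'   `write_guide`, `seed`.
#' @param out_dir Output directory; one sub-directory per condition plus
#'   `manifest.json`.
#' @param seed Overrides the config seed when given.
#' @return Invisibly, the output directory.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  cfg_path <- NULL
  if (is.character(config)) {
    cfg_path <- config
    config <- yaml::read_yaml(config)
  }
  cfg <- validate_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  expr <- read_expression(cfg$expression, exclude = cfg$exclude)
  metadata <- if (!is.null(cfg$metadata)) read_array_metadata(cfg$metadata) else NULL
  ann <- if (!is.null(cfg$annotations))
    read_annotations(cfg$annotations, obo = cfg$obo, propagate = cfg$propagate)
  else NULL

  for (cond in names(cfg$conditions)) {
    sel <- cfg$conditions[[cond]]
    sub <- if (length(sel)) {
      if (is.null(metadata)) stop("condition '", cond, "' needs metadata")
      do.call(subset_by_condition, c(list(expr, metadata), sel))
    } else expr
    cdir <- file.path(out_dir, cond)
    dir.create(cdir, showWarnings = FALSE)
    net <- hrr_network(sub)
    edges <- threshold_network(net, cfg$cutoff)
    write_edges(edges, file.path(cdir, "edges.tsv"))

    if (cfg$n_permutations > 0L) {
      nd <- permutation_null(sub, n_permutations = cfg$n_permutations,
                             seed = cfg$seed)
      write_significance_report(nd, file.path(cdir, "significance.tsv"),
                                alpha = cfg$alpha)
    }

    gc <- guide_clusters(net, k = cfg$k)
    if (isTRUE(cfg$write_guide))
      write_guide_clusters(gc, file.path(cdir, "guide_clusters.tsv"))

    if (length(cfg$inflation) > 1L) {
      if (is.null(ann)) stop("an inflation sweep needs annotations")
      sw <- sweep_inflation(edges, inflation_grid = cfg$inflation,
                            annotations = ann, min_size = cfg$min_size,
                            universe = cfg$universe)
      utils::write.table(sw$performance, file.path(cdir, "performance.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      cl <- sw$clusterings[[format(sw$best_inflation, nsmall = 1)]]
    } else {
      cl <- mcl(edges, inflation = cfg$inflation, min_size = cfg$min_size)
    }
    write_clusters(cl, file.path(cdir, "mcl_clusters.tsv"))
    conn <- cluster_connectivity(cl, edges)
    utils::write.table(as.data.frame(conn), file.path(cdir, "connectivity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    if (!is.null(ann)) {
      enr <- hypergeom_enrich(cl, ann, background = rownames(sub),
                              universe = cfg$universe)
      write_enrichment(enr, file.path(cdir, "enrichment.tsv"))
      if (length(cfg$inflation) == 1L) {
        perf <- clustering_performance(cl, ann, background = rownames(sub),
                                       universe = cfg$universe)
        utils::write.table(
          data.frame(dataset = cond, inflation = cfg$inflation,
                     n_clusters = perf$n_clusters,
                     specificity = perf$specificity,
                     sensitivity = perf$sensitivity,
                     f_measure = perf$f_measure),
          file.path(cdir, "performance.tsv"),
          sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }

    em <- esi(sub)
    write_esi(em, file.path(cdir, "esi.tsv"))
    if (length(cl$clusters)) {
      prof <- cesi(cl, em, metadata = metadata,
                   group = if (!is.null(metadata)) cfg$cesi_group else NULL)
      utils::write.table(prof, file.path(cdir, "cesi.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }

  inputs <- c(config = cfg_path, expression = cfg$expression,
              metadata = cfg$metadata, annotations = cfg$annotations,
              obo = cfg$obo)
  inputs <- inputs[!vapply(inputs, is.null, TRUE)]
  manifest <- list(
    tool = "hrrnet",
    version = as.character(utils::packageVersion("hrrnet")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    input_digests = as.list(tools::md5sum(unlist(inputs))),
    parameters = cfg[setdiff(names(cfg), c("expression", "metadata",
                                           "annotations", "obo"))])
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
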