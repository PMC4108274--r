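# Synthetic expression compendia with known ground truth. Each planted
# module follows a single-latent-factor model: in its active arrays every
# member gene is loading * factor + independent Gaussian noise, giving an
# expected pairwise correlation r = a^2 / (a^2 + sigma^2) in closed form
# (a = loading, sigma = member noise SD). Outside its active condition a
# module gene is flat noise, which is what makes condition-dependent
# sub-compendia recover condition-restricted modules. Per-array additive
# offsets emulate residual global intensity effects left after
# normalization.

#' Specification of one planted co-expression module
#'
#' @param size Number of member genes (>= 3).
#' @param within_correlation Target expected pairwise Pearson r in the
#'   active arrays, in (0, 1).
#' @param active Named list of metadata selector terms (as in
#'   [subset_by_condition()]), e.g. `list(organ = "fruit")`; `NULL` means
#'   active in every array.
#' @param base_expression Mean log-scale expression of member genes in their
#'   active arrays; outside the active condition members sit at the
#'   compendium background level, which is what makes a condition-restricted
#'   module tissue-specific in expression as well as in co-variation.
#' @param amplitude SD contributed by the shared latent factor (expression
#'   units); member noise is derived from it and `within_correlation`.
#' @param term Planted GO term id (default auto-generated).
#' @param annotated_fraction Fraction of member genes carrying the planted
#'   term.
#' @return A `module_spec` list.
#' @export
module_spec <- function(size, within_correlation = 0.9, active = NULL,
                        base_expression = 8, amplitude = 1.5, term = NULL,
                        annotated_fraction = 0.8) {
  if (size < 3L) stop("module size must be >= 3")
  if (within_correlation >= 1) stop("infeasible within_correlation >= 1")
  if (within_correlation <= 0) stop("within_correlation must be in (0, 1)")
  structure(list(size = as.integer(size),
                 within_correlation = within_correlation, active = active,
                 base_expression = base_expression, amplitude = amplitude,
                 term = term, annotated_fraction = annotated_fraction),
            class = "module_spec")
}

#' Default array metadata design
#'
#' Mirrors the composition of a typical plant microarray compendium: mostly
#' fruit and leaf arrays, dominated by one sub-species, with a majority of
#' biotic-stress experiments. Assignment is deterministic (contiguous blocks
#' per field, proportions rounded to the array count).
#'
#' @param n_arrays Number of arrays.
#' @return Metadata data.frame (array_id, subspecies, organ,
#'   experiment_type, description).
#' @export
default_metadata <- function(n_arrays) {
  fill <- function(levels, prop) {
    counts <- diff(round(cumsum(c(0, prop)) * n_arrays))
    counts[length(counts)] <- n_arrays - sum(counts[-length(counts)])
    rep(levels, times = counts)
  }
  data.frame(
    array_id = sprintf("arr%03d", seq_len(n_arrays)),
    subspecies = fill(c("sweet_orange", "mandarin", "lemon"), c(0.65, 0.2, 0.15)),
    organ = fill(c("fruit", "leaf", "root", "flower"), c(0.5, 0.25, 0.15, 0.1)),
    experiment_type = fill(c("biotic_stress", "development", "abiotic_stress"),
                           c(0.55, 0.3, 0.15)),
    description = sprintf("synthetic array %d", seq_len(n_arrays)),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic expression compendium with planted modules
#'
#' @param n_genes Total probesets (module sizes must fit inside).
#' @param n_arrays Number of arrays.
#' @param modules List of [module_spec()] objects.
#' @param metadata Optional metadata data.frame; default [default_metadata()].
#' @param noise_sd SD of background gene noise (and of module genes outside
#'   their active condition).
#' @param array_effect_sd SD of the per-array additive offset.
#' @param n_background_terms Number of non-planted GO terms scattered over
#'   all genes.
#' @param background_annotation_rate Probability a gene carries any given
#'   background term.
#' @param seed Integer seed; outputs are a deterministic function of it.
#' @return List of class `synthetic_compendium`: `expr` (matrix), `metadata`,
#'   `annotations` (`annotation_set`), `truth` (list: `membership` — named
#'   integer, 0 = background noise; `active_arrays` per module;
#'   `planted_terms` per module).
#' @export
simulate_compendium <- function(n_genes = 300L, n_arrays = 40L,
                                modules = list(), metadata = NULL,
                                noise_sd = 1, array_effect_sd = 0.25,
                                n_background_terms = 20L,
                                background_annotation_rate = 0.05,
                                seed = NULL) {
  sizes <- vapply(modules, function(m) m$size, 0L)
  if (sum(sizes) > n_genes) stop("module sizes exceed n_genes")
  if (is.null(metadata)) metadata <- default_metadata(n_arrays)
  if (nrow(metadata) != n_arrays) stop("metadata rows must equal n_arrays")
  gene_ids <- sprintf("ps%05d", seq_len(n_genes))
  membership <- stats::setNames(integer(n_genes), gene_ids)
  with_seed(seed, {
    offsets <- stats::rnorm(n_arrays, 0, array_effect_sd)
    x <- matrix(stats::rnorm(n_genes * n_arrays, 0, noise_sd), n_genes, n_arrays,
                dimnames = list(gene_ids, metadata$array_id)) + 7
    active_arrays <- list()
    planted_terms <- list()
    nxt <- 1L
    for (mi in seq_along(modules)) {
      sp <- modules[[mi]]
      rows <- nxt:(nxt + sp$size - 1L)
      nxt <- nxt + sp$size
      membership[rows] <- mi
      act <- active_selector(metadata, sp$active)
      r <- sp$within_correlation
      a <- sp$amplitude
      sigma <- a * sqrt((1 - r) / r)
      latent <- stats::rnorm(sum(act))
      block <- sp$base_expression +
        outer(rep(a, sp$size), latent) +
        matrix(stats::rnorm(sp$size * sum(act), 0, sigma), sp$size)
      x[rows, act] <- block
      x[rows, !act] <- 7 +
        matrix(stats::rnorm(sp$size * sum(!act), 0, noise_sd), sp$size)
      active_arrays[[mi]] <- metadata$array_id[act]
      planted_terms[[mi]] <- if (is.null(sp$term)) sprintf("GO:91%05d", mi) else sp$term
    }
    x <- sweep(x, 2L, offsets, "+")
    ann <- planted_annotations(gene_ids, membership, modules, planted_terms,
                               n_background_terms, background_annotation_rate)
  })
  names(active_arrays) <- names(planted_terms) <-
    if (length(modules)) paste0("module_", seq_along(modules)) else character(0)
  structure(list(expr = x, metadata = metadata, annotations = ann,
                 truth = list(membership = membership,
                              active_arrays = active_arrays,
                              planted_terms = planted_terms)),
            class = "synthetic_compendium")
}

#' @keywords internal
active_selector <- function(metadata, active) {
  if (is.null(active)) return(rep(TRUE, nrow(metadata)))
  keep <- rep(TRUE, nrow(metadata))
  for (field in names(active)) {
    if (!field %in% colnames(metadata)) stop("unknown metadata field: ", field)
    keep <- keep & metadata[[field]] %in% active[[field]]
  }
  if (!any(keep)) stop("module active condition matches no array")
  keep
}

#' @keywords internal
planted_annotations <- function(gene_ids, membership, modules, planted_terms,
                                n_background_terms, rate) {
  rows <- list()
  term_names <- character(0)
  for (mi in seq_along(modules)) {
    sp <- modules[[mi]]
    mem <- gene_ids[membership == mi]
    n_ann <- max(2L, ceiling(sp$annotated_fraction * length(mem)))
    term <- planted_terms[[mi]]
    rows[[length(rows) + 1L]] <- data.frame(
      probeset_id = mem[seq_len(min(n_ann, length(mem)))],
      term_id = term, namespace = "BP", stringsAsFactors = FALSE)
    term_names[term] <- sprintf("planted process of module %d", mi)
  }
  for (bt in seq_len(n_background_terms)) {
    term <- sprintf("GO:80%05d", bt)
    hit <- stats::runif(length(gene_ids)) < rate
    if (!any(hit)) next
    rows[[length(rows) + 1L]] <- data.frame(
      probeset_id = gene_ids[hit], term_id = term, namespace = "BP",
      stringsAsFactors = FALSE)
    term_names[term] <- sprintf("background process %d", bt)
  }
  assoc <- if (length(rows)) do.call(rbind, rows) else
    data.frame(probeset_id = character(0), term_id = character(0),
               namespace = character(0), stringsAsFactors = FALSE)
  annotation_set(assoc, term_names)
}

#' @export
print.synthetic_compendium <- function(x, ...) {
  k <- max(x$truth$membership)
  cat(sprintf("synthetic_compendium: %d genes x %d arrays, %d planted module(s), %d in background\n",
              nrow(x$expr), ncol(x$expr), k, sum(x$truth$membership == 0L)))
  invisible(x)
}

#' Write the four synthetic artifacts plus ground truth
#'
#' Emits `expression.tsv`, `metadata.tsv`, `annotations.tsv` and
#' `ground_truth.json` under `dir`.
#'
#' @param sim A `synthetic_compendium`.
#' @param dir Output directory (created if absent).
#' @export
write_compendium <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(sim$expr, file.path(dir, "expression.tsv"))
  write_array_metadata(sim$metadata, file.path(dir, "metadata.tsv"))
  write_annotations(sim$annotations, file.path(dir, "annotations.tsv"))
  truth <- sim$truth
  truth$membership <- as.list(truth$membership)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 = identical partitions, ~0 = independent.
#'
#' @param a,b Label vectors of equal length (any atomic type).
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("labelings differ in length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
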