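#' Read a normalized expression matrix
#'
#' Reads a tab-separated expression table (first column probeset identifiers,
#' header row array identifiers, values normalized log-scale intensities such
#' as RMA) into a numeric matrix with probesets as rows.
#'
#' @param path Path to a TSV file.
#' @param missing_policy How to treat probesets with missing (`NA`) values:
#'   `"drop_probeset"` removes the whole row (correlations and ranks are only
#'   comparable when every gene is measured over the same arrays);
#'   `"error"` aborts naming the offending cell.
#' @param exclude Optional character vector of probeset identifiers to drop
#'   before any analysis (e.g. platform control probesets).
#' @param normalize_ids If `TRUE`, upper-case probeset identifiers (microarray
#'   platforms mix spellings of the same probeset id).
#' @return A numeric matrix, probesets x arrays, with `dimnames`.
#' @export
read_expression <- function(path, missing_policy = c("drop_probeset", "error"),
                            exclude = NULL, normalize_ids = FALSE) {
  missing_policy <- match.arg(missing_policy)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", comment.char = "",
                          quote = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression file must have at least one array column")
  ids <- df[[1L]]
  if (normalize_ids) ids <- toupper(ids)
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate probeset identifier(s): ", paste(unique(dup), collapse = ", "))
  }
  arrays <- colnames(df)[-1L]
  dupa <- arrays[duplicated(arrays)]
  if (length(dupa)) {
    stop("duplicate array identifier(s): ", paste(unique(dupa), collapse = ", "))
  }
  vals <- suppressWarnings(
    vapply(df[-1L], function(col) as.numeric(ifelse(col %in% c("NA", "nan", ""), NA, col)),
           numeric(nrow(df))))
  if (nrow(df) == 1L) vals <- matrix(vals, nrow = 1L)
  dimnames(vals) <- list(ids, arrays)
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    if (missing_policy == "error") {
      stop(sprintf("non-numeric/missing value at probeset '%s', array '%s'",
                   ids[bad[1L, 1L]], arrays[bad[1L, 2L]]))
    }
    vals <- vals[-unique(bad[, 1L]), , drop = FALSE]
  }
  if (!is.null(exclude)) {
    if (normalize_ids) exclude <- toupper(exclude)
    vals <- vals[!rownames(vals) %in% exclude, , drop = FALSE]
  }
  validate_expression(vals)
  vals
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()]; numeric content round-trips at the printed
#' precision (15 significant digits).
#'
#' @param x Numeric matrix with probeset row names and array column names.
#' @param path Output path.
#' @export
write_expression <- function(x, path) {
  df <- data.frame(probeset_id = rownames(x), format(x, digits = 15, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @keywords internal
validate_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("expression must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix needs probeset row names and array column names")
  if (anyDuplicated(rownames(x))) stop("duplicate probeset identifiers")
  if (anyDuplicated(colnames(x))) stop("duplicate array identifiers")
  if (ncol(x) < 3L)
    stop("need at least 3 arrays (Pearson correlation is degenerate below that)")
  if (any(!is.finite(x))) stop("expression matrix contains non-finite values")
  invisible(x)
}

#' Read array metadata
#'
#' A TSV with header `array_id`, `subspecies`, `organ`, `experiment_type` and
#' optionally `description`, one row per array, used to slice a compendium
#' into condition-dependent sub-compendia.
#'
#' @param path Path to the metadata TSV.
#' @return A data.frame with one row per array.
#' @export
read_array_metadata <- function(path) {
  md <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          quote = "", comment.char = "", stringsAsFactors = FALSE)
  need <- c("array_id", "subspecies", "organ", "experiment_type")
  miss <- setdiff(need, colnames(md))
  if (length(miss)) stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(md$array_id))
    stop("duplicate array_id in metadata: ",
         paste(unique(md$array_id[duplicated(md$array_id)]), collapse = ", "))
  md
}

#' Write array metadata as TSV
#' @param metadata A metadata data.frame.
#' @param path Output path.
#' @export
write_array_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict a compendium to arrays matching a condition
#'
#' Condition-dependent co-expression networks (e.g. fruit-only or
#' stress-only compendia) are built from the columns whose metadata match a
#' conjunction of field = value terms.
#'
#' @param x Expression matrix (probesets x arrays).
#' @param metadata Metadata data.frame from [read_array_metadata()]; must
#'   cover every array of `x`.
#' @param ... Named selector terms, e.g. `organ = "fruit"`. Each value may be
#'   a vector (interpreted as "any of"); multiple arguments are ANDed.
#'   No terms selects every array.
#' @return The matrix restricted to matching arrays; probeset set unchanged.
#' @export
subset_by_condition <- function(x, metadata, ...) {
  sel <- list(...)
  if (!all(colnames(x) %in% metadata$array_id))
    stop("metadata does not cover every array of the matrix")
  md <- metadata[match(colnames(x), metadata$array_id), , drop = FALSE]
  keep <- rep(TRUE, ncol(x))
  for (field in names(sel)) {
    if (!field %in% colnames(md)) stop("unknown metadata field: ", field)
    keep <- keep & md[[field]] %in% sel[[field]]
  }
  if (sum(keep) < 3L)
    stop("selector matches ", sum(keep),
         " arrays; at least 3 are required for correlation")
  x[, keep, drop = FALSE]
}

# ---- GO annotations ---------------------------------------------------------

#' Read a probeset -> GO annotation table
#'
#' Expects a TSV of (probeset_id, term_id, namespace[, description]) where
#' namespace is one of `BP`, `MF`, `CC`. With an OBO ontology and
#' `propagate = TRUE` every association is propagated to all ancestor terms of
#' the same namespace (the GO true-path rule).
#'
#' @param path Annotation TSV path.
#' @param obo Optional path to an OBO 1.2 ontology file, or an object from
#'   [read_obo()].
#' @param propagate Apply true-path propagation using the ontology graph.
#' @return An object of class `annotation_set`: a list with `associations`
#'   (data.frame: probeset_id, term_id, namespace), `term_names` (named
#'   character) and optionally `dag` (named list: term -> parent terms).
#' @export
read_annotations <- function(path, obo = NULL, propagate = FALSE) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          quote = "", comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("annotation file needs >= 3 columns")
  colnames(df)[1:3] <- c("probeset_id", "term_id", "namespace")
  bad <- setdiff(unique(df$namespace), c("BP", "MF", "CC"))
  if (length(bad)) stop("unknown GO namespace(s): ", paste(bad, collapse = ", "))
  term_names <- character(0)
  if (ncol(df) >= 4L) {
    term_names <- tapply(df[[4L]], df$term_id, `[`, 1L)
    term_names <- stats::setNames(as.character(term_names), names(term_names))
  }
  ann <- annotation_set(df[, c("probeset_id", "term_id", "namespace")], term_names)
  if (!is.null(obo)) {
    ont <- if (is.character(obo)) read_obo(obo) else obo
    ann$dag <- ont$parents
    missing_names <- setdiff(ann$associations$term_id, names(term_names))
    ann$term_names[missing_names] <- ont$names[missing_names]
    if (propagate) ann <- propagate_annotations(ann)
  } else if (propagate) {
    warning("propagate = TRUE but no ontology given; associations left as-is")
  }
  ann
}

#' Construct an annotation set
#' @param associations data.frame (probeset_id, term_id, namespace).
#' @param term_names Named character vector of term descriptions.
#' @param dag Optional named list mapping term_id to its parent term ids.
#' @export
annotation_set <- function(associations, term_names = character(0), dag = NULL) {
  associations <- unique(associations[, c("probeset_id", "term_id", "namespace")])
  rownames(associations) <- NULL
  structure(list(associations = associations, term_names = term_names, dag = dag),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  a <- x$associations
  cat(sprintf("annotation_set: %d associations, %d probesets, %d terms (%s)%s\n",
              nrow(a), length(unique(a$probeset_id)), length(unique(a$term_id)),
              paste(sort(unique(a$namespace)), collapse = "/"),
              if (is.null(x$dag)) "" else ", with ontology DAG"))
  invisible(x)
}

#' Parse an OBO 1.2 ontology file
#'
#' Minimal parser keeping, per `[Term]` stanza: id, name, namespace and
#' `is_a` parents. Obsolete terms are skipped. Namespaces are mapped to
#' BP/MF/CC.
#'
#' @param path Path to an OBO file.
#' @return A list with `parents` (named list term -> parent ids), `names`
#'   (named character) and `namespace` (named character, BP/MF/CC).
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  parents <- list(); nm <- character(0); ns <- character(0)
  cur <- NULL; cur_par <- character(0); cur_name <- NA_character_
  cur_ns <- NA_character_; obsolete <- FALSE; in_term <- FALSE
  flush <- function() {
    if (!is.null(cur) && !obsolete) {
      parents[[cur]] <<- cur_par
      nm[cur] <<- cur_name
      ns[cur] <<- cur_ns
    }
  }
  ns_map <- c(biological_process = "BP", molecular_function = "MF",
              cellular_component = "CC")
  for (ln in lines) {
    if (startsWith(ln, "[")) {
      flush()
      in_term <- identical(ln, "[Term]")
      cur <- NULL; cur_par <- character(0); cur_name <- NA_character_
      cur_ns <- NA_character_; obsolete <- FALSE
    } else if (in_term) {
      if (startsWith(ln, "id: ")) cur <- sub("^id: ", "", ln)
      else if (startsWith(ln, "name: ")) cur_name <- sub("^name: ", "", ln)
      else if (startsWith(ln, "namespace: ")) {
        raw <- sub("^namespace: ", "", ln)
        cur_ns <- if (raw %in% names(ns_map)) ns_map[[raw]] else raw
      } else if (startsWith(ln, "is_a: ")) {
        cur_par <- c(cur_par, sub("\\s*!.*$", "", sub("^is_a: ", "", ln)))
      } else if (identical(ln, "is_obsolete: true")) obsolete <- TRUE
    }
  }
  flush()
  check_dag_acyclic(parents)
  list(parents = parents, names = nm, namespace = ns)
}

#' @keywords internal
check_dag_acyclic <- function(parents) {
  if (!length(parents)) return(invisible(TRUE))
  edges <- unlist(lapply(names(parents), function(t) {
    p <- intersect(parents[[t]], names(parents))
    if (length(p)) rbind(t, p) else NULL
  }))
  if (is.null(edges)) return(invisible(TRUE))
  g <- igraph::make_graph(edges, directed = TRUE)
  if (!igraph::is_dag(g)) stop("ontology graph contains a cycle")
  invisible(TRUE)
}

#' @keywords internal
term_ancestors <- function(term, parents, memo = new.env(parent = emptyenv())) {
  if (!is.null(memo[[term]])) return(memo[[term]])
  ps <- parents[[term]]
  anc <- character(0)
  for (p in ps) {
    anc <- c(anc, p)
    if (!is.null(parents[[p]])) anc <- c(anc, term_ancestors(p, parents, memo))
  }
  anc <- unique(anc)
  memo[[term]] <- anc
  anc
}

#' Apply the GO true-path rule to an annotation set
#'
#' Every probeset annotated to a term becomes annotated to all ancestors of
#' that term within the same namespace. Terms absent from the ontology are
#' kept unpropagated with a warning. Idempotent.
#'
#' @param ann An `annotation_set` whose `dag` is populated.
#' @return The propagated `annotation_set`.
#' @export
propagate_annotations <- function(ann) {
  stopifnot(inherits(ann, "annotation_set"))
  if (is.null(ann$dag)) stop("annotation set has no ontology DAG to propagate over")
  parents <- ann$dag
  check_dag_acyclic(parents)
  a <- ann$associations
  known <- a$term_id %in% names(parents)
  if (any(!known)) {
    warning("term(s) absent from ontology, kept unpropagated: ",
            paste(unique(a$term_id[!known]), collapse = ", "))
  }
  memo <- new.env(parent = emptyenv())
  extra <- lapply(which(known), function(i) {
    anc <- term_ancestors(a$term_id[i], parents, memo)
    if (!length(anc)) return(NULL)
    data.frame(probeset_id = a$probeset_id[i], term_id = anc,
               namespace = a$namespace[i], stringsAsFactors = FALSE)
  })
  extra <- do.call(rbind, extra)
  out <- unique(rbind(a, extra))
  rownames(out) <- NULL
  ann$associations <- out
  ann
}

#' Write an annotation set as TSV
#' @param ann An `annotation_set`.
#' @param path Output path.
#' @export
write_annotations <- function(ann, path) {
  a <- ann$associations
  a$description <- unname(ann$term_names[a$term_id])
  a$description[is.na(a$description)] <- ""
  utils::write.table(a, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
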