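# Expression specificity. Two-stage standardization: first each array is
# z-scored across probesets (removing per-array location/scale, e.g. global
# intensity differences), then each probeset is z-scored across arrays of
# the stage-1 matrix. The result expresses, in SD units, how unusually high
# a gene sits in one array relative to its own profile: > 1 is read as
# "well expressed" in that condition, > 5 as "specifically expressed".

#' Probeset expression specificity index (ESI)
#'
#' @param x Expression matrix, probesets x arrays (>= 3 arrays, >= 2
#'   probesets).
#' @param sd_denominator `"population"` (divide by n; default — makes the
#'   one-hot closed form sqrt(n - 1) exact) or `"sample"` (n - 1).
#' @return Numeric matrix of class `esi_matrix`, same dimnames as `x`.
#'   Probesets whose stage-1 profile is constant across arrays carry ESI 0
#'   everywhere (no specificity signal to standardize).
#' @export
esi <- function(x, sd_denominator = c("population", "sample")) {
  sd_denominator <- match.arg(sd_denominator)
  validate_expression(x)
  if (nrow(x) < 2L) stop("need at least 2 probesets")
  n <- nrow(x); m <- ncol(x)
  denom_c <- if (sd_denominator == "population") n else n - 1L
  denom_r <- if (sd_denominator == "population") m else m - 1L
  # stage 1: within-array z-score (over probesets)
  cm <- colMeans(x)
  s1 <- sweep(x, 2L, cm)
  csd <- sqrt(colSums(s1^2) / denom_c)
  if (any(csd == 0)) stop("array(s) with zero variance across probesets: ",
                          paste(colnames(x)[csd == 0], collapse = ", "))
  s1 <- sweep(s1, 2L, csd, "/")
  # stage 2: within-probeset z-score (over arrays)
  rm_ <- rowMeans(s1)
  s2 <- s1 - rm_
  rsd <- sqrt(rowSums(s2^2) / denom_r)
  degen <- rsd == 0
  rsd[degen] <- 1
  s2 <- s2 / rsd
  s2[degen, ] <- 0
  structure(s2, class = c("esi_matrix", "matrix"),
            sd_denominator = sd_denominator)
}

#' @export
print.esi_matrix <- function(x, ...) {
  cat(sprintf("esi_matrix: %d probesets x %d arrays (%s SD); %d values > 1, %d > 5\n",
              nrow(x), ncol(x), attr(x, "sd_denominator"),
              sum(x > 1), sum(x > 5)))
  invisible(x)
}

#' Cluster cumulative expression specificity (cESI)
#'
#' Per array, the fraction of a cluster's members with ESI above the
#' threshold; when `group` names a metadata field, per-array fractions are
#' additionally averaged within each level of that field (robust to unequal
#' group sizes).
#'
#' @param clusters Clustering object, list of member vectors, or a single
#'   character vector of probeset ids.
#' @param esi_matrix An `esi_matrix` covering all cluster members.
#' @param metadata Optional metadata data.frame (needed when `group` given).
#' @param group Optional metadata field name (e.g. `"organ"`) to aggregate
#'   arrays by.
#' @param threshold ESI threshold defining "expressed" (default 1).
#' @param all_profiles Keep zero rows (default `TRUE`); `FALSE` reports only
#'   array/group entries with cesi > 0.
#' @return Long data.frame: cluster_id, unit (`"array"` or the group field),
#'   label (array id or group level), cesi in [0, 1].
#' @export
cesi <- function(clusters, esi_matrix, metadata = NULL, group = NULL,
                 threshold = 1, all_profiles = TRUE) {
  cl <- normalize_clusters(clusters)
  if (any(lengths(cl) == 0L)) stop("empty cluster(s): ",
                                   paste(names(cl)[lengths(cl) == 0L], collapse = ", "))
  missing <- setdiff(unique(unlist(cl)), rownames(esi_matrix))
  if (length(missing)) stop("cluster member(s) absent from ESI matrix: ",
                            paste(utils::head(missing, 5L), collapse = ", "))
  arrays <- colnames(esi_matrix)
  rows <- lapply(names(cl), function(ci) {
    sub <- esi_matrix[cl[[ci]], , drop = FALSE]
    frac <- colMeans(sub > threshold)
    data.frame(cluster_id = ci, unit = "array", label = arrays,
               cesi = unname(frac), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(group)) {
    if (is.null(metadata)) stop("group aggregation needs metadata")
    if (!group %in% colnames(metadata)) stop("unknown metadata field: ", group)
    gl <- metadata[[group]][match(out$label, metadata$array_id)]
    if (anyNA(gl)) stop("metadata does not cover every ESI array")
    agg <- stats::aggregate(cesi ~ cluster_id + gl, data = cbind(out, gl = gl),
                            FUN = mean)
    out <- data.frame(cluster_id = agg$cluster_id, unit = group,
                      label = agg$gl, cesi = agg$cesi, stringsAsFactors = FALSE)
  }
  if (!all_profiles) out <- out[out$cesi > 0, , drop = FALSE]
  out <- out[order(out$cluster_id, out$label, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an ESI matrix as TSV
#' @param esi_matrix An `esi_matrix`.
#' @param path Output path.
#' @export
write_esi <- function(esi_matrix, path) {
  m <- esi_matrix
  attr(m, "class") <- NULL
  write_expression(m, path)
}
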