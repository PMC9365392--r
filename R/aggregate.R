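#' Gene-by-group profile matrix
#'
#' Aggregated expression: one column per retained group (metacell, cluster,
#' region, neurotransmitter class, ...), with the number of cells behind
#' each column recorded. Groups are only retained when they contain at least
#' the minimum number of cells used at aggregation time.
#'
#' @param values numeric gene x group matrix.
#' @param genes,groups identifiers.
#' @param unit unit of the aggregated values.
#' @param n_cells integer vector, cells per retained group.
#' @return A `ProfileMatrix`.
#' @export
profile_matrix <- function(values, genes, groups, unit, n_cells) {
  values <- as.matrix(values)
  genes <- as.character(genes)
  groups <- as.character(groups)
  stopifnot(nrow(values) == length(genes), ncol(values) == length(groups),
            length(n_cells) == length(groups))
  if (anyNA(values) || any(!is.finite(values)) || any(values < 0)) {
    stop("validation error: profile values must be finite and >= 0",
         call. = FALSE)
  }
  dimnames(values) <- list(genes, groups)
  structure(list(genes = genes, groups = groups, values = values,
                 unit = unit, n_cells = as.integer(n_cells)),
            class = "ProfileMatrix")
}

#' @export
print.ProfileMatrix <- function(x, ...) {
  cat("ProfileMatrix:", length(x$genes), "genes x", length(x$groups),
      "groups, unit =", x$unit, "\n")
  invisible(x)
}

#' @export
dim.ProfileMatrix <- function(x) dim(x$values)

#' Interquartile trimmed mean
#'
#' Sorts, removes `floor(n * trim)` values from each end, and averages the
#' remainder (`trim = 0.25` keeps the central 50% — the trimmed-mean
#' dialect used for droplet-atlas CPM profiles).
#'
#' @param x numeric vector.
#' @param trim fraction removed from each end (default 0.25).
#' @return The trimmed mean.
#' @export
trimmed_mean_iqr <- function(x, trim = 0.25) {
  n <- length(x)
  k <- floor(n * trim)
  s <- sort(x)
  mean(s[(k + 1):(n - k)])
}

#' Aggregate cells into group profiles
#'
#' Averages per-cell normalized expression within groups defined by a cell
#' metadata column, the step that turns a single-cell matrix into a
#' metacell/cluster profile. Groups with fewer than `min_cells` cells are
#' dropped (atlas convention: categories with fewer than 5 single cells are
#' not displayed); cells missing from the metadata are excluded and counted.
#'
#' @param m a [count_matrix()], normally already normalized
#'   (`cp10k_log2`).
#' @param meta a [cell_meta()] table.
#' @param key metadata column to group by.
#' @param stat `"mean"` or `"trimmed_mean_25_75"` (interquartile trimmed
#'   mean, the dialect used for droplet-atlas CPM profiles).
#' @param min_cells minimum cells per retained group (default 5).
#' @return A [profile_matrix()] with attributes `"dropped_groups"` (named
#'   integer vector of cell counts of groups below `min_cells`) and
#'   `"unannotated_cells"` (cells absent from `meta`).
#' @export
aggregate_by_group <- function(m, meta, key,
                               stat = c("mean", "trimmed_mean_25_75"),
                               min_cells = 5) {
  stopifnot(inherits(m, "CountMatrix"))
  stat <- match.arg(stat)
  if (!key %in% names(meta)) {
    stop("key '", key, "' not found in cell metadata", call. = FALSE)
  }
  labels <- stats::setNames(as.character(meta[[key]]), meta$cell)
  known <- m$cells %in% names(labels)
  if (!all(known)) {
    message(sum(!known), " cell(s) without metadata excluded from aggregation")
  }
  cells <- m$cells[known]
  grp <- labels[cells]
  sizes <- table(grp)
  keep <- names(sizes)[sizes >= min_cells]
  if (length(keep) == 0) {
    stop("empty-profile error: no group has >= ", min_cells, " cells",
         call. = FALSE)
  }
  dropped <- sizes[setdiff(names(sizes), keep)]
  if (length(dropped)) {
    message(length(dropped), " group(s) below min_cells = ", min_cells,
            " dropped: ", paste(names(dropped), collapse = ", "))
  }
  keep <- keep[order(match(keep, grp))]  # groups in first-appearance order
  v <- m$values[, known, drop = FALSE]
  agg <- vapply(keep, function(g) {
    sub <- v[, grp == g, drop = FALSE]
    if (stat == "mean") {
      rowMeans(sub)
    } else {
      apply(sub, 1, trimmed_mean_iqr)
    }
  }, numeric(nrow(v)))
  agg <- matrix(agg, nrow = nrow(v),
                dimnames = list(m$genes, keep))
  out <- profile_matrix(agg, m$genes, keep, unit = m$unit,
                        n_cells = as.integer(sizes[keep]))
  attr(out, "dropped_groups") <- stats::setNames(as.integer(dropped),
                                                 names(dropped))
  attr(out, "unannotated_cells") <- m$cells[!known]
  out
}

#' Rank-order a profile matrix by descending means
#'
#' Row and column orderings for ranked heatmaps: rows sorted by descending
#' row mean, columns by descending column mean, ties kept in input order.
#'
#' @param p a [profile_matrix()].
#' @return list with integer vectors `row_order` and `col_order`.
#' @export
rank_order <- function(p) {
  stopifnot(inherits(p, "ProfileMatrix"))
  rm <- rowMeans(p$values)
  cm <- colMeans(p$values)
  list(row_order = order(-rm, seq_along(rm)),
       col_order = order(-cm, seq_along(cm)))
}

#' Hierarchical leaf ordering of a profile matrix
#'
#' Agglomerative clustering leaf order for heatmap arrangement. Defaults
#' (euclidean distance, average linkage) are exposed because the tools used
#' interactively for such heatmaps rarely document theirs.
#'
#' @param p a [profile_matrix()].
#' @param axis `"rows"` (genes) or `"cols"` (groups).
#' @param metric distance metric for [stats::dist()].
#' @param linkage agglomeration method for [stats::hclust()].
#' @return Integer leaf order along the chosen axis.
#' @export
hierarchical_order <- function(p, axis = c("rows", "cols"),
                               metric = "euclidean", linkage = "average") {
  stopifnot(inherits(p, "ProfileMatrix"))
  axis <- match.arg(axis)
  x <- if (axis == "rows") p$values else t(p$values)
  if (nrow(x) < 2) {
    stop("hierarchical ordering needs >= 2 items on the chosen axis",
         call. = FALSE)
  }
  stats::hclust(stats::dist(x, method = metric), method = linkage)$order
}

#' Write a profile matrix as TSV with a sidecar JSON of group cell counts
#'
#' @param p a [profile_matrix()].
#' @param path output TSV path; the sidecar is `<path>.groups.json`.
#' @return `path`, invisibly.
#' @export
write_profile_matrix <- function(p, path) {
  stopifnot(inherits(p, "ProfileMatrix"))
  df <- data.frame(gene = p$genes, p$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("gene", p$groups)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(unit = p$unit,
         n_cells = stats::setNames(as.list(p$n_cells), p$groups)),
    paste0(path, ".groups.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a profile matrix written by [write_profile_matrix()]
#'
#' @param path TSV path with sidecar `<path>.groups.json`.
#' @return A [profile_matrix()].
#' @export
read_profile_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  side <- jsonlite::read_json(paste0(path, ".groups.json"),
                              simplifyVector = TRUE)
  genes <- as.character(df[[1]])
  v <- as.matrix(df[, -1, drop = FALSE])
  groups <- colnames(df)[-1]
  profile_matrix(v, genes, groups, unit = side$unit,
                 n_cells = as.integer(side$n_cells[groups]))
}
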