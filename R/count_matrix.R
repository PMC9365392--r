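#' Gene-by-cell expression matrix
#'
#' Container for a gene x cell (or gene x sample) expression matrix together
#' with its identifiers and unit. Values are dense; sparse inputs (Matrix
#' Market) are densified on read. Units track what the values mean:
#' `counts` (raw UMI/read counts), `fpkm`, `cp10k_log2` (log2 of counts per
#' 10,000 + 1) or `cpm_log2_trimmed` (trimmed-mean log2(CPM+1) profiles from
#' droplet atlases).
#'
#' @param values numeric matrix, genes in rows, cells in columns.
#' @param genes character vector of gene symbols (one per row).
#' @param cells character vector of cell identifiers (one per column).
#' @param unit one of `"counts"`, `"fpkm"`, `"cp10k_log2"`,
#'   `"cpm_log2_trimmed"`.
#' @return An object of class `CountMatrix`: a list with elements `genes`,
#'   `cells`, `values` (with dimnames set) and `unit`.
#' @export
count_matrix <- function(values, genes, cells,
                         unit = c("counts", "fpkm", "cp10k_log2",
                                  "cpm_log2_trimmed")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  genes <- as.character(genes)
  cells <- as.character(cells)
  if (nrow(values) != length(genes) || ncol(values) != length(cells)) {
    stop("format error: matrix is ", nrow(values), " x ", ncol(values),
         " but ", length(genes), " gene and ", length(cells),
         " cell identifiers were supplied", call. = FALSE)
  }
  if (anyNA(values)) {
    stop("validation error: matrix contains missing values", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("validation error: matrix contains negative values", call. = FALSE)
  }
  .check_unique_genes(genes)
  if (anyDuplicated(cells)) {
    stop("validation error: duplicated cell identifiers: ",
         paste(unique(cells[duplicated(cells)]), collapse = ", "),
         call. = FALSE)
  }
  dimnames(values) <- list(genes, cells)
  structure(list(genes = genes, cells = cells, values = values, unit = unit),
            class = "CountMatrix")
}

# Duplicate gene symbols are checked on the case-insensitive canonical key so
# that e.g. "Zdhhc5" and "ZDHHC5" collide; the error names the offenders.
.check_unique_genes <- function(genes) {
  key <- canonicalize_genes(genes)
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("validation error: duplicated gene symbols (after canonicalization): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat("CountMatrix:", length(x$genes), "genes x", length(x$cells),
      "cells, unit =", x$unit, "\n")
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$values)

#' Read an expression matrix
#'
#' Reads a gene x cell matrix from dense TSV (genes as rows, header row of
#' cell identifiers, first column gene symbols), Matrix Market MTX with
#' sidecar one-symbol-per-line gene and cell name files, or a loom (HDF5)
#' file with row attribute `"Gene"`. Input gene order is preserved.
#'
#' @param path path to the matrix file.
#' @param format `"tsv"`, `"mtx"` or `"loom"`.
#' @param unit unit of the stored values, default `"counts"`; pass `"fpkm"`
#'   for FPKM tables.
#' @param genes_path,cells_path sidecar name files (MTX only). Default
#'   `<path>.genes.tsv` / `<path>.cells.tsv`.
#' @param cells_attr loom column attribute holding cell identifiers
#'   (default `"CellID"`).
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, format = c("tsv", "mtx", "loom"),
                              unit = "counts",
                              genes_path = NULL, cells_path = NULL,
                              cells_attr = "CellID") {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  switch(format,
    tsv = .read_cm_tsv(path, unit),
    mtx = .read_cm_mtx(path, unit, genes_path, cells_path),
    loom = .read_cm_loom(path, unit, cells_attr)
  )
}

.read_cm_tsv <- function(path, unit) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) {
    stop("format error: TSV matrix needs a gene column plus >= 1 cell column",
         call. = FALSE)
  }
  genes <- as.character(df[[1]])
  values <- as.matrix(df[, -1, drop = FALSE])
  count_matrix(values, genes, colnames(df)[-1], unit = unit)
}

.read_cm_mtx <- function(path, unit, genes_path, cells_path) {
  if (is.null(genes_path)) genes_path <- paste0(path, ".genes.tsv")
  if (is.null(cells_path)) cells_path <- paste0(path, ".cells.tsv")
  for (p in c(genes_path, cells_path)) {
    if (!file.exists(p)) {
      stop("format error: MTX sidecar name file not found: ", p,
           call. = FALSE)
    }
  }
  m <- as.matrix(Matrix::readMM(path))
  genes <- readLines(genes_path)
  cells <- readLines(cells_path)
  if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
    stop("format error: MTX dimensions ", nrow(m), " x ", ncol(m),
         " do not match sidecar files (", length(genes), " genes, ",
         length(cells), " cells)", call. = FALSE)
  }
  count_matrix(m, genes, cells, unit = unit)
}

.read_cm_loom <- function(path, unit, cells_attr) {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    stop("loom reading requires the 'rhdf5' package", call. = FALSE)
  }
  m <- rhdf5::h5read(path, "matrix")
  genes <- as.character(rhdf5::h5read(path, "row_attrs/Gene"))
  cells <- as.character(rhdf5::h5read(path, paste0("col_attrs/", cells_attr)))
  rhdf5::h5closeAll()
  # loom stores genes x cells row-major; HDF5 dimension order can arrive
  # flipped depending on the writer, so orient by the attribute lengths
  if (nrow(m) == length(cells) && ncol(m) == length(genes) &&
      length(genes) != length(cells)) {
    m <- t(m)
  }
  if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
    stop("format error: loom matrix dimensions do not match row/col attributes",
         call. = FALSE)
  }
  count_matrix(m, genes, cells, unit = unit)
}

#' Write an expression matrix as TSV
#'
#' Dense TSV, genes as rows, first column `gene`, header row of cell
#' identifiers. Read back with [read_count_matrix()] `format = "tsv"`.
#'
#' @param m a [count_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(m, path) {
  stopifnot(inherits(m, "CountMatrix"))
  df <- data.frame(gene = m$genes, m$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("gene", m$cells)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cell metadata table
#'
#' One row per cell with grouping labels (cluster/metacell, region,
#' neurotransmitter, taxonomy, ...). The first column must be `cell`.
#'
#' @param df data.frame with a `cell` column and one or more label columns.
#' @return A validated data.frame of class `CellMeta`.
#' @export
cell_meta <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"cell" %in% names(df)) {
    stop("validation error: cell metadata needs a 'cell' column",
         call. = FALSE)
  }
  if (anyDuplicated(df$cell)) {
    stop("validation error: duplicated cell identifiers in metadata: ",
         paste(unique(df$cell[duplicated(df$cell)]), collapse = ", "),
         call. = FALSE)
  }
  df$cell <- as.character(df$cell)
  class(df) <- c("CellMeta", "data.frame")
  df
}

#' @rdname cell_meta
#' @param path TSV file with header, first column `cell`.
#' @export
read_cell_meta <- function(path) {
  cell_meta(utils::read.delim(path, header = TRUE, sep = "\t",
                              check.names = FALSE, stringsAsFactors = FALSE))
}
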