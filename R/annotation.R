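#' Gene annotation table
#'
#' Holds the background universe of gene symbols (e.g. all protein-coding
#' genes expressed in the postnatal brain) plus one or more named annotation
#' flags (e.g. a curated set of validated S-palmitoylation substrates). Every
#' flagged gene must lie in the universe; genes flagged outside the universe
#' are dropped with a warning.
#'
#' @param universe character vector of gene symbols (background).
#' @param flags named list of character vectors, one per annotation set.
#' @return An `AnnotationTable`: list with `universe` and `flags`.
#' @export
annotation_table <- function(universe, flags = list()) {
  universe <- unique(canonicalize_genes(universe))
  if (length(universe) == 0) {
    stop("validation error: empty annotation universe", call. = FALSE)
  }
  if (length(flags) && is.null(names(flags))) {
    stop("validation error: annotation flag sets must be named",
         call. = FALSE)
  }
  flags <- lapply(flags, function(g) {
    g <- unique(canonicalize_genes(g))
    out <- setdiff(g, universe)
    if (length(out)) {
      warning("dropping ", length(out),
              " flagged gene(s) absent from the universe: ",
              paste(utils::head(out, 10), collapse = ", "),
              if (length(out) > 10) ", ..." else "", call. = FALSE)
    }
    intersect(g, universe)
  })
  structure(list(universe = universe, flags = flags),
            class = "AnnotationTable")
}

#' @export
print.AnnotationTable <- function(x, ...) {
  cat("AnnotationTable: universe of", length(x$universe), "genes;",
      length(x$flags), "flag set(s)\n")
  for (nm in names(x$flags)) {
    cat("  ", nm, ": ", length(x$flags[[nm]]), " genes\n", sep = "")
  }
  invisible(x)
}

#' Read an annotation table from flat files
#'
#' The universe file and each flag file are one-symbol-per-line (or TSV whose
#' first column is the symbol). Flag sets are named by `names(flag_paths)`,
#' falling back to the file base name.
#'
#' @param universe_path path to the background gene list.
#' @param flag_paths named character vector of flag file paths.
#' @return An [annotation_table()].
#' @export
read_annotation_table <- function(universe_path, flag_paths = character()) {
  read_symbols <- function(p) {
    x <- utils::read.delim(p, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)[[1]]
    as.character(x)
  }
  universe <- read_symbols(universe_path)
  nms <- names(flag_paths)
  if (is.null(nms)) nms <- rep("", length(flag_paths))
  nms[nms == ""] <- sub("\\.[^.]*$", "", basename(flag_paths[nms == ""]))
  flags <- stats::setNames(lapply(flag_paths, read_symbols), nms)
  annotation_table(universe, flags)
}

#' Write an annotation table
#'
#' Writes the universe and each flag set as one-symbol-per-line text files:
#' `<stem>.universe.tsv` and `<stem>.<flag>.tsv`.
#'
#' @param tab an [annotation_table()].
#' @param stem output path stem.
#' @return The written paths, invisibly.
#' @export
write_annotation_table <- function(tab, stem) {
  stopifnot(inherits(tab, "AnnotationTable"))
  paths <- paste0(stem, ".universe.tsv")
  writeLines(tab$universe, paths)
  for (nm in names(tab$flags)) {
    p <- paste0(stem, ".", nm, ".tsv")
    writeLines(tab$flags[[nm]], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
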