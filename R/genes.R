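#' Canonicalize gene symbols
#'
#' Maps symbols to a deterministic, idempotent mouse-style display form:
#' first character upper case, the rest lower case, alphanumeric suffixes
#' preserved (`"ZDHHC9"` -> `"Zdhhc9"`, `"golga7b"` -> `"Golga7b"`).
#' Matching across studies is done on this key, so symbol case never splits
#' a gene.
#'
#' @param symbols character vector of gene symbols.
#' @return character vector of the same length.
#' @export
canonicalize_genes <- function(symbols) {
  symbols <- as.character(symbols)
  out <- tolower(symbols)
  substr(out, 1, 1) <- toupper(substr(out, 1, 1))
  out
}

# the 24 mouse Zdhhc palmitoyl-acyltransferase genes: Zdhhc1-Zdhhc25 with
# Zdhhc10 absent from the family in mouse nomenclature
.zdhhc_genes <- function() paste0("Zdhhc", setdiff(1:25, 10))

.depalm_genes <- function() {
  c("Ppt1", "Lypla1", "Lypla2", "Abhd4", "Abhd6", "Abhd10", "Abhd12",
    "Abhd13", "Abhd16a", "Abhd17a", "Abhd17b", "Abhd17c")
}

.accessory_genes <- function() c("Golga7", "Golga7b", "Selenok")

#' Gene panel of the S-palmitoylation machinery
#'
#' The built-in panel holds the 39 mouse genes that regulate
#' S-palmitoylation: the 24 ZDHHC palmitoyl-acyltransferases, 12
#' de-palmitoylating enzymes (PPT, APT/LYPLA and ABHD serine hydrolases
#' inhibited by palmitate-mimetic inhibitors), and the 3 ZDHHC accessory
#' proteins (GOLGA7, GOLGA7B, SELENOK). A user panel is a TSV with columns
#' `gene` and `category` (values `zdhhc`, `depalmitoylating`, `accessory`).
#'
#' @param path optional path to a user panel TSV; omit for the built-in
#'   panel.
#' @return A `GenePanel`: data.frame with columns `gene`, `category`.
#' @export
load_gene_panel <- function(path = NULL) {
  if (is.null(path)) {
    df <- data.frame(
      gene = c(.zdhhc_genes(), .depalm_genes(), .accessory_genes()),
      category = rep(c("zdhhc", "depalmitoylating", "accessory"),
                     times = c(24L, 12L, 3L)),
      stringsAsFactors = FALSE
    )
  } else {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    if (!all(c("gene", "category") %in% names(df))) {
      stop("validation error: panel file needs 'gene' and 'category' columns",
           call. = FALSE)
    }
    df$gene <- canonicalize_genes(df$gene)
    bad <- setdiff(unique(df$category),
                   c("zdhhc", "depalmitoylating", "accessory"))
    if (length(bad)) {
      stop("validation error: unknown panel categories: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (anyDuplicated(df$gene)) {
    stop("validation error: duplicated panel genes: ",
         paste(unique(df$gene[duplicated(df$gene)]), collapse = ", "),
         call. = FALSE)
  }
  class(df) <- c("GenePanel", "data.frame")
  df
}
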