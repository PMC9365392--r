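#' Cell-type z-scores of an abundance table
#'
#' Standardizes each gene's abundance across cell types:
#' `z = (x - mean) / sd` with the sample (n-1) standard deviation. Applied
#' separately to mRNA and protein abundance tables before comparing
#' cell-type enrichment patterns across the two measurement modalities.
#' Zero-variance genes cannot be standardized and are dropped with a
#' message.
#'
#' @param abundance numeric gene x cell-type matrix (rownames = genes), or
#'   data.frame whose first column is the gene symbol.
#' @param source tag recording the modality (`"mrna"` or `"protein"`).
#' @return A `ZScoreTable`: list with `genes`, `celltypes`, `z` (matrix)
#'   and `source`; attribute `"dropped_genes"` lists zero-variance genes.
#' @export
celltype_zscores <- function(abundance, source = c("mrna", "protein")) {
  source <- match.arg(source)
  if (is.data.frame(abundance)) {
    genes <- as.character(abundance[[1]])
    abundance <- as.matrix(abundance[, -1, drop = FALSE])
    rownames(abundance) <- genes
  }
  abundance <- as.matrix(abundance)
  if (ncol(abundance) < 2) {
    stop("z-scores need >= 2 cell types", call. = FALSE)
  }
  if (is.null(rownames(abundance))) {
    stop("validation error: abundance matrix needs gene rownames",
         call. = FALSE)
  }
  mu <- rowMeans(abundance)
  sdv <- apply(abundance, 1, stats::sd)
  drop <- sdv == 0
  if (any(drop)) {
    message(sum(drop), " zero-variance gene(s) dropped from z-scoring: ",
            paste(utils::head(rownames(abundance)[drop], 5), collapse = ", "),
            if (sum(drop) > 5) ", ..." else "")
  }
  if (all(drop)) {
    stop("validation error: every gene has zero variance", call. = FALSE)
  }
  z <- (abundance[!drop, , drop = FALSE] - mu[!drop]) / sdv[!drop]
  out <- structure(list(genes = rownames(abundance)[!drop],
                        celltypes = colnames(abundance),
                        z = z, source = source),
                   class = "ZScoreTable")
  attr(out, "dropped_genes") <- rownames(abundance)[drop]
  out
}

#' @export
print.ZScoreTable <- function(x, ...) {
  cat("ZScoreTable (", x$source, "): ", length(x$genes), " genes x ",
      length(x$celltypes), " cell types\n", sep = "")
  invisible(x)
}

#' mRNA-protein z-score concordance
#'
#' Pearson correlation between mRNA and protein cell-type z-scores over all
#' matched (gene, cell type) pairs — the summary of how far cell-type mRNA
#' enrichment is maintained at the protein level.
#'
#' @param z_m,z_p `ZScoreTable`s (from [celltype_zscores()]) for mRNA and
#'   protein.
#' @return list with `r` (Pearson), `p` (two-sided) and `n_pairs`.
#' @export
concordance <- function(z_m, z_p) {
  stopifnot(inherits(z_m, "ZScoreTable"), inherits(z_p, "ZScoreTable"))
  genes <- intersect(z_m$genes, z_p$genes)
  cts <- intersect(z_m$celltypes, z_p$celltypes)
  n_pairs <- length(genes) * length(cts)
  if (n_pairs < 3) {
    stop("concordance needs >= 3 matched (gene, cell type) pairs, got ",
         n_pairs, call. = FALSE)
  }
  a <- as.numeric(z_m$z[genes, cts])
  b <- as.numeric(z_p$z[genes, cts])
  ct <- stats::cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_pairs = n_pairs)
}

#' Acyl-RAC palmitoylated / unpalmitoylated fractions
#'
#' Densitometry fraction formulas for the resin-assisted capture
#' palmitoylation assay, evaluated exactly as printed in the assay
#' convention this package follows:
#' `palm_pct = 100 * (P - NSB) / ((P - NSB) + U)` with the non-specific
#' binding subtraction clipped at zero, and
#' `unpalm_pct = 100 * U / (P + U)` — note the NSB term is absent from the
#' second formula, so the two percentages need not sum to 100.
#' `consistent_nsb = TRUE` switches the unpalmitoylated formula to the
#' symmetric alternative `100 * U / ((P - NSB) + U)`.
#'
#' @param palm_signal,unpalm_signal,nsb_signal non-negative densitometry
#'   values: palmitoylated fraction, unpalmitoylated fraction and the
#'   non-specific binding control.
#' @param consistent_nsb apply the NSB subtraction in both formulas
#'   (default `FALSE`: verbatim convention).
#' @return list with `palm_pct` and `unpalm_pct`, both in \[0, 100\].
#' @export
acylrac_fractions <- function(palm_signal, unpalm_signal, nsb_signal = 0,
                              consistent_nsb = FALSE) {
  vals <- c(palm_signal, unpalm_signal, nsb_signal)
  if (anyNA(vals) || any(!is.finite(vals)) || any(vals < 0)) {
    stop("validation error: signals must be finite and non-negative",
         call. = FALSE)
  }
  p_adj <- palm_signal - nsb_signal
  if (p_adj < 0) {
    warning("NSB control exceeds the palmitoylated signal; ",
            "palmitoylated fraction clipped at 0", call. = FALSE)
    p_adj <- 0
  }
  denom_palm <- p_adj + unpalm_signal
  denom_unpalm <- if (consistent_nsb) p_adj + unpalm_signal else
    palm_signal + unpalm_signal
  if (denom_palm == 0 && denom_unpalm == 0) {
    stop("validation error: zero total signal in both fraction denominators",
         call. = FALSE)
  }
  list(palm_pct = if (denom_palm > 0) 100 * p_adj / denom_palm else 0,
       unpalm_pct = if (denom_unpalm > 0)
         100 * unpalm_signal / denom_unpalm else 0)
}
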