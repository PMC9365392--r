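#' Counts-per-10,000 log2 normalization
#'
#' Scales each cell's counts to sum to 10,000, then applies
#' `log2(scaled + 1)`. This is the per-cell normalization used throughout
#' single-cell atlases of the brain before any averaging by cell type.
#' Cells whose total count is zero cannot be scaled and are dropped with a
#' warning.
#'
#' @param m a [count_matrix()] with `unit = "counts"`.
#' @return A `CountMatrix` with `unit = "cp10k_log2"`; zero-total cells
#'   removed. The dropped cell identifiers are attached as attribute
#'   `"dropped_cells"`.
#' @export
cp10k_log2 <- function(m) {
  stopifnot(inherits(m, "CountMatrix"))
  if (m$unit != "counts") {
    stop("unit mismatch: cp10k_log2 expects raw counts, got unit '",
         m$unit, "'", call. = FALSE)
  }
  totals <- colSums(m$values)
  drop <- totals == 0
  if (all(drop)) {
    stop("validation error: every cell has zero total count", call. = FALSE)
  }
  if (any(drop)) {
    warning("dropping ", sum(drop), " cell(s) with zero total count: ",
            paste(utils::head(m$cells[drop], 5), collapse = ", "),
            if (sum(drop) > 5) ", ..." else "", call. = FALSE)
  }
  v <- m$values[, !drop, drop = FALSE]
  scaled <- sweep(v, 2, totals[!drop], "/") * 1e4
  out <- count_matrix(log2(scaled + 1), m$genes, m$cells[!drop],
                      unit = "cp10k_log2")
  attr(out, "dropped_cells") <- m$cells[drop]
  out
}
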