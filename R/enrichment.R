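# Two-sided p for a 2x2 table with fixed margins, by the point-probability
# rule: sum hypergeometric point probabilities not exceeding that of the
# observed table (with a 1 + 1e-7 relative tolerance, the convention of the
# classical exact test). K = flagged total, n1 = first column size, N = total.
# .hyper_two_sided_all returns the p for every x in the support at once:
# with the pmf sorted ascending, p(x) is the cumulative sum up to the last
# point probability <= pmf(x) * (1 + 1e-7).
.hyper_two_sided_all <- function(K, n1, N) {
  lo <- max(0L, n1 - (N - K))
  hi <- min(n1, K)
  xs <- lo:hi
  pmf <- stats::dhyper(xs, K, N - K, n1)
  ord <- order(pmf)
  cs <- cumsum(pmf[ord])
  p <- cs[findInterval(pmf * (1 + 1e-7), pmf[ord])]
  stats::setNames(pmin(p, 1), xs)
}

.hyper_two_sided <- function(x, K, n1, N) {
  unname(.hyper_two_sided_all(K, n1, N)[as.character(x)])
}

# sample odds ratio (ad/bc), Haldane-Anscombe 0.5 correction if any cell is 0
.sample_or <- function(a, b, c, d) {
  corrected <- any(c(a, b, c, d) == 0)
  if (corrected) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  list(or = (a * d) / (b * c), corrected = corrected)
}

#' Exact test of a 2x2 contingency table
#'
#' Two-sided exact test of association for counts
#' `rbind(c(a, b), c(c, d))` (rows: flagged / unflagged; columns: the two
#' gene sets), computed from the hypergeometric point-probability rule.
#' The odds ratio is the sample `ad/bc` estimate with Haldane-Anscombe 0.5
#' correction when any cell is zero.
#'
#' @param counts 2x2 non-negative integer matrix.
#' @return A `FisherResult`: list with `table`, `odds_ratio`,
#'   `p_two_sided`, `proportions` (flagged proportion per column) and
#'   `or_corrected` (whether the 0.5 correction was applied).
#' @export
fisher_test_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("validation error: counts must be a 2x2 non-negative integer matrix",
         call. = FALSE)
  }
  a <- counts[1, 1]; b <- counts[1, 2]
  cc <- counts[2, 1]; d <- counts[2, 2]
  n1 <- a + cc; n2 <- b + d
  if (n1 == 0) stop("empty margin: first column has zero total", call. = FALSE)
  if (n2 == 0) stop("empty margin: second column has zero total", call. = FALSE)
  p <- .hyper_two_sided(a, K = a + b, n1 = n1, N = n1 + n2)
  orr <- .sample_or(a, b, cc, d)
  structure(list(table = counts, odds_ratio = orr$or, p_two_sided = p,
                 proportions = c(set_a = a / n1, set_b = b / n2),
                 or_corrected = orr$corrected),
            class = "FisherResult")
}

#' @export
print.FisherResult <- function(x, ...) {
  cat("FisherResult: OR =", signif(x$odds_ratio, 4),
      if (x$or_corrected) "(Haldane-Anscombe corrected)" else "",
      " p =", signif(x$p_two_sided, 4), "\n")
  print(x$table)
  invisible(x)
}

# intersect a gene set with the universe, warning about outsiders
.in_universe <- function(genes, tab, what) {
  genes <- unique(canonicalize_genes(genes))
  out <- setdiff(genes, tab$universe)
  if (length(out)) {
    warning(length(out), " gene(s) in ", what,
            " outside the annotation universe excluded: ",
            paste(utils::head(out, 10), collapse = ", "),
            if (length(out) > 10) ", ..." else "", call. = FALSE)
  }
  intersect(genes, tab$universe)
}

#' Annotated proportion of a gene set
#'
#' Counts how many genes of a set carry an annotation flag, e.g. the
#' fraction of a candidate list that are validated palmitoylation
#' substrates. Genes outside the universe are excluded with a warning.
#'
#' @param gene_set character vector of gene symbols.
#' @param tab an [annotation_table()].
#' @param flag name of the flag set in `tab`.
#' @return list with `k` (flagged), `n` (in-universe set size) and
#'   `proportion = k/n`.
#' @export
annotation_proportion <- function(gene_set, tab, flag) {
  stopifnot(inherits(tab, "AnnotationTable"))
  if (!flag %in% names(tab$flags)) {
    stop("unknown annotation flag: ", flag, call. = FALSE)
  }
  set <- .in_universe(gene_set, tab, "gene set")
  if (length(set) == 0) {
    stop("undefined proportion: gene set is disjoint from the universe",
         call. = FALSE)
  }
  k <- length(intersect(set, tab$flags[[flag]]))
  list(k = k, n = length(set), proportion = k / length(set))
}

#' Annotation enrichment between two gene sets
#'
#' Exact two-sided test of whether `set_a` is enriched for an annotation
#' flag relative to `set_b`. When `set_a` is nested inside `set_b` (a
#' tighter co-expression tier inside a looser one, or a candidate list
#' against the whole background universe) the comparison column is
#' `set_b \\ set_a`; non-nested sets are disjointified by their symmetric
#' difference and the overlap size is reported.
#'
#' @param set_a,set_b character vectors of gene symbols; `set_b` may be
#'   `tab$universe` to compare against the background.
#' @param tab an [annotation_table()].
#' @param flag name of the flag set.
#' @return A `FisherResult` (see [fisher_test_2x2()]) with an extra
#'   `overlap_dropped` element giving the number of shared genes removed
#'   when the sets were not nested.
#' @export
fisher_enrichment <- function(set_a, set_b, tab, flag) {
  stopifnot(inherits(tab, "AnnotationTable"))
  if (!flag %in% names(tab$flags)) {
    stop("unknown annotation flag: ", flag, call. = FALSE)
  }
  set_a <- .in_universe(set_a, tab, "set_a")
  set_b <- .in_universe(set_b, tab, "set_b")
  if (length(set_a) == 0) stop("empty margin: set_a", call. = FALSE)
  if (length(set_b) == 0) stop("empty margin: set_b", call. = FALSE)
  overlap_dropped <- 0L
  if (all(set_a %in% set_b)) {
    col_b <- setdiff(set_b, set_a)
    col_a <- set_a
  } else {
    shared <- intersect(set_a, set_b)
    overlap_dropped <- length(shared)
    if (overlap_dropped) {
      warning("sets are not nested; ", overlap_dropped,
              " shared gene(s) excluded from both columns", call. = FALSE)
    }
    col_a <- setdiff(set_a, set_b)
    col_b <- setdiff(set_b, set_a)
  }
  if (length(col_a) == 0) stop("empty margin: set_a column", call. = FALSE)
  if (length(col_b) == 0) stop("empty margin: comparison column", call. = FALSE)
  flagged <- tab$flags[[flag]]
  a <- length(intersect(col_a, flagged))
  b <- length(intersect(col_b, flagged))
  counts <- matrix(c(a, length(col_a) - a, b, length(col_b) - b), nrow = 2,
                   dimnames = list(c("flagged", "unflagged"),
                                   c("set_a", "comparison")))
  res <- fisher_test_2x2(counts)
  res$overlap_dropped <- overlap_dropped
  res
}

#' Ranked substrate candidates from an enriched gene list
#'
#' Intersects an enriched gene list (with a per-gene statistic such as fold
#' enrichment or rho) with an annotation flag and orders it by descending
#' statistic — the step that turns a cell-type-enriched list into
#' experimentally testable substrate candidates.
#'
#' @param enriched named numeric vector (`names` = genes, values = the
#'   enrichment statistic), or a data.frame with columns `gene` and `stat`.
#' @param tab an [annotation_table()].
#' @param flag name of the flag set.
#' @return data.frame with columns `gene`, `stat`, flagged genes only,
#'   descending `stat`, ties in input order.
#' @export
substrate_candidates <- function(enriched, tab, flag) {
  stopifnot(inherits(tab, "AnnotationTable"))
  if (!flag %in% names(tab$flags)) {
    stop("unknown annotation flag: ", flag, call. = FALSE)
  }
  if (is.data.frame(enriched)) {
    genes <- canonicalize_genes(enriched$gene)
    stat <- enriched$stat
  } else {
    genes <- canonicalize_genes(names(enriched))
    stat <- as.numeric(enriched)
  }
  keep <- genes %in% tab$flags[[flag]]
  genes <- genes[keep]
  stat <- stat[keep]
  ord <- order(-stat, seq_along(stat))
  data.frame(gene = genes[ord], stat = stat[ord], stringsAsFactors = FALSE)
}
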