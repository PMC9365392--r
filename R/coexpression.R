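#' @section Spearman machinery:
#' Correlations are computed on average ranks (midranks for ties), i.e. the
#' Pearson correlation of the rank-transformed profiles. Two-sided p-values
#' use the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on
#' `n - 2` degrees of freedom for `n >= 10` groups, and exact enumeration of
#' all `n!` rank permutations for `n < 10`, where the asymptotic test is
#' unreliable.
#' @keywords internal
#' @name spearman-internals
NULL

# permutation index matrices, memoized per n (n <= 9 => at most 362,880 rows)
.perm_cache <- new.env(parent = emptyenv())

.permutations <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  perm <- function(v) {
    if (length(v) <= 1) return(matrix(v, nrow = 1))
    do.call(rbind, lapply(seq_along(v), function(i) {
      cbind(v[i], perm(v[-i]))
    }))
  }
  p <- perm(seq_len(n))
  .perm_cache[[key]] <- p
  p
}

# rho of one pair from pre-ranked vectors; NA when either side is constant
.rank_rho <- function(rx, ry) {
  sx <- stats::sd(rx)
  sy <- stats::sd(ry)
  if (sx == 0 || sy == 0) return(NA_real_)
  n <- length(rx)
  sum((rx - mean(rx)) * (ry - mean(ry))) / ((n - 1) * sx * sy)
}

.spearman_p_t <- function(rho, n) {
  if (is.na(rho)) return(NA_real_)
  if (abs(rho) >= 1) return(0)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

.spearman_p_exact <- function(rx, ry, rho_obs) {
  if (is.na(rho_obs)) return(NA_real_)
  n <- length(rx)
  P <- .permutations(n)
  ryp <- matrix(ry[P], nrow = nrow(P))
  s <- as.numeric(ryp %*% rx)
  # rho is affine in sum(rx * ry_perm); compare on that scale
  denom <- (n - 1) * stats::sd(rx) * stats::sd(ry)
  rho_perm <- (s - n * mean(rx) * mean(ry)) / denom
  mean(abs(rho_perm) >= abs(rho_obs) - 1e-12)
}

#' Pairwise Spearman co-expression across group profiles
#'
#' Computes Spearman rho and two-sided p for every pair between two gene
#' sets, across the columns (groups) of a profile matrix — the
#' metacell-level co-expression used to build enzyme networks and
#' substrate candidate lists. Pairs in which either gene has zero variance
#' across groups get `NA` rho/p and are excluded from the multiple-testing
#' family; `q` is the Benjamini-Hochberg adjustment over all defined pairs
#' of this one call.
#'
#' @param p a [profile_matrix()] with at least 3 groups.
#' @param set_a character vector of gene symbols (rows of `p`).
#' @param set_b second set; defaults to `set_a`, in which case all
#'   unordered within-set pairs are emitted.
#' @return A `CorrelationTable`: data.frame with columns `gene_a`,
#'   `gene_b`, `rho`, `p`, `q`, `n_groups`, one row per unordered pair.
#' @export
spearman_pairs <- function(p, set_a, set_b = NULL) {
  stopifnot(inherits(p, "ProfileMatrix"))
  n <- length(p$groups)
  if (n < 3) {
    stop("spearman_pairs needs >= 3 groups, got ", n, call. = FALSE)
  }
  set_a <- canonicalize_genes(set_a)
  within <- is.null(set_b)
  set_b <- if (within) set_a else canonicalize_genes(set_b)
  missing <- setdiff(c(set_a, set_b), p$genes)
  if (length(missing)) {
    stop("gene(s) not in profile: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ia <- match(set_a, p$genes)
  ib <- match(set_b, p$genes)
  if (within) {
    pairs <- which(upper.tri(diag(length(ia))), arr.ind = TRUE)
    pa <- ia[pairs[, 1]]
    pb <- ia[pairs[, 2]]
  } else {
    grid <- expand.grid(a = ia, b = ib)
    grid <- grid[grid$a != grid$b, , drop = FALSE]
    key <- paste(pmin(grid$a, grid$b), pmax(grid$a, grid$b))
    grid <- grid[!duplicated(key), , drop = FALSE]
    pa <- grid$a
    pb <- grid$b
  }
  used <- sort(unique(c(pa, pb)))
  ranks <- t(apply(p$values[used, , drop = FALSE], 1, rank))
  sds <- apply(ranks, 1, stats::sd)
  ra <- match(pa, used)
  rb <- match(pb, used)
  if (n >= 10) {
    # vectorized: Pearson on rank rows
    cr <- suppressWarnings(stats::cor(t(ranks)))
    rho <- cr[cbind(ra, rb)]
    rho[sds[ra] == 0 | sds[rb] == 0] <- NA_real_
    pval <- vapply(rho, .spearman_p_t, numeric(1), n = n)
  } else {
    rho <- numeric(length(pa))
    pval <- numeric(length(pa))
    for (i in seq_along(pa)) {
      rx <- ranks[ra[i], ]
      ry <- ranks[rb[i], ]
      rho[i] <- .rank_rho(rx, ry)
      pval[i] <- .spearman_p_exact(rx, ry, rho[i])
    }
  }
  q <- rep(NA_real_, length(pval))
  ok <- !is.na(pval)
  if (any(ok)) q[ok] <- adjust_fdr(pval[ok])
  out <- data.frame(gene_a = p$genes[pa], gene_b = p$genes[pb],
                    rho = rho, p = pval, q = q, n_groups = n,
                    stringsAsFactors = FALSE)
  class(out) <- c("CorrelationTable", "data.frame")
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone-enforced, capped at 1), input order
#' preserved. Thin validating wrapper over [stats::p.adjust()].
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same length and order.
#' @export
adjust_fdr <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("validation error: p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Build a co-expression network from a correlation table
#'
#' Edges are pairs with `rho` strictly above `rho_min` (negative
#' correlations never form edges) and, when `q_max` is given, `q < q_max`.
#' Nodes are the genes incident to at least one edge; when the source
#' profile matrix is supplied each node carries its mean expression across
#' all groups (used as node color in the published network figures).
#'
#' @param tab a `CorrelationTable` from [spearman_pairs()].
#' @param rho_min edge threshold on signed rho, in (0, 1\].
#' @param q_max optional FDR threshold; `NULL` disables it.
#' @param profile optional [profile_matrix()] for node mean expression.
#' @return A `Network`: list with data.frames `nodes` (`gene`,
#'   `mean_expr`) and `edges` (`gene_a`, `gene_b`, `rho`).
#' @export
build_network <- function(tab, rho_min, q_max = NULL, profile = NULL) {
  stopifnot(rho_min > 0, rho_min <= 1)
  keep <- !is.na(tab$rho) & tab$rho > rho_min
  if (!is.null(q_max)) keep <- keep & !is.na(tab$q) & tab$q < q_max
  edges <- tab[keep, c("gene_a", "gene_b", "rho"), drop = FALSE]
  rownames(edges) <- NULL
  genes <- unique(c(edges$gene_a, edges$gene_b))
  mean_expr <- rep(NA_real_, length(genes))
  if (!is.null(profile) && length(genes)) {
    idx <- match(genes, profile$genes)
    mean_expr[!is.na(idx)] <- rowMeans(
      profile$values[idx[!is.na(idx)], , drop = FALSE])
  }
  structure(list(nodes = data.frame(gene = genes, mean_expr = mean_expr,
                                    stringsAsFactors = FALSE),
                 edges = edges),
            class = "Network")
}

#' @export
print.Network <- function(x, ...) {
  cat("Network:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Write a network as an edge-list TSV (and optionally GraphML)
#'
#' @param net a `Network` from [build_network()].
#' @param path edge-list TSV path (`gene_a`, `gene_b`, `rho`).
#' @param graphml optional GraphML output path (requires igraph).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, graphml = NULL) {
  stopifnot(inherits(net, "Network"))
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphml)) {
    if (!requireNamespace("igraph", quietly = TRUE)) {
      stop("GraphML export requires the 'igraph' package", call. = FALSE)
    }
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = net$nodes)
    igraph::write_graph(g, graphml, format = "graphml")
  }
  invisible(path)
}

#' Genes co-expressed with a panel
#'
#' Extracts the genes outside a panel that have at least one panel partner
#' with `rho > rho_min` (and `q < q_max` when given) — the construction of
#' transcriptome-wide co-expressed substrate candidate tiers.
#'
#' @param tab a `CorrelationTable` containing panel-vs-transcriptome pairs.
#' @param panel character vector of panel gene symbols, or a `GenePanel`.
#' @param rho_min threshold on signed rho (strict).
#' @param q_max FDR threshold (strict); `NULL` disables the FDR filter,
#'   reproducing a plain rho cutoff. Default 0.05.
#' @return Character vector of co-expressed non-panel genes, in order of
#'   first appearance in `tab`.
#' @export
coexpressed_gene_set <- function(tab, panel, rho_min, q_max = 0.05) {
  if (inherits(panel, "GenePanel")) panel <- panel$gene
  panel <- canonicalize_genes(panel)
  keep <- !is.na(tab$rho) & tab$rho > rho_min
  if (!is.null(q_max)) keep <- keep & !is.na(tab$q) & tab$q < q_max
  a_in <- tab$gene_a %in% panel
  b_in <- tab$gene_b %in% panel
  hit <- keep & xor(a_in, b_in)
  partners <- ifelse(a_in[hit], tab$gene_b[hit], tab$gene_a[hit])
  unique(as.character(partners))
}

#' Write a correlation table as TSV
#'
#' @param tab a `CorrelationTable`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_correlation_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
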