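# Independent brute-force oracles, kept deliberately naive and separate from
# the package's computational paths.

# average (mid) rank of each element, by direct counting
brute_rank <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }, numeric(1))
}

# Spearman rho as Pearson on brute-force average ranks
brute_spearman <- function(x, y) {
  rx <- brute_rank(x)
  ry <- brute_rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# exact two-sided permutation p for Spearman, by full enumeration (n <= 7)
brute_spearman_exact_p <- function(x, y) {
  n <- length(y)
  perm_all <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perm_all(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  obs <- brute_spearman(x, y)
  rhos <- vapply(perm_all(seq_len(n)),
                 function(p) brute_spearman(x, y[p]), numeric(1))
  mean(abs(rhos) >= abs(obs) - 1e-12)
}

# Benjamini-Hochberg by the direct step-up definition
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# two-sided hypergeometric p by explicit enumeration with choose()
brute_hyper_two_sided <- function(a, b, c, d) {
  K <- a + b; n1 <- a + c; N <- a + b + c + d
  lo <- max(0, n1 - (N - K))
  hi <- min(n1, K)
  xs <- lo:hi
  pmf <- choose(K, xs) * choose(N - K, n1 - xs) / choose(N, n1)
  obs <- pmf[xs == a]
  sum(pmf[pmf <= obs * (1 + 1e-7)])
}

# small in-memory ProfileMatrix from a plain matrix; values are shifted to
# be non-negative (a global shift, so all ranks are untouched)
toy_profile <- function(values, genes = NULL, groups = NULL,
                        unit = "cp10k_log2") {
  if (min(values) < 0) values <- values - min(values)
  if (is.null(genes)) genes <- sprintf("G%02d", seq_len(nrow(values)))
  if (is.null(groups)) groups <- sprintf("grp%02d", seq_len(ncol(values)))
  profile_matrix(values, genes, groups, unit = unit,
                 n_cells = rep(5L, length(groups)))
}

extdata <- function(name) system.file("extdata", name, package = "palmexpr")
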