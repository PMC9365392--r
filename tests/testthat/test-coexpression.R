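test_that("spearman_pairs recovers monotone and reversed relationships", {
  p <- toy_profile(rbind(x = c(1, 2, 3, 4),
                         y = c(2, 4, 6, 8),
                         z = c(8, 6, 4, 2)),
                   genes = c("X", "Y", "Z"))
  tab <- spearman_pairs(p, c("X", "Y", "Z"))
  get <- function(a, b) tab$rho[(tab$gene_a == a & tab$gene_b == b) |
                                  (tab$gene_a == b & tab$gene_b == a)]
  expect_equal(get("X", "Y"), 1)
  expect_equal(get("X", "Z"), -1)
  expect_equal(get("Y", "Z"), -1)
})

test_that("tied profiles match the brute-force average-rank oracle", {
  p <- toy_profile(rbind(a = c(1, 2, 2, 4), b = c(3, 1, 4, 4)),
                   genes = c("A", "B"))
  tab <- spearman_pairs(p, c("A", "B"))
  expect_equal(tab$rho, brute_spearman(c(1, 2, 2, 4), c(3, 1, 4, 4)),
               tolerance = 1e-12)
})

test_that("small-n p-values come from exact permutation enumeration", {
  set.seed(5)
  for (i in 1:6) {
    n <- sample(4:6, 1)
    x <- sample(1:8, n, replace = TRUE)  # ties allowed
    y <- sample(1:8, n, replace = TRUE)
    p <- toy_profile(rbind(x, y), genes = c("X", "Y"))
    if (sd(x) == 0 || sd(y) == 0) next
    tab <- spearman_pairs(p, c("X", "Y"))
    expect_equal(tab$p, brute_spearman_exact_p(x, y), tolerance = 1e-12)
  }
  # tie-free case agrees with the classical exact null distribution
  x <- c(3, 1, 4, 2, 5)
  y <- c(2, 1, 5, 3, 4)
  p <- toy_profile(rbind(x, y), genes = c("X", "Y"))
  tab <- spearman_pairs(p, c("X", "Y"))
  ref <- cor.test(x, y, method = "spearman", exact = TRUE)
  expect_equal(tab$rho, unname(ref$estimate))
  expect_equal(tab$p, ref$p.value, tolerance = 1e-9)
})

test_that("large-n p-values use the t approximation on n - 2 df", {
  set.seed(6)
  x <- rnorm(30)
  y <- 0.5 * x + rnorm(30)
  p <- toy_profile(rbind(x, y), genes = c("X", "Y"))
  tab <- spearman_pairs(p, c("X", "Y"))
  rho <- brute_spearman(x, y)
  tt <- rho * sqrt(28 / (1 - rho^2))
  expect_equal(tab$rho, rho, tolerance = 1e-12)
  expect_equal(tab$p, 2 * pt(-abs(tt), 28), tolerance = 1e-12)
})

test_that("rho is invariant under strictly monotone transforms", {
  set.seed(8)
  x <- rnorm(20)
  y <- rnorm(20)
  base <- spearman_pairs(toy_profile(rbind(x, y), genes = c("X", "Y")),
                         c("X", "Y"))
  warp <- spearman_pairs(
    toy_profile(rbind(exp(x), 5 + (y - min(y) + 0.1)^3),
                genes = c("X", "Y")),
    c("X", "Y"))
  expect_equal(warp$rho, base$rho, tolerance = 1e-12)
})

test_that("zero-variance genes are excluded from the BH family", {
  p <- toy_profile(rbind(a = 1:5, flat = rep(2, 5), b = c(2, 1, 5, 4, 3)),
                   genes = c("A", "Flat", "B"))
  tab <- spearman_pairs(p, c("A", "Flat", "B"))
  flat_rows <- tab$gene_a == "Flat" | tab$gene_b == "Flat"
  expect_true(all(is.na(tab$rho[flat_rows])))
  expect_true(all(is.na(tab$q[flat_rows])))
  expect_false(anyNA(tab$q[!flat_rows]))
  expect_error(spearman_pairs(toy_profile(matrix(1:4, 2), genes = c("A", "B")),
                              c("A", "B")), ">= 3 groups")
})

test_that("adjust_fdr is the BH step-up and validates its input", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_fdr(0.5), 0.5)
  expect_error(adjust_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(9)
  for (i in 1:20) {
    pv <- runif(sample(1:40, 1))
    q <- adjust_fdr(pv)
    expect_equal(q, brute_bh(pv), tolerance = 1e-12)
    expect_true(all(q <= 1 + 1e-15) && all(q >= pv - 1e-15))
  }
})

test_that("networks take strict-threshold positive edges only", {
  tab <- data.frame(gene_a = c("A", "A", "B", "C"),
                    gene_b = c("B", "C", "C", "D"),
                    rho = c(0.6, 0.5, 0.4, -0.9),
                    p = c(1e-4, 1e-4, 1e-4, 1e-6),
                    q = c(1e-3, 1e-3, 1e-3, 1e-5), n_groups = 50)
  class(tab) <- c("CorrelationTable", "data.frame")
  net <- build_network(tab, rho_min = 0.5)
  expect_equal(nrow(net$edges), 1)  # 0.5 is excluded, negatives never edge
  expect_identical(sort(net$nodes$gene), c("A", "B"))
  empty <- build_network(tab[0, ], rho_min = 0.5)
  expect_equal(nrow(empty$edges), 0)
  expect_equal(nrow(empty$nodes), 0)
})

test_that("node attributes carry mean expression from the source profile", {
  set.seed(10)
  vals <- matrix(runif(40, 1, 3), 4, 10)
  prof <- toy_profile(vals, genes = c("A", "B", "C", "D"))
  tab <- data.frame(gene_a = "A", gene_b = "B", rho = 0.9, p = 1e-5,
                    q = 1e-4, n_groups = 10)
  net <- build_network(tab, 0.5, profile = prof)
  expect_equal(net$nodes$mean_expr[net$nodes$gene == "A"], mean(vals[1, ]))
})

test_that("co-expressed gene sets nest as the threshold tightens", {
  set.seed(12)
  panel <- c("Zdhhc17", "Zdhhc9")
  others <- sprintf("G%02d", 1:20)
  n <- 40
  base <- rnorm(n)
  vals <- rbind(base + rnorm(n, sd = 0.1), rnorm(n),
                matrix(rnorm(20 * n), 20, n))
  vals[3, ] <- base + rnorm(n, sd = 0.2)   # correlated with panel gene 1
  vals <- vals - min(vals)
  prof <- toy_profile(vals, genes = c(panel, others))
  tab <- spearman_pairs(prof, panel, c(panel, others))
  loose <- coexpressed_gene_set(tab, panel, rho_min = 0.4)
  tight <- coexpressed_gene_set(tab, panel, rho_min = 0.8)
  expect_true(all(tight %in% loose))
  expect_true("G01" %in% loose)
  expect_false(any(panel %in% loose))
})

test_that("networks export as edge-list TSV and GraphML", {
  tab <- data.frame(gene_a = c("A", "B"), gene_b = c("B", "C"),
                    rho = c(0.8, 0.7), p = c(1e-5, 1e-4), q = c(1e-4, 1e-3),
                    n_groups = 20)
  net <- build_network(tab, 0.5)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "edges.tsv")
  gml <- file.path(dir, "net.graphml")
  write_network(net, path, graphml = if (requireNamespace("igraph",
                                                          quietly = TRUE))
    gml else NULL)
  back <- read.delim(path)
  expect_equal(nrow(back), 2)
  expect_equal(back$rho, c(0.8, 0.7))
  if (requireNamespace("igraph", quietly = TRUE)) {
    g <- igraph::read_graph(gml, format = "graphml")
    expect_equal(igraph::gsize(g), 2)
  }
})

test_that("BH keeps the null rejection rate controlled on null profiles", {
  set.seed(314)
  frac <- vapply(1:20, function(s) {
    vals <- matrix(rlnorm(30 * 265, sdlog = 0.5), 30, 265)
    prof <- toy_profile(vals)
    tab <- spearman_pairs(prof, prof$genes)
    mean(tab$q < 0.05, na.rm = TRUE)
  }, numeric(1))
  expect_lte(mean(frac), 0.06)
})
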