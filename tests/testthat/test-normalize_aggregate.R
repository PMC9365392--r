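test_that("cp10k_log2 matches hand-evaluated scaling", {
  m <- count_matrix(matrix(c(1, 0, 3), ncol = 1), c("Ga", "Gb", "Gc"), "c1")
  out <- cp10k_log2(m)
  expect_equal(unname(out$values[, 1]),
               c(log2(2501), 0, log2(7501)))
  expect_equal(unname(out$values[, 1]), c(11.2884, 0, 12.8729),
               tolerance = 1e-4)

  # single nonzero gene takes the whole cell budget
  m1 <- count_matrix(matrix(c(0, 7, 0), ncol = 1), c("Ga", "Gb", "Gc"), "c1")
  out1 <- cp10k_log2(m1)
  expect_equal(unname(out1$values[, 1]), c(0, log2(10001), 0))

  # uniform cell: every gene at log2(10000/G + 1)
  g <- 8
  mu <- count_matrix(matrix(3, nrow = g, ncol = 1),
                     sprintf("G%d", 1:g), "c1")
  expect_equal(unname(cp10k_log2(mu)$values[, 1]),
               rep(log2(1e4 / g + 1), g))
})

test_that("pre-log scaled columns sum to exactly 10,000", {
  set.seed(41)
  v <- matrix(rpois(50 * 30, 4), 50, 30)
  v[, 3] <- 0  # a dead cell
  m <- count_matrix(v, sprintf("G%02d", 1:50), sprintf("c%02d", 1:30))
  expect_warning(out <- cp10k_log2(m), "zero total")
  expect_identical(attr(out, "dropped_cells"), "c03")
  scaled <- 2^out$values - 1
  expect_true(all(abs(colSums(scaled) - 1e4) < 1e-6))
})

test_that("cp10k_log2 preserves within-cell ordering and rejects wrong units", {
  set.seed(42)
  v <- matrix(rpois(40 * 10, 5), 40, 10)
  m <- count_matrix(v, sprintf("G%02d", 1:40), sprintf("c%02d", 1:10))
  out <- cp10k_log2(m)
  for (j in 1:10) {
    expect_identical(order(out$values[, j]), order(v[, j]))
  }
  expect_error(cp10k_log2(out), "unit mismatch")
})

test_that("group aggregation averages cells and enforces min_cells", {
  v <- matrix(0, 1, 9)
  v[1, ] <- c(0, 0, 1, 2, 2,  5, 5, 5, 5)  # group a: 5 cells, group b: 4
  m <- count_matrix(v, "Ga", sprintf("c%d", 1:9), unit = "cp10k_log2")
  meta <- cell_meta(data.frame(cell = sprintf("c%d", 1:9),
                               cluster = rep(c("a", "b"), c(5, 4))))
  expect_message(p <- aggregate_by_group(m, meta, "cluster"), "below min_cells")
  expect_identical(p$groups, "a")
  expect_equal(unname(p$values[1, 1]), 1.0)
  expect_equal(attr(p, "dropped_groups"), c(b = 4L))
  expect_error(aggregate_by_group(m, meta, "cluster", min_cells = 10),
               "empty-profile")
  expect_error(aggregate_by_group(m, meta, "missing_key"), "missing_key")
})

test_that("interquartile trimmed mean removes floor(n/4) from each end", {
  expect_equal(trimmed_mean_iqr(c(0, 1, 2, 3, 100)), 2.0)
  expect_equal(trimmed_mean_iqr(c(100, 3, 0, 2, 1)), 2.0)  # order-free
  expect_equal(trimmed_mean_iqr(1:4), mean(2:3))
  v <- matrix(c(0, 1, 2, 3, 100), 1, 5)
  m <- count_matrix(v, "Ga", sprintf("c%d", 1:5), unit = "cpm_log2_trimmed")
  meta <- cell_meta(data.frame(cell = sprintf("c%d", 1:5), k = "a"))
  p <- aggregate_by_group(m, meta, "k", stat = "trimmed_mean_25_75")
  expect_equal(unname(p$values[1, 1]), 2.0)
})

test_that("aggregation commutes with gene subsetting", {
  set.seed(7)
  spec <- simulation_spec(seed = 7, n_genes = 30L, n_groups = 6L,
                          cells_per_group = 10L)
  sim <- simulate_counts(spec)
  norm <- cp10k_log2(sim$counts)
  full <- aggregate_by_group(norm, sim$meta, "metacell")
  sub_genes <- sample(norm$genes, 12)
  sub <- count_matrix(norm$values[sub_genes, , drop = FALSE], sub_genes,
                      norm$cells, unit = norm$unit)
  p_sub <- aggregate_by_group(sub, sim$meta, "metacell")
  expect_equal(p_sub$values, full$values[sub_genes, , drop = FALSE])
})

test_that("rank_order sorts by descending means with stable ties", {
  p <- toy_profile(matrix(c(1, 1, 3, 3), 2, byrow = TRUE))
  expect_identical(rank_order(p)$row_order, c(2L, 1L))

  flat <- toy_profile(matrix(2, 3, 4))
  expect_identical(rank_order(flat)$row_order, 1:3)
  expect_identical(rank_order(flat)$col_order, 1:4)

  p3 <- toy_profile(matrix(c(2, 5, 5), 1))  # column means 2, 5, 5
  expect_identical(rank_order(p3)$col_order, c(2L, 3L, 1L))

  # a permutation, idempotent under re-application
  set.seed(11)
  pr <- toy_profile(matrix(runif(30), 5, 6))
  ro <- rank_order(pr)$row_order
  expect_setequal(ro, 1:5)
  sorted <- toy_profile(pr$values[ro, , drop = FALSE])
  expect_identical(rank_order(sorted)$row_order, 1:5)
})

test_that("hierarchical ordering matches hand-computed average linkage", {
  # 1-D points 0, 1, 4, 10: merges at heights 1, 3.5, 25/3
  p <- toy_profile(matrix(c(0, 1, 4, 10), 4, 1))
  h <- hclust(dist(p$values), method = "average")
  expect_equal(h$height, c(1, 3.5, 25 / 3))

  near <- toy_profile(matrix(c(0, 0, 0, 0.1, 5, 5), 3, byrow = TRUE))
  ord <- hierarchical_order(near, "rows")
  expect_equal(abs(diff(match(c(1, 2), ord))), 1)  # near-identical adjacent

  dup <- toy_profile(matrix(c(1, 2, 1, 2, 9, 9), 3, byrow = TRUE))
  hh <- hclust(dist(dup$values), method = "average")
  expect_equal(min(hh$height), 0)  # duplicates merge first
  expect_error(hierarchical_order(toy_profile(matrix(1, 1, 2)), "rows"),
               ">= 2 items")
})

test_that("profile matrices round-trip with their group-count sidecar", {
  p <- toy_profile(matrix(runif(12), 3, 4))
  path <- file.path(withr::local_tempdir(), "prof.tsv")
  write_profile_matrix(p, path)
  back <- read_profile_matrix(path)
  expect_equal(back$values, p$values)
  expect_identical(back$n_cells, p$n_cells)
  expect_identical(back$unit, p$unit)
})
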