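test_that("TSV matrices round-trip through write and read", {
  v <- matrix(c(1, 0, 3, 2, 0, 5), nrow = 3, byrow = TRUE)
  m <- count_matrix(v, c("Zdhhc5", "Zdhhc9", "Golga7"), c("c1", "c2"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix(m, path)
  back <- read_count_matrix(path, "tsv")
  expect_identical(back$genes, m$genes)
  expect_identical(back$cells, m$cells)
  expect_equal(back$values, m$values)
  expect_identical(back$unit, "counts")
})

test_that("MTX triplets expand to the dense matrix with implicit zeros", {
  dir <- withr::local_tempdir()
  mtx <- file.path(dir, "m.mtx")
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "3 3 4",
               "1 1 5", "2 3 7", "3 1 2", "3 3 1"), mtx)
  writeLines(c("Ga", "Gb", "Gc"), paste0(mtx, ".genes.tsv"))
  writeLines(c("c1", "c2", "c3"), paste0(mtx, ".cells.tsv"))
  m <- read_count_matrix(mtx, "mtx")
  # hand-expanded dense form of the 4 listed nonzeros
  expect_equal(unname(m$values),
               matrix(c(5, 0, 0, 0, 0, 7, 2, 0, 1), nrow = 3, byrow = TRUE))
  expect_equal(sum(m$values == 0), 5)
})

test_that("MTX with mismatched sidecar names is a format error", {
  dir <- withr::local_tempdir()
  mtx <- file.path(dir, "m.mtx")
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "2 2 1", "1 1 3"), mtx)
  writeLines(c("Ga", "Gb", "Gc"), paste0(mtx, ".genes.tsv"))
  writeLines(c("c1", "c2"), paste0(mtx, ".cells.tsv"))
  expect_error(read_count_matrix(mtx, "mtx"), "format error")
})

test_that("duplicate and negative entries are rejected with the culprit named", {
  expect_error(count_matrix(matrix(1, 2, 1), c("Zdhhc5", "ZDHHC5"), "c1"),
               "Zdhhc5")
  expect_error(count_matrix(matrix(-1, 1, 1), "Ga", "c1"), "negative")
})

test_that("loom matrices read through the HDF5 path", {
  skip_if_not_installed("rhdf5")
  path <- withr::local_tempfile(fileext = ".loom")
  v <- matrix(c(0, 2, 4, 1, 3, 9), nrow = 3)
  rhdf5::h5createFile(path)
  rhdf5::h5write(v, path, "matrix")
  rhdf5::h5createGroup(path, "row_attrs")
  rhdf5::h5createGroup(path, "col_attrs")
  rhdf5::h5write(c("Ga", "Gb", "Gc"), path, "row_attrs/Gene")
  rhdf5::h5write(c("c1", "c2"), path, "col_attrs/CellID")
  rhdf5::h5closeAll()
  m <- read_count_matrix(path, "loom")
  expect_identical(m$genes, c("Ga", "Gb", "Gc"))
  expect_equal(unname(m$values), v)
})

test_that("gene symbols canonicalize case-insensitively and idempotently", {
  expect_identical(canonicalize_genes(c("ZDHHC9", "Abhd16a", "golga7b")),
                   c("Zdhhc9", "Abhd16a", "Golga7b"))
  sym <- c("Ppt1", "LYPLA1", "abhd17A")
  once <- canonicalize_genes(sym)
  expect_identical(canonicalize_genes(once), once)
})

test_that("the builtin panel is the 39-gene palmitoylation machinery", {
  panel <- load_gene_panel()
  expect_equal(nrow(panel), 39)
  expect_equal(as.vector(table(panel$category)[c("zdhhc", "depalmitoylating",
                                                 "accessory")]),
               c(24L, 12L, 3L))
  expect_false("Zdhhc10" %in% panel$gene)
  expect_true(all(c("Zdhhc25", "Abhd17c", "Golga7b") %in% panel$gene))
  expect_identical(panel$category[panel$gene == "Selenok"], "accessory")
})

test_that("user panels with duplicate genes are rejected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tcategory", "Zdhhc3\tzdhhc", "Zdhhc3\tzdhhc"), path)
  expect_error(load_gene_panel(path), "Zdhhc3")
})

test_that("annotation flags intersect with the universe and report outsiders", {
  expect_warning(
    tab <- annotation_table(c("A", "B", "C"), list(s = c("B", "E"))),
    "E")
  expect_identical(tab$flags$s, "B")
  tab2 <- annotation_table(c("A", "B", "C", "D"),
                           list(s1 = c("B", "D"), s2 = "A"))
  expect_equal(lengths(tab2$flags), c(s1 = 2L, s2 = 1L))
  expect_error(annotation_table(character()), "empty")
})

test_that("annotation tables round-trip through their file format", {
  tab <- annotation_table(c("Gria1", "Grin1", "Dlg4", "Snap25"),
                          list(substrate = c("Gria1", "Snap25")))
  stem <- file.path(withr::local_tempdir(), "ann")
  write_annotation_table(tab, stem)
  back <- read_annotation_table(paste0(stem, ".universe.tsv"),
                                c(substrate = paste0(stem, ".substrate.tsv")))
  expect_identical(back$universe, tab$universe)
  expect_identical(back$flags, tab$flags)
})
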