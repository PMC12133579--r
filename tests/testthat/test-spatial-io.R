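test_that("cell and transcript readers validate and round-trip", {
  cells <- toy_cells(c(1, 2, 3), c(4, 5, 6), c("BC1", "BC2", "goblet"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cells(cells, f)
  back <- read_cells(f)
  expect_equal(back, cells)

  tx <- data.frame(gene = c("IL33", "CXCL8"), x_um = c(1.5, 2.5),
                   y_um = c(3, 4), qv = c(40, 18),
                   cell_id = c("c0001", UNASSIGNED_CELL),
                   stringsAsFactors = FALSE)
  g <- withr::local_tempfile(fileext = ".csv")
  write_transcripts(tx, g)
  expect_equal(read_transcripts(g), tx)

  ## missing required column is named in the error
  h <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(feature_name = tx$gene, x_location = tx$x_um,
                       y_location = tx$y_um, quality = tx$qv,
                       cell_id = tx$cell_id), h, row.names = FALSE)
  expect_error(read_transcripts(h), "qv")

  ## non-numeric coordinate reported with its row
  i <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(cell_id = c("a", "b"), x_centroid = c("1", "oops"),
                       y_centroid = c(2, 3)), i, row.names = FALSE)
  expect_error(read_cells(i), "x_centroid.*row 2")
})

test_that("transcript QC removes qv < q_min and zero-transcript cells", {
  cells <- toy_cells(c(0, 10, 20), c(0, 0, 0), "BC1")
  tx <- data.frame(gene = "IL33", x_um = 1:3, y_um = 0,
                   qv = c(19, 20, 25),
                   cell_id = c("c0001", "c0002", "c0003"),
                   stringsAsFactors = FALSE)
  res <- qc_filter(tx, cells, q_min = 20)
  ## strict less-than removal: qv = 20 is kept
  expect_equal(nrow(res$transcripts), 2)
  expect_true(all(res$transcripts$qv >= 20))
  ## the cell whose only transcript had qv 19 is gone
  expect_equal(res$cells$cell_id, c("c0002", "c0003"))
  expect_equal(res$report$n_transcripts_removed, 1)
  expect_equal(res$report$n_cells_removed, 1)
  expect_equal(res$report$median_transcripts_per_cell, 1)

  ## identity when everything passes, and idempotence in general
  res2 <- qc_filter(res$transcripts, res$cells)
  expect_identical(res2$transcripts, res$transcripts)
  expect_identical(res2$cells, res$cells)
})

test_that("QC is idempotent on generated tissue", {
  g <- generate_tissue(single_cluster_config(n_cells = 150), seed = 11)
  r1 <- qc_filter(g$transcripts, g$cells)
  r2 <- qc_filter(r1$transcripts, r1$cells)
  expect_identical(r1$transcripts, r2$transcripts)
  expect_identical(r1$cells, r2$cells)
})

test_that("count matrix tallies transcripts per cell and gene", {
  cells <- toy_cells(c(0, 1), c(0, 0), "BC1")
  tx <- data.frame(gene = c("G1", "G1", "G2"), x_um = 0, y_um = 0, qv = 30,
                   cell_id = "c0001", stringsAsFactors = FALSE)
  cm <- build_count_matrix(tx, cells)
  expect_equal(as.vector(cm$raw["c0001", c("G1", "G2")]), c(2, 1))
  expect_equal(sum(cm$raw["c0002", ]), 0)

  ## unassigned transcripts never enter the matrix
  tx$cell_id <- UNASSIGNED_CELL
  cm0 <- build_count_matrix(tx, cells)
  expect_equal(sum(cm0$raw), 0)
  expect_equal(dim(cm0$raw), c(2L, 2L))

  ## unknown cell reference is a consistency error
  bad <- tx; bad$cell_id <- "ghost"
  expect_error(build_count_matrix(bad, cells), "consistency error.*ghost")
})

test_that("count matrix equals a brute-force tally on random tissue", {
  g <- generate_tissue(single_cluster_config(n_cells = 50), seed = 3)
  qc <- qc_filter(g$transcripts, g$cells)
  cm <- build_count_matrix(qc$transcripts, qc$cells)
  tx <- qc$transcripts[qc$transcripts$cell_id != UNASSIGNED_CELL, ]
  for (i in seq_len(nrow(qc$cells))) {
    for (gname in colnames(cm$raw)) {
      expect_equal(cm$raw[qc$cells$cell_id[i], gname],
                   sum(tx$cell_id == qc$cells$cell_id[i] & tx$gene == gname))
    }
  }
  ## total matrix mass = retained assigned transcripts
  expect_equal(sum(cm$raw), nrow(tx))
})

test_that("normalization follows the closed form and preserves ranks", {
  m <- rbind(c(2, 0), c(1, 1))
  dimnames(m) <- list(c("a", "b"), c("G1", "G2"))
  cm <- normalize_counts(cm_from_matrix(m))
  ## m = median total = 2; cell a: log(1 + 2 * 2/2) = log 3
  expect_equal(cm$normalized["a", "G1"], log(3))
  expect_equal(cm$normalized["a", "G2"], 0)
  expect_equal(cm$normalization, "median_size_log")

  ## within-cell rank order of genes is preserved
  set.seed(5)
  m2 <- matrix(rpois(200, 3), 10, 20,
               dimnames = list(sprintf("c%d", 1:10), sprintf("g%d", 1:20)))
  m2[, 1] <- m2[, 1] + 1  # no zero-total cells
  cm2 <- normalize_counts(cm_from_matrix(m2))
  for (i in 1:10) {
    expect_equal(order(cm2$normalized[i, ], colnames(m2)),
                 order(m2[i, ], colnames(m2)))
  }

  ## zero-total cells must be rejected
  m3 <- rbind(c(0, 0), c(1, 1))
  dimnames(m3) <- list(c("a", "b"), c("G1", "G2"))
  expect_error(normalize_counts(cm_from_matrix(m3)), "zero total")
})

test_that("expressing-cell fractions ignore normalization", {
  g <- generate_tissue(single_cluster_config(n_cells = 120), seed = 9)
  qc <- qc_filter(g$transcripts, g$cells)
  cm <- build_count_matrix(qc$transcripts, qc$cells)
  f_raw <- frac_expressing(cm, qc$cells, "epi", "CXCL8")
  f_norm <- frac_expressing(normalize_counts(cm), qc$cells, "epi", "CXCL8")
  expect_identical(f_raw, f_norm)
})

test_that("matrix export writes MTX plus index files", {
  m <- matrix(c(1, 0, 2, 3), 2, 2,
              dimnames = list(c("c1", "c2"), c("g1", "g2")))
  d <- withr::local_tempdir()
  write_count_matrix(cm_from_matrix(m), d)
  expect_true(all(file.exists(file.path(d, c("matrix.mtx", "genes.tsv", "cells.tsv")))))
  back <- as.matrix(Matrix::readMM(file.path(d, "matrix.mtx")))
  expect_equal(unname(back), unname(m))
})
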