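## Xenium-dialect IO, transcript/cell QC, and count-matrix construction.
##
## The on-disk dialect follows the Xenium per-cell and per-transcript CSV
## exports: cells carry `cell_id, x_centroid, y_centroid` (+ optional
## annotation columns), transcripts carry
## `feature_name, x_location, y_location, qv, cell_id`. In memory both are
## plain data frames with micrometre coordinates.

#' Sentinel cell id for transcripts outside any segmented cell
#' @export
UNASSIGNED_CELL <- "UNASSIGNED"

.check_numeric_column <- function(x, col) {
  suppressWarnings(num <- as.numeric(x))
  bad <- which(is.na(num) & !is.na(x))
  if (length(bad)) {
    abort_format(sprintf("non-numeric value in column '%s' at data row %d",
                         col, bad[1]))
  }
  num
}

#' Read a Xenium-dialect cell table
#'
#' Required columns: `cell_id`, `x_centroid`, `y_centroid`. Optional
#' annotation columns (`cluster_label`, `donor_id`, `condition`,
#' `niche_label`) are carried through; unknown columns are preserved but
#' ignored by the analysis.
#'
#' @param path CSV path (plain or gzip).
#' @return data frame with columns `cell_id`, `x_um`, `y_um` and any
#'   annotation columns present.
#' @export
read_cells <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c("cell_id", "x_centroid", "y_centroid")) {
    if (!col %in% names(df)) abort_format(sprintf("missing required column '%s'", col))
  }
  out <- data.frame(
    cell_id = as.character(df$cell_id),
    x_um = .check_numeric_column(df$x_centroid, "x_centroid"),
    y_um = .check_numeric_column(df$y_centroid, "y_centroid"),
    stringsAsFactors = FALSE
  )
  for (col in c("cluster_label", "donor_id", "condition", "niche_label")) {
    if (col %in% names(df)) out[[col]] <- as.character(df[[col]])
  }
  if (anyDuplicated(out$cell_id)) abort_format("cell_id values are not unique")
  out
}

#' Read a Xenium-dialect transcript table
#'
#' Required columns: `feature_name`, `x_location`, `y_location`, `qv`,
#' `cell_id`. Transcripts not assigned to a cell use the
#' [UNASSIGNED_CELL] sentinel.
#'
#' @param path CSV path (plain or gzip).
#' @return data frame with columns `gene`, `x_um`, `y_um`, `qv`, `cell_id`.
#' @export
read_transcripts <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c("feature_name", "x_location", "y_location", "qv", "cell_id")) {
    if (!col %in% names(df)) abort_format(sprintf("missing required column '%s'", col))
  }
  out <- data.frame(
    gene = as.character(df$feature_name),
    x_um = .check_numeric_column(df$x_location, "x_location"),
    y_um = .check_numeric_column(df$y_location, "y_location"),
    qv = .check_numeric_column(df$qv, "qv"),
    cell_id = as.character(df$cell_id),
    stringsAsFactors = FALSE
  )
  if (any(out$qv < 0)) abort_format("qv values must be non-negative")
  out
}

#' Write cell / transcript tables in the Xenium column dialect
#'
#' Inverse of [read_cells()] / [read_transcripts()]; a write-read round trip
#' reproduces the input table.
#'
#' @param cells,transcripts tables as returned by the readers.
#' @param path output CSV path.
#' @export
write_cells <- function(cells, path) {
  out <- data.frame(cell_id = cells$cell_id,
                    x_centroid = cells$x_um,
                    y_centroid = cells$y_um,
                    stringsAsFactors = FALSE)
  for (col in c("cluster_label", "donor_id", "condition", "niche_label")) {
    if (col %in% names(cells)) out[[col]] <- cells[[col]]
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cells
#' @export
write_transcripts <- function(transcripts, path) {
  out <- data.frame(feature_name = transcripts$gene,
                    x_location = transcripts$x_um,
                    y_location = transcripts$y_um,
                    qv = transcripts$qv,
                    cell_id = transcripts$cell_id,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Transcript and cell quality control
#'
#' Removes low-quality transcripts (`qv < q_min`; the threshold itself is
#' kept) and then removes cells left with no assigned transcripts. QC is
#' idempotent.
#'
#' @param transcripts transcript table.
#' @param cells cell table.
#' @param q_min quality threshold; transcripts with `qv < q_min` are dropped
#'   (default 20).
#' @return list with elements `transcripts`, `cells` and `report`
#'   (a `qc_report` with removal counts and median transcripts per retained
#'   cell computed both before and after the transcript filter).
#' @export
qc_filter <- function(transcripts, cells, q_min = 20) {
  stopifnot(is.numeric(q_min), length(q_min) == 1L)
  keep_tx <- transcripts$qv >= q_min
  tx <- transcripts[keep_tx, , drop = FALSE]

  per_cell_pre <- table(factor(
    transcripts$cell_id[transcripts$cell_id != UNASSIGNED_CELL],
    levels = cells$cell_id))
  per_cell_post <- table(factor(
    tx$cell_id[tx$cell_id != UNASSIGNED_CELL], levels = cells$cell_id))

  keep_cells <- as.vector(per_cell_post) > 0
  out_cells <- cells[keep_cells, , drop = FALSE]
  rownames(out_cells) <- NULL
  rownames(tx) <- NULL

  report <- structure(list(
    n_transcripts_in = nrow(transcripts),
    n_transcripts_removed = sum(!keep_tx),
    n_transcripts_retained = nrow(tx),
    n_cells_in = nrow(cells),
    n_cells_removed = sum(!keep_cells),
    n_cells_retained = nrow(out_cells),
    median_transcripts_per_cell_pre_filter =
      if (nrow(cells)) stats::median(as.vector(per_cell_pre)) else NA_real_,
    median_transcripts_per_cell =
      if (nrow(out_cells)) stats::median(as.vector(per_cell_post)[keep_cells]) else NA_real_,
    q_min = q_min
  ), class = "qc_report")

  list(transcripts = tx, cells = out_cells, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "qc_report: %d/%d transcripts retained (qv >= %g), %d/%d cells retained, median %g transcripts/cell\n",
    x$n_transcripts_retained, x$n_transcripts_in, x$q_min,
    x$n_cells_retained, x$n_cells_in, x$median_transcripts_per_cell))
  invisible(x)
}

#' Write a QC report as JSON
#' @param report a `qc_report`.
#' @param path output path.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Build the cells-by-genes raw count matrix
#'
#' Entry (c, g) counts retained transcripts assigned to cell c for gene g.
#' Transcripts carrying the [UNASSIGNED_CELL] sentinel are excluded from the
#' matrix (they still contribute to density maps).
#'
#' @param transcripts QC-filtered transcript table.
#' @param cells QC-filtered cell table; defines row order.
#' @param panel optional character vector fixing the gene space (column
#'   order); defaults to the sorted genes observed.
#' @return a `count_matrix` object (sparse raw layer, no normalized layer
#'   yet).
#' @export
build_count_matrix <- function(transcripts, cells, panel = NULL) {
  tx <- transcripts[transcripts$cell_id != UNASSIGNED_CELL, , drop = FALSE]
  unknown <- setdiff(unique(tx$cell_id), cells$cell_id)
  if (length(unknown)) {
    stop("consistency error: transcripts reference unknown cell_id ",
         unknown[1], call. = FALSE)
  }
  genes <- panel %||% sort(unique(transcripts$gene))
  if (!all(tx$gene %in% genes)) {
    abort_format(sprintf("gene '%s' not in the panel",
                         setdiff(unique(tx$gene), genes)[1]))
  }
  i <- match(tx$cell_id, cells$cell_id)
  j <- match(tx$gene, genes)
  raw <- Matrix::sparseMatrix(i = i, j = j, x = rep(1, nrow(tx)),
                              dims = c(nrow(cells), length(genes)),
                              dimnames = list(cells$cell_id, genes))
  new_count_matrix(raw)
}

new_count_matrix <- function(raw, normalized = NULL, normalization = "none") {
  structure(list(raw = raw, normalized = normalized,
                 normalization = normalization),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d cells x %d genes, %s normalization\n",
              nrow(x$raw), ncol(x$raw), x$normalization))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$raw)

#' Median-library-size log normalization
#'
#' Adds the normalized layer `log(1 + raw * m / total_c)` with `m` the median
#' per-cell total. This monotone per-cell rescaling is used only for displayed
#' expression levels; expressing-cell frequencies always use the raw layer.
#'
#' @param counts a `count_matrix`.
#' @return the `count_matrix` with its `normalized` layer filled in and the
#'   provenance flag set to `"median_size_log"`.
#' @export
normalize_counts <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  totals <- Matrix::rowSums(counts$raw)
  if (any(totals == 0)) {
    stop("cells with zero total counts present; run qc_filter() first",
         call. = FALSE)
  }
  m <- stats::median(totals)
  norm <- log1p(counts$raw * (m / totals))
  new_count_matrix(counts$raw, normalized = norm,
                   normalization = "median_size_log")
}

#' Export a count matrix as MatrixMarket plus index files
#'
#' Writes `matrix.mtx` (raw layer), `genes.tsv` and `cells.tsv` under `dir`.
#'
#' @param counts a `count_matrix`.
#' @param dir output directory (created if needed).
#' @export
write_count_matrix <- function(counts, dir) {
  stopifnot(inherits(counts, "count_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(counts$raw, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(gene = colnames(counts$raw)),
                     file.path(dir, "genes.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  utils::write.table(data.frame(cell = rownames(counts$raw)),
                     file.path(dir, "cells.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(dir)
}
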