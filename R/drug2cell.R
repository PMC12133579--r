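## Spatial drug-to-cell scoring: each cell is scored for each drug as the
## mean expression of the drug's target genes, summarized per cluster
## (frequency of impacted cells, mean interaction strength, rank-based P,
## top-5 drugs), and projected onto tissue coordinates for overlay rendering.

#' Load a drug-to-target map and filter it to the measured panel
#'
#' Accepts a TSV path or a data frame with `drug` and `target` columns
#' (ChEMBL-derived tables fit this shape). Duplicate (drug, target) rows are
#' deduplicated, targets outside the panel removed, and drugs left with no
#' measured target dropped (their number is recorded).
#'
#' @param table TSV path or data frame with columns `drug`, `target`.
#' @param panel character vector of measured gene symbols.
#' @param provenance free-text provenance tag (e.g. "ChEMBL v30").
#' @return a `drug_target_map`: named list drug -> character vector of
#'   targets, with attributes `n_dropped` and `provenance`.
#' @export
load_drug_targets <- function(table, panel, provenance = "user-supplied") {
  if (is.character(table) && length(table) == 1L) {
    df <- utils::read.delim(table, stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(table, stringsAsFactors = FALSE)
  }
  for (col in c("drug", "target")) {
    if (!col %in% names(df)) abort_format(sprintf("missing required column '%s'", col))
  }
  bad <- which(is.na(df$drug) | df$drug == "" | is.na(df$target) | df$target == "")
  if (length(bad)) {
    abort_format(sprintf("malformed row at data row %d (empty drug or target)",
                         bad[1]))
  }
  df <- unique(df[, c("drug", "target")])
  df <- df[df$target %in% panel, , drop = FALSE]
  map <- split(df$target, df$drug)
  n_in <- length(unique(df$drug))
  all_drugs <- if (is.character(table)) NULL else table$drug
  n_total <- length(unique(all_drugs %||% df$drug))
  map <- map[lengths(map) > 0]
  structure(map,
            n_dropped = n_total - length(map),
            provenance = provenance,
            class = "drug_target_map")
}

#' @export
print.drug_target_map <- function(x, ...) {
  cat(sprintf("drug_target_map: %d drugs (%s), %d dropped with no panel target\n",
              length(x), attr(x, "provenance"), attr(x, "n_dropped")))
  invisible(x)
}

#' Score every cell for every drug
#'
#' `score(cell, drug)` is the mean over the drug's target genes of the cell's
#' expression; drugs with a single target reduce exactly to that gene's
#' value. The normalized layer is the default scoring substrate; `layer =
#' "raw"` scores on raw counts for literal fidelity to raw-expression
#' scoring.
#'
#' @param counts a `count_matrix` (normalized when `layer = "normalized"`).
#' @param map a panel-filtered [load_drug_targets()] map.
#' @param layer `"normalized"` (default) or `"raw"`.
#' @return dense matrix, cells by drugs.
#' @export
score_cells <- function(counts, map, layer = c("normalized", "raw")) {
  layer <- match.arg(layer)
  stopifnot(inherits(counts, "count_matrix"), inherits(map, "drug_target_map"))
  if (layer == "normalized" && is.null(counts$normalized)) {
    counts <- normalize_counts(counts)
  }
  X <- if (layer == "normalized") counts$normalized else counts$raw
  genes <- colnames(counts$raw)
  missing <- setdiff(unique(unlist(map)), genes)
  if (length(missing)) {
    stop("assertion error: drug target '", missing[1],
         "' is not measured; filter the map to the panel first", call. = FALSE)
  }
  ## indicator matrix genes x drugs, scaled so X %*% W takes target means
  W <- Matrix::sparseMatrix(
    i = match(unlist(map), genes),
    j = rep(seq_along(map), lengths(map)),
    x = rep(1 / lengths(map), lengths(map)),
    dims = c(length(genes), length(map)),
    dimnames = list(genes, names(map)))
  scores <- as.matrix(X %*% W)
  rownames(scores) <- rownames(counts$raw)
  scores
}

#' Per-cluster drug interaction summary
#'
#' For every cluster and drug: the frequency of impacted cells (score above
#' `impact_threshold`, default 0), the mean interaction strength, and a
#' two-sided rank-based P of the cluster's scores against all other cells.
#' The per-cluster top-5 list ranks drugs by strength, ties broken
#' lexicographically.
#'
#' @param scores matrix from [score_cells()].
#' @param cells cell table aligned with the score rows (needs
#'   `cluster_label`).
#' @param impact_threshold score above which a cell counts as impacted
#'   (default 0).
#' @param top_n size of the per-cluster top drug list (default 5).
#' @return list with `summary` (data frame cluster x drug) and `top`
#'   (named list of per-cluster top drug vectors).
#' @export
cluster_summary <- function(scores, cells, impact_threshold = 0, top_n = 5) {
  stopifnot(nrow(scores) == nrow(cells))
  clusters <- sort(unique(cells$cluster_label))
  rows <- list()
  top <- list()
  for (cl in clusters) {
    in_cl <- cells$cluster_label == cl
    if (!any(in_cl)) {
      warning("cluster '", cl, "' is empty; skipped")
      next
    }
    strength <- colMeans(scores[in_cl, , drop = FALSE])
    freq <- colMeans(scores[in_cl, , drop = FALSE] > impact_threshold)
    p <- vapply(colnames(scores), function(dr) {
      compare_two_sided(scores[in_cl, dr], scores[!in_cl, dr])$p
    }, numeric(1))
    rows[[cl]] <- data.frame(cluster = cl, drug = colnames(scores),
                             frequency_impacted = unname(freq),
                             strength = unname(strength), p = unname(p),
                             stringsAsFactors = FALSE)
    ord <- order(-strength, colnames(scores))
    top[[cl]] <- colnames(scores)[ord][seq_len(min(top_n, ncol(scores)))]
  }
  structure(list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 top = top),
            class = "drug_score_result")
}

#' @export
print.drug_score_result <- function(x, ...) {
  cat(sprintf("drug_score_result: %d clusters x %d drugs\n",
              length(x$top), length(unique(x$summary$drug))))
  invisible(x)
}

#' Project drug scores onto tissue coordinates
#'
#' Joins one drug's per-cell scores with cell centroids and grids them on the
#' same kind of raster as [density_map()] (raster value = mean score of the
#' cells in the bin).
#'
#' @param scores matrix from [score_cells()].
#' @param cells cell table aligned with the score rows.
#' @param drug drug name (must be scored).
#' @param bin_size raster bin size in micrometres (default 10).
#' @return list with `table` (cell_id, x_um, y_um, score) and `raster`
#'   (matrix with `xb`, `yb` breaks as attributes).
#' @export
spatial_projection <- function(scores, cells, drug, bin_size = 10) {
  if (!drug %in% colnames(scores)) {
    stop("unknown drug '", drug, "'", call. = FALSE)
  }
  s <- scores[, drug]
  tab <- data.frame(cell_id = cells$cell_id, x_um = cells$x_um,
                    y_um = cells$y_um, score = unname(s),
                    stringsAsFactors = FALSE)
  bbox <- c(min(cells$x_um), max(cells$x_um), min(cells$y_um), max(cells$y_um))
  grid <- .density_grid(cells$x_um, cells$y_um, bin_size, bbox)
  sums <- .bin_counts(grid, grid$gx, grid$gy)
  tot <- matrix(0, grid$nx, grid$ny)
  for (i in seq_len(nrow(tab))) {
    tot[grid$gx[i], grid$gy[i]] <- tot[grid$gx[i], grid$gy[i]] + s[i]
  }
  raster <- ifelse(sums > 0, tot / sums, 0)
  attr(raster, "xb") <- grid$xb
  attr(raster, "yb") <- grid$yb
  list(table = tab, raster = raster)
}
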