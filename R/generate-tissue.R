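## Synthetic tissue generation. Each donor occupies its own section on a
## virtual slide (sections are spaced farther apart than any neighbor
## window, so pooled spatial statistics never cross sections). Cells are
## placed uniformly within their cluster's niche, disease-condition cells
## are contracted toward the nearest hub anchor, and transcripts are drawn
## per cell from negative-binomial counts with hub and condition effects.

.sample_in_polygon <- function(n, poly) {
  if (n == 0) return(cbind(x = numeric(0), y = numeric(0)))
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  out <- matrix(NA_real_, 0, 2)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 16L)
    px <- stats::runif(m, xr[1], xr[2])
    py <- stats::runif(m, yr[1], yr[2])
    ok <- point_in_polygon(px, py, poly)
    out <- rbind(out, cbind(px[ok], py[ok]))
  }
  out[seq_len(n), , drop = FALSE]
}

.tissue_bbox_poly <- function(config) {
  ys <- unlist(lapply(config$niches$polygons, function(p) p[, 2]))
  xs <- unlist(lapply(config$niches$polygons, function(p) p[, 1]))
  rect_poly(min(xs), min(ys), max(xs), max(ys))
}

#' Generate a synthetic tissue with recorded ground truth
#'
#' Produces a cell table, a transcript table and a `synthetic_truth` record
#' (planted hub anchors, fold changes, the expected disease/reference median
#' shortest-distance ratio, and the seed). Identical `(config, seed)` give
#' bit-identical outputs.
#'
#' @param config a [tissue_config()].
#' @param seed integer seed.
#' @return list with `cells`, `transcripts`, `truth`.
#' @export
generate_tissue <- function(config, seed = 1) {
  stopifnot(inherits(config, "tissue_config"))
  withr::with_seed(as.integer(seed), .generate_tissue_impl(config, seed))
}

.generate_tissue_impl <- function(config, seed) {
  panel <- config$panel
  clus <- config$clusters
  weights <- clus$weight / sum(clus$weight)
  bbox_poly <- .tissue_bbox_poly(config)
  sec_w <- max(bbox_poly[, 1]) - min(bbox_poly[, 1]) + config$section_gap_um

  cells_l <- list(); tx_l <- list(); hubs_l <- list()
  section <- 0L
  for (ci in seq_along(config$conditions)) {
    cond <- config$conditions[ci]
    contraction <- config$condition_effects$contraction[[cond]]
    fc <- 2^config$condition_effects$log2fc[, cond]
    for (di in seq_len(config$donors_per_condition)) {
      donor <- sprintf("%s%d", toupper(substr(cond, 1, 1)), di)
      xoff <- section * sec_w
      section <- section + 1L
      n <- config$n_cells_per_donor

      ## per-donor log-normal factor on gene means
      donor_factor <- exp(stats::rnorm(length(panel), 0, config$donor_sigma))

      ## hub anchors for this section
      hub_poly <- if (config$hubs$placement == "any") bbox_poly
                  else config$niches$polygons[[config$hubs$placement]]
      hub_xy <- .sample_in_polygon(config$hubs$n_hubs, hub_poly)
      if (nrow(hub_xy)) {
        hubs_l[[length(hubs_l) + 1L]] <- data.frame(
          condition = cond, donor = donor,
          x_um = hub_xy[, 1] + xoff, y_um = hub_xy[, 2],
          radius_um = config$hubs$radius_um, stringsAsFactors = FALSE)
      }
      if (n == 0) next

      ## cluster assignment and placement
      cl_idx <- sample.int(nrow(clus), n, replace = TRUE, prob = weights)
      xy <- matrix(NA_real_, n, 2)
      for (k in sort(unique(cl_idx))) {
        rows <- which(cl_idx == k)
        poly <- if (clus$niche[k] == "any") bbox_poly
                else config$niches$polygons[[clus$niche[k]]]
        xy[rows, ] <- .sample_in_polygon(length(rows), poly)
      }

      ## disease-condition contraction toward the nearest hub anchor
      if (contraction < 1 && nrow(hub_xy)) {
        anchor <- .nn_index(xy[, 1], xy[, 2], hub_xy[, 1], hub_xy[, 2])
        ax <- hub_xy[anchor, 1]; ay <- hub_xy[anchor, 2]
        xy[, 1] <- ax + contraction * (xy[, 1] - ax)
        xy[, 2] <- ay + contraction * (xy[, 2] - ay)
      }

      ## hub membership (before the slide offset; anchors are section-local)
      in_hub <- rep(FALSE, n)
      if (nrow(hub_xy)) {
        for (hh in seq_len(nrow(hub_xy))) {
          d2 <- (xy[, 1] - hub_xy[hh, 1])^2 + (xy[, 2] - hub_xy[hh, 2])^2
          in_hub <- in_hub | d2 <= config$hubs$radius_um^2
        }
      }

      cell_id <- sprintf("%s_%s_c%05d", cond, donor, seq_len(n))
      niche_label <- rep("unassigned", n)
      for (nm in names(config$niches$polygons)) {
        todo <- niche_label == "unassigned"
        hit <- point_in_polygon(xy[todo, 1], xy[todo, 2],
                                config$niches$polygons[[nm]])
        niche_label[todo][hit] <- nm
      }

      ## expression means: cluster profile x donor factor x condition FC
      ## (x hub multiplier for hub genes in in-hub cells)
      mu <- config$expression$mu[clus$name[cl_idx], , drop = FALSE]
      mu <- sweep(mu, 2, donor_factor * fc, "*")
      hub_genes <- intersect(config$hubs$genes, panel)
      if (any(in_hub) && length(hub_genes)) {
        mu[in_hub, hub_genes] <- mu[in_hub, hub_genes] * config$hubs$multiplier
      }
      counts <- matrix(
        stats::rnbinom(length(mu), mu = as.vector(mu),
                       size = config$expression$size),
        nrow = n)

      ## expand counts to molecules
      tot <- rowSums(counts)
      if (sum(tot) > 0) {
        cell_of <- rep(seq_len(n), times = tot)
        gene_of <- rep(rep(panel, each = 0), 0)
        nz <- which(counts > 0, arr.ind = TRUE)
        gene_of <- rep(panel[nz[, 2]], counts[nz])
        mol_cell <- rep(nz[, 1], counts[nz])
        ord <- order(mol_cell)
        mol_cell <- mol_cell[ord]; gene_of <- gene_of[ord]
        m <- length(mol_cell)
        mx <- xy[mol_cell, 1] + stats::rnorm(m, 0, config$transcript_jitter_um)
        my <- xy[mol_cell, 2] + stats::rnorm(m, 0, config$transcript_jitter_um)
        low <- stats::runif(m) < config$qv_low_fraction
        qv <- ifelse(low,
                     stats::rnorm(m, config$qv_modes[["low"]], config$qv_sds[["low"]]),
                     stats::rnorm(m, config$qv_modes[["high"]], config$qv_sds[["high"]]))
        qv <- pmax(qv, 0)
        owner <- cell_id[mol_cell]
        owner[stats::runif(m) < config$unassigned_fraction] <- UNASSIGNED_CELL
        tx_l[[length(tx_l) + 1L]] <- data.frame(
          gene = gene_of, x_um = mx + xoff, y_um = my, qv = qv,
          cell_id = owner, stringsAsFactors = FALSE)
      }

      cells_l[[length(cells_l) + 1L]] <- data.frame(
        cell_id = cell_id, x_um = xy[, 1] + xoff, y_um = xy[, 2],
        cluster_label = clus$name[cl_idx], donor_id = donor,
        condition = cond, niche_label = niche_label,
        stringsAsFactors = FALSE)
    }
  }

  empty_cells <- data.frame(cell_id = character(), x_um = numeric(),
                            y_um = numeric(), cluster_label = character(),
                            donor_id = character(), condition = character(),
                            niche_label = character(), stringsAsFactors = FALSE)
  empty_tx <- data.frame(gene = character(), x_um = numeric(),
                         y_um = numeric(), qv = numeric(),
                         cell_id = character(), stringsAsFactors = FALSE)
  cells <- if (length(cells_l)) do.call(rbind, cells_l) else empty_cells
  transcripts <- if (length(tx_l)) do.call(rbind, tx_l) else empty_tx
  rownames(cells) <- NULL; rownames(transcripts) <- NULL

  hubs <- if (length(hubs_l)) do.call(rbind, hubs_l) else
    data.frame(condition = character(), donor = character(), x_um = numeric(),
               y_um = numeric(), radius_um = numeric(), stringsAsFactors = FALSE)
  if (nrow(cells) == 0) hubs <- hubs[0, , drop = FALSE]

  ref <- config$conditions[1]
  truth <- structure(list(
    hubs = hubs,
    log2fc = config$condition_effects$log2fc,
    contraction = config$condition_effects$contraction,
    expected_distance_ratio = stats::setNames(
      config$condition_effects$contraction /
        config$condition_effects$contraction[[ref]],
      names(config$condition_effects$contraction)),
    hub_multiplier = config$hubs$multiplier,
    hub_genes = intersect(config$hubs$genes, config$panel),
    seed = seed
  ), class = "synthetic_truth")

  list(cells = cells, transcripts = transcripts, truth = truth)
}

## index of nearest anchor for each point (small anchor sets; exact)
.nn_index <- function(px, py, ax, ay) {
  vapply(seq_along(px), function(i) {
    which.min((ax - px[i])^2 + (ay - py[i])^2)
  }, integer(1))
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "synthetic_truth: %d planted hubs, hub multiplier %g, contraction: %s (seed %s)\n",
    nrow(x$hubs), x$hub_multiplier,
    paste(sprintf("%s=%g", names(x$contraction), x$contraction), collapse = ", "),
    format(x$seed)))
  invisible(x)
}

#' Write a synthetic truth record as JSON
#' @param truth a `synthetic_truth`.
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  out <- list(hubs = truth$hubs,
              contraction = as.list(truth$contraction),
              expected_distance_ratio = as.list(truth$expected_distance_ratio),
              hub_multiplier = truth$hub_multiplier,
              hub_genes = truth$hub_genes,
              seed = truth$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
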