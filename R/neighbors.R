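## Cellular neighbor analysis: per-cell shortest distance between clusters,
## distance repartition histograms, neighbor counts within a radius, the
## positive-interaction rule, and condition comparisons.
##
## Nearest-neighbor queries use a uniform grid of buckets with expanding ring
## search. The search is exact (a candidate found in ring k bounds the
## remaining rings that must be scanned) and is verified against an O(n^2)
## oracle in the test suite.

.grid_index <- function(x, y, x0, y0, s, nx) {
  gx <- floor((x - x0) / s)
  gy <- floor((y - y0) / s)
  list(gx = gx, gy = gy, key = gx + gy * nx + 1)
}

.build_grid <- function(bx, by, s = NULL) {
  x0 <- min(bx); y0 <- min(by)
  span <- max(max(bx) - x0, max(by) - y0)
  if (is.null(s)) s <- max(span / max(1, floor(sqrt(length(bx)))), 1e-9)
  nx <- floor((max(bx) - x0) / s) + 2L
  ny <- floor((max(by) - y0) / s) + 2L
  idx <- .grid_index(bx, by, x0, y0, s, nx)
  buckets <- split(seq_along(bx), idx$key)
  list(x0 = x0, y0 = y0, s = s, nx = nx, ny = ny, buckets = buckets)
}

.ring_candidates <- function(grid, gx, gy, k) {
  if (k == 0) {
    keys <- gx + gy * grid$nx + 1
  } else {
    kk <- -k:k
    top <- cbind(gx + kk, gy - k)
    bot <- cbind(gx + kk, gy + k)
    kk2 <- (-k + 1):(k - 1)
    sides <- if (k > 0 && length(kk2)) {
      rbind(cbind(gx - k, gy + kk2), cbind(gx + k, gy + kk2))
    } else NULL
    cells <- rbind(top, bot, sides)
    keys <- cells[, 1] + cells[, 2] * grid$nx + 1
  }
  unlist(grid$buckets[as.character(keys)], use.names = FALSE)
}

## Exact nearest-neighbor distances from points (ax, ay) to the set
## (bx, by). `self` gives, per A point, the index in B to exclude (or NA).
.nn_dist <- function(ax, ay, bx, by, self = NULL) {
  nB <- length(bx)
  grid <- .build_grid(bx, by)
  out <- numeric(length(ax))
  max_ring <- max(grid$nx, grid$ny)
  for (i in seq_along(ax)) {
    ## clamp to the grid: rings around the nearest grid cell still satisfy
    ## the (k - 1) * s lower bound on distance, so pruning stays valid
    gx <- min(max(floor((ax[i] - grid$x0) / grid$s), 0), grid$nx - 1L)
    gy <- min(max(floor((ay[i] - grid$y0) / grid$s), 0), grid$ny - 1L)
    best <- Inf
    k <- 0L
    k_stop <- max_ring
    while (k <= k_stop) {
      cand <- .ring_candidates(grid, gx, gy, k)
      if (!is.null(self) && !is.na(self[i])) cand <- cand[cand != self[i]]
      if (length(cand)) {
        d2 <- (bx[cand] - ax[i])^2 + (by[cand] - ay[i])^2
        m <- min(d2)
        if (m < best) {
          best <- m
          ## candidates beyond ring ceil(d/s)+1 cannot beat distance d
          k_stop <- min(k_stop, ceiling(sqrt(best) / grid$s) + 1)
        }
      }
      k <- k + 1L
    }
    out[i] <- sqrt(best)
  }
  out
}

## Exact count of B points within radius R of each A point.
.range_count <- function(ax, ay, bx, by, R, self = NULL) {
  grid <- .build_grid(bx, by, s = max(R, 1e-9))
  out <- integer(length(ax))
  for (i in seq_along(ax)) {
    ## clamping to one cell beyond the grid keeps the true cell index for
    ## every query that can have an in-range neighbor (s >= R)
    gx <- min(max(floor((ax[i] - grid$x0) / grid$s), -1), grid$nx)
    gy <- min(max(floor((ay[i] - grid$y0) / grid$s), -1), grid$ny)
    cand <- unlist(lapply(0:1, function(k) .ring_candidates(grid, gx, gy, k)),
                   use.names = FALSE)
    ## with s >= R, rings 0-1 cover every point within distance R
    if (!is.null(self) && !is.na(self[i])) cand <- cand[cand != self[i]]
    if (length(cand)) {
      d2 <- (bx[cand] - ax[i])^2 + (by[cand] - ay[i])^2
      out[i] <- sum(d2 <= R^2)
    }
  }
  out
}

.cluster_xy <- function(cells, cluster, niche = NULL) {
  sel <- cells$cluster_label == cluster
  if (!is.null(niche)) sel <- sel & cells$niche_label == niche
  which(sel)
}

#' Per-cell shortest distance from one cluster to another
#'
#' For every cell of cluster `A`, the Euclidean distance to the nearest cell
#' of cluster `B`. When `A == B` each cell's own record is excluded. When
#' `niche` is given the analysis is restricted to cells of that niche.
#'
#' @param cells cell table with `cluster_label` (and `niche_label` when
#'   `niche` is used).
#' @param A source cluster.
#' @param B target cluster.
#' @param niche optional niche label restricting both clusters.
#' @return numeric vector, one distance (micrometres) per A cell, in row
#'   order of the cell table.
#' @export
shortest_distances <- function(cells, A, B, niche = NULL) {
  ia <- .cluster_xy(cells, A, niche)
  ib <- .cluster_xy(cells, B, niche)
  if (!length(ib)) stop("cluster '", B, "' is empty", call. = FALSE)
  if (!length(ia)) stop("cluster '", A, "' is empty", call. = FALSE)
  if (A == B && length(ib) < 2) {
    stop("cluster '", B, "' has a single cell; no neighbor exists", call. = FALSE)
  }
  self <- if (A == B) match(ia, ib) else NULL
  .nn_dist(cells$x_um[ia], cells$y_um[ia],
           cells$x_um[ib], cells$y_um[ib], self = self)
}

#' Distance repartition histogram
#'
#' Per-bin fraction of source cells whose shortest distance falls in the
#' right-open bin `[lo, hi)`; distances at or beyond `d_max` are excluded, so
#' the fractions sum to the fraction of cells within `d_max`.
#'
#' @param distances distances from [shortest_distances()].
#' @param bin_width bin width in micrometres (default 5).
#' @param d_max histogram ceiling (default 100; 150 is the wider display
#'   window).
#' @return data frame with `lo`, `hi`, `fraction`.
#' @export
repartition <- function(distances, bin_width = 5, d_max = 100) {
  stopifnot(bin_width > 0, d_max > 0)
  lo <- seq(0, d_max - bin_width, by = bin_width)
  hi <- lo + bin_width
  n <- length(distances)
  counts <- vapply(seq_along(lo), function(i) {
    sum(distances >= lo[i] & distances < hi[i])
  }, numeric(1))
  data.frame(lo = lo, hi = hi,
             fraction = if (n) counts / n else rep(0, length(lo)))
}

#' Mean number of neighboring cells within a radius
#'
#' Mean over source-cluster cells of the number of target-cluster cells at
#' distance `<= R`; a cell is never its own neighbor.
#'
#' @inheritParams shortest_distances
#' @param R radius in micrometres (default 50).
#' @return mean neighbor count.
#' @export
mean_neighbors_within <- function(cells, A, B, R = 50, niche = NULL) {
  ia <- .cluster_xy(cells, A, niche)
  ib <- .cluster_xy(cells, B, niche)
  if (!length(ia)) stop("cluster '", A, "' is empty", call. = FALSE)
  if (!length(ib) || R <= 0) return(0)
  self <- if (A == B) match(ia, ib) else NULL
  mean(.range_count(cells$x_um[ia], cells$y_um[ia],
                    cells$x_um[ib], cells$y_um[ib], R, self = self))
}

#' Positive-interaction rule
#'
#' `TRUE` when at least one cell from each cluster lies within `R` of a cell
#' of the other (equivalently, the minimum inter-cluster distance is `<= R`).
#'
#' @inheritParams mean_neighbors_within
#' @return logical flag; symmetric in (A, B).
#' @export
interaction_positive <- function(cells, A, B, R = 50, niche = NULL) {
  ia <- .cluster_xy(cells, A, niche)
  ib <- .cluster_xy(cells, B, niche)
  if (!length(ia) || !length(ib)) return(FALSE)
  if (A == B && length(ia) < 2) return(FALSE)
  self <- if (A == B) match(ia, ib) else NULL
  d <- .nn_dist(cells$x_um[ia], cells$y_um[ia],
                cells$x_um[ib], cells$y_um[ib], self = self)
  any(d <= R)
}

#' Compare shortest-distance distributions between conditions
#'
#' Two-sided Mann-Whitney on the per-cell shortest distances of the two
#' conditions, with the sign of the median difference
#' (disease minus reference; negative means contraction).
#'
#' @param dist_ref distances in the reference condition.
#' @param dist_alt distances in the comparison condition.
#' @return list with `p`, `direction` (-1, 0, 1) and `median_difference`.
#' @export
compare_conditions <- function(dist_ref, dist_alt) {
  res <- compare_two_sided(dist_alt, dist_ref)
  md <- stats::median(dist_alt) - stats::median(dist_ref)
  list(p = res$p, direction = sign(md), median_difference = md)
}

#' Neighbor profile for a cluster pair
#'
#' Bundles the shortest distances, repartition histogram, mean neighbor count
#' within `R` and the positive-interaction flag for one source/target pair.
#'
#' @inheritParams shortest_distances
#' @param R neighbor radius (default 50).
#' @param d_max repartition ceiling (default 100).
#' @param bin_width repartition bin width (default 5).
#' @return a `neighbor_profile` list.
#' @export
neighbor_profile <- function(cells, A, B, R = 50, d_max = 100, bin_width = 5,
                             niche = NULL) {
  d <- shortest_distances(cells, A, B, niche = niche)
  structure(list(
    source = A, target = B, distances = d,
    histogram = repartition(d, bin_width = bin_width, d_max = d_max),
    R = R, d_max = d_max,
    mean_neighbors = mean_neighbors_within(cells, A, B, R = R, niche = niche),
    interaction = interaction_positive(cells, A, B, R = R, niche = niche)
  ), class = "neighbor_profile")
}

#' @export
print.neighbor_profile <- function(x, ...) {
  cat(sprintf(
    "neighbor_profile %s -> %s: median shortest distance %.1f um, %.2f neighbors within %g um, interaction %s\n",
    x$source, x$target, stats::median(x$distances), x$mean_neighbors, x$R,
    if (x$interaction) "positive" else "negative"))
  invisible(x)
}
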