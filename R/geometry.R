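## Low-level planar geometry shared by the region annotator and the tissue
## generator. All coordinates are physical micrometres.

## Is point (px, py) on segment (x1,y1)-(x2,y2)? Tolerance is absolute.
.on_segment <- function(px, py, x1, y1, x2, y2, tol = 1e-9) {
  cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
  seg_len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  if (seg_len == 0) return(abs(px - x1) < tol & abs(py - y1) < tol)
  abs(cross) / seg_len < tol &
    px >= pmin(x1, x2) - tol & px <= pmax(x1, x2) + tol &
    py >= pmin(y1, y2) - tol & py <= pmax(y1, y2) + tol
}

#' Boundary-inclusive point-in-polygon test
#'
#' Crossing-number (even-odd) test with an explicit on-boundary check, so
#' points exactly on an edge or vertex are counted as inside. Cells sitting on
#' hand-drawn niche outlines are therefore never dropped.
#'
#' @param px,py point coordinates (vectors of equal length).
#' @param poly two-column matrix of polygon vertices (closed implicitly).
#' @return logical vector, `TRUE` when the point lies inside or on the
#'   boundary.
#' @export
point_in_polygon <- function(px, py, poly) {
  poly <- as.matrix(poly)
  stopifnot(ncol(poly) == 2, nrow(poly) >= 3, length(px) == length(py))
  vx <- poly[, 1]; vy <- poly[, 2]
  n <- nrow(poly)
  jx <- vx[c(n, seq_len(n - 1L))]  # previous vertex
  jy <- vy[c(n, seq_len(n - 1L))]
  inside <- rep(FALSE, length(px))
  on_bnd <- rep(FALSE, length(px))
  for (e in seq_len(n)) {
    x1 <- jx[e]; y1 <- jy[e]; x2 <- vx[e]; y2 <- vy[e]
    on_bnd <- on_bnd | .on_segment(px, py, x1, y1, x2, y2)
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      flip <- crosses & (px < xint)
      inside[flip] <- !inside[flip]
    }
  }
  inside | on_bnd
}

## Proper (interior) crossing of two segments; collinear touching does not
## count, so adjacent polygons sharing an edge are not flagged.
.segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

## Simple-polygon check: no two non-adjacent edges properly cross.
.polygon_is_simple <- function(poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  edges <- lapply(seq_len(n), function(i) {
    rbind(poly[i, ], poly[if (i == n) 1L else i + 1L, ])
  })
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ## skip adjacent edges (share a vertex), including the wrap-around pair
      if (j == i + 1L || (i == 1L && j == n)) next
      if (.segments_cross(edges[[i]][1, ], edges[[i]][2, ],
                          edges[[j]][1, ], edges[[j]][2, ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

## Do two simple polygons share interior area? Shared boundaries are allowed
## (adjacent tissue bands touch along an edge without overlapping).
.polygons_overlap <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  na <- nrow(a); nb <- nrow(b)
  for (i in seq_len(na)) {
    i2 <- if (i == na) 1L else i + 1L
    for (j in seq_len(nb)) {
      j2 <- if (j == nb) 1L else j + 1L
      if (.segments_cross(a[i, ], a[i2, ], b[j, ], b[j2, ])) return(TRUE)
    }
  }
  ## strict containment of a vertex (boundary contact excluded)
  strict_in <- function(px, py, poly) {
    ins <- point_in_polygon(px, py, poly)
    on_b <- vapply(seq_along(px), function(k) {
      n <- nrow(poly)
      any(vapply(seq_len(n), function(e) {
        e2 <- if (e == n) 1L else e + 1L
        .on_segment(px[k], py[k], poly[e, 1], poly[e, 2], poly[e2, 1], poly[e2, 2])
      }, logical(1)))
    }, logical(1))
    ins & !on_b
  }
  any(strict_in(a[, 1], a[, 2], b)) || any(strict_in(b[, 1], b[, 2], a))
}

## Axis-aligned rectangle as a closed polygon matrix.
rect_poly <- function(xmin, ymin, xmax, ymax) {
  cbind(x = c(xmin, xmax, xmax, xmin), y = c(ymin, ymin, ymax, ymax))
}

## Shoelace area (positive regardless of orientation).
.polygon_area <- function(poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1L))
  abs(sum(poly[j, 1] * poly[, 2] - poly[, 1] * poly[j, 2])) / 2
}
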