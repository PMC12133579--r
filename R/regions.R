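## Niche region annotation. The epithelial and mucous-gland niches of the
## airway wall are delineated manually in practice; here they arrive as named
## simple polygons (GeoJSON FeatureCollection) and cells are labelled by
## centroid membership.

#' Create a set of named niche regions
#'
#' @param polygons named list of two-column vertex matrices (micrometres).
#'   Names are the niche labels (conventionally `epithelial`, `mucous_gland`,
#'   `smooth_muscle`, or `custom:*`).
#' @return a `region_set` object.
#' @export
region_set <- function(polygons) {
  if (length(polygons) == 0) abort_config("region set is empty")
  nm <- names(polygons)
  if (is.null(nm) || any(nm == "")) abort_config("every region needs a name")
  if (anyDuplicated(nm)) abort_config("region names must be unique")
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    storage.mode(p) <- "double"
    colnames(p) <- c("x", "y")
    p
  })
  for (i in seq_along(polygons)) {
    p <- polygons[[i]]
    if (nrow(p) < 3 || any(!is.finite(p))) {
      abort_config(sprintf("region '%s' is not a valid polygon", nm[i]))
    }
    if (!.polygon_is_simple(p)) {
      abort_config(sprintf("region '%s' is self-intersecting", nm[i]))
    }
  }
  structure(list(polygons = polygons), class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat("region_set with", length(x$polygons), "regions:",
      paste(names(x$polygons), collapse = ", "), "\n")
  invisible(x)
}

#' Read niche regions from a GeoJSON file
#'
#' Expects a FeatureCollection of Polygon features, each carrying a `name`
#' property; coordinates are micrometres. Only the outer ring is used.
#'
#' @param path path to a GeoJSON file.
#' @return a [region_set()].
#' @export
read_regions <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) {
    abort_format("expected a GeoJSON FeatureCollection")
  }
  polys <- list()
  for (ft in gj$features) {
    if (!identical(ft$geometry$type, "Polygon")) {
      abort_format("every feature must be a Polygon")
    }
    name <- ft$properties$name
    if (is.null(name)) abort_format("feature without a 'name' property")
    ring <- ft$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    ## GeoJSON rings repeat the first vertex; drop the closing copy
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    polys[[name]] <- m
  }
  region_set(polys)
}

#' Write niche regions as GeoJSON
#'
#' @param regions a [region_set()].
#' @param path output path.
#' @export
write_regions <- function(regions, path) {
  stopifnot(inherits(regions, "region_set"))
  features <- lapply(names(regions$polygons), function(nm) {
    p <- regions$polygons[[nm]]
    ring <- lapply(seq_len(nrow(p) + 1L), function(i) {
      i <- if (i > nrow(p)) 1L else i
      c(p[i, 1], p[i, 2])
    })
    list(type = "Feature",
         properties = list(name = nm),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Annotate cells with their niche label
#'
#' Each cell receives the name of the first region (in file order) whose
#' polygon contains its centroid, boundary inclusive; cells outside every
#' region are labelled `"unassigned"`. The first-match rule resolves any
#' overlap between hand-drawn regions deterministically.
#'
#' @param cells a cell table (see [read_cells()]).
#' @param regions a [region_set()].
#' @return the cell table with `niche_label` filled in.
#' @export
assign_niche <- function(cells, regions) {
  stopifnot(inherits(regions, "region_set"))
  label <- rep("unassigned", nrow(cells))
  for (nm in names(regions$polygons)) {
    todo <- label == "unassigned"
    if (!any(todo)) break
    hit <- point_in_polygon(cells$x_um[todo], cells$y_um[todo],
                            regions$polygons[[nm]])
    label[todo][hit] <- nm
  }
  cells$niche_label <- label
  cells
}
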