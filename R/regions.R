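# Census-style region handling: polygon collections keyed by GEOID, the
# standard GEOID prefix hierarchy, and point-to-region assignment.

.GEOID_LEVELS <- c(state = 2L, county = 5L, tract = 11L,
                   block_group = 12L, block = 15L)

#' Construct a region set
#'
#' A `region_set` is a data.frame of polygonal regions at one geographic
#' level, keyed by GEOID. Geometry is stored as a list column: each element
#' is a list of rings, each ring a two-column (lon, lat) matrix; the first
#' ring is the exterior, any further rings are holes. Standard census levels
#' enforce the usual GEOID lengths (state 2, county 5, tract 11, block group
#' 12, block 15 characters); `level = "custom"` accepts any key.
#'
#' @param geoid character vector of region keys.
#' @param level one of `"state"`, `"county"`, `"tract"`, `"block_group"`,
#'   `"block"`, `"custom"`.
#' @param geometry list of polygons (list of ring matrices each).
#' @param validate check ring validity (>= 3 vertices, no proper
#'   self-intersection). Invalid features raise an error naming the feature.
#' @return a `region_set` (data.frame with columns `geoid`, `geometry`, and
#'   bbox columns `xmin`, `ymin`, `xmax`, `ymax`; attribute `level`).
#' @export
region_set <- function(geoid, level, geometry, validate = TRUE) {
  level <- match.arg(level, c(names(.GEOID_LEVELS), "custom"))
  geoid <- as.character(geoid)
  stopifnot(length(geoid) == length(geometry))
  if (anyDuplicated(geoid)) stop("duplicate geoids in region set")
  if (level != "custom") {
    bad <- nchar(geoid) != .GEOID_LEVELS[[level]]
    if (any(bad)) {
      stop(sprintf("geoid '%s' does not have the standard %d-character length for level '%s'",
                   geoid[which(bad)[1]], .GEOID_LEVELS[[level]], level))
    }
  }
  geometry <- lapply(seq_along(geometry), function(i) {
    rings <- lapply(geometry[[i]], .ring_open)
    if (validate) {
      for (r in rings) {
        if (.ring_self_intersects(r)) {
          stop(sprintf("feature '%s' has a self-intersecting ring", geoid[i]))
        }
      }
    }
    rings
  })
  bb <- t(vapply(geometry, .poly_bbox, numeric(4)))
  out <- data.frame(geoid = geoid, xmin = bb[, 1], ymin = bb[, 2],
                    xmax = bb[, 3], ymax = bb[, 4],
                    stringsAsFactors = FALSE)
  out$geometry <- geometry
  attr(out, "level") <- level
  class(out) <- c("region_set", "data.frame")
  out
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("region_set: %d region(s) at level '%s'\n",
              nrow(x), region_level(x)))
  invisible(x)
}

#' Level of a region set
#' @param x a `region_set`.
#' @return the level string.
#' @export
region_level <- function(x) attr(x, "level")

# Parse a GeoJSON geometry object into a list of polygons (each a list of
# ring matrices). Polygon -> one polygon; MultiPolygon -> its parts merged
# into one ring list (even-odd containment is insensitive to the split).
.geojson_rings <- function(geom) {
  to_ring <- function(coords) {
    do.call(rbind, lapply(coords, function(xy) c(xy[[1]], xy[[2]])))
  }
  if (is.null(geom$type)) stop("feature has no geometry type")
  if (geom$type == "Polygon") {
    lapply(geom$coordinates, to_ring)
  } else if (geom$type == "MultiPolygon") {
    unlist(lapply(geom$coordinates, function(poly) lapply(poly, to_ring)),
           recursive = FALSE)
  } else {
    stop(sprintf("non-polygonal geometry type '%s'", geom$type))
  }
}

#' Load regions from a GeoJSON file
#'
#' Reads a GeoJSON FeatureCollection of Polygon/MultiPolygon features into a
#' [region_set]. The GEOID is taken from the named feature property
#' (default `"GEOID"`, the TIGER convention). Features with invalid
#' (self-intersecting) rings are rejected with a report naming the feature;
#' non-polygonal features are a geometry error.
#'
#' @param path GeoJSON file.
#' @param level region level (see [region_set()]).
#' @param geoid_field feature property holding the region key.
#' @return a [region_set]; zero-feature files yield an empty set with a
#'   warning.
#' @export
read_regions <- function(path, level, geoid_field = "GEOID") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features
           else stop("expected a GeoJSON FeatureCollection")
  if (length(feats) == 0) {
    warning(sprintf("no features in %s", path))
    return(region_set(character(0), level, list()))
  }
  geoids <- vapply(feats, function(f) {
    v <- f$properties[[geoid_field]]
    if (is.null(v)) stop(sprintf("feature missing property '%s'", geoid_field))
    as.character(v)
  }, character(1))
  geoms <- lapply(feats, function(f) .geojson_rings(f$geometry))
  region_set(geoids, level, geoms)
}

#' Assign points to covering regions
#'
#' The point-in-region spatial join: for each point, the GEOID of the region
#' covering it (boundary inclusive), or `NA` when no region covers it. A
#' grid index over region bounding boxes keeps the join far below pairwise
#' point-by-polygon cost. On a valid tessellation each point receives at
#' most one region; a point lying exactly on a shared edge is covered by
#' several regions and is deterministically assigned the lexicographically
#' smallest covering GEOID. Two regions both covering a point in their
#' interiors indicate overlapping polygons and raise an ambiguity error
#' naming both.
#'
#' @param points data.frame with columns `lon`, `lat` (an `id` column is
#'   carried through by callers, not needed here).
#' @param regions a [region_set] (one level).
#' @param tol boundary tolerance in degrees.
#' @return character vector of geoids, `NA` where uncovered.
#' @export
assign_region <- function(points, regions, tol = 1e-12) {
  stopifnot(inherits(regions, "region_set"),
            all(c("lon", "lat") %in% names(points)))
  n <- nrow(points)
  m <- nrow(regions)
  out <- rep(NA_character_, n)
  if (n == 0 || m == 0) return(out)

  # grid index over region bboxes
  k <- max(1L, as.integer(ceiling(sqrt(m))))
  gx0 <- min(regions$xmin); gx1 <- max(regions$xmax)
  gy0 <- min(regions$ymin); gy1 <- max(regions$ymax)
  dx <- max(gx1 - gx0, .Machine$double.eps)
  dy <- max(gy1 - gy0, .Machine$double.eps)
  cell_of <- function(x, y) {
    cx <- pmin(k - 1L, pmax(0L, as.integer(floor((x - gx0) / dx * k))))
    cy <- pmin(k - 1L, pmax(0L, as.integer(floor((y - gy0) / dy * k))))
    cx * k + cy + 1L
  }
  # region -> cells its bbox overlaps
  region_cells <- vector("list", m)
  for (j in seq_len(m)) {
    cx <- seq(max(0L, floor((regions$xmin[j] - gx0) / dx * k)),
              min(k - 1L, floor((regions$xmax[j] - gx0) / dx * k)))
    cy <- seq(max(0L, floor((regions$ymin[j] - gy0) / dy * k)),
              min(k - 1L, floor((regions$ymax[j] - gy0) / dy * k)))
    region_cells[[j]] <- as.integer(outer(cx * k, cy + 1L, `+`))
  }

  px <- points$lon; py <- points$lat
  pt_cell <- cell_of(px, py)
  cover_count <- integer(n)
  interior_count <- integer(n)
  first_interior <- rep(NA_character_, n)

  # loop over regions; each tests only the points in its cells and bbox
  pts_by_cell <- split(seq_len(n), pt_cell)
  for (j in seq_len(m)) {
    cand <- unlist(pts_by_cell[as.character(region_cells[[j]])],
                   use.names = FALSE)
    if (is.null(cand) || length(cand) == 0) next
    cand <- cand[px[cand] >= regions$xmin[j] - tol &
                 px[cand] <= regions$xmax[j] + tol &
                 py[cand] >= regions$ymin[j] - tol &
                 py[cand] <= regions$ymax[j] + tol]
    if (length(cand) == 0) next
    rings <- regions$geometry[[j]]
    cov <- .covers(px[cand], py[cand], rings, tol)
    if (!any(cov)) next
    hit <- cand[cov]
    stri <- .strictly_inside(px[hit], py[hit], rings, tol)
    g <- regions$geoid[j]
    cover_count[hit] <- cover_count[hit] + 1L
    newi <- hit[stri]
    dupi <- newi[interior_count[newi] > 0L]
    if (length(dupi) > 0) {
      stop(sprintf(
        "ambiguous assignment: point (%.9f, %.9f) lies in the interior of both '%s' and '%s'",
        px[dupi[1]], py[dupi[1]], first_interior[dupi[1]], g))
    }
    interior_count[newi] <- interior_count[newi] + 1L
    first_interior[newi] <- g
    # lexicographically smallest covering geoid wins for boundary ties
    take <- is.na(out[hit]) | g < out[hit]
    out[hit[take]] <- g
  }
  out
}

#' Ancestor GEOID at a coarser level
#'
#' GEOIDs are prefix-nested: truncating a 15-character block id to 12, 11,
#' 5, or 2 characters yields its block group, tract, county, or state.
#'
#' @param geoid character vector of standard-level GEOIDs.
#' @param target_level the ancestor level wanted.
#' @return character vector of ancestor geoids.
#' @export
parent_geoid <- function(geoid, target_level) {
  target_level <- match.arg(target_level, names(.GEOID_LEVELS))
  len <- .GEOID_LEVELS[[target_level]]
  nc <- nchar(geoid)
  if (!all(nc %in% .GEOID_LEVELS)) {
    stop(sprintf("nonstandard geoid length %d (expected one of %s)",
                 nc[!nc %in% .GEOID_LEVELS][1],
                 paste(.GEOID_LEVELS, collapse = "/")))
  }
  if (any(nc < len)) {
    stop("geoid is at a coarser level than the requested ancestor")
  }
  substr(geoid, 1L, len)
}

#' Bundle per-level region sets into a hierarchy
#'
#' A `region_hierarchy` is a named list of [region_set]s (names are levels).
#' Construction checks GEOID prefix nesting: every geoid at a finer level
#' must extend some geoid at each coarser level present.
#'
#' @param ... named `region_set` arguments, or a single named list.
#' @return a `region_hierarchy`.
#' @export
region_hierarchy <- function(...) {
  levels <- list(...)
  if (length(levels) == 1 && is.list(levels[[1]]) &&
      !inherits(levels[[1]], "region_set")) {
    levels <- levels[[1]]
  }
  stopifnot(length(levels) > 0, !is.null(names(levels)))
  ord <- intersect(names(.GEOID_LEVELS), names(levels))
  stopifnot(length(ord) == length(levels))
  levels <- levels[ord]
  for (i in seq_along(levels)) {
    stopifnot(inherits(levels[[i]], "region_set"))
    if (i > 1) {
      coarser <- levels[[i - 1]]$geoid
      fine <- levels[[i]]$geoid
      pref <- substr(fine, 1L, .GEOID_LEVELS[[ord[i - 1]]])
      orphan <- !(pref %in% coarser)
      if (any(orphan)) {
        stop(sprintf("geoid '%s' has no parent at level '%s'",
                     fine[which(orphan)[1]], ord[i - 1]))
      }
    }
  }
  structure(levels, class = "region_hierarchy")
}

#' @export
print.region_hierarchy <- function(x, ...) {
  cat("region_hierarchy:\n")
  for (lv in names(x)) cat(sprintf("  %-12s %d region(s)\n", lv, nrow(x[[lv]])))
  invisible(x)
}

#' Write point-to-region assignments as CSV
#'
#' @param ids point ids.
#' @param geoids assigned geoids (NA allowed).
#' @param level level string recorded per row.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_assignments <- function(ids, geoids, level, path) {
  utils::write.csv(data.frame(id = ids, geoid = geoids, level = level),
                   path, row.names = FALSE, na = "")
  invisible(path)
}
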