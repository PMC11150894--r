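# Low-level planar geometry: containment tests, bounding boxes, unit helpers.
# Containment is computed in lon/lat coordinate space (EPSG:4326), matching
# how TIGER geometries are distributed; no projection is applied.

# WGS84 semi-major axis; one degree of arc at the equator in meters.
.WGS84_A <- 6378137
.M_PER_DEG <- pi * .WGS84_A / 180

#' Convert square feet to square meters
#'
#' Exact conversion (1 ft = 0.3048 m), used by the census-block minimum-size
#' sanity check: blocks bounded by roads must be at least 30,000 sq ft
#' (2787.1 m^2), other blocks at least 40,000 sq ft (3716.1 m^2).
#'
#' @param sqft numeric vector of areas in square feet.
#' @return areas in square meters.
#' @examples
#' sqft_to_sqm(c(30000, 40000))
#' @export
sqft_to_sqm <- function(sqft) {
  stopifnot(is.numeric(sqft))
  sqft * 0.3048^2
}

#' Minimum census block areas in square meters
#'
#' The Census Bureau's minimum block size is 30,000 square feet for polygons
#' bounded by roads and 40,000 square feet otherwise. Returned in square
#' meters, rounded to one decimal as conventionally printed.
#'
#' @return named numeric vector with elements `road_bounded` and `other`.
#' @export
min_block_area_sqm <- function() {
  round(sqft_to_sqm(c(road_bounded = 30000, other = 40000)), 1)
}

# Ensure a ring matrix is open (no repeated closing vertex) with >= 3 vertices.
.ring_open <- function(ring) {
  ring <- as.matrix(ring)
  if (ncol(ring) != 2) stop("ring must have two columns (lon, lat)")
  n <- nrow(ring)
  if (n >= 2 && all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
  if (nrow(ring) < 3) stop("ring must have at least 3 distinct vertices")
  ring
}

# Even-odd crossing test, vectorized over points, for one ring.
# Boundary points are ambiguous here; callers combine with .on_edges().
.crossings_odd <- function(px, py, ring) {
  x1 <- ring[, 1]; y1 <- ring[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  inside <- logical(length(px))
  for (k in seq_along(x1)) {
    crosses <- ((y1[k] > py) != (y2[k] > py))
    if (any(crosses)) {
      xint <- x1[k] + (py - y1[k]) * (x2[k] - x1[k]) / (y2[k] - y1[k])
      inside <- xor(inside, crosses & px < xint)
    }
  }
  inside
}

# TRUE where (px,py) lies on any edge of `ring`, within `tol` (degrees).
.on_edges <- function(px, py, ring, tol = 1e-12) {
  x1 <- ring[, 1]; y1 <- ring[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  on <- logical(length(px))
  for (k in seq_along(x1)) {
    dx <- x2[k] - x1[k]; dy <- y2[k] - y1[k]
    len2 <- dx * dx + dy * dy
    if (len2 == 0) {
      hit <- abs(px - x1[k]) <= tol & abs(py - y1[k]) <= tol
    } else {
      t <- ((px - x1[k]) * dx + (py - y1[k]) * dy) / len2
      t <- pmin(1, pmax(0, t))
      qx <- x1[k] + t * dx; qy <- y1[k] + t * dy
      hit <- abs(px - qx) <= tol & abs(py - qy) <= tol
    }
    on <- on | hit
  }
  on
}

# Boundary-inclusive ("covered by") containment of points in a polygon given
# as a list of rings (first exterior, rest holes; even-odd rule makes the
# orientation irrelevant). Vectorized over points.
.covers <- function(px, py, rings, tol = 1e-12) {
  parity <- logical(length(px))
  boundary <- logical(length(px))
  for (ring in rings) {
    parity <- xor(parity, .crossings_odd(px, py, ring))
    boundary <- boundary | .on_edges(px, py, ring, tol)
  }
  parity | boundary
}

# Strict-interior test (covered but not on any boundary edge).
.strictly_inside <- function(px, py, rings, tol = 1e-12) {
  parity <- logical(length(px))
  boundary <- logical(length(px))
  for (ring in rings) {
    parity <- xor(parity, .crossings_odd(px, py, ring))
    boundary <- boundary | .on_edges(px, py, ring, tol)
  }
  parity & !boundary
}

.poly_bbox <- function(rings) {
  xs <- unlist(lapply(rings, function(r) r[, 1]))
  ys <- unlist(lapply(rings, function(r) r[, 2]))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

# Proper self-intersection check for one ring: any two non-adjacent edges
# crossing. O(n^2); rings in census-style data are small.
.ring_self_intersects <- function(ring) {
  n <- nrow(ring)
  x1 <- ring[, 1]; y1 <- ring[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  seg_int <- function(ax, ay, bx, by, cx, cy, dx, dy) {
    d1 <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
    d2 <- (bx - ax) * (dy - ay) - (by - ay) * (dx - ax)
    d3 <- (dx - cx) * (ay - cy) - (dy - cy) * (ax - cx)
    d4 <- (dx - cx) * (by - cy) - (dy - cy) * (bx - cx)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      if (seg_int(x1[i], y1[i], x2[i], y2[i], x1[j], y1[j], x2[j], y2[j])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# Signed planar area of a ring (degrees^2); magnitude used for conservation
# checks on synthetic tessellations.
.ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}
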