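# Getis-Ord Gi* hotspot analysis on region-aggregated counts, and the
# before/after comparison that exposes hotspot distortion from masking.

#' Aggregate points into per-region counts
#'
#' Zero-filled counts of points per region (boundary-inclusive assignment);
#' points covered by no region are counted in the `unassigned` attribute,
#' so `sum(counts) + unassigned == nrow(points)`.
#'
#' @param points data.frame with columns `lon`, `lat`.
#' @param regions a [region_set] (one level).
#' @return named integer vector of counts (names = geoids), attribute
#'   `unassigned`.
#' @export
aggregate_counts <- function(points, regions) {
  g <- assign_region(points, regions)
  counts <- stats::setNames(integer(nrow(regions)), regions$geoid)
  tab <- table(g[!is.na(g)])
  counts[names(tab)] <- as.integer(tab)
  attr(counts, "unassigned") <- sum(is.na(g))
  counts
}

# Shared boundary point between two polygons: a shared vertex, or a vertex
# of one lying on an edge of the other. Exact for valid tessellations,
# where any shared boundary segment contains a vertex of one polygon.
.touches <- function(rings_a, rings_b, tol = 1e-9) {
  va <- do.call(rbind, rings_a); vb <- do.call(rbind, rings_b)
  for (r in rings_b) {
    if (any(.on_edges(va[, 1], va[, 2], r, tol))) return(TRUE)
  }
  for (r in rings_a) {
    if (any(.on_edges(vb[, 1], vb[, 2], r, tol))) return(TRUE)
  }
  FALSE
}

#' Queen-contiguity spatial weights (self-inclusive)
#'
#' Regions sharing any boundary point (edge or corner) are neighbors, with
#' binary weights; every region is included in its own neighborhood with
#' weight 1, as the Gi* statistic requires. Neighbor search is pruned by
#' bounding-box overlap before the exact boundary test.
#'
#' @param regions a [region_set].
#' @param tol coordinate tolerance (degrees) for boundary coincidence.
#' @return a `spatial_weights` object: list with `ids`, `neighbors`
#'   (integer index lists, self included), `weights` (parallel lists), and
#'   `self_included = TRUE`.
#' @export
queen_weights <- function(regions, tol = 1e-9) {
  stopifnot(inherits(regions, "region_set"))
  m <- nrow(regions)
  nb <- lapply(seq_len(m), function(i) i)
  if (m > 1) {
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        if (regions$xmin[j] > regions$xmax[i] + tol ||
            regions$xmax[j] < regions$xmin[i] - tol ||
            regions$ymin[j] > regions$ymax[i] + tol ||
            regions$ymax[j] < regions$ymin[i] - tol) next
        if (.touches(regions$geometry[[i]], regions$geometry[[j]], tol)) {
          nb[[i]] <- c(nb[[i]], j)
          nb[[j]] <- c(nb[[j]], i)
        }
      }
    }
  }
  nb <- lapply(nb, sort)
  structure(list(ids = regions$geoid, neighbors = nb,
                 weights = lapply(nb, function(x) rep(1, length(x))),
                 self_included = TRUE),
            class = "spatial_weights")
}

#' Fixed-distance-band spatial weights (self-inclusive)
#'
#' Regions whose centroids lie within `band_m` geodesic meters of each
#' other are neighbors (binary weights, self included). Centroids are the
#' area centroids of the exterior rings.
#'
#' @param regions a [region_set].
#' @param band_m band distance in meters.
#' @return a `spatial_weights` object.
#' @export
distance_band_weights <- function(regions, band_m) {
  stopifnot(inherits(regions, "region_set"), band_m > 0)
  cent <- t(vapply(regions$geometry, function(rings) {
    r <- rings[[1]]
    a <- .ring_area(r)
    if (abs(a) < .Machine$double.eps) return(colMeans(r))
    x <- r[, 1]; y <- r[, 2]
    x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
    cr <- x * y2 - x2 * y
    c(sum((x + x2) * cr), sum((y + y2) * cr)) / (6 * a)
  }, numeric(2)))
  m <- nrow(regions)
  nb <- lapply(seq_len(m), function(i) {
    d <- geosphere::distGeo(cent[i, , drop = FALSE], cent)
    sort(which(d <= band_m))
  })
  structure(list(ids = regions$geoid, neighbors = nb,
                 weights = lapply(nb, function(x) rep(1, length(x))),
                 self_included = TRUE),
            class = "spatial_weights")
}

.gi_bins <- c("cold99", "cold95", "cold90", "not_significant",
              "hot90", "hot95", "hot99")

.bin_z <- function(z) {
  cut_pts <- c(1.645, 1.960, 2.576)
  lvl <- findInterval(abs(z), cut_pts)  # 0..3
  factor(ifelse(lvl == 0, "not_significant",
                paste0(ifelse(z > 0, "hot", "cold"), c(90, 95, 99)[lvl])),
         levels = .gi_bins)
}

#' Getis-Ord Gi* statistic on region counts
#'
#' For each region i with self-inclusive neighborhood weights w_ij, the
#' z-score
#' \deqn{z_i = (\sum_j w_{ij} x_j - \bar X W_i) /
#'   (S \sqrt{(n \sum_j w_{ij}^2 - W_i^2)/(n-1)})}
#' where \eqn{W_i = \sum_j w_{ij}}, \eqn{\bar X} and
#' \eqn{S = \sqrt{\sum_j x_j^2 / n - \bar X^2}} are the global mean and
#' standard deviation of all counts including i. Two-tailed normal p-values
#' and confidence bins at |z| thresholds 1.645 / 1.960 / 2.576 (90/95/99%).
#' A flat landscape (S = 0) yields z = 0 everywhere; a region whose
#' neighborhood spans all regions has an undefined denominator and gets
#' z = 0 with a warning.
#'
#' @param counts named numeric vector of per-region counts (names must
#'   match `weights$ids`).
#' @param weights a `spatial_weights` object with `self_included = TRUE`.
#' @param fdr apply Benjamini-Hochberg adjustment to the p-values before
#'   binning (bins then use the adjusted p at the 0.10/0.05/0.01 cutoffs).
#' @return data.frame with columns `geoid`, `count`, `z`, `p`, `bin`.
#' @export
gi_star <- function(counts, weights, fdr = FALSE) {
  stopifnot(inherits(weights, "spatial_weights"), isTRUE(weights$self_included))
  n <- length(weights$ids)
  if (n < 2) stop("Gi* needs at least 2 regions")
  x <- counts[weights$ids]
  if (anyNA(x)) stop("counts must cover every region in the weights")
  x <- as.numeric(x)
  xbar <- mean(x)
  S <- sqrt(sum(x^2) / n - xbar^2)
  z <- numeric(n)
  degenerate <- FALSE
  if (S > 0) {
    for (i in seq_len(n)) {
      w <- weights$weights[[i]]
      j <- weights$neighbors[[i]]
      Wi <- sum(w)
      num <- sum(w * x[j]) - xbar * Wi
      den2 <- (n * sum(w^2) - Wi^2) / (n - 1)
      if (den2 <= 0) {
        z[i] <- 0
        degenerate <- TRUE
      } else {
        z[i] <- num / (S * sqrt(den2))
      }
    }
    if (degenerate) {
      warning("region(s) whose neighborhood spans all regions: z set to 0")
    }
  }
  p <- 2 * stats::pnorm(-abs(z))
  if (fdr) {
    padj <- stats::p.adjust(p, "BH")
    lvl <- findInterval(-padj, -c(0.10, 0.05, 0.01))
    bin <- factor(ifelse(lvl == 0 | z == 0, "not_significant",
                         paste0(ifelse(z > 0, "hot", "cold"),
                                c(90, 95, 99)[pmax(lvl, 1)])),
                  levels = .gi_bins)
  } else {
    bin <- .bin_z(z)
  }
  data.frame(geoid = weights$ids, count = x, z = z, p = p, bin = bin,
             stringsAsFactors = FALSE)
}

#' Compare two hotspot classifications
#'
#' Reports every region whose confidence bin differs between two [gi_star()]
#' results on the same region set, categorized as `emergent` (not
#' significant before, significant after), `vanished` (the reverse),
#' `strengthened` / `weakened` (same hot/cold side, confidence moved up /
#' down), or `reversed` (hot to cold or cold to hot).
#'
#' @param result_a,result_b data.frames from [gi_star()].
#' @return data.frame with columns `geoid`, `bin_a`, `bin_b`, `change`;
#'   zero rows when the classifications are identical.
#' @export
compare_hotspots <- function(result_a, result_b) {
  if (!setequal(result_a$geoid, result_b$geoid) ||
      nrow(result_a) != nrow(result_b)) {
    stop("hotspot results cover different region sets")
  }
  b <- result_b[match(result_a$geoid, result_b$geoid), ]
  ord <- stats::setNames(c(-3L, -2L, -1L, 0L, 1L, 2L, 3L), .gi_bins)
  sa <- ord[as.character(result_a$bin)]
  sb <- ord[as.character(b$bin)]
  ch <- sa != sb
  if (!any(ch)) {
    return(data.frame(geoid = character(0), bin_a = character(0),
                      bin_b = character(0), change = character(0),
                      stringsAsFactors = FALSE))
  }
  cls <- function(a, bb) {
    if (a == 0) "emergent"
    else if (bb == 0) "vanished"
    else if (sign(a) != sign(bb)) "reversed"
    else if (abs(bb) > abs(a)) "strengthened"
    else "weakened"
  }
  data.frame(
    geoid = result_a$geoid[ch],
    bin_a = as.character(result_a$bin)[ch],
    bin_b = as.character(b$bin)[ch],
    change = mapply(cls, sa[ch], sb[ch]),
    stringsAsFactors = FALSE
  )
}
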