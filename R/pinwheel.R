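# Pinwheel obfuscation: the displacement draw, the forward projection, and
# the unconstrained / region-constrained masking of single points.

#' Pinwheel obfuscation parameters
#'
#' The pinwheel mask displaces a point along a random azimuth `a` drawn
#' uniformly on \[0, 360), by a distance that is a sawtooth in the azimuth:
#' `d = r_max * ((a mod theta) / theta)`. `theta` is the angular width of a
#' pinwheel blade, so candidate clouds show `360 / theta` blades and reach at
#' most `r_max` meters; small `theta` yields many narrow, closely spaced
#' blades. The asymmetric, non-uniform noise is what distinguishes the
#' pinwheel from uniform jittering.
#'
#' @param theta blade angular width in degrees, in (0, 360].
#' @param r_max maximum displacement in meters, >= 0.
#' @param distance_model `"geodesic"` (WGS84 ellipsoid, the default) or
#'   `"planar"` (local tangent-plane approximation; convenient for
#'   closed-form checks and fast simulation).
#' @param independent_azimuth if `TRUE`, the travel azimuth is drawn
#'   independently of the blade phase that sets the distance, further
#'   decoupling direction from displacement. Default `FALSE`: one shared
#'   draw `a` serves as both.
#' @return an object of class `pinwheel_params`.
#' @examples
#' pinwheel_params(theta = 45, r_max = 1000)
#' @export
pinwheel_params <- function(theta, r_max,
                            distance_model = c("geodesic", "planar"),
                            independent_azimuth = FALSE) {
  if (!is.numeric(theta) || length(theta) != 1 || !is.finite(theta) ||
      theta <= 0 || theta > 360) {
    stop("`theta` must be a single number in (0, 360]")
  }
  if (!is.numeric(r_max) || length(r_max) != 1 || !is.finite(r_max) ||
      r_max < 0) {
    stop("`r_max` must be a single non-negative number")
  }
  distance_model <- match.arg(distance_model)
  structure(
    list(theta = theta, r_max = r_max, distance_model = distance_model,
         independent_azimuth = isTRUE(independent_azimuth)),
    class = "pinwheel_params"
  )
}

#' @export
print.pinwheel_params <- function(x, ...) {
  cat(sprintf("pinwheel parameters: theta = %g deg, r_max = %g m, %s model%s\n",
              x$theta, x$r_max, x$distance_model,
              if (x$independent_azimuth) ", independent azimuth" else ""))
  invisible(x)
}

#' Sawtooth displacement distance for a given random degree
#'
#' Deterministic core of the pinwheel draw: maps the random degree `a` to a
#' displacement distance `r_max * ((a mod theta) / theta)`.
#'
#' @param a random degree(s) in \[0, 360).
#' @param params a [pinwheel_params()] object.
#' @return distances in meters, in \[0, r_max).
#' @export
pinwheel_distance <- function(a, params) {
  stopifnot(inherits(params, "pinwheel_params"))
  params$r_max * ((a %% params$theta) / params$theta)
}

#' Draw pinwheel displacements
#'
#' Draws `n` displacement vectors from the current RNG stream: a random
#' degree `a ~ Uniform[0, 360)` gives both the azimuth and, through the
#' sawtooth, the distance (unless `independent_azimuth` was set, in which
#' case the azimuth is a second independent uniform draw).
#'
#' @param params a [pinwheel_params()] object.
#' @param n number of draws.
#' @return data.frame with columns `azimuth` (degrees, clockwise from north)
#'   and `distance` (meters).
#' @export
draw_displacement <- function(params, n = 1) {
  stopifnot(inherits(params, "pinwheel_params"))
  a <- stats::runif(n, 0, 360)
  azimuth <- if (params$independent_azimuth) stats::runif(n, 0, 360) else a
  data.frame(azimuth = azimuth, distance = pinwheel_distance(a, params))
}

#' Project points along an azimuth
#'
#' Forward position problem: the point reached by travelling `distance`
#' meters from (`lon`, `lat`) along initial bearing `azimuth`. The geodesic
#' model solves the direct geodesic on the WGS84 ellipsoid; the planar model
#' uses meters-per-degree scaling at the starting latitude.
#'
#' @param lon,lat starting coordinates, degrees WGS84 (vectorized).
#' @param azimuth initial bearing, degrees clockwise from geographic north.
#' @param distance travel distance in meters, >= 0.
#' @param model `"geodesic"` or `"planar"`.
#' @return data.frame with columns `lon`, `lat`.
#' @export
project_point <- function(lon, lat, azimuth, distance,
                          model = c("geodesic", "planar")) {
  model <- match.arg(model)
  stopifnot(is.numeric(lon), is.numeric(lat), all(is.finite(lon)),
            all(is.finite(lat)), all(abs(lon) <= 180), all(abs(lat) <= 90),
            all(distance >= 0))
  n <- max(length(lon), length(lat), length(azimuth), length(distance))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  azimuth <- rep_len(azimuth, n); distance <- rep_len(distance, n)
  if (model == "geodesic") {
    res <- geosphere::geodesic(cbind(lon, lat), azimuth, distance)
    out <- data.frame(lon = res[, "longitude"], lat = res[, "latitude"])
    # zero displacement is the identity, exactly (no solver roundoff)
    z <- distance == 0
    out$lon[z] <- lon[z]
    out$lat[z] <- lat[z]
  } else {
    az <- azimuth * pi / 180
    dlat <- distance * cos(az) / .M_PER_DEG
    dlon <- distance * sin(az) / (.M_PER_DEG * cos(lat * pi / 180))
    out <- data.frame(lon = lon + dlon, lat = lat + dlat)
  }
  if (any(abs(out$lat) > 90)) {
    stop("projection overflowed the pole: resulting latitude outside [-90, 90]")
  }
  out
}

#' Obfuscate points with the unconstrained pinwheel
#'
#' Applies one pinwheel displacement draw per point, using the current RNG
#' stream (seed it with `set.seed()`, or use [obfuscate_points()] for
#' per-record reproducible substreams). The geodesic distance between input
#' and output never exceeds `r_max` (up to roundoff); `r_max = 0` is the
#' identity.
#'
#' @param lon,lat coordinates, degrees WGS84 (vectorized).
#' @param params a [pinwheel_params()] object.
#' @return data.frame with columns `lon`, `lat`, `azimuth`, `distance`.
#' @export
pinwheel_obfuscate <- function(lon, lat, params) {
  stopifnot(inherits(params, "pinwheel_params"))
  n <- max(length(lon), length(lat))
  d <- draw_displacement(params, n)
  out <- project_point(lon, lat, d$azimuth, d$distance, params$distance_model)
  cbind(out, d)
}

#' Obfuscate one point under a region constraint
#'
#' Rejection-sampling variant: displacement draws are repeated until the
#' candidate point is covered by `rings` (boundary inclusive), so the masked
#' point keeps the original point's region and hence all region-linked
#' attributes. The original point must itself be covered by the constraint.
#'
#' @param lon,lat one point, degrees WGS84.
#' @param params a [pinwheel_params()] object.
#' @param rings constraint polygon: list of rings (two-column lon/lat
#'   matrices; first exterior, rest holes).
#' @param max_attempts rejection budget; exhausting it is an error, never a
#'   silent pass-through.
#' @return list with `lon`, `lat`, `azimuth`, `distance`, and `attempts`
#'   (number of candidates drawn, >= 1).
#' @export
constrained_pinwheel <- function(lon, lat, params, rings,
                                 max_attempts = 10000) {
  stopifnot(inherits(params, "pinwheel_params"), length(lon) == 1,
            length(lat) == 1, max_attempts >= 1)
  rings <- lapply(rings, .ring_open)
  if (!.covers(lon, lat, rings)) {
    stop(structure(
      class = c("geomask_precondition_error", "error", "condition"),
      list(message = "original point is not covered by the constraint polygon",
           call = sys.call())
    ))
  }
  attempts <- 0L
  batch <- 1L  # first attempt alone so an immediate accept matches
               # pinwheel_obfuscate() draw-for-draw under one seed
  while (attempts < max_attempts) {
    b <- min(batch, max_attempts - attempts)
    d <- draw_displacement(params, b)
    cand <- project_point(lon, lat, d$azimuth, d$distance,
                          params$distance_model)
    ok <- .covers(cand$lon, cand$lat, rings)
    if (any(ok)) {
      i <- which(ok)[1]
      return(list(lon = cand$lon[i], lat = cand$lat[i],
                  azimuth = d$azimuth[i], distance = d$distance[i],
                  attempts = attempts + i))
    }
    attempts <- attempts + b
    batch <- 64L
  }
  stop(structure(
    class = c("geomask_budget_error", "error", "condition"),
    list(message = sprintf(
      "no contained candidate after %d attempts (r_max = %g m); the constraint polygon may be too thin for this radius",
      attempts, params$r_max), call = sys.call())
  ))
}

# Deterministic per-record seed: 31-bit polynomial rolling hash of
# "<id>:<master_seed>", so substreams depend only on (master seed, id) and
# results are independent of record order.
point_seed <- function(master_seed, id) {
  p <- 2147483647
  vapply(as.character(id), function(s) {
    h <- as.numeric(as.integer(master_seed) %% p)
    for (b in utf8ToInt(paste0(s, ":", as.integer(master_seed)))) {
      h <- (h * 31 + b) %% p
    }
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

#' Obfuscate a point set, optionally constrained to regions
#'
#' Masks every record with the pinwheel, deriving one RNG substream per
#' record from `(seed, id)` so output is reproducible and independent of
#' record order. In constrained mode each record is first assigned to its
#' covering region at the given level, and candidates are redrawn until the
#' masked point stays in that region; records that resolve to no region are
#' collected into the `failures` attribute, never silently dropped.
#'
#' @param points data.frame with columns `id`, `lon`, `lat`; ids unique.
#' @param params a [pinwheel_params()] object.
#' @param regions optional [region_set] used as the constraint (one level).
#'   `NULL` for unconstrained masking.
#' @param seed master seed (integer).
#' @param max_attempts per-record rejection budget in constrained mode.
#' @return data.frame parallel to `points` (same ids, same order) with
#'   columns `id`, `lon`, `lat`, `attempts`, `displacement_m`; attribute
#'   `failures` holds a data.frame of unresolvable records (empty when all
#'   succeed), and `geoid` the constraint region per record (constrained
#'   mode only).
#' @export
obfuscate_points <- function(points, params, regions = NULL, seed = 1L,
                             max_attempts = 10000) {
  stopifnot(inherits(params, "pinwheel_params"),
            all(c("id", "lon", "lat") %in% names(points)))
  if (anyDuplicated(points$id)) stop("point ids must be unique")
  n <- nrow(points)
  out <- data.frame(id = points$id, lon = numeric(n), lat = numeric(n),
                    attempts = integer(n), displacement_m = numeric(n))
  failures <- points[0, c("id", "lon", "lat")]
  geoids <- NULL

  ring_lookup <- NULL
  if (!is.null(regions)) {
    geoids <- assign_region(points, regions)
    bad <- is.na(geoids)
    if (any(bad)) {
      failures <- points[bad, c("id", "lon", "lat")]
      failures$reason <- "no covering constraint region"
    }
    ring_lookup <- stats::setNames(regions$geometry, regions$geoid)
  }

  seeds <- point_seed(seed, points$id)
  for (i in seq_len(n)) {
    if (!is.null(regions) && is.na(geoids[i])) {
      out$lon[i] <- NA_real_; out$lat[i] <- NA_real_
      out$attempts[i] <- 0L; out$displacement_m[i] <- NA_real_
      next
    }
    set.seed(seeds[i])
    if (is.null(regions)) {
      r <- pinwheel_obfuscate(points$lon[i], points$lat[i], params)
      out$lon[i] <- r$lon; out$lat[i] <- r$lat
      out$attempts[i] <- 1L
    } else {
      r <- constrained_pinwheel(points$lon[i], points$lat[i], params,
                                ring_lookup[[geoids[i]]], max_attempts)
      out$lon[i] <- r$lon; out$lat[i] <- r$lat
      out$attempts[i] <- r$attempts
    }
  }
  ok <- !is.na(out$lon)
  out$displacement_m[ok] <- geosphere::distGeo(
    cbind(points$lon[ok], points$lat[ok]), cbind(out$lon[ok], out$lat[ok]))
  attr(out, "failures") <- failures
  if (!is.null(geoids)) attr(out, "geoid") <- geoids
  out
}
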