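# Point file round-tripping: CSV (id,lon,lat) and GeoJSON Point features.

#' Read a point file
#'
#' Accepts CSV with an `id,lon,lat` header or a GeoJSON FeatureCollection of
#' Point features (format inferred from content). Order-preserving; ids
#' must be unique; non-numeric coordinates are reported row by row.
#'
#' @param path input file.
#' @return data.frame with columns `id`, `lon`, `lat`.
#' @export
read_points <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1, warn = FALSE)
  if (grepl("^\\s*\\{", first) || grepl("\\.(geo)?json$", path)) {
    gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (!identical(gj$type, "FeatureCollection")) {
      stop("expected a GeoJSON FeatureCollection of Point features")
    }
    pts <- lapply(gj$features, function(f) {
      if (!identical(f$geometry$type, "Point")) {
        stop(sprintf("non-Point feature in %s", path))
      }
      data.frame(id = as.character(f$properties$id),
                 lon = as.numeric(f$geometry$coordinates[[1]]),
                 lat = as.numeric(f$geometry$coordinates[[2]]),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, pts)
    if (is.null(out)) out <- data.frame(id = character(0), lon = numeric(0),
                                        lat = numeric(0))
  } else {
    out <- utils::read.csv(path, colClasses = c("character", "character",
                                                "character"))
    if (!all(c("id", "lon", "lat") %in% names(out))) {
      stop("CSV point file must have id,lon,lat columns")
    }
    lon <- suppressWarnings(as.numeric(out$lon))
    lat <- suppressWarnings(as.numeric(out$lat))
    bad <- which(is.na(lon) | is.na(lat))
    if (length(bad)) {
      stop(sprintf("non-numeric coordinates on row(s): %s",
                   paste(utils::head(bad, 10), collapse = ", ")))
    }
    out <- data.frame(id = out$id, lon = lon, lat = lat,
                      stringsAsFactors = FALSE)
  }
  if (anyDuplicated(out$id)) {
    stop(sprintf("duplicate point id '%s'", out$id[anyDuplicated(out$id)]))
  }
  if (nrow(out) &&
      (any(abs(out$lon) > 180) || any(abs(out$lat) > 90))) {
    stop("coordinates out of WGS84 bounds")
  }
  out
}

#' Write a point file
#'
#' CSV or RFC 7946 GeoJSON (lon,lat order), coordinates serialized with at
#' least 9 decimal places so round-trips are lossless at survey precision.
#'
#' @param points data.frame with columns `id`, `lon`, `lat` (extra columns
#'   are carried into CSV output / GeoJSON properties).
#' @param path output file.
#' @param format `"csv"` or `"geojson"`.
#' @return the path, invisibly.
#' @export
write_points <- function(points, path, format = c("csv", "geojson")) {
  format <- match.arg(format)
  stopifnot(all(c("id", "lon", "lat") %in% names(points)))
  if (format == "csv") {
    out <- points
    out$lon <- sprintf("%.9f", out$lon)
    out$lat <- sprintf("%.9f", out$lat)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    extra <- setdiff(names(points), c("lon", "lat"))
    feats <- lapply(seq_len(nrow(points)), function(i) {
      props <- as.list(points[i, extra, drop = FALSE])
      list(type = "Feature",
           properties = props,
           geometry = list(type = "Point",
                           coordinates = c(points$lon[i], points$lat[i])))
    })
    gj <- list(type = "FeatureCollection", features = feats)
    writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE, digits = 10,
                                na = "null"), path)
  }
  invisible(path)
}
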