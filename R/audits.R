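# Obfuscation audits: how often masking moves a record across region
# boundaries, and how much the linked neighborhood poverty rate changes.

#' Poverty rate of a region
#'
#' `100 * below_poverty / total_pop`, the population-based percentage of
#' individuals below the poverty level. Regions with zero total population
#' (e.g. uninhabited water tracts) get the undefined sentinel `NA`.
#'
#' @param geoid character vector of region keys (vectorized).
#' @param demo demographic table: data.frame with columns `geoid`,
#'   `below_poverty`, `total_pop` (counts, `below_poverty <= total_pop`).
#' @return numeric percentages in \[0, 100\], `NA` where undefined.
#' @export
poverty_rate <- function(geoid, demo) {
  stopifnot(all(c("geoid", "below_poverty", "total_pop") %in% names(demo)))
  if (any(demo$below_poverty > demo$total_pop)) {
    stop("below_poverty exceeds total_pop for some region")
  }
  i <- match(geoid, demo$geoid)
  if (anyNA(i)) {
    stop(sprintf("geoid '%s' not present in the demographic table",
                 geoid[which(is.na(i))[1]]))
  }
  ifelse(demo$total_pop[i] == 0, NA_real_,
         100 * demo$below_poverty[i] / demo$total_pop[i])
}

.check_parallel <- function(before, after) {
  stopifnot(all(c("id", "lon", "lat") %in% names(before)),
            all(c("id", "lon", "lat") %in% names(after)))
  if (nrow(before) != nrow(after) ||
      !identical(as.character(before$id), as.character(after$id))) {
    stop("`before` and `after` must be parallel point lists with matching ids")
  }
}

#' Audit region shifts caused by obfuscation
#'
#' For each requested level, counts records whose assigned GEOID differs
#' between the original and masked coordinates. Records unassigned (outside
#' every region) at a level in either list are excluded from that level's
#' denominator and reported in `n_unassigned`.
#'
#' @param before,after parallel point data.frames (`id`, `lon`, `lat`).
#' @param hierarchy a [region_hierarchy] (or named list of [region_set]s).
#' @param levels levels to audit (default: all in the hierarchy).
#' @param radius_label optional label (e.g. the masking radius in meters)
#'   carried into the output.
#' @return data.frame (one row per level) with columns `radius`, `level`,
#'   `n_total`, `n_shifted`, `pct_shifted`, `n_unassigned`.
#' @export
audit_region_shifts <- function(before, after, hierarchy,
                                levels = names(hierarchy),
                                radius_label = NA) {
  .check_parallel(before, after)
  out <- lapply(levels, function(lv) {
    rs <- hierarchy[[lv]]
    if (is.null(rs)) stop(sprintf("hierarchy has no level '%s'", lv))
    g1 <- assign_region(before, rs)
    g2 <- assign_region(after, rs)
    ok <- !is.na(g1) & !is.na(g2)
    n_total <- sum(ok)
    n_shifted <- sum(g1[ok] != g2[ok])
    data.frame(radius = radius_label, level = lv, n_total = n_total,
               n_shifted = n_shifted,
               pct_shifted = if (n_total > 0) 100 * n_shifted / n_total
                             else NA_real_,
               n_unassigned = sum(!ok), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Audit poverty-rate changes caused by obfuscation
#'
#' Links each record to its covering tract before and after masking, looks
#' up the tract poverty rate, and summarizes the changes. A record counts as
#' changed when both rates are defined and their unrounded difference
#' exceeds `min_change` percentage points (default 0: any nonzero change).
#' Mean/SD/median are of absolute differences over changed records; max and
#' min are of signed differences (positive: masked record was assigned a
#' higher poverty rate). Records with either rate undefined (unassigned, or
#' zero-population tract) are excluded and counted in `n_excluded`.
#'
#' @param before,after parallel point data.frames (`id`, `lon`, `lat`).
#' @param tract_regions [region_set] of tracts.
#' @param demo demographic table (see [poverty_rate()]); must cover every
#'   assigned tract.
#' @param min_change change threshold in percentage points.
#' @return list of class `rate_change_audit` with fields `n_total`,
#'   `n_changed`, `pct_changed`, `mean_abs_diff`, `sd_abs_diff`,
#'   `median_abs_diff`, `max_signed_diff`, `min_signed_diff`, `n_excluded`,
#'   and `diffs` (signed differences of changed records).
#' @export
audit_rate_changes <- function(before, after, tract_regions, demo,
                               min_change = 0) {
  .check_parallel(before, after)
  g1 <- assign_region(before, tract_regions)
  g2 <- assign_region(after, tract_regions)
  r1 <- rep(NA_real_, length(g1)); r2 <- rep(NA_real_, length(g2))
  r1[!is.na(g1)] <- poverty_rate(g1[!is.na(g1)], demo)
  r2[!is.na(g2)] <- poverty_rate(g2[!is.na(g2)], demo)
  ok <- !is.na(r1) & !is.na(r2)
  d <- r2[ok] - r1[ok]
  changed <- abs(d) > min_change
  dc <- d[changed]
  structure(list(
    n_total = sum(ok),
    n_changed = sum(changed),
    pct_changed = if (sum(ok) > 0) 100 * sum(changed) / sum(ok) else NA_real_,
    mean_abs_diff = if (length(dc)) mean(abs(dc)) else NA_real_,
    sd_abs_diff = if (length(dc) > 1) stats::sd(abs(dc)) else NA_real_,
    median_abs_diff = if (length(dc)) stats::median(abs(dc)) else NA_real_,
    max_signed_diff = if (length(dc)) max(dc) else NA_real_,
    min_signed_diff = if (length(dc)) min(dc) else NA_real_,
    n_excluded = sum(!ok),
    diffs = dc
  ), class = "rate_change_audit")
}

#' @export
print.rate_change_audit <- function(x, ...) {
  cat(sprintf(
    "poverty-rate change audit: %d/%d records changed (%.1f%%)\n",
    x$n_changed, x$n_total, x$pct_changed))
  if (x$n_changed > 0) {
    cat(sprintf("  |diff| mean %.1f (SD %.1f), median %.1f; signed range %.1f to %.1f\n",
                x$mean_abs_diff, x$sd_abs_diff, x$median_abs_diff,
                x$max_signed_diff, x$min_signed_diff))
  }
  if (x$n_excluded > 0) {
    cat(sprintf("  %d record(s) excluded (rate undefined)\n", x$n_excluded))
  }
  invisible(x)
}

#' Classify regions into poverty-rate quintiles
#'
#' Cut points at the 20/40/60/80th percentiles of the defined rates; ties at
#' a cut point fall into the lower quintile. Regions with undefined rates
#' get `NA`.
#'
#' @param demo demographic table (see [poverty_rate()]).
#' @return named integer vector (names = geoids) of quintiles 1..5.
#' @export
quintile_classify <- function(demo) {
  rates <- poverty_rate(demo$geoid, demo)
  def <- !is.na(rates)
  if (sum(def) < 5) stop("need at least 5 regions with defined poverty rates")
  q <- stats::quantile(rates[def], c(0.2, 0.4, 0.6, 0.8), names = FALSE)
  quint <- rep(NA_integer_, length(rates))
  quint[def] <- 1L + (rates[def] > q[1]) + (rates[def] > q[2]) +
    (rates[def] > q[3]) + (rates[def] > q[4])
  stats::setNames(quint, demo$geoid)
}

#' Summarize geodesic displacement between point lists
#'
#' @param before,after parallel point data.frames (`id`, `lon`, `lat`).
#' @return list with `mean_m`, `median_m`, `max_m`, and the per-record
#'   `distances_m` (WGS84 geodesic meters).
#' @export
displacement_summary <- function(before, after) {
  .check_parallel(before, after)
  d <- if (nrow(before) == 0) numeric(0) else
    geosphere::distGeo(cbind(before$lon, before$lat),
                       cbind(after$lon, after$lat))
  list(mean_m = if (length(d)) mean(d) else NA_real_,
       median_m = if (length(d)) stats::median(d) else NA_real_,
       max_m = if (length(d)) max(d) else NA_real_,
       distances_m = d)
}
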