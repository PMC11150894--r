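# Synthetic study geography: nested rectangular tessellations with census
# style GEOIDs, plus point sets and tract demographics with known truth, so
# the obfuscation/audit/hotspot pipeline is testable without any download.

#' Configuration for the synthetic geography generator
#'
#' The generator builds a grid of rectangular census tracts, each subdivided
#' into block groups and blocks, anchored at a lon/lat origin. Defaults are
#' sized like dense urban geography: 1500 m tract sides, so that a 1000 m
#' masking radius produces high region-shift rates, and tract populations
#' around the census-design optimum of 4000 people with Beta(2, 8)
#' poverty rates (mean 20%).
#'
#' @param grid_tracts integer (rows, cols) of the tract grid.
#' @param tract_side_m tract side length in meters.
#' @param bg_split per-axis subdivision of a tract into block groups
#'   (`bg_split^2` block groups per tract; at most 3 so the one-digit
#'   block-group GEOID suffix stays standard).
#' @param block_split per-axis subdivision of a block group into blocks.
#' @param origin lon/lat anchor of the grid's southwest corner; default on
#'   the equator so meters-per-degree scaling is uniform.
#' @param pop_mean expected persons per tract (Poisson).
#' @param poverty_beta shape parameters (alpha, beta) of the Beta
#'   distribution of tract poverty rates.
#' @param poverty_rate_fixed optional fixed rate in \[0, 1\] overriding the
#'   Beta draw (degenerate option for limit-case checks).
#' @param n_points number of points to sample.
#' @param cluster optional list(`tract` = geoid, `spread_m` = Gaussian sd in
#'   meters, `fraction` = share of points clustered) for hotspot scenarios.
#' @param seed default RNG seed used by the sampling functions.
#' @return a `synth_config` list.
#' @export
synth_config <- function(grid_tracts = c(6L, 6L), tract_side_m = 1500,
                         bg_split = 2L, block_split = 2L,
                         origin = c(0, 0), pop_mean = 4000,
                         poverty_beta = c(2, 8), poverty_rate_fixed = NULL,
                         n_points = 2000L, cluster = NULL, seed = 1L) {
  stopifnot(length(grid_tracts) == 2, all(grid_tracts >= 1),
            tract_side_m > 0, bg_split >= 1, bg_split <= 3,
            block_split >= 1, block_split <= 31,
            length(origin) == 2, pop_mean > 0,
            length(poverty_beta) == 2, all(poverty_beta > 0),
            is.null(poverty_rate_fixed) ||
              (poverty_rate_fixed >= 0 && poverty_rate_fixed <= 1),
            n_points >= 0)
  structure(list(
    grid_tracts = as.integer(grid_tracts), tract_side_m = tract_side_m,
    bg_split = as.integer(bg_split), block_split = as.integer(block_split),
    origin = as.numeric(origin), pop_mean = pop_mean,
    poverty_beta = as.numeric(poverty_beta),
    poverty_rate_fixed = poverty_rate_fixed,
    n_points = as.integer(n_points), cluster = cluster,
    seed = as.integer(seed)
  ), class = "synth_config")
}

# meters-per-degree at the config origin (lon scaled by cos(latitude))
.synth_scale <- function(config) {
  c(lon = .M_PER_DEG * cos(config$origin[2] * pi / 180), lat = .M_PER_DEG)
}

.rect_ring <- function(x0, y0, x1, y1, config) {
  sc <- .synth_scale(config)
  lon <- config$origin[1] + c(x0, x1, x1, x0) / sc["lon"]
  lat <- config$origin[2] + c(y0, y0, y1, y1) / sc["lat"]
  cbind(lon, lat)
}

.tract_geoid <- function(r, c) sprintf("99001%03d%03d", r, c)

#' Build the synthetic nested tessellation
#'
#' Produces a [region_hierarchy] with one state ("99", a code reserved so it
#' cannot collide with a real FIPS state), one county, a `rows x cols` grid
#' of square tracts, and nested block groups and blocks. GEOIDs obey the
#' standard 2/5/11/12/15 prefix scheme, interiors are disjoint, and the
#' union of a tract's blocks is exactly the tract.
#'
#' @param config a [synth_config()].
#' @return a [region_hierarchy] with levels state, county, tract,
#'   block_group, block; meters-per-degree scale stored in attribute
#'   `scale`.
#' @export
make_tessellation <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  rows <- config$grid_tracts[1]; cols <- config$grid_tracts[2]
  nblocks <- rows * cols * (config$bg_split * config$block_split)^2
  if (nblocks > 1e5) {
    stop(sprintf("tessellation would have %d blocks (> 1e5); reduce the grid",
                 nblocks))
  }
  side <- config$tract_side_m
  W <- cols * side; H <- rows * side
  bgs <- config$bg_split; bls <- config$block_split

  t_geoid <- character(0); t_geom <- list()
  bg_geoid <- character(0); bg_geom <- list()
  bl_geoid <- character(0); bl_geom <- list()
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      tx0 <- (c - 1) * side; ty0 <- (r - 1) * side
      tg <- .tract_geoid(r, c)
      t_geoid <- c(t_geoid, tg)
      t_geom <- c(t_geom, list(list(.rect_ring(tx0, ty0, tx0 + side,
                                               ty0 + side, config))))
      bg_side <- side / bgs
      for (br in seq_len(bgs)) {
        for (bc in seq_len(bgs)) {
          bx0 <- tx0 + (bc - 1) * bg_side; by0 <- ty0 + (br - 1) * bg_side
          bgg <- paste0(tg, (br - 1) * bgs + bc)
          bg_geoid <- c(bg_geoid, bgg)
          bg_geom <- c(bg_geom, list(list(.rect_ring(bx0, by0, bx0 + bg_side,
                                                     by0 + bg_side, config))))
          bl_side <- bg_side / bls
          for (lr in seq_len(bls)) {
            for (lc in seq_len(bls)) {
              lx0 <- bx0 + (lc - 1) * bl_side
              ly0 <- by0 + (lr - 1) * bl_side
              bl_geoid <- c(bl_geoid,
                            paste0(bgg, sprintf("%03d", (lr - 1) * bls + lc)))
              bl_geom <- c(bl_geom,
                           list(list(.rect_ring(lx0, ly0, lx0 + bl_side,
                                                ly0 + bl_side, config))))
            }
          }
        }
      }
    }
  }
  hier <- region_hierarchy(
    state = region_set("99", "state",
                       list(list(.rect_ring(0, 0, W, H, config)))),
    county = region_set("99001", "county",
                        list(list(.rect_ring(0, 0, W, H, config)))),
    tract = region_set(t_geoid, "tract", t_geom),
    block_group = region_set(bg_geoid, "block_group", bg_geom),
    block = region_set(bl_geoid, "block", bl_geom)
  )
  attr(hier, "scale") <- .synth_scale(config)
  attr(hier, "config") <- config
  hier
}

# geoid of the block containing planar-frame point (x, y); NA outside grid
.truth_block <- function(x, y, config) {
  rows <- config$grid_tracts[1]; cols <- config$grid_tracts[2]
  side <- config$tract_side_m
  bgs <- config$bg_split; bls <- config$block_split
  out <- rep(NA_character_, length(x))
  ok <- x >= 0 & x < cols * side & y >= 0 & y < rows * side
  if (!any(ok)) return(out)
  tc <- pmin(cols, floor(x[ok] / side) + 1)
  tr <- pmin(rows, floor(y[ok] / side) + 1)
  xin <- x[ok] - (tc - 1) * side; yin <- y[ok] - (tr - 1) * side
  bg_side <- side / bgs
  bgc <- pmin(bgs, floor(xin / bg_side) + 1)
  bgr <- pmin(bgs, floor(yin / bg_side) + 1)
  xbg <- xin - (bgc - 1) * bg_side; ybg <- yin - (bgr - 1) * bg_side
  bl_side <- bg_side / bls
  blc <- pmin(bls, floor(xbg / bl_side) + 1)
  blr <- pmin(bls, floor(ybg / bl_side) + 1)
  out[ok] <- paste0(.tract_geoid(tr, tc), (bgr - 1) * bgs + bgc,
                    sprintf("%03d", (blr - 1) * bls + blc))
  out
}

#' Sample synthetic points with known region membership
#'
#' Uniform points over the tract grid, or (with `config$cluster`) a mixture
#' of uniform background and a Gaussian cluster centered on a chosen
#' tract, for hotspot scenarios. The returned `block` column is the true
#' containing block GEOID computed arithmetically from the grid layout; it
#' agrees exactly with [assign_region()] on the generated tessellation
#' (truth at coarser levels follows by [parent_geoid()]).
#'
#' @param hierarchy tessellation from [make_tessellation()].
#' @param config the matching [synth_config()].
#' @param seed RNG seed (default `config$seed`).
#' @return data.frame with columns `id`, `lon`, `lat`, `block` (`NA` for
#'   cluster-tail points falling off the grid).
#' @export
sample_points <- function(hierarchy, config, seed = config$seed) {
  stopifnot(inherits(hierarchy, "region_hierarchy"),
            inherits(config, "synth_config"))
  set.seed(seed)
  n <- config$n_points
  rows <- config$grid_tracts[1]; cols <- config$grid_tracts[2]
  side <- config$tract_side_m
  x <- stats::runif(n, 0, cols * side)
  y <- stats::runif(n, 0, rows * side)
  if (!is.null(config$cluster)) {
    cl <- config$cluster
    tract_ids <- hierarchy$tract$geoid
    if (!cl$tract %in% tract_ids) {
      stop(sprintf("cluster tract '%s' is not in the tessellation", cl$tract))
    }
    rc <- regmatches(cl$tract, regexec("^99001(\\d{3})(\\d{3})$", cl$tract))[[1]]
    ctr_x <- (as.integer(rc[3]) - 0.5) * side
    ctr_y <- (as.integer(rc[2]) - 0.5) * side
    k <- stats::rbinom(n, 1, cl$fraction) == 1
    x[k] <- stats::rnorm(sum(k), ctr_x, cl$spread_m)
    y[k] <- stats::rnorm(sum(k), ctr_y, cl$spread_m)
  }
  sc <- .synth_scale(config)
  data.frame(
    id = sprintf("p%06d", seq_len(n)),
    lon = config$origin[1] + x / sc[["lon"]],
    lat = config$origin[2] + y / sc[["lat"]],
    block = .truth_block(x, y, config),
    stringsAsFactors = FALSE
  )
}

#' Sample synthetic tract demographics
#'
#' Per tract: total population drawn Poisson(`pop_mean`), poverty rate drawn
#' Beta(alpha, beta) (or fixed at `poverty_rate_fixed`), persons below
#' poverty = round(rate * total), capped at total.
#'
#' @param hierarchy tessellation from [make_tessellation()].
#' @param config the matching [synth_config()].
#' @param seed RNG seed (default `config$seed`).
#' @return data.frame with columns `geoid`, `below_poverty`, `total_pop`.
#' @export
sample_demographics <- function(hierarchy, config, seed = config$seed) {
  stopifnot(inherits(hierarchy, "region_hierarchy"),
            inherits(config, "synth_config"))
  set.seed(seed)
  g <- hierarchy$tract$geoid
  total <- stats::rpois(length(g), config$pop_mean)
  rate <- if (!is.null(config$poverty_rate_fixed)) {
    rep(config$poverty_rate_fixed, length(g))
  } else {
    stats::rbeta(length(g), config$poverty_beta[1], config$poverty_beta[2])
  }
  below <- pmin(total, round(rate * total))
  data.frame(geoid = g, below_poverty = below, total_pop = total,
             stringsAsFactors = FALSE)
}
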