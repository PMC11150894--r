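# Spatial weights, the Gi* statistic, and hotspot comparison.

grid_regions <- function(nr, nc) {
  geoids <- character(0); geoms <- list()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    geoids <- c(geoids, sprintf("g%02d%02d", r, c))
    geoms <- c(geoms, list(rect_poly(c - 1, r - 1, c, r)))
  }
  region_set(geoids, "custom", geoms)
}

test_that("count aggregation zero-fills and conserves points", {
  rs <- region_set(c("A", "B"), "custom",
                   list(rect_poly(0, 0, 1, 1), rect_poly(1, 0, 2, 1)))
  none <- aggregate_counts(data.frame(lon = numeric(0), lat = numeric(0)), rs)
  expect_equal(as.integer(none), c(0L, 0L))
  expect_equal(attr(none, "unassigned"), 0L)

  pts <- data.frame(lon = c(0.2, 0.4, 0.6, 9), lat = c(0.5, 0.5, 0.5, 9))
  cts <- aggregate_counts(pts, rs)
  expect_equal(cts[["A"]], 3L)
  expect_equal(cts[["B"]], 0L)
  expect_equal(sum(cts) + attr(cts, "unassigned"), nrow(pts))
})

test_that("queen contiguity links edge and corner neighbors, self included", {
  rs <- grid_regions(3, 3)
  w <- queen_weights(rs)
  center <- which(rs$geoid == "g0202")
  expect_length(w$neighbors[[center]], 9)            # 8 neighbors + self
  expect_true(center %in% w$neighbors[[center]])
  corner <- which(rs$geoid == "g0101")
  expect_length(w$neighbors[[corner]], 4)            # 3 neighbors + self
  # symmetry
  for (i in seq_along(w$neighbors)) {
    for (j in w$neighbors[[i]]) {
      expect_true(i %in% w$neighbors[[j]])
    }
  }
  # disjoint islands are never neighbors
  isl <- region_set(c("I", "J"), "custom",
                    list(rect_poly(0, 0, 1, 1), rect_poly(5, 5, 6, 6)))
  wi <- queen_weights(isl)
  expect_identical(wi$neighbors, list(1L, 2L))
})

test_that("Gi* matches the loop oracle and handles degenerate cases", {
  # flat landscape: S = 0 convention
  rs <- grid_regions(2, 2)
  w <- queen_weights(rs)
  flat <- gi_star(stats::setNames(rep(3, 4), rs$geoid), w)
  expect_true(all(flat$z == 0))
  expect_true(all(flat$bin == "not_significant"))

  # 3-region line, counts {0, 9, 0}: hand-computed z = (1/sqrt(2), 0, 1/sqrt(2));
  # the middle region neighbors all regions, hence the degenerate z = 0
  line <- region_set(c("A", "B", "C"), "custom",
                     list(rect_poly(0, 0, 1, 1), rect_poly(1, 0, 2, 1),
                          rect_poly(2, 0, 3, 1)))
  wl <- queen_weights(line)
  expect_warning(res <- gi_star(stats::setNames(c(0, 9, 0), c("A", "B", "C")),
                                wl),
                 "spans all regions")
  expect_equal(res$z, c(0.70710678118, 0, 0.70710678118), tolerance = 1e-9)
  orc <- oracle_gi_star(c(0, 9, 0), wl$neighbors, wl$weights)
  expect_equal(res$z, orc, tolerance = 1e-12)

  # 5x5 grid with one loaded center cell: center is the unique positive max
  rs5 <- grid_regions(5, 5)
  w5 <- queen_weights(rs5)
  x <- stats::setNames(rep(0, 25), rs5$geoid)
  x["g0303"] <- 25
  res5 <- gi_star(x, w5)
  orc5 <- oracle_gi_star(as.numeric(x), w5$neighbors, w5$weights)
  expect_equal(res5$z, orc5, tolerance = 1e-9)
  center <- which(rs5$geoid == "g0303")
  expect_gt(res5$z[center], 0)
  expect_equal(res5$z[center], max(res5$z))

  expect_error(gi_star(c(A = 1), list(ids = "A", neighbors = list(1L),
                                      weights = list(1),
                                      self_included = TRUE) |>
                         structure(class = "spatial_weights")),
               "at least 2")
})

test_that("z-scores are permutation-equivariant in the region labels", {
  rs <- grid_regions(4, 4)
  w <- queen_weights(rs)
  set.seed(66)
  x <- stats::setNames(rpois(16, 4), rs$geoid)
  res <- gi_star(x, w)
  perm <- sample(16)
  rs2 <- region_set(rs$geoid[perm], "custom", rs$geometry[perm])
  w2 <- queen_weights(rs2)
  res2 <- gi_star(x[rs2$geoid], w2)
  m <- match(res$geoid, res2$geoid)
  expect_equal(res$z, res2$z[m], tolerance = 1e-12)
})

test_that("hotspot comparison categorizes bin changes", {
  rs <- grid_regions(4, 4)
  w <- queen_weights(rs)
  set.seed(12)
  x <- stats::setNames(rpois(16, 5), rs$geoid)
  a <- gi_star(x, w)
  expect_equal(nrow(compare_hotspots(a, a)), 0)

  b <- a
  i <- 4L
  a$bin[i] <- "hot95"; b$bin[i] <- "not_significant"
  rep <- compare_hotspots(a, b)
  expect_equal(nrow(rep), 1)
  expect_identical(rep$change, "vanished")
  expect_identical(rep$geoid, a$geoid[i])

  a$bin[i] <- "not_significant"; b$bin[i] <- "cold90"
  expect_identical(compare_hotspots(a, b)$change, "emergent")
  a$bin[i] <- "hot90"; b$bin[i] <- "hot99"
  expect_identical(compare_hotspots(a, b)$change, "strengthened")
  a$bin[i] <- "cold99"; b$bin[i] <- "hot90"
  expect_identical(compare_hotspots(a, b)$change, "reversed")

  expect_error(compare_hotspots(a, b[-1, ]), "different region sets")
})

test_that("constrained masking leaves tract hotspots bit-identical", {
  cfg <- synth_config(grid_tracts = c(4, 4), n_points = 500, seed = 21,
                      cluster = list(tract = "99001002002", spread_m = 700,
                                     fraction = 0.5))
  hier <- make_tessellation(cfg)
  pts <- sample_points(hier, cfg)
  w <- queen_weights(hier$tract)
  before <- gi_star(aggregate_counts(pts, hier$tract), w)
  masked <- obfuscate_points(pts, pinwheel_params(45, 1000),
                             regions = hier$tract, seed = 33)
  after <- gi_star(aggregate_counts(masked, hier$tract), w)
  expect_identical(before, after)
  expect_equal(nrow(compare_hotspots(before, after)), 0)
})
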