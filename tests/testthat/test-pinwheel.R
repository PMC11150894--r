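# Pinwheel displacement geometry and the constrained rejection loop.

test_that("sawtooth displacement evaluates the blade formula", {
  p45 <- pinwheel_params(theta = 45, r_max = 1000)
  expect_equal(pinwheel_distance(0, p45), 0)
  expect_equal(pinwheel_distance(22.5, p45), 500)
  expect_equal(pinwheel_distance(90, p45), 0)     # blade boundary
  p360 <- pinwheel_params(theta = 360, r_max = 1000)
  expect_equal(pinwheel_distance(180, p360), 500) # single-blade case
})

test_that("parameter validation rejects out-of-range theta and radius", {
  expect_error(pinwheel_params(0, 100), "theta")
  expect_error(pinwheel_params(361, 100), "theta")
  expect_error(pinwheel_params(45, -1), "r_max")
})

test_that("projection solves the forward problem in both models", {
  # zero distance is the identity
  for (m in c("geodesic", "planar")) {
    out <- project_point(12.3, 45.6, azimuth = 77, distance = 0, model = m)
    expect_equal(out$lon, 12.3)
    expect_equal(out$lat, 45.6)
  }
  # one degree of longitude at the equator: 2*pi*a/360 m for WGS84 a
  out <- project_point(0, 0, 90, 111319.4908, model = "planar")
  expect_equal(out$lon, 1, tolerance = 1e-7)
  expect_equal(out$lat, 0)
  # northward geodesic bearing: lat increases, lon unchanged
  out <- project_point(0, 0, 0, 1000, model = "geodesic")
  expect_gt(out$lat, 0)
  expect_equal(out$lon, 0)
  # geodesic forward agrees with the independent inverse solver
  out <- project_point(-87.6, 41.8, 123, 800, model = "geodesic")
  expect_equal(geosphere::distGeo(c(-87.6, 41.8), c(out$lon, out$lat)),
               800, tolerance = 1e-6)
  # planar and geodesic agree for short hops away from the poles
  g <- project_point(10, 50, 240, 200, model = "geodesic")
  pl <- project_point(10, 50, 240, 200, model = "planar")
  expect_lt(geosphere::distGeo(c(g$lon, g$lat), c(pl$lon, pl$lat)), 1)
  # polar overflow is an error
  expect_error(project_point(0, 89.999, 0, 50000, model = "planar"),
               "pole")
})

test_that("zero radius is the identity and seeds are deterministic", {
  p0 <- pinwheel_params(45, 0)
  set.seed(11)
  out <- pinwheel_obfuscate(3.21, 48.85, p0)
  expect_identical(out$lon, 3.21)
  expect_identical(out$lat, 48.85)

  p <- pinwheel_params(45, 1000)
  set.seed(99); a <- pinwheel_obfuscate(3.21, 48.85, p)
  set.seed(99); b <- pinwheel_obfuscate(3.21, 48.85, p)
  expect_identical(a, b)
})

test_that("displacements respect the r_max bound and the uniform sawtooth law", {
  p <- pinwheel_params(45, 1000)
  set.seed(5)
  n <- 10000
  out <- pinwheel_obfuscate(rep(-87.6, n), rep(41.8, n), p)
  d <- geosphere::distGeo(cbind(-87.6, 41.8), cbind(out$lon, out$lat))
  expect_true(all(d <= 1000 + 1e-6))
  # a mod theta is uniform, so P(d < r/2) = 1/2
  expect_equal(mean(out$distance < 500), 0.5, tolerance = 0.03)
})

test_that("candidate clouds form 360/theta blades", {
  # recover azimuth and distance from output coordinates; near-maximal
  # displacements must sit just below multiples of theta
  for (theta in c(45, 15)) {
    p <- pinwheel_params(theta, 1000, distance_model = "planar")
    set.seed(2024)
    n <- 20000
    out <- pinwheel_obfuscate(rep(0, n), rep(0, n), p)
    d <- geosphere::distGeo(cbind(0, 0), cbind(out$lon, out$lat))
    az <- (geosphere::bearing(cbind(0, 0), cbind(out$lon, out$lat))) %% 360
    hi <- d > 0.9 * 1000
    expect_gt(sum(hi), 100)
    # azimuths concentrate just below multiples of theta (recovered
    # bearings can wrap a hair past the blade boundary)
    phase <- (az[hi] %% theta) / theta
    expect_true(all(phase > 0.85 | phase < 0.02))
    # every blade is populated
    blades <- round(az[hi] / theta) %% (360 / theta)
    expect_equal(length(unique(blades)), 360 / theta)
  }
})

test_that("constrained draws accept immediately inside a roomy constraint", {
  sq <- rect_poly(-0.05, -0.05, 0.05, 0.05)   # ~11 km square at equator
  p <- pinwheel_params(45, 100)
  set.seed(1); con <- constrained_pinwheel(0, 0, p, sq)
  set.seed(1); unc <- pinwheel_obfuscate(0, 0, p)
  expect_equal(con$attempts, 1)
  expect_identical(c(con$lon, con$lat), c(unc$lon, unc$lat))
  expect_lte(geosphere::distGeo(c(0, 0), c(con$lon, con$lat)), 100 + 1e-6)
})

test_that("constrained draws enforce preconditions and the attempt budget", {
  sq <- rect_poly(0, 0, 0.01, 0.01)
  p <- pinwheel_params(45, 1000)
  err <- tryCatch(constrained_pinwheel(5, 5, p, sq), condition = identity)
  expect_s3_class(err, "geomask_precondition_error")
  # a 2 m-wide sliver rejects nearly everything: tiny budget must error
  sliver <- rect_poly(0, 0, 2 / 111319.4908, 0.027)
  set.seed(8)
  err <- tryCatch(
    constrained_pinwheel(1 / 111319.4908, 0.01, p, sliver, max_attempts = 3),
    condition = identity)
  expect_s3_class(err, "geomask_budget_error")
  expect_match(conditionMessage(err), "3 attempts")
})

test_that("constraining shrinks mean displacement on a narrow tract", {
  # 100 m x 3000 m sliver, r_max 1000: the paper-style ordering
  w <- 100 / 111319.4908
  h <- 3000 / 111319.4908
  sliver <- rect_poly(0, 0, w, h)
  p <- pinwheel_params(45, 1000)
  n <- 400
  set.seed(31)
  px <- runif(n, 0, w); py <- runif(n, 0, h)
  set.seed(77)
  unc <- pinwheel_obfuscate(px, py, p)
  d_unc <- geosphere::distGeo(cbind(px, py), cbind(unc$lon, unc$lat))
  d_con <- numeric(n)
  for (i in seq_len(n)) {
    set.seed(1000 + i)
    r <- constrained_pinwheel(px[i], py[i], p, sliver)
    d_con[i] <- geosphere::distGeo(c(px[i], py[i]), c(r$lon, r$lat))
  }
  expect_lt(mean(d_con), mean(d_unc))
})

test_that("set obfuscation is parallel, order-independent, and collects failures", {
  w <- toy_world(n_points = 60)
  p <- pinwheel_params(45, 300)

  empty <- obfuscate_points(w$points[0, ], p, seed = 1)
  expect_equal(nrow(empty), 0)

  out <- obfuscate_points(w$points, p, regions = w$hier$tract, seed = 9)
  expect_identical(out$id, w$points$id)
  expect_identical(assign_region(out, w$hier$tract),
                   assign_region(w$points, w$hier$tract))

  # shuffling the input rows leaves every record's mask unchanged
  shuf <- w$points[rev(seq_len(nrow(w$points))), ]
  out2 <- obfuscate_points(shuf, p, regions = w$hier$tract, seed = 9)
  m <- match(out$id, out2$id)
  expect_equal(out$lon, out2$lon[m])
  expect_equal(out$lat, out2$lat[m])

  # unconstrained mode equals mapping the single-point mask per derived seed
  out3 <- obfuscate_points(w$points[1:5, ], p, seed = 4)
  for (i in 1:5) {
    set.seed(geomask:::point_seed(4, w$points$id[i]))
    one <- pinwheel_obfuscate(w$points$lon[i], w$points$lat[i], p)
    expect_equal(out3$lon[i], one$lon)
    expect_equal(out3$lat[i], one$lat)
  }

  # a point outside every region is reported, not dropped
  far <- rbind(w$points[1:3, c("id", "lon", "lat")],
               data.frame(id = "lost", lon = 20, lat = 20))
  out4 <- obfuscate_points(far, p, regions = w$hier$tract, seed = 2)
  expect_equal(nrow(out4), 4)
  expect_identical(attr(out4, "failures")$id, "lost")
  expect_true(is.na(out4$lon[out4$id == "lost"]))
})
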