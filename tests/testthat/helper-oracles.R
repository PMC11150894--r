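# Independent oracles, written before the implementations they check and
# kept deliberately naive: a winding-number containment test (the package
# uses even-odd crossing) and a loop-based Gi* evaluator.

# Boundary-inclusive winding-number containment for a single point.
# Simple rings only (|winding| <= 1), holes handled by parity of the sum.
oracle_covers <- function(px, py, rings, tol = 1e-12) {
  on_seg <- function(ax, ay, bx, by) {
    dx <- bx - ax; dy <- by - ay
    len2 <- dx * dx + dy * dy
    if (len2 == 0) return(abs(px - ax) <= tol && abs(py - ay) <= tol)
    t <- ((px - ax) * dx + (py - ay) * dy) / len2
    t <- min(1, max(0, t))
    abs(px - (ax + t * dx)) <= tol && abs(py - (ay + t * dy)) <= tol
  }
  parity <- 0L
  for (ring in rings) {
    n <- nrow(ring)
    wn <- 0L
    for (k in seq_len(n)) {
      ax <- ring[k, 1]; ay <- ring[k, 2]
      kk <- if (k == n) 1L else k + 1L
      bx <- ring[kk, 1]; by <- ring[kk, 2]
      if (on_seg(ax, ay, bx, by)) return(TRUE)
      if (ay <= py) {
        if (by > py && (bx - ax) * (py - ay) - (by - ay) * (px - ax) > 0) {
          wn <- wn + 1L
        }
      } else if (by <= py &&
                 (bx - ax) * (py - ay) - (by - ay) * (px - ax) < 0) {
        wn <- wn - 1L
      }
    }
    parity <- parity + abs(wn)
  }
  parity %% 2L == 1L
}

# Brute-force Gi*: plain loops over the published formula, no shared code
# with gi_star(). Degenerate neighborhoods (denominator 0) yield z = 0.
oracle_gi_star <- function(x, neighbors, weights) {
  n <- length(x)
  xbar <- sum(x) / n
  S <- sqrt(sum(x * x) / n - xbar^2)
  z <- numeric(n)
  if (S == 0) return(z)
  for (i in seq_len(n)) {
    num <- 0; Wi <- 0; W2 <- 0
    for (k in seq_along(neighbors[[i]])) {
      j <- neighbors[[i]][k]
      w <- weights[[i]][k]
      num <- num + w * x[j]
      Wi <- Wi + w
      W2 <- W2 + w * w
    }
    den <- S * sqrt((n * W2 - Wi^2) / (n - 1))
    z[i] <- if (den > 0) (num - xbar * Wi) / den else 0
  }
  z
}

# One-ring axis-aligned rectangle polygon.
rect_poly <- function(x0, y0, x1, y1) {
  list(cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1)))
}

# Star-shaped simple polygon with random vertex radii (always non-self-
# intersecting), for containment fuzzing.
star_poly <- function(n_vertices = 12, cx = 0, cy = 0, r_range = c(0.3, 1)) {
  ang <- sort(stats::runif(n_vertices, 0, 2 * pi))
  r <- stats::runif(n_vertices, r_range[1], r_range[2])
  list(cbind(cx + r * cos(ang), cy + r * sin(ang)))
}

# Small tessellation + points used across tests.
toy_world <- function(rows = 2, cols = 2, n_points = 200, seed = 42,
                      tract_side_m = 1500) {
  cfg <- synth_config(grid_tracts = c(rows, cols), n_points = n_points,
                      seed = seed, tract_side_m = tract_side_m)
  hier <- make_tessellation(cfg)
  list(cfg = cfg, hier = hier, points = sample_points(hier, cfg))
}
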