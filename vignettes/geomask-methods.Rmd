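---
title: "Constrained pinwheel masking: model, audits, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained pinwheel masking: model, audits, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geomask)
```

## The problem

Patient-level coordinates (geocoded residential addresses, incident
locations) cannot usually be released as-is. Geographic masking perturbs
each point so the person it represents cannot be re-identified, while
keeping the data useful for spatial analysis. The catch: most downstream
public-health analyses do not use the coordinate itself — they use the
census region it falls in, through which neighborhood attributes such as
the ACS poverty rate are linked. A mask that moves a point a few hundred
meters can silently move it into a different census block, block group, or
tract, changing every region-linked attribute and distorting
region-aggregated statistics such as hotspot maps. This package implements
a masking method with a hard guarantee against that failure mode, plus the
audit machinery to measure the damage when the guarantee is not used.

## The pinwheel mask

One draw masks one point. A random degree $a \sim \mathrm{Uniform}[0,
360)$ is the travel azimuth, and the displacement distance is a sawtooth
in $a$:

$$d = r_{\max}\cdot\frac{a \bmod \theta}{\theta},$$

after which the point is projected distance $d$ along bearing $a$ (forward
geodesic on the WGS84 ellipsoid, via `geosphere`). Because $a \bmod
\theta$ is uniform on $[0, \theta)$, $d / r_{\max}$ is uniform on $[0,
1)$, and candidate clouds form $360/\theta$ blades whose tips sit just
below each multiple of $\theta$ — small $\theta$ gives many narrow,
closely spaced blades. The distance law is deliberately coupled to the
direction: the noise is asymmetric and non-uniform, which is the
pinwheel's defense against filtering attacks that assume symmetric
jitter. An `independent_azimuth` option decouples the two draws for users
who want direction itself to carry no information about distance; it is
off by default, keeping the classic single-draw geometry.

Two distance models are provided. `geodesic` (default) solves the direct
geodesic problem on WGS84 and is what production masking should use.
`planar` scales meters to degrees at the point's latitude; it admits
closed-form unit tests and is faster for large simulations, at the cost of
sub-percent distance error away from the poles.

## The geographically constrained variant

`constrained_pinwheel()` redraws displacements until the candidate lies in
a designated constraint polygon — typically the census region (block,
block group, tract, county, or state, or any custom polygon) containing
the original point. The accepted point therefore has, by construction,
exactly the original point's region-linked attributes: region-shift
audits, poverty-rate-change audits, and region-aggregated hotspot maps are
all invariant under the constrained mask. This is a rejection sampler, so
its per-point cost is the observable price of the guarantee;
`obfuscate_points()` reports attempts per record and the CLI summarizes
them. The rejection budget defaults to 10,000 attempts and exhaustion is a
hard error — a silent fall-through would void the guarantee. The flip side
of the guarantee is a shorter typical displacement (the candidate disc is
clipped by the region), which the narrow-tract example below quantifies;
whether that displacement still meets a given privacy requirement is a
policy question the package reports on but does not decide.

Containment everywhere in the package is *covered-by* (boundary
inclusive). A boundary-exclusive rule would make a point lying exactly on
its region's edge fail its own constraint, and the rejection loop could
not terminate; boundary inclusion makes the loop's precondition ("the
original point is in its own region") self-consistent. For assignment,
a point on a shared edge of two regions is deterministically given the
lexicographically smallest covering GEOID; two regions covering a point in
their *interiors* indicate broken input geometry and raise an error.

## Reproducibility model

All masking is driven by one master seed. `obfuscate_points()` derives a
per-record substream seed from `(master seed, record id)` with a
polynomial hash, so a record's mask does not depend on the order or
presence of other records, and re-running with the same seed reproduces
output byte for byte. In constrained mode the first candidate is drawn
alone (so an immediately accepted draw matches the unconstrained mask
draw-for-draw under the same substream), with later attempts drawn in
batches of 64 for speed.

## Geometry without a simple-features stack

Region polygons live in plain lon/lat (EPSG:4326) and containment is
computed in that coordinate space, matching how TIGER geometries are
distributed. The package carries its own computational geometry: an
even-odd crossing containment test (vectorized over points, holes handled
by ring parity), a grid index over region bounding boxes so assigning
$N$ points to $M$ polygons does not degrade to $N \times M$ exact tests,
and a proper-intersection check that rejects self-intersecting rings at
load time (there is no repair step; invalid features are reported and
refused). The test suite checks the containment predicate against an
independently written winding-number oracle on $10^4$ random and
near-edge points. Region input is GeoJSON FeatureCollections (the `GEOID`
property configurable); point files are CSV or GeoJSON.

## Audits

`audit_region_shifts()` counts, per level, records whose assigned GEOID
differs before vs after masking. Records unassigned at a level in either
list (e.g. masked off the study area) are excluded from that level's
denominator and reported separately. `audit_rate_changes()` links each
record to its tract poverty rate — $100\cdot\text{below poverty} /
\text{total population}$, undefined (`NA`) for zero-population tracts —
and summarizes changes: mean/SD/median of *absolute* differences over
changed records, extremes of *signed* differences (both reported
explicitly because a summary that mixes the two is ambiguous), where
"changed" means any nonzero difference of unrounded rates (a
`min_change` threshold in percentage points is available, default 0).
Rates are carried at full precision and only rounded for printing.

`gi_star()` implements the standard Getis-Ord Gi* z-score on
region-aggregated counts with self-inclusive weights,

$$z_i = \frac{\sum_j w_{ij}x_j - \bar{X}\sum_j w_{ij}}
{S\sqrt{\left[n\sum_j w_{ij}^2 - (\sum_j w_{ij})^2\right]/(n-1)}},$$

with $\bar X$ and $S$ the global (population) mean and standard deviation
of all counts, two-tailed normal p-values, and 90/95/99% confidence bins
at $|z|$ 1.645/1.960/2.576. Queen contiguity with self-inclusion is the
default neighborhood; a fixed distance band on region centroids and an
optional Benjamini–Hochberg FDR adjustment are provided. Two degenerate
cases are defined rather than left undefined: a flat count landscape
($S = 0$) yields $z = 0$ everywhere, and a region whose neighborhood
spans *all* regions has a zero denominator and gets $z = 0$ with a
warning (visible on very small tessellations, e.g. the center of a 3×3
grid). `compare_hotspots()` reports every region whose bin changed
between two runs, categorized as emergent, vanished, strengthened,
weakened, or reversed — on constrained-mask output this report is empty
on every instance, which the tests assert.

## Synthetic study geography

`make_tessellation()` builds a grid of square tracts subdivided into
block groups and blocks, with GEOIDs obeying the standard 2/5/11/12/15
prefix scheme under the reserved state code "99" (never a real FIPS
code). The tessellation is constructed in a local planar frame and
anchored at a configurable lon/lat — on the equator by default, where
meters-per-degree is the same both axes and unit tests have closed forms.
Defaults emulate dense urban geography: 1500 m tract sides (so a 1000 m
masking radius crosses boundaries often), tract populations
Poisson(4000) around the census design optimum, and tract poverty rates
Beta(2, 8) — mean 20%, long right tail, occasionally extreme — which is
what an audit needs to show meaningful rate changes. `sample_points()`
returns uniform or cluster-mixture points with their true block
membership computed arithmetically from the grid, so assignment can be
verified exactly.

What the generator does *not* emulate: real tract shapes (convoluted,
water-clipped, wildly varying in size), spatially autocorrelated poverty,
population-weighted point density, or geocoding artifacts (points on
street centerlines, in water). Passing audits on synthetic geography
therefore demonstrate correctness of the machinery and the direction and
rough magnitude of the effects — not the exact shift percentages of any
real study area, which depend on that area's region sizes.

## Problem sizes and numerical choices

The shipped tests run the property suites at $10^4$–$10^5$ draws/points
(displacement bound, uniformity, constraint preservation, oracle
equivalence), the radius sweep at radii {1, 10, 100, 500, 1000} m over 10
seeds on a 3×3-tract tessellation with 400 points per seed, and the
narrow-tract displacement comparison at 5,000 points — sizes chosen so
the whole suite completes in minutes on one CPU while keeping Monte-Carlo
error well inside the asserted margins. Distance assertions allow
$10^{-6}$ m slack for geodesic roundoff; containment uses a configurable
degree tolerance ($10^{-12}$ default) for boundary coincidence; the
zero-distance projection returns the input coordinates exactly rather
than through the geodesic solver, so a zero radius is the identity map
bit for bit.

## A worked pipeline

```{r pipeline}
cfg <- synth_config(grid_tracts = c(4, 4), n_points = 1000, seed = 7)
hier <- make_tessellation(cfg)
pts <- sample_points(hier, cfg)
demo <- sample_demographics(hier, cfg)
params <- pinwheel_params(theta = 45, r_max = 1000)

# unconstrained masking: how much damage?
masked_u <- obfuscate_points(pts, params, seed = 7)
audit_region_shifts(pts, masked_u, hier, c("block", "block_group", "tract"),
                    radius_label = 1000)
audit_rate_changes(pts, masked_u, hier$tract, demo)

# constrained masking: the audits are exact nulls
masked_c <- obfuscate_points(pts, params, regions = hier$tract, seed = 7)
audit_region_shifts(pts, masked_c, hier, "tract")
summary(masked_c$attempts)

# the price: shorter displacements
c(unconstrained = displacement_summary(pts, masked_u)$mean_m,
  constrained = displacement_summary(pts, masked_c)$mean_m)
```

## Known limitations

- Shapefile input is not supported; convert to GeoJSON first (e.g. with
  `ogr2ogr`). GeoJSON and CSV cover the package's scope.
- Queen contiguity detects shared boundary points via shared vertices or
  a vertex of one polygon lying on an edge of the other. This is exact on
  tessellations whose shared segments contain a vertex of at least one
  participant (true of any non-overlapping tiling), but two polygons
  crossing edge-through-edge without a coincident vertex — already
  invalid as a tessellation — would be missed.
- The Gi* neighborhood conceptualizations offered (queen, fixed distance
  band) are the standard ones; results from GIS products using other
  defaults (inverse distance, zone-of-indifference, FDR on by default)
  will bin borderline regions differently.
- Constraining guarantees region-linked invariance only at (and above)
  the constraint level: a tract-constrained mask still shifts blocks
  within the tract, and distance-based analyses are still perturbed —
  deliberately so, since that perturbation is the privacy protection.
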