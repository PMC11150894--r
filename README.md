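# geomask

Geographic masking ("geomasking") for patient-level point data: pinwheel
point obfuscation, a geographically constrained variant with a hard
guarantee that masked points never leave their census region, and audit
tools quantifying what unconstrained masking does to region-linked
neighborhood measures and hotspot maps.

## Why

Health-records coordinates must be blurred before release to protect the
people they represent. But most spatial epidemiology does not consume the
coordinate — it consumes the census region containing it, through which
neighborhood attributes (ACS poverty rate, deprivation indices) are
linked. A mask that moves a point a few hundred meters routinely moves it
across block, block-group, or tract boundaries, silently swapping its
neighborhood demographics and creating or destroying hotspots in
region-aggregated analyses. `geomask` implements:

- **Pinwheel masking** (`pinwheel_obfuscate`): draw a random degree
  `a ~ U[0, 360)`, displace along bearing `a` by the sawtooth distance
  `d = r_max * ((a mod theta) / theta)` (forward geodesic on WGS84).
  Candidate clouds form `360 / theta` blades reaching at most `r_max`
  meters; the coupling of distance to direction makes the noise
  asymmetric and hard to filter out.
- **Constrained pinwheel** (`constrained_pinwheel`, `obfuscate_points`
  with `regions`): rejection-sample displacements until the masked point
  stays inside its original region (block … state, or custom polygons).
  Region-linked attributes are then invariant under masking *by
  construction*.
- **Audits**: `audit_region_shifts` (how many records change region, per
  level and radius), `audit_rate_changes` (poverty-rate differences
  before/after masking), `displacement_summary`, `quintile_classify`.
- **Hotspots**: Getis-Ord Gi* (`gi_star`) on region-aggregated counts
  with queen or distance-band self-inclusive weights, and
  `compare_hotspots` to report emergent/vanished/strengthened/weakened
  bins between runs.
- **Synthetic geography** (`make_tessellation`, `sample_points`,
  `sample_demographics`): nested tract/block-group/block tessellations
  with census-style prefix-nested GEOIDs (reserved state code "99"),
  known true memberships, and Beta-distributed tract poverty rates, so
  the whole pipeline is testable offline.
- **GEOID plumbing**: `read_regions` (GeoJSON), `assign_region`
  (boundary-inclusive point-in-region join with a bbox grid index),
  `parent_geoid` (prefix truncation to 2/5/11/12 characters).

## Worked example

```r
library(geomask)

cfg    <- synth_config(grid_tracts = c(4, 4), n_points = 1000, seed = 7)
hier   <- make_tessellation(cfg)      # 16 tracts, 64 block groups, 256 blocks
pts    <- sample_points(hier, cfg)
demo   <- sample_demographics(hier, cfg)
params <- pinwheel_params(theta = 45, r_max = 1000)

# unconstrained masking: how much damage?
masked_u <- obfuscate_points(pts, params, seed = 7)
audit_region_shifts(pts, masked_u, hier,
                    c("block", "block_group", "tract"), radius_label = 1000)
#>   radius       level n_total n_shifted pct_shifted n_unassigned
#> 1   1000       block     884       712    80.54299          116
#> 2   1000 block_group     884       545    61.65158          116
#> 3   1000       tract     884       281    31.78733          116

audit_rate_changes(pts, masked_u, hier$tract, demo)
#> poverty-rate change audit: 281/884 records changed (31.8%)
#>   |diff| mean 6.4 (SD 4.7), median 5.1; signed range 18.5 to -19.7
#>   116 record(s) excluded (rate undefined)

# constrained masking: the audit is an exact null
masked_c <- obfuscate_points(pts, params, regions = hier$tract, seed = 7)
audit_region_shifts(pts, masked_c, hier, "tract")
#>   radius level n_total n_shifted pct_shifted n_unassigned
#> 1     NA tract    1000         0           0            0

# the price of the guarantee: shorter displacements
c(unconstrained = displacement_summary(pts, masked_u)$mean_m,
  constrained   = displacement_summary(pts, masked_c)$mean_m)
#> unconstrained   constrained
#>      502.2931      397.4429
```

Reading: with 1000 m masking on 1500 m urban-scale tracts, 80% of records
change census block and 32% change tract — and those tract changes drag
the linked poverty rate with them (mean absolute change 6.4 percentage
points). The 116 excluded records were masked off the study area and are
reported, not silently dropped. Constrained to tracts, zero records shift
and zero rates change, at the cost of a shorter mean displacement.

A command-line wrapper with subcommands `synth`, `obfuscate`,
`audit-shift`, `audit-rates`, `hotspot`, `hotspot-compare` is installed
at `inst/cli/geomask.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/geomask.R", package="geomask"))')" \
  obfuscate --points points.csv --theta 45 --radius 1000 \
  --constrain tract --regions tracts.geojson --seed 1 --out masked.csv
```

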