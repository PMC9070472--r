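# geoaccess

Geospatial accessibility analysis of health-facility networks: how are
facilities distributed over a region, where do they cluster, and do insured
clients actually use the facility nearest to their home — or **bypass** it
for one further away?

The package is aimed at health-systems and spatial-epidemiology analysts
working with three plain inputs on planar (projected, metre) coordinates:

* a facility table (id, care level, accreditation flag, x/y),
* an enrollee table (id, proxy-residence x/y, id of the facility actually
  used),
* the study area (a polygon, or just its area in m²).

From these it computes:

* **Clark–Evans nearest-neighbour analysis** (`clark_evans()`): the ratio
  `Rn = D̄_O / D̄_E` of the observed mean nearest-neighbour distance to its
  expectation under complete spatial randomness, `D̄_E = 0.5·√(A/n)`, with
  `z = (D̄_O − D̄_E)/SE`, `SE = 0.26136/√(n²/A)`; `Rn < 1` clustered,
  `≈ 1` random, `> 1` dispersed.
* **Getis–Ord Gi\* hotspot mapping** (`hotspot_analysis()`): fishnet
  aggregation of facility points, the Gi\* z-score with fixed-distance
  weights (focal cell included), Benjamini–Hochberg FDR correction and
  signed 90/95/99% confidence bins.
* **Nearest-facility assignment and bypassing** (`assign_nearest()`,
  `bypass_table()`, `distance_summary()`, `hub_lines()`): Euclidean
  nearest accredited facility per enrollee, per-facility bypass rates, the
  shortest/longest distance travelled per facility, and "spider-web" hub
  lines exportable as GeoJSON.
* **Coverage statistics and sample size** (`coverage_stats()`,
  `kish_sample_size()`): stratum-level enrolment coverage from an
  administrative summary table, and the Leslie Kish minimum sample size
  `⌈z²·p(1−p)/d²⌉`.
* A **synthetic study generator** (`synthetic_config()`,
  `simulate_dataset()`): CSR / Thomas-cluster / lattice facility patterns,
  uniform residences, exponential distance-decay facility choice and a
  300–500 m landmark-proxy geocoding error — so the whole pipeline is
  testable end to end without field data.

`run_pipeline()` orchestrates simulate (or load) → nearest-neighbour
analysis → hotspots → assignment → report tables from a single YAML/JSON
config and writes CSV/GeoJSON products plus a run manifest. A thin
command-line wrapper lives at `inst/scripts/geoaccess.R`.

## Worked example

```r
library(geoaccess)

cfg <- synthetic_config(seed = 20, pattern = "thomas")  # clustered facilities
dat <- simulate_dataset(cfg)

clark_evans(dat$facilities, cfg$area)
#> Clark-Evans nearest-neighbour analysis
#>   n = 531 points over 3.19813e+09 m^2
#>   observed mean NN distance Do = 554.3628 m
#>   expected mean NN distance De = 1227.0741 m
#>   Rn = 0.451776, z = -24.167741, p = 4.86e-129
#>   Pattern: Clustered (alpha = 0.05)

a <- assign_nearest(dat$enrollees, dat$facilities)
tail(bypass_table(a), 1)
#>  facility_id n_patrons n_bypassed pct_bypassed n_non_bypassed pct_non_bypassed
#>        Total       431        398         92.3             33              7.7

tail(distance_summary(a), 1)
#>  facility_id shortest_km longest_km
#>      Average       5.652     13.464

cells <- hotspot_analysis(dat$facilities, cfg$area, cell_size = 2000, band = 4000)
#> hotspot: cell_size = 2000 m, band = 4000 m, 841 cells
sum(cells$bin == 3)   # cells that are hotspots at 99% confidence
#> [1] 97
```

Reading the output: the 531 clustered facilities have a mean
nearest-neighbour distance of 554 m against the 1227 m expected if they
were scattered at random over the 3.2 × 10⁹ m² region — `Rn ≈ 0.45`, 24
standard errors below 1, so the pattern is firmly *clustered*. Of the 431
simulated enrollees, 92.3% bypass their nearest accredited facility (the
decay-based choice model plus the 300–500 m geocoding jitter both
contribute), and the per-facility shortest/longest distances travelled
average 5.7–13.5 km. The Gi\* map flags 97 of 841 grid cells as
99%-confidence hotspots around the planted cluster centers.

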