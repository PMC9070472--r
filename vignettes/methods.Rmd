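---
title: "Methods: point patterns, hotspots and facility bypassing"
author: "geoaccess"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: point patterns, hotspots and facility bypassing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geoaccess)
```

## The problem

Health-insurance schemes in many low- and middle-income settings accredit
only a subset of facilities (typically secondary and tertiary care) as
service providers. Two spatial questions then decide whether enrolment
translates into access: are the accredited facilities spread out over the
population or piled up in the urban core, and do enrollees actually use the
facility nearest to their home — or do they *bypass* it for one further
away? `geoaccess` packages the analyses used to answer both questions from
nothing more than facility coordinates, enrollee (proxy-)residence
coordinates and the identity of the facility each enrollee uses.

All computation is on planar coordinates in metres (a projected system such
as UTM). The package never computes on longitude/latitude: distances are
Euclidean straight lines, a deliberate proxy for travel cost in settings
where travel-time data are unavailable. Road networks, elevation and other
barriers are out of scope by design.

## Clark–Evans nearest-neighbour analysis

For $n$ points over a declared study area $A$, the observed mean
nearest-neighbour distance is
$$\bar D_O = \frac{1}{n} \sum_i \min_{j \neq i} d_{ij},$$
and under complete spatial randomness (CSR) its expectation is
$\bar D_E = 0.5\sqrt{A/n}$. The Clark–Evans ratio $R_n = \bar D_O / \bar
D_E$ is below 1 for clustered patterns, near 1 for random ones and above 1
(at most 2.149) for dispersed ones. The test statistic is
$$z = \frac{\bar D_O - \bar D_E}{SE}, \qquad SE =
\frac{0.26136}{\sqrt{n^2/A}},$$
with a two-sided normal p-value; $z$ is negative for clustering ($\bar D_O
< \bar D_E$). The pattern label uses $\alpha = 0.05$ by default.

Two design points matter:

* **The area is a required input, never inferred.** $R_n$ is meaningless
  without a declared $A$ — the same points are "clustered" relative to a
  large declared region and "dispersed" relative to a tight one — and
  reproducing a published analysis requires the published area.
* **No edge correction.** The statistic matches the plain (ArcGIS-style)
  average-nearest-neighbour computation. This has a known consequence: in a
  bounded region the observed mean NN distance is biased upward because a
  point near the boundary has no neighbours beyond it (Donnelly's
  approximation puts the bias at roughly $0.0514\,P/n$ for perimeter $P$).
  `csr_calibration()` measures this directly: at $n = 531$ over a
  $3.198\times 10^9$ m² square the mean simulated $R_n$ is about 1.018 and
  the $\alpha = 0.05$ rejection rate about 0.13 rather than the nominal
  0.05. The uncorrected test is therefore *anti-conservative against
  dispersion and conservative against clustering*; for strongly clustered
  empirical patterns ($R_n \approx 0.84$, many SEs below 1) the
  classification is unaffected, but marginal calls near $R_n = 1$ should
  not be trusted. An edge-corrected variant is deliberately not offered, to
  keep the statistic exactly comparable with the field's standard tooling.

`mean_nn_distance()` is the plain $O(n^2)$ reference scan, vectorised in
blocks so a 10,000-point input needs a few seconds and bounded memory; no
spatial-index fast path is included because every problem size the package
targets stays well inside that budget.

## Gi\* hotspot mapping

`hotspot_analysis()` reproduces an "optimized hotspot"-style pipeline with
every choice explicit:

1. **Aggregation** (`aggregate_to_grid()`): a square fishnet anchored at
   the study bounding box's minimum corner; half-open cells so boundary
   points land in the larger-index cell; cells whose centers fall outside
   the study polygon are dropped; zero-count cells inside are kept — they
   are what cold spots are made of.
2. **Statistic** (`gi_star()`): Getis–Ord Gi\* with binary fixed-distance
   weights on cell centers, focal cell included ($w_{ii}=1$). The
   normal-approximation p-value is two-sided. Degenerate inputs (all counts
   equal, or a band so wide some cell neighbours everything) are errors,
   not NaNs.
3. **Multiplicity** (`bh_fdr()`): Benjamini–Hochberg step-up adjustment.
   The proprietary FDR variant of the commercial tool is not publicly
   specified at formula level; BH provides the same control guarantee and
   is the field standard (delegated to `stats::p.adjust`).
4. **Binning** (`assign_bins()`): $\pm 3/\pm 2/\pm 1$ for adjusted $p <
   0.01/0.05/0.10$, sign from the z-score, 0 otherwise — the conventional
   90/95/99% confidence rendering.

**Scale defaults.** The band (neighbourhood radius) defaults to
`default_band()`: the largest nearest-neighbour distance among cell
centers, the smallest radius at which no cell is isolated. When only a band
is given, `cell_size = band/2`. When neither is given, the cell size is
1/30 of the longer bounding-box side. All three are logged on every run.
When a cluster scale is known (e.g. a Thomas process with offspring scatter
$\sigma$), a band of about $2\sigma$ matches the neighbourhood to the
signal and is what the package's own recovery tests use: wider bands make
adjacent cells' neighbourhoods cover the whole cluster, and the maximum
z-score is then decided by tail noise rather than by which cell holds the
cluster center.

## Nearest-facility assignment and bypassing

`assign_nearest()` computes, per enrollee, the Euclidean-nearest facility
(by default among accredited facilities only, the set an enrollee may use),
the distance to it, and the distance to the facility actually used.
**Bypassing** is operationalised as: the used facility is not in the
*co-nearest set* — all facilities within $10^{-6}$ m of the minimum
distance. The tolerance makes exact ties safe: using any co-nearest
facility is not bypassing. Ties are reported as the lexicographically
smallest id for determinism.

`bypass_table()` groups by the facility *used* (the study design interviews
patrons at each facility), with percentages recomputed from counts at 1
decimal place, half-up; the total row recomputes from summed counts.
`distance_summary()` reports each facility's patrons' minimum and maximum
travel distance in km at 3 decimals, plus an unweighted column mean over
facilities — this min/max reading is the one whose column means reproduce
the published summary row exactly; per-row averages of other distances do
not, and are not offered.

## The synthetic study generator

`synthetic_config()` defines the simulated conditions; the defaults emulate
the motivating field study and are not tuning knobs:

| parameter | default | meaning |
|---|---|---|
| `area` | $3.19813\times 10^9$ m² | study region (implicit ~56.6 km square) |
| `n_facilities` | 531 | facility points |
| `pattern` | `csr` | facility process (`csr`, `thomas`, `grid`) |
| `thomas_parents`, `thomas_sd` | 10, 2000 m | cluster process geometry |
| `n_enrollees` | 431 | interviewed enrollees |
| `decay_lambda` | 3000 m | distance-decay scale of facility choice |
| `jitter_min`, `jitter_max` | 300, 500 m | landmark-proxy geocoding error |

Facility attributes mirror the study's mix: ~42% primary / ~58% secondary /
a residual tertiary share, with accreditation only possible for
secondary/tertiary facilities (56% of them, the observed accreditation
share). Residences are uniform in the region — a declared modelling choice,
not an inference about any real city. Facility choice applies exponential
distance decay at the **true** residence, restricted to accredited
facilities; the **recorded** residence is then displaced by a uniform angle
and a radius uniform on [`jitter_min`, `jitter_max`], emulating
landmark-proxy geocoding. This reproduces the measurement structure that
matters downstream: apparent bypassing is a mixture of genuine non-nearest
choice (governed by `decay_lambda`) and positional error (governed by the
jitter), and the package's tests check both directions — zero jitter with
near-rational choice drives the bypass rate to zero, while 300–500 m jitter
keeps it positive. A `decay_lambda` of 3000 m produces the high (≫50%)
bypass rates the analysis is designed to summarise, with travelled
distances of roughly 1–6 km over this region.

Determinism: one seed drives everything; facility coordinates are drawn
before facility attributes, and enrollees from an offset stream, so adding
enrollees never perturbs the facility pattern. Region truncation uses
rejection sampling (never reflection), keeping conditional uniformity
exact.

What the generator does **not** emulate: population density gradients, road
networks, facility capacity, or any behavioural response beyond distance
decay. Tests passing on this generator demonstrate the *pipeline's*
correctness and the statistics' behaviour under controlled regimes — not
that any real city's bypass rate has a particular value.

## Coverage statistics and sample size

`coverage_stats()` recomputes every percentage from raw administrative
sums (never from cached percentages): the urban share of population, the
within-stratum enrolment coverage, the stratum shares of enrollees, and the
per-LGA accreditation share, whose denominator is **all** facilities in the
LGA — the convention the source tables use. Percentages are half-up at 1
decimal. `kish_sample_size()` is $\lceil z^2 p (1-p) / d^2 \rceil$; the
ceiling is the conservative convention. Published sample sizes often
include an unstated non-response inflation on top of this formula; the
function reports the formula value only.

## Numerical choices and degenerate inputs

* Distances: exact Euclidean on doubles; coincident points are legal
  everywhere (NN distance 0).
* Rounding for report tables: half away from zero (`round_half_up()`),
  because base R's banker's rounding does not reproduce published tables.
* Point-in-polygon: even-odd rule via `mgcv::in.out`; holes supported.
* Polygon area: shoelace, orientation-independent, holes subtracted;
  degenerate rings (< 3 distinct vertices) are errors.
* Grid aggregation conserves points: every point inside the extent is
  counted exactly once (half-open cells; the outer max edge closed).
* `gi_star` refuses zero-variance inputs and all-neighbour bands instead of
  returning infinities.

## Problem sizes used by the test-suite

The checks run at the study's own scale where that is what is being
verified (531 facilities for the expectation constant; a 10,000-point
lattice for the dispersion limit; 1,000 CSR replicates for calibration;
500-point cluster processes over 20 seeds for hotspot recovery) and at
reduced sizes (100–300 points, 5–20 seeds) for brute-force oracle
comparisons, where the property holds identically at any size. The full
suite completes in well under a minute on one core.

## Known limitations

* The uncorrected Clark–Evans test's type-I error is not nominal in
  bounded regions (see above); this is a property of the statistic the
  package intentionally reproduces, and `csr_calibration()` exists to make
  it visible rather than hide it.
* Euclidean distance understates true travel cost asymmetrically (more in
  river-cut or congested areas); bypass rates on real data inherit the
  300–500 m geocoding error of landmark proxies.
* Normal-approximation Gi\* p-values are optimistic for very sparse grids;
  no permutation option is provided.
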