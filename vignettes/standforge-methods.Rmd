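---
title: "Methods: biomass accounting, scaling fits and spatial inference in standforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biomass accounting, scaling fits and spatial inference in standforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`standforge` analyzes fully mapped rectangular forest plots: every live
stem ≥ 1 cm dbh tagged and located, snags ≥ 10 cm dbh and ≥ 1.8 m tall
with heights and top diameters, shrub patches ≥ 2 m² mapped as polygons,
and downed fuels sampled by 20 m planar-intercept transects. This
vignette records the models the package implements, the assumptions and
defaults behind them, and the design decisions that were genuinely open.

## Coordinate and bookkeeping conventions

Coordinates are meters from the southwest corner, x east, y north. The
plot must tile into square quadrats (default 20 m); quadrat assignment
uses half-open intervals [k·20, (k+1)·20) with a stem exactly on the far
plot boundary mapped into the last quadrat, so the assignment is total
and unambiguous. Basal area is π(dbh/200)² m² per stem. "Large-diameter"
means dbh ≥ 100 cm throughout — the threshold conventionally used for
old-growth forests of the Pacific Slope — and the boundary value is
large. Report percentages are rounded half-even at one decimal, biomass
at three decimals (1 kg/ha), densities at one decimal, so report files
are comparable across runs and platforms.

## Live-tree biomass

Each species resolves to either a whole-tree allometric equation or a
set of component equations (bole, bark, branch, foliage) of the forms
log10-linear, ln-linear or power, each with a diameter validity range
and a log-scale root-mean-square error. Three structural rules reflect
how registries for mixed-conifer forests are actually assembled:

* **Proxy substitution.** At and above a diameter threshold, selected
  components are routed to a proxy species (e.g. the largest white fir
  boles evaluated with a noble fir equation; sugar pine branch and
  foliage with Douglas-fir equations).
* **Capping.** Where no equations exist for the very largest crowns,
  branch and foliage mass above a cap diameter is held at the value for
  the cap (110 cm for *Abies*, 162 cm for *Pseudotsuga* in the shipped
  rules) — crown mass plateaus; bole mass keeps growing.
* **Range enforcement.** A diameter outside every applicable equation's
  range is an error, not an extrapolation.

Log-scale equations are back-transformed without a smearing correction;
the lognormal spread enters only through the error term. For an estimate
m̂ from an equation with log-base-b RMSE s, the per-tree arithmetic SD is

> SD = m̂ · sqrt(exp((s·ln b)²) − 1),

the lognormal moment identity. Per-species SDs are the *arithmetic sums*
of per-tree SDs, and the plot SD the sum of species SDs: trees of one
species share the same equations, so their errors are treated as fully
correlated. This is deliberately conservative relative to a
root-sum-of-squares and matches the convention in which a published
plot-total SD equals the sum of its species SDs.

The shipped registry (`inst/extdata/registry/`) carries demonstration
coefficients with realistic magnitudes; it is not an authoritative
equation compilation, and real analyses should replace it (the schema is
documented in `?read_equations`).

## Dead and surface pools

**Snags.** Bole volume is a frustum of a cone, V = πh/3·(R² + Rr + r²),
with R = dbh/200 and r = top/200 in meters; mass is volume times a
decay-class (1–5) wood density for the species group, with densities
constrained non-increasing in decay class.

**Coarse woody debris.** For intercept diameters dᵢ (m, ≥ 10 cm
recorded) on a transect of length L, volume per area is π²Σdᵢ²/(8L);
each piece converts to mass with its decay-class density. The plot value
is the mean over transects and the reported SD the across-transect SD.

**Fine fuels.** Timelag classes (1-h < 0.6 cm, 10-h 0.6–2.5 cm, 100-h
2.5–7.6 cm) are tallied on 2 m / 2 m / 4 m sub-lengths; mass per area is
(π²/8)·n·QMD²·SG·c_angle·c_slope/L — the same planar-intercept physics
with the squared quadratic-mean diameter standing in for per-piece
measurement. The shipped coefficients (QMD² = 0.097/1.86/17.81 cm²,
SG = 0.48/0.48/0.40, angle = 1.13/1.13/1.00, slope = 1) are standard
western mixed-conifer values.

**Litter and duff.** Mass (Mg/ha) = depth (m) × bulk density (kg/m³) ×
10. The default bulk densities, litter 125.2 and duff 200.1 kg/m³, are
calibrated for Sierra Nevada mixed-conifer forest floors (they invert a
published mass/mean-depth pair for such stands).

Pool additivity (≥100 ⊆ ≥10 ⊆ ≥1; species rows summing to pool totals;
grand total = live + snags + debris + shrubs + fine fuels including
litter and duff) is enforced by construction and by test.

## Shrub extrapolation

Per species, summed patch cover (m²) is multiplied by the
demography-subplot densities (stems/m² of stems reaching 1 cm dbh, and
kg/m²) and scaled by plot area. Species without their own subplots route
through a proxy table that can scale density and biomass independently —
including the degenerate case of a species whose stems never reach
breast height (density scale 0, biomass scale 0.5 in the shipped table).

## Diameter-distribution fits

Stems are binned into 5 cm dbh classes, the first class [1, 5) cm, bin
centers expressed as radius (midpoint/2). Interior empty classes are
kept at zero; classes beyond the largest occupied one are dropped so an
unbounded zero tail cannot deflate r². Three models are fit:

* Δn = c·r⁻² and M_bin = c·r^(2/3) — the scaling-theory forms, exponent
  fixed, with the closed-form least-squares constant
  c = Σ(yᵢ·rᵢᵖ)/Σrᵢ²ᵖ;
* Δn = a·e^(−b·dbh) — nonlinear least squares (Levenberg–Marquardt with
  a log-linear start).

For the negative exponential, counts are first normalized to densities
per cm of bin width: the first census class is 4 cm wide, and fitting
raw counts at midpoints would bias the recovered rate by several
percent; normalization is exact for the equal-width classes and reduces
the first-class distortion to ~0.3%.

r² = 1 − SSres/SStot is computed on untransformed values and floored at
zero for reporting. The arithmetic scale is the default because the
variance of binned biomass is dominated by the large-diameter classes
there — which is exactly the regime in which the scaling biomass form
fails in old-growth data and the reported r² collapses to the floor. A
`log_scale` flag exposes the log-space alternative, since conventions
differ across the literature.

## Spatial inference

**Estimators.** K̂(r) = |A|/(n(n−1))·ΣΣ_{i≠j} w_ij⁻¹·1(d_ij ≤ r), with
Ripley's isotropic correction: w_ij is the fraction of the circumference
of the circle of radius d_ij centered on i that lies inside the
rectangle, in closed form (the arc lost beyond each near edge subtends
2·acos(e/d); overlapping corner arcs are removed by inclusion–exclusion;
valid whenever r < min(W,H)/2, guaranteed by the default r_max of a
quarter of the minimum dimension, and verified against an independent
union-of-arcs oracle). The reported statistic is the centered
L̂(r) − r = sqrt(K̂/π) − r, so positive means clustering and negative
inhibition; a flag returns raw L. The bivariate K̂₁₂ uses the
symmetrized weight (w_i⁻¹ + w_j⁻¹)/2, which mirrors the univariate
estimator (both pair orientations counted) and makes the estimator
exactly symmetric in the two types.

**Null models.** CSR is a binomial process conditioned on the observed
count. Population independence holds each sub-pattern internally rigid
and applies an independent uniform toroidal shift to each before
recomputing L̂₁₂; only the relative placement is randomized. Whether one
or both populations should be shifted is ambiguous in the field's usage;
independent shifts of both are the default and a `shift_mode =
"relative"` flag shifts only the second, the two being distributionally
equivalent for the relative displacement. All simulated curves are
retained, so exploratory comparison beyond pointwise 2.5%/97.5% bounds
is possible.

**Goodness of fit.** The Loosmore–Ford statistic integrates squared
deviations of each curve from the mean of the *other* curves over
[r_min, r_max] (defaults 0–9 m, the estimated neighborhood radius for
Sierra Nevada mixed conifer), on the default grid of 0.25 m steps with
Δr the grid step; the p-value is the rank of the observed deviation with
ties counted as extreme (conservative). L̂ is the default summary
function; K̂ can be supplied by building the envelope from it. With m
simultaneous tests the Bonferroni threshold α/m is reported to three
decimals (0.05/12 = 0.004).

**Correlogram.** Transect fuel loads are compared by distance class:
pairs binned by inter-midpoint distance, per-class Pearson correlation
of the paired values (both orderings, so the statistic is symmetric),
permutation p-values (999 permutations of values across transects), and
explicit not-estimable flags for classes with fewer than two pairs or
zero variance. Pearson-by-class was chosen over Moran's I to keep the
per-class statistic readable against the permutation null; the choice is
documented rather than forced.

## The synthetic stand generator

The generator produces `stand_dataset`s with the statistical structure
the analyses assume, so every downstream stage has a testable input:

* **Small trees:** a Thomas cluster process (parents Poisson κ on a
  4σ-expanded window, Poisson(μ) offspring with Gaussian(σ) dispersal) —
  clustering concentrated below ~20 m.
* **Large trees:** a sequential hard-core thinning of a Poisson proposal
  (minimum spacing h) — near-random at broad scales, inhibited at 0–3 m.
* **Segregation:** small trees within ρ of a large tree removed with
  probability p, inducing bivariate repulsion below ρ.
* **Diameters:** small trees 1 + Exp(rate), the census truncation at
  1 cm; a rotated-sigmoid alternative as a mixture of the truncated
  exponential with a Gaussian mid-diameter hump (no canonical parametric
  family exists for rotated-sigmoid distributions; the mixture is a
  documented stand-in). Large trees 100 + Exp(mean 30), truncated at
  250 cm, with species drawn from the taxa that actually reach those
  sizes.
* **Snags:** a Binomial(n_live≥10, f) draw of source stems, jittered
  positions, drawn heights, top-diameter fractions and decay classes.
* **Shrubs:** non-overlapping discs (24-gon polygons) added until the
  summed patch area reaches the cover target; patch areas are exact
  polygon areas, so the cover fraction lands within one disc of target.
* **Debris and transects:** straight constant-diameter segments
  (Poisson midpoints, uniform orientation and length, truncated
  lognormal diameters ≥ 10 cm); transect intercepts are exact
  segment–segment intersections, and the intercept diameter equals the
  piece diameter because the measurement is perpendicular to the piece.

Default parameters are calibrated to an old-growth Sierra Nevada
mixed-conifer census: ≈ 1,350 stems/ha after segregation thinning
(κ = 0.006/m², μ = 28.6, σ = 4 m, ρ = 10 m, p = 0.5), ≈ 19
large-diameter trees/ha (λ = 0.00191/m², h = 2 m), a snag:live ratio of
0.199 among stems ≥ 10 cm, 15% shrub cover, fine-fuel tally means
(34.8/8.3/2.1 per transect) that reproduce realistic 1-h/10-h/100-h
loads under the shipped coefficients, and litter/duff depth moments of
1.05 ± 0.38 and 1.20 ± 0.68 cm. The debris intensity (0.0184
segments/m², mean length 10 m) is calibrated to intercept *frequency*
(≈ 2.4 coarse intercepts per 20 m transect, with ≈ 4% of pieces
≥ 100 cm), not to debris mass, which is more sensitive to the diameter
tail than any desk-scale check requires.

Each census layer draws from its own stream (seed + layer index), so a
layer can be regenerated bit-identically without generating the others —
the debris tests rebuild the segment field this way to verify intercept
geometry. Identical seeds give byte-identical datasets.

**What the generator does not emulate:** topography and density
gradients (the pattern is homogeneous), inter-species spatial structure
(species labels are independent of location), temporal dynamics, decay
progression, and any correlation between tree size and local
competition. Passing tests therefore demonstrate that the estimators and
tests behave correctly on data *with the assumed structure*; they do not
validate the ecological models against real censuses.

## Numerical choices and degenerate inputs

* Envelope bounds use type-7 quantiles of the retained curves; GoF ties
  count as extreme.
* L̂(0) = 0 by construction; near-zero radii (r ≲ 2 m at typical test
  densities) have deterministically low-biased L̂ because the square
  root of a near-zero discrete pair count sits below its mean — the
  near-unbiasedness property is meaningful (and tested) from 2 m out.
* Hard-core thinning warns and returns the achievable pattern when the
  proposal intensity cannot be packed at spacing h.
* Empty patterns, zero covers, zero depths, zero tallies and empty bins
  all return exact zeros or explicit errors (`?fit_scaling`,
  `?k_hat_isotropic`), never NaN.
* All-tie GoF (observed identical to every simulation) returns p = 1.

## Test problem sizes

The statistical acceptance checks run at sizes chosen to give stable
operating characteristics on one CPU: GoF size under CSR with n = 50
points in a 100 × 100 m window, 99 simulations and 400 replicates
(binomial SE ≈ 0.011 at α = 0.05); power against a Thomas process
(κ = 0.002/m², μ = 8, σ = 4 m, ≈ 160 points) with 200 replicates;
population-independence coverage with two independent 40-point patterns
and 500 replicates; rate recovery at n = 50,000; design-unbiasedness of
the intercept estimator with 500 random transects over a periodic
debris field (toroidal tiling removes edge effects, making the
estimator exactly design-unbiased under random transect placement).

## Known limitations

* The isotropic correction is the only edge correction implemented; for
  heavily elongated windows translation corrections can be preferable.
* The SD convention (fully correlated within and across species) is an
  upper bound; a variance-based alternative would need equation-level
  covariance information that registries do not carry.
* The registry ships demonstration coefficients; results from it are
  structurally, not numerically, meaningful.
* Spatial analyses cost O(n²) per curve; patterns beyond ~5,000 points
  make 999-simulation envelopes expensive (the field's concession of
  250 simulations for the densest patterns is available via `n_sim`).
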