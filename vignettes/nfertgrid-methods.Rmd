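---
title: "Reconstructing crop-specific N fertilization grids: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing crop-specific N fertilization grids: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nfertgrid)
```

# The reconstruction problem

Gridded, crop-specific nitrogen inputs are required by most process-based
models of agricultural nutrient cycling, yet the primary statistics are
national: harvested areas and fertilizer amounts per country and year,
crop-group fertilizer consumption for a handful of survey years, and a
fertilizer-type consumption panel with large gaps. `nfertgrid` reconstructs
annual, crop-specific N application rates, 13-way fertilizer-type shares and
surface/deep placement fractions on a regular WGS84 grid by allocating those
statistics across an administrative scaffold (grid cell ⊂ county ⊂ country ⊂
reporting region), conserving every consumed total exactly.

The master identity, for crop *cro*, fertilizer type *f*, placement *p*,
year *y* and grid cell *g*:

$$Namount_{cro,f,p,y,g} = Harea_{cro,y,g} \cdot Nrate_{cro,y,g} \cdot
FerRatio_{f,y,g} \cdot Placement_{cro,f,p,y,g}$$

The stages run in a fixed order because each consumes the previous symbol:
harvested area → class amounts → crop rates → calibration → type shares →
placement. All county-level corrections are single multiplicative factors,
which is why the conservation audits can demand 1e-9 relative error.

# Stage by stage

## Harvested area

A year-2000 county reference map `ref[cro, i]` is extended by national
ratios,

$$Harea_{cro,y,i} = ref_{cro,i} \cdot
\frac{HareaNat_{cro,y,j}}{HareaNat_{cro,2000,j}},$$

so every county inherits its country's annual change. Political
disintegration leaves gaps in the national series (the parent reports before
the split, successors after); parent-era values are attributed to successors
in proportion to their harvested area in the first post-split year, per crop.
County totals are then spread over grid cells proportionally to cropland —
the rice cropland layer for rice, the upland layer for all other crops — and
finally rescaled so national sums match the statistics exactly. The cropland
cube is decadal-constant before 2000, annual to 2017, and frozen at its 2017
slice afterwards, mirroring the temporal structure of the underlying land-use
product.

Degenerate inputs are handled without inventing spatial structure: a zero
reference-year national value spreads the series uniformly over the
country's counties; a county with crop area but no matching cropland spreads
uniformly over its cells; a zero gridded sum with a positive national target
spreads uniformly over the country's cropland cells. Every fallback is
logged.

## Class amounts and crop rates

The county-level prior of class amounts (synthetic N, manure, crop residues)
covers 1961–2014; 2015–2020 are extended by national class ratios anchored at
2014. Synthetic-N county amounts are then rescaled by one factor per
country-year so they re-sum to the national SN series (after multiplying the
national series by the per-country cropland-use fraction, which removes
pasture applications; the fraction defaults to 1 and is a world input because
its source data are external). Manure and residues pass through.

Rates follow from the **constant-ratio assumption**: within a county, all
crops change their rate by the same factor over time, anchored at a
year-2000 crop×class rate map:

$$Nrate_{cro,f,y,i} = refRate_{cro,f,i} \cdot
\frac{Namount_{f,y,i}}{\sum_{cro} refRate_{cro,f,i} \, Harea_{cro,y,i}}.$$

This conserves the county class amount identically. From 2003 onwards,
SN rates are calibrated per country and FUBC crop group against the survey
consumption of the nearest anchor year (2003–2006 → 2006, 2007–2008 → 2007,
2009–2012 → 2010, 2013–2016 → 2014, ≥2017 → 2018). The calibration factor is
computed once from pre-calibration rates — a single multiplicative
correction reproduces the survey totals exactly, so no fixed-point iteration
is needed. Years before 2003 are left uncalibrated: the early survey reports
(1978–2001) are kept as a validation reference instead. Rates are rasterized
by broadcasting: every cell of a county carries the county rate.

## Fertilizer-type shares

The type-consumption panel (11 synthetic types × reporting unit × year) is
missing for all units in 1962–1972 plus scattered cells. Missing cells are
imputed with a bootstrap-EM multivariate-normal model in the spirit of
time-series cross-section multiple imputation: variables are the
log(x+1)-transformed consumptions, the observed total SN consumption, log
covariates (GDP, population, cropland area aggregated to the reporting
unit), and linear plus quadratic time terms. Each of *m* = 5 imputations
bootstraps the unit's rows, fits the normal model by EM (conditional-moment
E-step with pattern grouping, ridge-stabilized inversions), draws the
missing entries from their conditional distribution, and the *m* draws are
averaged, back-transformed and clamped at zero. Observed cells are never
modified. A unit with fewer than three observed years for any series falls
back to within-unit linear interpolation/extrapolation. Averaging rather
than keeping separate completed datasets is a deliberate choice: the
downstream use is a share denominator, not a variance estimate.

Shares follow the two-branch rule: CR and MA get their amount fraction of
the total; each synthetic type gets its share of the unit's consumption mix
times the SN fraction of the total. The mix is always normalized by the sum
of the 11 components (not the separately reported total), which guarantees
that the 13 shares sum to exactly 1 wherever the total amount is positive —
dividing by an inconsistent reported total would break that invariant. The
class amounts used here are the ones implied by the calibrated rates
(Σ rate × area per county and class), so the identity
rate × share × placement ⇒ amount holds exactly in calibrated years too. A
unit-year with zero consumption across all components but positive SN mass
routes that mass to urea, the globally dominant carrier; the event is
logged.

## Placement and the no-till surface

Deep-placement fractions depend only on the fertilizer category and the crop
no-till fraction:

* injected fertilizers — anhydrous ammonia and N solutions — are always deep
  (the equation-level grouping {AA, AN} can be restored with
  `literalInjected = TRUE`; the mechanism named in the accompanying
  description is injection, which applies to AA and NS, so that is the
  default);
* other synthetic types: deep = 0.7 × NoTill, 0.7 being the base-topdressing
  application ratio — only the base fraction of a split application is
  incorporated, and only under no-till seeding;
* manure and residues: deep = 1 − NoTill (incorporation happens by tillage).

Surface is the complement, so surface + deep = 1 exactly, everywhere.

The no-till surface itself: national no-till areas come from census
(province×year series for designated census countries, summed nationally)
or, elsewhere, from a monotone regression of the no-till fraction on
log(cropland per rural capita) — a quasibinomial GLM fitted to the census
observations, with a non-negative slope constraint (refit intercept-only if
violated) so the monotone contract holds by construction. The functional
form is a design choice; the coefficients are refit per world and pluggable
by config. National areas are downscaled by (i) eligibility — the rain-fed
harvested area of the 11 no-till-suitable crops, zeroed in low-income cells
without dominant large fields, (ii) a four-predictor logit over water
erosion, aridity (precipitation/PET), crop mix and field size, and (iii)
greedy ranked allocation: cells sorted by decreasing probability (ties by
cell index, for determinism), each contributing potential × probability,
the last cell taken partially so the target is hit exactly; targets above
the achievable total are capped and logged. Cell no-till area is split
across crops by harvested-area share.

The logit slopes and midpoints are **mandatory configuration**: published
fitted values exist but are not reproduced here, so the package ships
documented placeholders (`defaultLogitParams()`: unit slopes, per-driver
medians as midpoints) and refuses to run without an explicit choice
(`useDefaultLogit = TRUE` opts into the placeholders).

## Monte Carlo uncertainty

The dominant assumption is the constant-ratio rule, so the uncertainty model
perturbs exactly that: per crop group and region, the CV of survey
consumption across the five anchor years (sample SD over mean) scales mean-1
normal noise (truncated at 0) applied multiplicatively to every year-to-year
change ratio of the regional rate trajectory. Trajectories are rebuilt from
the year-2000 anchor — the reference epoch of the whole reconstruction —
outward in both directions. Pre-anchor years are rebuilt with perturbed
*backward* ratios rather than by dividing by perturbed forward ratios:
dividing by a mean-1 draw would bias the expectation upward (E[1/X] > 1/E[X]),
whereas the backward-ratio form keeps the Monte Carlo mean at the point
estimate on both sides. 1,000 iterations give the 2.5/97.5 percentile
envelope; CV = 0 degenerates to the point estimate, and a missing CV (zero
mean consumption) leaves the envelope at the point estimate with a flag.

## Validation operators

`relativeDifference()` implements the percent difference
(rate − reference)/rate × 100 with the reconstructed rate always in the
denominator; zero rates are undefined, excluded from summaries and counted.
`conservationReport()` audits the five exact contracts (national harvested
area, national SN, anchor-year group amounts, share sums, placement sums) at
1e-9 relative — appropriate because every correction in the pipeline is a
single multiplicative factor — and returns per-country-year error tables so
a corrupted input can be localized, not just detected.

# The synthetic world

Real inputs are external data products, so testing is done against a
generated world whose ground truth is known. The generator works backwards
from the truth so that every statistical panel is exactly consistent when
noise is off:

* county harvested areas are fixed within-country shares times national
  growth curves — precisely the structure the national-ratio extension
  assumes, so extension is exact; the two successors of the generated
  disintegration event share growth curves, making the first-post-split-year
  ratio reconstruction exact as well;
* class amounts are county year-2000 amounts (implied by the year-2000 rate
  map and areas) times country-level growth curves — the constant-ratio
  assumption holds by construction, and the extension/correction chain
  recovers the truth;
* the prior SN panel is biased low by a country-uniform factor (default
  0.88, i.e. 12% below the national series) that the SN correction removes
  exactly;
* survey tables (anchor and historic years) and the type panel are
  re-aggregations of the truth; the type panel then receives the canonical
  missingness (1962–1972 block for all units plus 6% at random);
* no-till adoption follows a logistic in log(cropland per rural capita) with
  asymptote 0.12 — a realistic ceiling for national conservation-tillage
  adoption — and the two census countries report county-level series over
  census windows mirroring the real reporting periods (2000–2016 and
  1989–2008).

Optional multiplicative log-normal noise (default sd 0.05, a plausible
statistical-reporting error) makes the panels mutually inconsistent the way
real sources are; the pipeline then still conserves whatever it is forced
to (the audits hold on noisy worlds), but point recovery is no longer exact.

What the synthetic world does **not** emulate: real geography and coastlines
(countries are contiguous column blocks, counties row blocks, every cell is
land), crop-specific type mixes (shares are region-level, as in the real
panel), sub-national reporting inconsistencies, and satellite-vs-census
cropland disagreement. Passing tests therefore demonstrate the correctness
of the allocation algebra and its conservation properties, and recovery
under the model's own assumptions — not the realism of any particular global
product.

Default sizes: a 24×48-cell grid (7.5°), 4 countries × 3 counties, 60 years.
The production 5-arc-min grid (2160×4320) runs through the same code path;
the desk-scale default keeps a full end-to-end run at a few seconds. Unit
tests use a 12×12 grid with 2 countries. Monte Carlo tests use 200–1,000
iterations; the package default is 1,000.

# Numerical choices and edge cases

* Cell indexing is row-major from the north-west corner; areas are per-cell
  totals (ha), with spherical cell areas (R = 6371 km).
* Zero denominators never poison results: they trigger documented fallbacks
  (uniform spreads, zero rates with the unallocatable amount flagged, urea
  as the default SN carrier) and are always logged.
* The EM imputer regularizes conditional inversions with a small ridge
  scaled to the mean variance and floors variances at 1e-8; conditional
  draws use an eigendecomposition square root, robust to semi-definite
  conditional covariances.
* Greedy allocation ties are broken by cell index; every stochastic step
  (world generation, bootstrap, conditional draws, Monte Carlo) is seeded,
  so identical seeds give bit-identical worlds, runs and envelopes.
* HDF5 records are year-major `year × row × col` arrays, gzip level 4; file
  names use a plain hyphen in the year span by default (an `enDash` flag
  restores the deposited punctuation exactly).

# Known limitations

* The constant-ratio assumption is strong; the Monte Carlo envelope
  quantifies only that assumption, not imputation or no-till uncertainty.
* Calibration before 2003 is not attempted; early survey records serve as a
  validation reference only.
* The type mix is not crop-specific — no long-term statistic reports it —
  so every crop in a county shares the county's 13-way split.
* The national no-till regression form (logistic in log cropland per rural
  capita, asymptote 1 in the GLM) is a modeling choice; where census data
  exist they always win.
* Placement rests on the 0.7 base-topdressing constant applied uniformly
  across crops, and on the income/field-size mechanization proxy; both are
  acknowledged simplifications.
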