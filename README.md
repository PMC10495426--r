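# nfertgrid

Crop-specific nitrogen (N) fertilization grids — application rate, fertilizer
type, and placement — reconstructed from national statistics.

Process-based land-surface and emission models (DNDC-type biogeochemistry,
NH₃/N₂O flux upscaling, crop models) need gridded, crop-specific N inputs
split by fertilizer type and by surface vs deep placement, over decades.
National statistics report none of that directly: harvested areas and
fertilizer consumption are country totals, crop-specific consumption exists
only for scattered survey years, fertilizer-type consumption panels are full
of holes, and placement is never reported at all. `nfertgrid` implements the
reconstruction that bridges this gap: it allocates national statistics onto a
county/grid scaffold, producing annual cubes of

- **N application rate** per crop (kg N per hectare of harvested area), split
  into synthetic N (SN), manure (MA) and crop residues (CR),
- **fertilizer-type shares** over 13 types (AA, AN, AS, CAN, NS, ONS, Urea,
  AP, NK, NPK, ONP, CR, MA),
- **surface/deep placement fractions** per crop and type,

for 21 crop groups on a regular WGS84 grid, 1961–2020, written in a per-crop
HDF5 layout (26 records `{type}_{placement}` per crop file plus one
harvested-area file).

## The allocation model

Everything factorizes through one identity for the N amount applied to crop
*cro* with fertilizer *f* and placement *p* in grid cell *g* and year *y*:

    Namount[cro,f,p,y,g] = Harea[cro,y,g] × Nrate[cro,y,g]
                           × FerRatio[f,y,g] × Placement[cro,f,p,y,g]

Each factor is reconstructed in a fixed stage order, each stage conserving
the statistics it consumed:

1. **Harvested area.** A year-2000 county reference map is extended through
   time by national ratios (counties inherit their country's annual change;
   countries that disintegrated are reconstructed from each successor's share
   in the first post-split year), disaggregated to the grid in proportion to
   cropland (a rice layer for rice, upland for everything else), and finally
   rescaled to match national totals exactly.
2. **Rates.** A county-level prior of class amounts (SN/MA/CR) is extended
   past its last year by national ratios, its SN corrected to the national
   statistical series, and split across crops under the *constant-ratio
   assumption* — all crops in a county change their rate by the same factor
   over time, anchored at a year-2000 crop-specific rate map. From 2003 on,
   SN rates are calibrated per country and crop group against
   fertilizer-use-by-crop (FUBC) survey totals for the anchor years 2006,
   2007, 2010, 2014 and 2018.
3. **Type shares.** The missing cells of the fertilizer-type consumption
   panel (all of 1962–1972, plus scattered gaps) are filled by bootstrap-EM
   multivariate-normal multiple imputation with GDP, population, cropland and
   polynomial time covariates; shares then follow the two-branch rule: CR and
   MA by their amount fraction, each synthetic type by its consumption mix
   share times the SN fraction.
4. **Placement.** A gridded no-till surface is built from national no-till
   areas (census where available, otherwise a monotone regression on
   cropland per rural capita), eligibility screening (rain-fed area of 11
   suitable crops; field size and income class), a four-predictor logit, and
   ranked greedy allocation. Deep placement is then 1 for injected
   fertilizers (AA, NS), `0.7 × NoTill` for other synthetic types, and
   `1 − NoTill` for manure and residues; surface is the complement.

Monte Carlo envelopes for the rates perturb every year-to-year change ratio
with mean-1 normal draws whose SD is the crop-group × region CV estimated
from the five FUBC anchor years (1,000 iterations, 95% interval).

Because the real global inputs are external data products, the package ships
a **synthetic world generator**: a small self-consistent planet (countries,
counties, grid, every statistical panel and raster) derived from a known
ground truth, so the whole pipeline is testable offline — with noise
disabled, reconstruction recovers the truth to machine precision.

## Worked example

```r
library(nfertgrid)

world <- generateWorld(worldConfig(seed = 1))
world
#> SyntheticWorld: 4 countries / 12 counties on a 24x48 grid, 1961-2020 (seed 1)

run <- runPipeline(world, list(useDefaultLogit = TRUE))
run
#> NfertRun
#>               check    maxRelErr
#>   harea_vs_national 2.219628e-16
#>      sn_vs_national 2.604296e-16
#>  fubc_anchor_groups 2.992982e-16
#>      type_share_sum 2.220446e-16
#>       placement_sum 0.000000e+00
#> 1 logged notice(s)
```

The audit table shows the five conservation contracts: the gridded harvested
area re-sums to the national series, county SN amounts to the national SN,
anchor-year crop-group amounts to the FUBC table, type shares to 1, and
surface + deep to 1 — all at machine precision here.

Regional wheat rate trajectories and their Monte Carlo envelope:

```r
reg <- regionalRates(run$napp$rates, run$harea$county, world@hierarchy)
round(reg["Wheat", , c("1961", "1990", "2020")], 1)
#>    1961 1990 2020
#> R1 15.1 42.8 50.5
#> R2 14.6 41.6 51.2

cv  <- estimateCvFromFubc(world@fubcTables, world@hierarchy@regions)
env <- monteCarloRates(reg, cv, world@vocabulary, nIter = 1000, seed = 7)
round(c(lower = env$lower["Wheat", "R1", "2020"],
        point = env$point["Wheat", "R1", "2020"],
        upper = env$upper["Wheat", "R1", "2020"]), 1)
#> lower point upper
#>  17.0  50.5 112.7
```

Rates grow from ~15 to ~51 kg N ha⁻¹ over the six decades in this synthetic
world; the 95% interval at 2020 is wide because the anchor-year CV for wheat
in region R1 (~10%) compounds over the 20 annual change ratios separating
2020 from the year-2000 anchor.

Writing the published layout:

```r
out <- writeOutputs(run$napp$cube, run$shares, run$placement$placement,
                    run$harea$cube, "outdir", world@vocabulary)
listOutputRecords(out$rateFiles[["Wheat"]])   # 26 records: AA_Surface ... MA_Deep
```

A thin command-line driver over the same functions lives in
`inst/cli/nfert.R` (`generate`, `run`, `uncertainty`, `validate`).

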