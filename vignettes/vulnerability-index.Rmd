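---
title: "Methods: a composite vulnerability index for climate impacts on marine fisheries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a composite vulnerability index for climate impacts on marine fisheries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishvuln)
```

## The model

The package computes a national composite index in the IPCC vulnerability
framing: a country is vulnerable to climate impacts on its marine
fisheries to the extent that it is *exposed* (its waters warm), is
*sensitive* (its economy and diet depend on fisheries), and lacks
*adaptive capacity* (resources to adjust). After min–max normalization of
each ingredient over the country set (subscript N),

$$V = \big[\,E_N + S_N - AC_N\,\big]_N,$$

with

- $E = E1_N$ — one exposure variable: the mean sea-surface-temperature
  anomaly over the country's exclusive economic zone (EEZ), in Δ°C, for a
  given representative concentration pathway (RCP 2.6, 4.5 or 8.5) and
  projection window (2016–2050 or 2066–2100) relative to a 1900–1950
  reference climatology;
- $S = [\tfrac15\sum_{i=1}^{5} Si_N]_N$ — fisher numbers, export share,
  fisher share of the economically active population, mean 2012–2014
  landings, and marine-protein share;
- $AC = [\tfrac12(\overline{AC1_N, AC2_N} +
  \overline{AC3_N,\dots,AC6_N})]_N$ — a fisheries-specific half (subsidy
  intensity, industrial catch share) and a broad socio-economic half
  (healthy life expectancy, governance, education, GDP per capita). The
  weighting deliberately counts each fisheries variable twice as heavily
  as each socio-economic one ($\partial AC/\partial AC1_N = 1/4$ versus
  $\partial AC/\partial AC3_N = 1/8$), tying the capacity component to
  the sector under stress.

All six adaptive-capacity variables are oriented so that larger values
mean more capacity; in particular industrial fishing share and subsidy
intensity are treated as capacity-increasing (industrial fleets are more
mobile and better capitalized; subsidies proxy the state's capacity to
cushion the sector). Countries are ranked by descending $V$ (rank 1 =
most vulnerable) and partitioned into quartiles by contiguous rank
blocks, the remainder going to the earlier quartiles (147 countries →
37/37/37/36). Ties in the score are broken alphabetically by country
key, making ranks deterministic.

The index is run once per scenario — three RCPs × two 35-year windows =
six tables. Only exposure varies across scenarios; the sensitivity and
adaptive-capacity columns are identical by construction.

## Exposure: from gridded fields to one number per country

The exposure chain is: regrid each climate model's monthly SST field to a
common rectilinear grid → cellwise ensemble mean over models → time mean
over the projection window and over the reference period → subtract →
average the anomaly over the grid cells inside each country's EEZ.

Numerical choices, in the order they bite:

- **Units.** Fields whose non-missing median exceeds 200 are taken to be
  Kelvin and shifted by −273.15; gridded SST archives commonly use K.
- **Regridding** is bilinear on cell centers. Where fewer than four of
  the surrounding source cells are valid: three valid → bilinear with
  weights renormalized over the valid corners; one or two valid → the
  valid corner with the largest weight (nearest neighbor); none → missing.
  This keeps interpolated values inside the source range (no overshoot)
  and never invents data more than one source cell away. Longitude wraps
  when the source grid spans the full circle.
- **Ensemble rule.** A cell's ensemble mean is kept when at least half
  the models are valid there, otherwise missing. Coastal masks differ
  slightly between models; requiring a majority avoids cells whose
  "ensemble" is one model.
- **Window means** are unweighted means over all monthly steps whose year
  falls in the inclusive range — no annual pre-averaging. For complete
  years the two are identical; operating on months directly is simpler
  and keeps partially missing cells well-defined (missing steps are
  ignored cell by cell).
- **Zonal statistics.** EEZ polygons are first merged by their
  sovereignty label (exact string match), so a country divided into many
  shapefile features is one region. A grid cell belongs to a region when
  its *center* lies inside the polygon union under the even-odd rule,
  boundary points counting as inside; rings crossing the antimeridian are
  split at ±180° (half-plane clipping on the unwrapped ring) before
  testing. Cell averaging is unweighted, i.e. not cosine-latitude
  weighted — each extracted grid point counts once; an area-weighting
  flag exists but defaults off, and at EEZ scale the difference is well
  under the inter-model spread.
- **Tiny islands.** A small-island EEZ can fall entirely between the
  centers of a coarse grid; dropping such countries would silently
  remove exactly the states the index is most concerned with. A region
  that contains no valid cell center falls back to the single valid cell
  nearest its vertex centroid, flagged `fallback`; if no valid cell lies
  within 5° the country is marked missing-exposure and excluded
  downstream.

## Indicators, gap rules and exclusion

The eleven socio-economic variables come from a flat CSV schema
(`?read_country_table`). Derivations are deliberately dull — ratios,
multi-year means — with explicit gap rules:

- Shares (export, protein, fisher) are clamped to [0, 1] with a warning
  if a raw ratio exceeds 1 (inconsistent source tables do occur); a zero
  or missing denominator makes the variable missing rather than infinite.
- Landings use the mean of whichever of 2012–2014 are reported; subsidy
  intensity averages the available years.
- Governance is the unweighted mean of the six Worldwide Governance
  Indicators dimensions; at least four must be present, otherwise the
  variable is missing. The four-of-six floor is this package's choice:
  two dimensions are too little signal to stand in for "governance".
- Education uses literacy, falling back to school enrolment when literacy
  is unreported. The two are nearly collinear where both exist, which is
  what justifies the interchange; literacy is preferred as the stock
  (rather than flow) measure, and the source used is recorded per
  country.
- The industrial:small-scale ratio is represented as the bounded
  industrial *share* industrial/(industrial + small-scale). The raw ratio
  is unbounded and min–max normalization of an unbounded, heavy-tailed
  quantity is dominated by its single largest value; the share is a
  monotone transform of the ratio, so orderings are preserved.
  `industrial_share(mode = "ratio")` restores the literal ratio.

Landlocked countries are excluded outright (they have no EEZ and no
marine exposure). The default exclusion policy is complete-case: a
country missing any analysis variable after gap-filling is dropped before
normalization, so every min–max sees the same country set; an
available-case policy is available behind a flag. A country excluded in
any scenario is excluded from all six tables, keeping them comparable.

## Min–max normalization

`minmax_normalize()` maps the observed minimum to 0 and maximum to 1 and
is invariant under positive affine transforms of its input; normalizing
twice changes nothing. A constant vector carries no ranking information
and maps to 0.5 everywhere with a warning — 0.5 leaves the constant
component uninformative rather than pinning every country to an extreme.
Fewer than two non-missing values is an error, not a warning: the index
is undefined.

## The synthetic world

The generator (`synth_config()`, seed-deterministic throughout) emulates
the statistical structure the analysis assumes, not any real geography:

- **Climate**: per model, monthly SST = latitudinal base profile
  ($-1.5 + 30\cos^2\phi$ °C) + linear scenario trend + model bias +
  Gaussian weather noise. Default trends are 0.10/0.18/0.30 °C per
  decade for RCP 2.6/4.5/8.5 — ordered as the pathways are — with a 60%
  pole-ward amplification, on a 2° global grid with 5 models, monthly
  noise sd 0.4 °C and model bias sd 0.3 °C. A model's bias is shared
  between its historical and scenario runs, as a real model's
  climatological bias is, so biases cancel in anomalies; with noise set
  to zero the ensemble anomaly equals trend × elapsed time exactly, which
  the tests exploit as a closed form.
- **Geography**: rectangular EEZs tile six 12°-high ocean bands separated
  by 4° land strips, with polar ice poleward of 66°; about 10% of
  countries are written as two abutting polygons under one sovereignty
  label (exercising the merge) and a few countries are slivers placed
  between cell centers (exercising the fallback).
- **Countries**: 150 countries in three archetypes (20% LDC-like, 20%
  OECD-like, 60% middle). LDC-like draws have low GDP, governance, life
  expectancy and education, high fish-protein and fisher shares, low
  subsidies and industrial share; OECD-like the reverse; the middle
  archetype sits between with wider spread. Per-capita CO₂ emissions are
  log-linearly coupled to GDP. Five percent of middle-archetype countries
  receive one missing indicator, so the exclusion machinery runs on every
  default pipeline pass without diluting the archetype statistics.

Archetype effect sizes were fixed once, by simulation across seeds at the
default n = 150, so that the end-to-end recovery pattern — at least 90% of
LDC-like countries in the vulnerable half and at least 90% of OECD-like
countries in the resilient half, and a clearly negative
emissions–vulnerability rank correlation — holds robustly across seeds;
they have been frozen since. The test suite verifies the pattern at the
default seed.

What passing these tests does **not** show: the generator has no spatial
covariance beyond the latitudinal trend structure, no ENSO-like temporal
dependence, no realistic EEZ shapes or country-size distribution, and its
archetypes are cleaner than real development gradients. Synthetic
recovery demonstrates that the pipeline's plumbing and aggregation
arithmetic do what they claim, not that the index has predictive skill on
real data.

## Problem sizes

The default study conditions (2° grid, 5 models, monthly series
1900–1950 and 2016–2100, 150 countries) run the full six-scenario
pipeline in about 90 seconds on one CPU. Unit tests run on coarser grids
(4°–20°) and shorter windows, where every expected value is either a
closed form or a brute-force oracle.

## Known limitations and flagged oddities

- Cell averaging over an EEZ homogenizes latitudinally long zones; a
  country spanning 30° of latitude gets one number.
- Published tables of this index family sometimes show normalized
  extremes slightly off 0/1, indicating a normalization applied before a
  final exclusion pass; this package always normalizes over the final
  included set, so score values from other implementations are comparable
  only up to that convention — ranks and counts are the robust quantities
  to compare.
- The six-dimension governance mean hides offsetting dimensions; the
  four-of-six floor is pragmatic, not principled.
- Complete-case exclusion couples the country set (and hence every
  min–max) to data availability: adding a data-poor country can move
  every score. This is inherent to min–max composite indices.
- p-values for both correlation coefficients use the t approximation;
  with n ≈ 150 and the effect sizes involved, exact methods would not
  change any conclusion.
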