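---
title: "Quantile-based forest condition monitoring: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantile-based forest condition monitoring: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestcondition)
```

## The monitoring problem

Forest decline after droughts, late frosts, flooding, ice storms and
windthrow shows up as anomalously low canopy greenness. A satellite NDVI
record sampled every 16 days over two decades can expose such hot spots in
near real time — but only after the raw series are conditioned (clouds and
snow depress NDVI) and only if each pixel is referenced against *its own*
history, because absolute NDVI differs with species, soil and stand
structure.

This package implements that computation chain for 16-day maximum-value
composite NDVI cubes on a regular grid (nominal pixel 231.25 m, 23
composites per year starting at day-of-year 1, the last composite of each
year absorbing the leap day):

1. **Quality masking.** Only observations with good (0) or marginal (1)
   reliability codes are kept; snow/ice (2), cloud (3) and fill (-1) become
   missing.
2. **Gap filling.** Interior gaps are linearly interpolated between the
   nearest flanking observations; leading/trailing gaps are filled by
   nearest-value extension. A pixel with no retained observation at all is
   excluded with an explicit signal, never guessed.
3. **Negative-outlier screening.** Residual contamination survives quality
   flags as implausibly *low* values. Let `d = filled - smoothed`, with the
   smoothed reference from the same Gaussian filter used below. Steps whose
   standardized `d` falls below -2 are replaced by the reference value. The
   screen runs once and is one-sided: high values are real greenness.
4. **Smoothing.** A truncated Gaussian filter spanning five composite steps
   (80 days), weights renormalized to sum to one.
5. **Detrending.** An ordinary-least-squares line over the time index is
   removed per pixel and the mean added back, so multi-decadal greening or
   browning trends do not masquerade as condition anomalies while the
   pixel's level is preserved exactly.

From the conditioned record, for each pixel and composite step the `n`
yearly values (one per year) are transformed into two complementary
metrics:

* **Q**, the centered rank quantile
  `Q_t = R(NDVI_t)/n - 1/(2n)`,
  with `R` the mid-rank among the `n` observations. `Q` ranges over
  `1/(2n) ... 1 - 1/(2n)`; the record minimum maps to `1/(2n)`, the maximum
  to `1 - 1/(2n)`, and for tie-free data the mean over years is exactly
  0.5. Being rank-based, `Q` is invariant under any strictly monotone
  transform of the values and immune to the skew that range-scaled indices
  (such as the VCI) suffer when an extreme year enters the record.
* **PDM**, the proportional deviation from the median,
  `PDM_t = NDVI_t / median - 1`,
  which carries absolute magnitude and is therefore comparable across
  pixels; it is invariant to rescaling a pixel's record by a positive
  constant. A non-positive median (never expected over forest, where NDVI
  is typically above 0.5) yields a missing PDM with a warning.

Both metrics are deliberately non-parametric: NDVI has a bounded, usually
skewed distribution, so z-scores would depend on a normality assumption the
data do not satisfy.

Maps are resolved into classes on fixed break schemes: for a 20-year record
`Q` uses the 20 attainable tie-free values (1/40 to 1 - 1/40 in steps of
1/20) as breaks, giving 21 classes; `PDM` uses breaks from -10% to +10% in
steps of 2.5% (10 classes). The -10% lower bound corresponds to
proportional deviations at which individual-tree die-back has been observed
after severe drought. Spatial-share histograms over the analysis mask
summarize each date.

## Masks

**Forest mask.** A pixel is analysed only if its land-cover class is
broadleaved (311), coniferous (312) or mixed forest (313) in *every*
mapping epoch (2000, 2006, 2012, 2018 in the standard stack). We read
"consistently forest" as membership in the forest *set* each epoch — a
pixel may switch between forest classes and still qualify; the stricter
reading (no class change at all) would also discard routine
re-classification noise between neighbouring forest types, which is not
what the consistency rule is for. Fine-grained land-cover maps are brought
onto the analysis grid by nearest-neighbour remapping (each target cell
takes the class of the nearest source cell center), which retains the
original class set; distance ties break toward the smaller source row, then
column, so the operation is deterministic.

**Growing-season mask.** Monthly mean-temperature climatologies are
interpolated to 365 daily values per pixel and the growing season is the
set of days above 5 degC, a standard threshold for cambial activity and
growth. Numerical choices the monthly-to-daily step needs:

* anchors at mid-month days-of-year (15, 46, 74, 105, 135, 166, 196, 227,
  258, 288, 319, 349), with wrap-around interpolation December-January and
  the leap day ignored;
* if the climatology crosses the threshold more than twice, *all*
  above-threshold days count as in-season (no longest-segment selection) —
  a rule is needed for multimodal cases and keeping all warm days is the
  least surprising one;
* a composite step is in-season iff its start day-of-year is in-season.

Out-of-season steps are computed but flagged, and all classification and
histogram summaries honour the flag.

## Event statistics

The statistics used to analyse disturbance hot spots are thin, tested
surfaces over standard machinery:

* `extract_groups()` selects metric values by covariate threshold rules
  (species share > 70%, minimum temperature < -1 degC, gust-speed bins, a
  0/1 affected-area mask, ...).
* `wilcoxon_rank_sum()` reports the mid-rank rank-sum statistic with an
  exact p-value (full enumeration) when the combined sample is at most 20
  and tie-free, and the normal approximation with continuity and tie
  correction otherwise.
* `compare_groups()` runs all pairwise two-sided tests and summarises them
  as a compact letter display (insert-and-absorb): groups connected by any
  non-significant pair share a letter, with letters ordered by descending
  group median. Pairwise p-values are unadjusted by default, matching
  common practice for these displays; a Holm option exists.
* `linear_fit()` is the OLS regression of a yearly mean metric on a ground
  observable (e.g. mean budburst day-of-year), reporting slope, intercept,
  explained variance and the slope p-value.
* `frost_probability()` converts an interpolated minimum temperature into a
  frost probability under a Gaussian interpolation-error model with sigma =
  0.5 degC; at the -1 degC threshold this gives `pnorm(2)`, about 97.7%
  (often quoted as "roughly 97.5%" — the model is the exact Gaussian tail,
  not the rounded figure).
* `bin_by_gust()` bins maximum gust speed into `<20`, five 5 m/s steps, and
  `>45` m/s, interior bins left-closed.

## Key parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `filter_window` | 5 | composite steps | 80 days; wide enough to bridge short contamination runs, short enough to keep phenology |
| `kernel_sigma` | 1.0 | composite steps | smooth, symmetric weights over the 5-step window; exposed in `preprocess_config()` since only the window span is canonical |
| `outlier_z` | -2 | standard deviations | one-sided screen for contamination-depressed values |
| `keep_quality` | {0, 1} | codes | good + marginal reliability |
| `season_threshold` | 5 | degC | cambial activity / growth threshold |
| PDM breaks | -10% ... +10% by 2.5% | proportion | die-back observed around -10% |
| `pixel_size` | 231.25 | m | nominal 250 m-class vegetation-index grid |

Standardizing the outlier differences subtracts the sample mean of `d`
(rather than assuming mean 0); with a renormalized symmetric kernel the
mean of `d` is near zero anyway, and using the sample estimate keeps the
screen centered for series with strong seasonal asymmetry. Detrending is
linear OLS on the conditioned series; no nonlinear trend model is fitted
because the quantity of interest is the *relative* position of a year
within the record, for which removing a straight line is the least
structured correction.

Class intervals are left-closed `[b_k, b_{k+1})` with open-ended extremes.
The Q breaks are computed with the same floating-point expression as the
quantile transform so that attainable tie-free values coincide with their
breaks bit for bit; a value exactly at the last break belongs to the
highest class. One consequence worth knowing: a PDM of exactly -0.10 sits
*at* the first break and therefore falls in the `[-10%, -7.5%)` class, not
in the open "below -10%" class; only strictly lower values reach class 0.

## The synthetic scene generator

`generate_scene()` produces the inputs the pipeline reads, with known
ground truth: per-pixel double-sigmoid seasonal curves (the standard
land-surface-phenology form) with winter NDVI drawn from 0.45-0.55, summer
amplitude 0.25-0.35, green-up around DOY 110-130 and senescence around DOY
280-300; additive Gaussian noise (sd 0.02, a typical residual noise level
for quality-screened composites); optional linear trend; cloud (10%) and
winter snow (5%) contamination that *both* degrades the reliability code
and biases the value low by 0.1-0.5 — coupling chosen deliberately so the
quality mask and the outlier screen are exercised against the same
artifact structure they face in real series. Land cover is forest
(311-313) with a 5% non-forest share and a 2% forest-loss share in the
last epoch; the climatology is a July-peaked annual cycle around 8 degC
with a north-south gradient, giving an April-October growing season.
`inject_disturbance()` multiplies NDVI by `1 - magnitude` inside a
footprint/year/step range with optional linear recovery and returns the
truth mask.

What the generator does *not* emulate: spatial autocorrelation of noise
and contamination (pixels are independent), mixed pixels at forest edges,
sensor-geometry effects, or real phenological interannual variability
beyond noise. Tests passing on these scenes therefore demonstrate the
correctness of the computation chain and the statistical behaviour of the
metrics under the stated noise model — not retrieval accuracy on real
imagery.

## Raster storage

No GDAL binding is required: stacks are stored as one single-band ESRI
ASCII grid per composite step (`<var>_<year>_<doy>.asc`, nodata -9999
outside the NDVI range) plus a JSON sidecar with the calendar, CRS label
and file list. ASCII grid is a plain-text geospatial format that any GIS
reads, and `%.17g` encoding makes write/read round trips value-identical —
a property the determinism guarantees of the pipeline rely on. In-memory
missingness is always `NA`; the sentinel exists only on disk.

## Problem sizes and determinism

The test-suite and the acceptance script use 64 x 64 pixel scenes over 20
years (94,208 pixel-steps) for the metric invariants and disturbance
recovery, 8 x 8 and 16 x 16 scenes for chain and pipeline checks, and
2,000 null simulations for the Wilcoxon type-I-error check — sizes chosen
so each property is measured with comfortable statistical resolution while
the whole suite runs in about a minute. The pipeline is deterministic end
to end: the only random-number use in the package is inside
`generate_scene()` (single seeded stream) and re-running `run_pipeline()`
on the same inputs reproduces every numeric output bit for bit.

## Limitations

* The per-step ranking uses the years of the record at that step
  (`n` = number of years, possibly fewer where years are missing); with a
  20-year record `Q` is resolved in steps of 1/20 and cannot distinguish
  finer gradations.
* A 5.3 ha pixel cannot resolve single trees: a 10 x 10 m canopy is about
  2 permille of a pixel, so individual die-back must be confirmed on the
  ground; low Q/PDM marks *candidate* hot spots.
* Recovering NDVI after stand-level die-back often reflects understory
  regrowth, not forest recovery; interpretation needs ancillary data
  (climate, phenology, higher-resolution imagery).
* The package does not reproject between coordinate systems; inputs are
  assumed co-registered, with nearest-neighbour remapping available for
  categorical layers on a shared projection.
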