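---
title: "Methods: change/variability decomposition and resampling inference for palaeoclimate site series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: change/variability decomposition and resampling inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the models and
procedures implemented, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, the numerical choices
made where the design was genuinely open, and the known limitations. It
states no empirical result that the test suite or `scripts/acceptance.R` do
not themselves compute.

## 1. The problem

A dated occupation layer gives a window in time (ka BP) and a point in
space. A palaeoclimate time-cube gives climate variables on a grid at
1,000-year steps. The package asks how *predictable* the climate was at
occupied places: how much of the local climatic variance over an
occupation's span was slow, autocorrelated change versus white-noise-like
millennial variability. It then compares regions (here labelled `EAST` and
`NORTHWEST`, taken from the input inventory, never inferred from
coordinates) and stress-tests those comparisons against dating uncertainty
and the regional background.

## 2. From dates to occupations

Each layer may carry several radiometric dates with 1σ uncertainties. The
range protocol is: maximum age = oldest date + *k*·sd, minimum age =
youngest date − *k*·sd (floored at 0), mid-age = midpoint. The multiplier
*k* defaults to 1 — the minimal reading of "use the standard deviation of
each date" — and is exposed because 2σ is an equally defensible convention.
Occupations identical in (lon, lat, age_min, age_max) are duplicates of the
same evidential record and collapse to one; coordinate equality is judged
after rounding to 4 decimals (~11 m), which treats re-entered copies of the
same site as equal without merging genuinely distinct localities. Site
spans are unions of occupation ranges; a site (or a single occupation) is
eligible for CVD only when its span covers at least one full precession
cycle (≥ 23 ka), since shorter series cannot contain even one realisation
of the lowest-frequency component the embedding is designed to capture.

## 3. Bioclimatic variables

bio01 = mean of the 12 monthly mean temperatures; bio04 = 100 × sd of the
monthly means; bio12 = sum of monthly precipitation; bio15 = 100 × sd/mean
of monthly precipitation. Two dialect switches exist because upstream
conventions differ and the choice is not recoverable from a variable's
name: `sd_denominator` (default n−1, matching common bioclim software) and
`worldclim_offset` for bio15 (default off: the plain textbook CV). All-zero
precipitation returns bio15 = 0 rather than NaN so hyper-arid synthetic
cells do not poison downstream statistics.

## 4. Extraction

Points map to grid cells with half-open bounds (a point on a shared edge
belongs to the larger-index cell — an arbitrary but deterministic rule).
Sea points are relocated to the land cell with minimal great-circle
distance between cell centres, ties broken by smaller row then column;
great-circle rather than planar distance because the grids are geographic.
Values are averaged over the focal cell and its in-grid land neighbours
(8-neighbourhood), *unconditionally* — the buffer exists to absorb local
landscape variability, not merely to patch missing cells; the
alternative NA-fallback reading can be recovered by ignoring the buffer.
Ages snap to the 1 ka grid by nearest integer with midpoint ties toward the
older slice (a fixed convention, recorded in the output). Series are stored
oldest→youngest; every CVD output is invariant to that orientation (tested).
Ranges partially outside the cube are clipped to the cube's span; a range
with no overlap is an error naming the offending occupation.

The cube container is an in-memory object with plain-text serialization
(`write_climate_cube()`/`read_climate_cube()`), because no netCDF reader is
assumed to be installed; `as_climate_cube()` is the documented adapter hook
for converting external reconstruction exports (e.g. a long-format data
frame produced from a pastclim region series) into this layout.

## 5. The change/variability decomposition

**Preprocessing.** OLS linear detrend, then scaling to unit sample
variance. Percentages are therefore comparable across series, and variance
removed by the trend is *excluded* from both components — trends slower
than the embedding window are simply outside the decomposition's scope. A
residual variance below 1e−12 is a constant series and an error: the
decomposition is undefined. The detrend is linear because nothing in the
procedure requires more and higher orders would silently absorb
low-frequency signal into "trend".

**SSA.** The trajectory matrix of K = N − M + 1 lagged windows is
decomposed by SVD (Broomhead–King), not via the Toeplitz lag-covariance
matrix: the SVD route is numerically stable and makes the completeness
identity (ΣRC = series) exact under diagonal averaging. The covariance
route survives as an independent oracle in the tests, where both must agree
to 1e−6 on small instances. Eigenvalue ties are left in SVD output order
and components are grouped by index only, so ties cannot change the
percentage split. When K < M (very short series) the decomposition has rank
K and the trailing eigenvalues are exactly zero; completeness still holds.

**White-noise rule.** The periodogram is taken at positive Fourier
frequencies, excluding zero and (for even N) the Nyquist ordinate, and
normalised so each ordinate is asymptotically Exp(mean σ²) under white
noise, with σ² estimated by the mean ordinate. The default acceptance rule
is **family-wise**: the residual is white noise iff its largest ordinate
lies below `−σ̂² · log(1 − (1 − α)^(1/n))`, the exact level-α envelope of
the maximum of n exponential ordinates. The design was genuinely open
here, and an alternative — counting ordinates outside the pointwise
central 95% band and comparing the count to a binomial quantile — is
implemented as `rule = "binomial_count"`. It is not the default for a
measured reason: a leftover periodic component concentrates its variance
in very few ordinates, which barely moves a *count* but dominates a
*maximum*. In calibration/recovery simulations (reproduced in the
acceptance suite) the count rule accepted residuals still containing most
of a 23 ka cycle, driving recovered %change to near zero at true signal
fractions of 0.2–0.5, while the family-wise rule is exactly calibrated
under the null (w = 0 in ~95% of white-noise series) and recovers the
planted variance split within a few percentage points. The rule stays
isolated behind `is_white_noise()` and α is configurable (default 0.05).

**Search and split.** w ascends from 0; the first residual accepted as
white noise stops the search. A zero-variance residual counts as a
noise-free remainder, so w = M (variability = 0) is a guaranteed terminal
case. `unpredictability()` returns %variability — the headline proxy;
higher = less predictable.

**Parameters.** M (default 23 slices = 23,000 years) should be at least
the reciprocal of the slowest frequency that must be resolvable — one
precession cycle here; larger M resolves lower frequencies but needs more
repetitions of the window within the series. A warning (not an error) is
emitted for N < 2M, since K ≈ N − M windows then sample the
eigen-structure coarsely; N ≤ M is an error.

## 6. Regional statistics and resampling

Mann–Whitney (location) and Ansari–Bradley (dispersion) are implemented
with exact small-sample paths (MW: `pwilcox` tail, untied, min(n) ≤ 8; AB:
an authored generating-function convolution of the score distribution,
untied, pooled n ≤ 30) and tie-corrected normal approximations otherwise;
two-sided p is 2·min(tails) capped at 1. Both agree with exhaustive
label-enumeration oracles to 1e−12 on all small fixtures (tested). The
coefficient of variation uses the signed mean — the textbook definition —
and errors on a zero mean; it is reported for context and is unstable for
near-zero-mean variables such as Celsius temperatures, which the report
flags as a warning.

**Sensitivity permutation.** Each of n_iter iterations re-draws, for every
occupation independently, one slice uniformly from its inclusive range,
re-extracts buffered values and re-runs the test. The mid-age statistic's
percentile within the permuted distribution uses the mean-rank-of-ties
convention (a constant-in-time cube therefore yields exactly the 50th
percentile). A single root seed spawns per-iteration substreams, making
results bit-reproducible and invariant to input row order (rows are sorted
internally before sampling).

**Background resampling.** Each iteration draws, with replacement, as many
(land cell in the region box, slice in [t_min, t_max]) pairs as there are
observations and tests observed vs sample; per-iteration direction is the
sign of median(observed) − median(sample) and the summary direction is the
sign of the median of those signs. Sampling is with replacement because
nothing in the procedure requires exclusivity and exchangeability keeps
the null simple; a without-replacement variant would only matter when the
box is small relative to the sample. The region boxes default to eastern
(30, 55, −9, 20) and northwestern (−15, 35, 18, 39) Africa. No
multiple-testing correction is applied anywhere: tests are reported
per-variable with their iteration counts, and readers combine them.

**Calibration design.** Within one `background_resample()` call the
observed sample is *fixed*, so the fraction of significant iterations
conditional on that one draw is not the procedure's size: it can be near 0
or far above α depending on the luck of the observed sample (simulation:
the conditional rate at n = 59 spans ~0–0.3). The acceptance suite
therefore estimates the *unconditional* size by replicating the whole
procedure over 20 fresh null draws of the observed sample at 50 iterations
each (1,000 test iterations in total), which concentrates the estimate
near α. The sensitivity permutation does not have this issue under a
temporally white null world, since every iteration re-draws all values.

## 7. The synthetic world

Each land cell's underlying annual series (for temperature mean, seasonal
amplitude, precipitation mean, seasonal concentration) is

  base(|lat|, lon) + A₁·sin(2πt/100 + φ₁) + A₂·sin(2πt/23 + φ₂) + noise,

with the precession phase φ₂ shifted by π south of the equator (mirrored
cells are exact antiphase copies), amplitudes depending only on (|lat|,
lon), and the noise (white, or AR(1) by option) scaled per cell so its
variance fraction equals the configured `f_noise` — hence signal fraction
+ noise fraction = 1 by construction and `f_noise` is the generator's
ground truth for %variability recovery. Monthly stacks are built from
these annual fields with a cosine seasonal shape (southern-hemisphere
seasons offset six months) and the emitted bio variables are computed from
those stacks *via the package's own bioclim operations*, so internal
consistency is exact rather than approximate. NPP is a saturating
(Miami-model-like) function of annual precipitation plus noise — a
synthetic convention only.

Defaults, chosen once as a realistic desk-scale world and not revisited:
grid lon [−16, 56] × lat [−10, 40] at 2°, time 0–300 ka at 1 ka steps,
sea fraction 0.25, noise fractions EAST = 0.35 and NORTHWEST = 0.65
(regionally distinct so that end-to-end recovery of the regional ordering
has a defined truth; cells outside both boxes use 0.5, and the small box
overlap resolves to NORTHWEST), 37 eastern sites with few repeat
occupations vs 21 northwestern sites with more (mirroring the shape of the
real inventories), half the sites engineered to span ≥ 23 ka, a 10%
verbatim-duplicate rate to exercise deduplication, and dates at 1σ
uncertainties of 2–8 ka in the 35–280 ka range.

What the generator does **not** emulate: real orbital forcing beyond two
sinusoids, glacial–interglacial asymmetry, orography and coastline change,
spatial autocorrelation of the noise field, red spectra of real Holocene/
Pleistocene proxies (except through the AR(1) option), or dating-quality
heterogeneity. A green end-to-end test therefore establishes that the
pipeline recovers *planted* structure of this kind — not that any real
reconstruction has such structure. With AR(1) noise the white-noise
criterion will, correctly by its own definition, classify strongly
autocorrelated noise as "change"; the recovery acceptance uses the white
noise model for exactly this reason, and this behaviour is a property of
the predictability definition, not a bug.

## 8. Numerical choices and degenerate inputs

- Completeness (change + variability = preprocessed series) holds to
  1e−8 max abs; eigenvalue normalisation to 100 holds to 1e−9; both are
  asserted on every decomposition in the tests.
- Reconstructed components are computed as convolutions of the singular
  vector pairs divided by antidiagonal counts — O(M·N log N) and exactly
  linear, so ΣRC = series to machine precision.
- Snapping ties toward the older slice; half-open cell bounds toward the
  larger index; nearest-land ties toward smaller row then column; all
  arbitrary-but-fixed, and recorded here so results are reproducible.
- Constant series: error in CVD (undefined); constant *residuals* are
  accepted as noise-free; all-zero precipitation gives bio15 = 0; zero
  mean errors the CV.
- Seeds: every stochastic routine takes a root seed and derives
  substreams; fixed seed ⇒ bit-identical outputs, including across input
  row permutations.

## 9. Known limitations

- The white-noise acceptance rule is a concrete choice among defensible
  readings of a frequency-domain 95% criterion; results for series whose
  residuals are marginal under one rule can differ under the other. Both
  rules ship; swap via `rule =`.
- %variability conflates measurement/model noise with genuine millennial
  unpredictability; with a single realisation they are indistinguishable.
- Short eligible series (N barely above M) yield coarse eigen-spectra; the
  N < 2M warning marks every such case in the reports.
- The CV on Celsius temperatures can be arbitrarily large near zero mean;
  it is reported but should not be compared across variables with
  different zeros.
- Extraction assumes the cube's land mask is authoritative; no
  sea-level-dependent coastline reconstruction is attempted.
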