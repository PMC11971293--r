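# paleocvd

Quantifying climate seasonality and **predictability** at dated
archaeological occupations.

Early *Homo sapiens* populations in Africa during the Middle Stone Age
(~300–30 ka BP) occupied environments that differed not only in their mean
climate but in how *predictable* that climate was from millennium to
millennium. Given (a) a gridded palaeoclimate time-cube at 1,000-year
resolution and (b) an inventory of dated occupation layers with their
chronometric uncertainties, this package answers: at each occupied
location, what fraction of climatic variance is structured, autocorrelated
**change** — something inhabitants (or their descendants) could in
principle track — and what fraction is white-noise-like **variability**
that cannot be anticipated? It also provides the nonparametric machinery to
compare regions and to check that conclusions survive dating uncertainty
and differ from the regional environmental background.

The package is built around synthetic data with known ground truth: every
stage can be exercised and validated end-to-end without access to any
external climate reconstruction.

## The change/variability decomposition (CVD)

For a climate series \(x_t\) (one value per 1 ka slice across a site's
occupation span), detrended and z-scored:

1. **SSA embedding.** Form the trajectory matrix of lagged windows of
   length \(M\) (default \(M = 23\) slices = 23,000 years, one precession
   cycle) and take its SVD. The squared singular values
   \(\lambda_1 \ge \dots \ge \lambda_M\), normalised to sum to 100, give
   the percentage of variance captured by each empirical orthogonal
   function (EOF); diagonal averaging of the rank-one terms yields
   reconstructed components \(RC_1, \dots, RC_M\) that sum exactly to the
   series.
2. **Smallest-w white-noise search.** Find the smallest
   \(w \in \{0, \dots, M\}\) such that \(\sum_{i>w} RC_i\) is consistent
   with white noise, judged in the frequency domain: under white noise
   every periodogram ordinate is exponentially distributed around the flat
   theoretical spectrum, and the residual is accepted when its largest
   ordinate stays inside the family-wise 95% envelope of that flat
   spectrum.
3. **Variance split.** The *change* component is
   \(\sum_{i \le w} RC_i\) with variance share
   \(\%\text{change} = \sum_{i \le w} \lambda_i\); the *variability*
   component is the remainder, and
   \(\%\text{variability} = 100 - \%\text{change}\) is the
   **unpredictability proxy** — higher means less predictable.

Supporting modules: bioclimatic variables from monthly climatologies
(bio01, bio04 = 100·sd of monthly means, bio12, bio15 = CV% of monthly
totals); cell location, nearest-land relocation and 8-neighbour buffered
extraction from the cube; date-range derivation (oldest date + 1σ to
youngest date − 1σ, mid-age = midpoint), deduplication and site spans;
Mann–Whitney and Ansari–Bradley tests with exact small-sample paths; a
1000-iteration slice-permutation sensitivity analysis and a space-time
background resampling null; and the synthetic generator.

## Worked example

```r
library(paleocvd)

cfg  <- generator_config(seed = 11)            # the default synthetic world
sim  <- make_climate_cube(cfg)                 # cube + ground truth
occs <- dedupe_occupations(normalize_occupations(make_occupations(cfg, sim$cube)))
sites <- site_spans(occs)

s   <- extract_site_series(sim$cube, "bio01", sites[sites$covers_precession, ][1, ])
res <- cvd_decompose(s$values, M = 23)
res
#> <cvd_result> N = 35, M = 23, w = 2: change 77.7% / variability 22.3%
unpredictability(res)
#> [1] 22.30697
```

The site's 35-slice mean-annual-temperature series needs two EOFs before
the remainder looks like white noise; 77.7% of its variance is structured
change, so only 22.3% of the (detrended) variance was unpredictable at the
millennial scale. The full regional report:

```r
rep <- run_predictability_report(sim$cube, occs, sites)
subset(rep$comparisons, test == "MANN_WHITNEY" & level == "site")
#>    variable mean_pct_variability_east mean_pct_variability_northwest  p_value
#> 7     bio01                      36.1                           72.8 0.001250
#> 9     bio12                      23.9                           41.3 0.000674
#> 11      npp                      24.1                           59.0 0.000141
```

The generator gave eastern cells a noise fraction of 0.35 and northwestern
cells 0.65; the report recovers exactly that ordering (east more
predictable) for all three variables, with significant Mann–Whitney
differences.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli/paleocvd", package = "paleocvd"))')
Rscript $CLI simulate --out sim --seed 11
Rscript $CLI cvd --series my_series.csv --M 23 --out cvd.json
Rscript $CLI run-all --out run --seed 11
```

Subcommands: `simulate`, `extract`, `cvd`, `compare`, `sensitivity`,
`background`, `run-all`; configuration via `--config cfg.yaml` (or JSON).

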