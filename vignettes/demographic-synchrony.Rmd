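---
title: "Methods: demographic synchrony from constant-effort capture data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: demographic synchrony from constant-effort capture data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `cessync`, the assumptions they
make, the tunable parameters and their defaults, the numerical choices,
and what the synthetic-data tests do and do not demonstrate about real
constant-effort (CES) ringing data.

## The estimation problem

CES schemes run standardised mist-netting visits at fixed sites through the
breeding season. From the resulting capture table (site, coordinates,
species, year, visit, ring number, age class adult/juvenile) we want, per
grid cell and year: an abundance index (adults captured), productivity (the
juvenile share of the catch) and adult apparent survival; and from those
annual series, the spatial scale, strength, congruence and timescale of
synchrony across cells, compared between demographic rates and between
migratory-status groups.

Effort comparability is protected by the inclusion rules implemented in
`filter_site_years()`: a site-year needs at least 7 visits with at least 3
in each half of the season, a site needs at least 5 qualifying years, and
productivity/survival are only estimated for sites with at least 2 adults
ever captured (the minimum that makes either rate estimable). Because the
capture table is the only effort record available here, visit counts are
inferred from distinct visit indices, and the two "halves" of the season
split each site's observed visit-index range at its midpoint; calendar
dates are not modelled.

## Annual rates per grid cell

Sites are snapped to square cells of side 25, 50 or 100 km
(`assign_grid_cells()`, local equirectangular projection). The published
resolution values are printed with an area unit; this package reads them as
cell side lengths, the conventional gridding, since a literal reading would
give cells only 5–10 km wide.

*Counts.* `fit_annual_counts()` fits adults-per-site-season with Poisson
errors, log link and year as a categorical effect; with more than five
sites in a cell, site enters as a random intercept (Laplace ML via lme4),
otherwise a plain GLM is used. Singular random-intercept fits fall back to
the GLM with a warning. Estimates are reported on the response scale with
delta-method standard errors. All-zero years sit on the boundary of the
log link and are reported as 0 with a `boundary` flag rather than fitted.

*Productivity.* `fit_annual_productivity()` is the binomial analogue:
juveniles as the response, all birds as the denominator, so the estimate is
the juvenile proportion in [0, 1]. Years with no birds are missing, not
zero; all-juvenile or no-juvenile years are boundary-flagged.

*Survival.* `fit_cjs()` fits a Cormack–Jolly–Seber model conditional on
first capture, with a transience mixture: a newly ringed adult is a
resident with probability ρ and then follows the CJS process with
year-specific apparent survival φ_t and a year-constant recapture
probability p; with probability 1 − ρ it is a transient never seen again.
The likelihood (`cjs_transient_loglik()`, Rcpp) is a per-individual forward
recursion over the latent alive state, with identical histories collapsed
to multiplicities. Posterior sampling uses single-site random-walk
Metropolis on the logit scale (step 0.35) under Uniform(0, 1) priors on
every parameter — the published analysis says only that priors were vague,
so the uniform is assumed — and ρ is taken year-constant because its time
structure is unstated. Convergence is summarised by the Gelman–Rubin
statistic; any R-hat ≥ 1.1 flags the fit. The classic PSRF estimator
equals sqrt((n−1)/n) when chains are identical, so values below 1 are
truncated to 1. The desk-scale default schedule is 4 chains × 20,000
iterations (burn-in 10,000, thin 10); the reference schedule of 2 chains ×
5,000,000 (burn-in 2,000,000, thin 5,000, 1,200 retained draws) remains one
`mcmc_config()` call away. Seeds for every cell fit derive from a master
seed hashed with the cell and species labels, so partial reruns are
reproducible.

## Scale, strength and congruence of synchrony

Annual estimate series are detrended by OLS on year (`detrend_series()`),
which removes linear trends that would otherwise manufacture spurious
correlation while leaving genuine temporal autocorrelation in place.
Pearson correlations are computed for all cell pairs overlapping ≥ 5 years
(`pairwise_correlations()`), with haversine distances between cell
centroids (Earth radius 6371.0088 km). For congruence the count series is
lagged one year — count in year t+1 against productivity or survival in
year t — and all ordered pairs (focal count cell × other rate cell) are
used; self-pairs are excluded throughout, so strength is always a spline
evaluation at distance 0, never a raw datum.

`fit_correlogram()` smooths correlation against distance with a cubic
regression spline and requires ≥ 20 pairs. **Smoothing choice.** The
default is a fixed sqrt(n_pairs)-df regression spline, the convention of
the spline spatial correlogram literature, rather than REML/GCV penalized
smoothing. The reason is specific to the quantity extracted downstream:
under a spherical correlation the true curve approaches zero tangentially,
and in simulation the REML-optimal amount of smoothing leaves the fitted
tail 0.02–0.04 above zero, so the mean curve often never crosses zero and
the estimated scale collapses to the minimum-distance cap; the fixed-df
spline tracks the crossing without that bias. Penalized variants remain
available via `smoothing = "REML"` or `"GCV.Cp"`. Uncertainty comes from
1000 draws (count unstated in the source analysis) from the approximate
multivariate-normal posterior of the spline coefficients; predictions run
from 0 to the maximum pair distance in 1-km steps.

`extract_scale_strength()` reads strength as the fitted curve at distance
0 (negative values retained) and scale as the first distance where the
curve reaches ≤ 0, localised by linear interpolation between grid points;
the first crossing is used if there are several. Scales that never cross
within the grid are set to the species' minimum distance, and all scales
are capped there, giving relative scale in [0, 1]. The minimum distance
(`minimum_distance()`) is the literal two-step procedure: per focal cell
the maximum distance to any other occupied cell, then the minimum of those
maxima. Precision weights for the comparative models are 1 / mean
posterior-simulation SE between distance 0 and the scale (for scale) and
1 / width of the 95% band at distance 0 (for strength).

One ambiguity in the source analysis is whether correlograms pooled all
pairs per species or were fitted per focal cell; `run_pipeline()` defaults
to per-focal-cell fits with species-level pooling available
(`correlogram$pool`), and the shipped tiny configuration uses pooling
because a 9-cell landscape yields only 8 pairs per focal cell.

## Periodicity: wavelet phasor mean fields

Series are standardised per cell by linear detrend + de-mean
(`clean_series()`, the "clev 2" cleaning level; cells with internal gaps
or fewer than 8 years are excluded). `morlet_cwt()` computes a continuous
Morlet transform with central frequency parameter 1 on a geometric
timescale grid from 2 years to T/2 with ratio 1.05; points within one
e-folding time (sqrt(2)·s) of either series end are outside the cone of
influence and stay missing everywhere downstream. The wpmf (`wpmf()`)
normalises each cell's coefficient to a unit phasor and takes the modulus
of the across-cell mean: 1 under perfect phase synchrony, small under
random phases. Significance uses the seeded Monte-Carlo (1 − α) quantile
of the modulus of the mean of n independent uniform phasors
(`wpmf_threshold()`, α = 0.05 by default, 10,000 draws; for large n this
approaches the Rayleigh limit sqrt(−log α / n)); this is the
phasor-randomisation ("quick"-style) null, chosen because the surrogate
family used in the original analysis is unstated. Year counts per
timescale band (`significant_year_counts()`) use bands [2, 3], (3, 5] and
(6, T/2], with (5, 6] deliberately unassigned, mirroring the published
band labels; the bands are configurable. Composite fields average
magnitudes entrywise, missing-aware, across species.

## Comparative models

`fit_weighted_lmm()` fits Gaussian mixed models of relative scale or
strength with the stated precision weights scaling residual variance, the
demographic metric and migratory status as fixed effects, and cell and
species as random intercepts. Random terms with fewer than five levels, or
that make the fit singular, are dropped and flagged; the fit then
gracefully degrades to weighted least squares. Term tests are
likelihood-ratio chi-squares between nested ML fits (the original test
type is unstated; LRTs keep the nesting coherent), with type-II handling
of the congruence pairing × status interaction in `fit_congruence_lmm()`.
`fit_periodicity_glm()` models significant-year proportions per band with
quasibinomial errors; timescale enters as the band midpoint (a continuous
covariate, matching the single degree of freedom reported for it), and
both dispersion-adjusted chi-square and F statistics are reported because
the published table header is ambiguous between them. The published
wording lists these predictors as "response variables"; that is read as a
typo for explanatory variables.

## The synthetic generator

`make_landscape()` lays out square cells and uniformly jittered sites on a
local equirectangular plane (longitude scaled by the cosine of each
point's latitude, keeping planar and haversine distances within ~1% over
the few-hundred-km extents used). `simulate_rate_field()` draws zero-mean
unit-variance Gaussian-process anomalies per metric with a spherical or
exponential spatial correlation (Cholesky factorisation with 1e-10
diagonal jitter), stationary AR(1) temporal structure whose innovations
carry the spatial correlation, an optional common sinusoid for controlled
periodicity, and linear trends so detrending is exercised. The anomaly
scale is set by `anomaly_sd` (default 0.25 on the logit/log link scales) —
a value giving realistic year-to-year swings of roughly ±10 percentage
points in survival; unit-variance anomalies on a logit scale would be
implausibly volatile.

`simulate_captures()` tracks individuals: adults survive with
plogis(qlogis(φ₀) + survival anomaly), juveniles arise as
Poisson(N · productivity) with productivity = π₀ · exp(productivity
anomaly), and recruits join as Poisson(N · productivity · φ₀) — i.e.
juveniles recruit with the adult survival probability, which makes the
population stationary in expectation at the defaults (φ₀ = 0.5, π₀ = 1).
Detection is per-visit Bernoulli (default 0.25 over 8 visits, a seasonal
encounter probability of ~0.90). Residency is decided by a Bernoulli(ρ)
flag at first capture; transients emit that season's records and leave the
population, exactly the data-generating story of the transience term in
the likelihood. Ringed juveniles are never re-identified as returning
adults (recruits are new individuals), consistent with the model's
exclusion of juveniles from capture histories and the absence of
age-structured survival.

What the generator does **not** emulate: within-season phenology and
timing, real CES network geometry, observer or weather effects on
detection, age-structured or density-dependent dynamics, dispersal between
sites, and measurement error in ageing. Passing recovery tests therefore
demonstrates the estimators' correctness under the stated model, not
robustness to these real-data complications.

## Numerical choices and problem sizes

- Cholesky jitter 1e-10; non-PSD covariances are an error, not silently
  repaired.
- Metropolis step 0.35 on the logit scale; chains start from independent
  uniform draws in (0.2, 0.8) on the probability scale.
- Correlogram prediction grid 1 km; zero crossings linearly interpolated.
- The test and acceptance workloads use scaled problem sizes chosen as
  sensible desk-scale defaults: CJS recovery at 300 individuals × 10
  occasions with 2 chains × 4,000–6,000 iterations; correlogram recovery
  from 500 pairs per replicate; wavelet calibration from 10–20 cells × 30–32
  years; comparative-model calibration at 300 records × 50–100 replicates;
  and a 9-cell, 2-sites-per-cell, 20-year, two-species end-to-end pipeline.
- All stochastic stages consume seeds derived by hashing a master seed
  with a stage label, so every artifact is bit-reproducible.

## Known limitations

- Survival-estimate uncertainty is not propagated into the correlograms
  (each pair correlation treats the annual estimates as data); the same
  limitation applies to the original analysis design.
- The CJS model has no goodness-of-fit testing beyond R-hat, no
  age-structured survival and no robust-design within-season modelling.
- The wpmf significance test is pointwise per year × timescale; band-level
  counts inherit the multiplicity of correlated timescales within a band,
  so "any in-band timescale significant" has a null rate well above α per
  year — comparisons between bands or groups are meaningful, absolute
  per-year rates are not.
- With a single small landscape, migratory-status contrasts in the
  comparative models rest on few species; the pipeline drops random terms
  with fewer than five levels and flags it, but such fits are illustrative
  rather than inferential.
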