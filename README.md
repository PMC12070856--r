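# cessync

Spatial and temporal synchrony of demographic rates from constant-effort
bird-ringing data.

## What it does

Populations that fluctuate in step across space (population synchrony) face
higher extinction risk than populations that fluctuate independently, and
the synchrony of abundance ultimately has to come from synchrony in the
underlying demographic rates. `cessync` implements a complete analysis chain
for quantifying that structure from constant-effort ringing-site (CES)
capture data — the standardised mist-netting scheme in which fixed net
positions and visit schedules make annual captures comparable across years
and sites:

1. **Effort filtering.** Site-years are retained only with ≥ 7 visits
   (≥ 3 in each half of the season), sites only with ≥ 5 qualifying years;
   sites enter survival/productivity estimation only once ≥ 2 adults have
   been captured.
2. **Annual demographic rates per grid cell** (cells of side 25, 50 or
   100 km): counts of adults via Poisson year-effect models, productivity
   (juvenile proportion of the catch) via binomial models — both with a
   site random intercept when a cell holds more than five sites — and
   adult apparent survival via a Bayesian Cormack–Jolly–Seber model with a
   transience term,

   L(history) = ρ · L_CJS(φ₁…φ_{K−1}, p) + (1 − ρ) · 1{never re-encountered},

   sampled by random-walk Metropolis on the logit scale under Uniform(0,1)
   priors, with Gelman–Rubin R-hat convergence checks (fits flagged at
   R-hat ≥ 1.1).
3. **Scale and strength of synchrony.** Series are linearly detrended;
   Pearson correlations between all cell pairs overlapping ≥ 5 years are
   smoothed against great-circle distance with a cubic regression spline
   (≥ 20 pairs required). *Strength* is the fitted correlation at distance
   zero; *scale* is the first distance at which the fitted curve reaches
   zero, capped at the species' *minimum distance* (the smallest over
   focal cells of each cell's maximum distance to another occupied cell),
   and *relative scale* = scale / minimum distance ∈ [0, 1]. Count–rate
   *congruence* repeats this with counts lagged one year against
   productivity or survival.
4. **Periodicity of synchrony.** Wavelet phasor mean fields (wpmf): Morlet
   transforms per cell, unit-phasor normalisation, and the modulus of the
   across-cell mean phasor per year × timescale, tested against a
   Monte-Carlo random-phase null at p < 0.05, summarised in short (2–3 y),
   intermediate (3–5 y) and long (> 6 y) timescale bands.
5. **Comparative models.** Weighted Gaussian mixed models (precision
   weights from the correlogram posterior simulation) of relative scale
   and strength against demographic rate and migratory status; a
   quasibinomial GLM of the proportion of years with significant synchrony
   per timescale band.

Because the real Euro-CES data are not public, the package ships a
first-class synthetic generator: a landscape of grid cells and jittered
sites, Gaussian-process rate anomalies with a spherical or exponential
spatial correlation (Cholesky factorisation), AR(1)/sinusoidal temporal
structure and linear trends, and an individual-based capture process with
per-visit detection and Bernoulli residency at first capture. Every stage
of the pipeline is validated by parameter recovery against the generator's
known truth.

## Worked example

```r
library(cessync)

lay  <- make_landscape(n_cells = 9, extent_km = 300, resolution_km = 100,
                       sites_per_cell = 2, seed = 1)
fld  <- simulate_rate_field(lay, years = 20,
                            spatial_corr_model("spherical", range_km = 250,
                                               sill = 0.5),
                            temporal_model(sine_amplitude = 0.15), seed = 2)
recs <- simulate_captures(lay, fld, sim_params(seed = 3), species = "SPA")
fl   <- filter_site_years(recs, "SPA")

rr   <- fl$rates[fl$rates$age == "A", ]
post <- fit_cjs(build_capture_histories(rr),
                mcmc_config(2, 3000, 1000, 4, seed = 5))
print(post)
#> cjs_posterior: 516 individuals, 1000 retained draws
#>      phi_1 phi_2 ...     p   rho
#> mean 0.650 0.499 ... 0.879 0.696
#> rhat 1.007 1.010 ... 1.000 1.008
```

The simulation used true survival 0.5, residency 0.7 and a seasonal
encounter probability of 1 − (1 − 0.25)⁸ ≈ 0.90; the posterior means above
(year-specific survival scattered around 0.5, p ≈ 0.88, ρ ≈ 0.70) recover
all three, with every R-hat < 1.1. `run_pipeline(run_config(), "out/")`
chains all stages — simulate, filter, rates, synchrony, wavelet, compare —
into tidy CSVs plus a JSON manifest, and the `inst/scripts/cessync` script
exposes the same pipeline as a shell command with subcommands
`simulate | rates | synchrony | wavelet | compare | all`.

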