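# isomove

Geolocating grazing animals from sulfur stable isotopes in tail hair.

Tail hair grows continuously (≈ 0.76 mm/day) and keratin locks in the
δ³⁴S signature of the diet at the time each section grew, so a hair
sectioned into 8 mm segments is a ~105-day diary of where an animal fed.
Turning that diary into geography requires three statistical components,
all implemented here:

1. **Isoscape** (`fit_isoscape`, `select_isoscape`, `predict_isoscape`) —
   a penalized additive model of grass δ³⁴S,

   δ³⁴S<sub>L</sub> = **x**ᵀγ + f(east, north) + e,

   with dummy-coded lithology effects and a tensor-product spatial
   smoother (REML smoothness selection, AIC/Akaike-weight model choice),
   predicting a mean surface and its uncertainty SD σ<sub>L</sub> on a
   raster grid.

2. **Errors-in-variables calibration** (`fit_calibration`) — a Bayesian
   hierarchical model linking hair to grass while admitting that the local
   grass value is itself a noisy observation of a latent truth:

   δ³⁴S<sub>T,i,j</sub> ~ N(α<sub>j</sub> + β·M<sub>L,j</sub>, σ<sub>ε</sub>),  δ³⁴S<sub>L,j</sub> ~ N(M<sub>L,j</sub>, σ<sub>M</sub>),  α<sub>j</sub> ~ N(α, σ<sub>α</sub>),

   with weakly informative t(3) priors and σ<sub>M</sub> ~ N(σ<sub>L</sub>, 0.25).
   Sampled with JAGS on an exactly collapsed parameterisation (latents
   integrated out analytically, then recovered by conjugate sampling), so
   the full default MCMC protocol — 3 chains × 10,000 iterations, 5,000
   warmup, 3,000 kept draws — converges with split-Rhat ≤ 1.01 and large
   effective sample sizes. `variance_partition()`, `predict_tail()` and
   `convergence_check()` operate on the result.

3. **Movement detectability** (`sample_pairs`, `detection_polar`,
   `classify_movement`) — Monte-Carlo over random point pairs on the
   isoscape: for each pair, a within-animal z-test on the difference of
   posterior-predictive hair values (slope and intercept draws shared
   across endpoints; β, σ<sub>ε</sub> and both endpoints' σ<sub>L</sub>
   propagated), then a direction-resolved detection-distance curve by
   bearing bin. Individual hairs are classified moved / not-moved by
   pairwise z-tests with familywise correction.

A first-class synthetic-data generator (`make_landscape`, `sample_grass`,
`simulate_herd`) reproduces the statistical structure the analysis
assumes — lithology patches plus a Gaussian random field, 5-quadrat plot
pooling, hierarchical hair series over piecewise-constant movement
histories — so everything above is testable without any download.
`run_pipeline()` chains all stages from one seeded, resumable, hashed
configuration.

## Worked example

```r
library(isomove)

land  <- make_landscape(landscape_config(nx = 40, ny = 40, cell_km = 2.24, seed = 1))
grass <- sample_grass(land, n_sites = 116, quadrat_sd = 0.5, seed = 2)

sel <- select_isoscape(grass, list(
  lith_smooth = d34S_permil ~ factor(lithology) + te(x_km, y_km, k = c(6, 6)),
  smooth_only = d34S_permil ~ te(x_km, y_km, k = c(6, 6))))
sel[, c("model", "aic", "delta_aic", "weight", "edf")]
#> # A tibble: 2 × 5
#>   model         aic delta_aic   weight   edf
#>   <chr>       <dbl>     <dbl>    <dbl> <dbl>
#> 1 lith_smooth  94.9        0  1   e+ 0  12.7
#> 2 smooth_only 303.       208. 5.69e-46  26.2
```

The lithology-plus-smooth model takes essentially all the Akaike weight —
geology drives the surface. Predict the isoscape and its uncertainty:

```r
iso <- predict_isoscape(attr(sel, "best_fit"), land)
attr(iso, "mean_sigma_L")
#> [1] 0.115
```

Simulate a herd of 46 cattle in 20 villages (the generator's hair model
uses slope 1.736, intercept −4.670, σ_ε 0.64, σ_α 0.292 by default) and
refit the calibration from the hair and village-grass tables:

```r
post <- fit_calibration(cal_data, sigma_L = 1.0, seed = 5)
post
#> <calibration_posterior> 3000 draws x 3 chains (JAGS (collapsed likelihood, adaptive Gibbs))
#> # A tibble: 5 × 5
#>   param         mean     sd     q2.5  q97.5
#>   <chr>        <dbl>  <dbl>    <dbl>  <dbl>
#> 1 alpha       -4.60  0.394  -5.40    -3.83
#> 2 beta         1.74  0.0506  1.64     1.84
#> 3 sigma_M      0.219 0.0576  0.0770   0.317
#> 4 sigma_alpha  0.178 0.118   0.00670  0.430
#> 5 sigma_eps    0.632 0.0219  0.590    0.677
```

The generative slope (1.736) and intercept (−4.670) are recovered within
a posterior SD. Direction-resolved detectability from 50,000 random
pairs:

```r
pairs <- sample_pairs(iso, post, n_pairs = 50000, seed = 6)
polar <- detection_polar(pairs)
head(polar, 4)
#> # A tibble: 4 × 6
#>   bearing_deg detection_km censored n_pairs low_n estimator
#>         <dbl>        <dbl> <lgl>      <int> <lgl> <chr>
#> 1           5         38.0 FALSE       3299 FALSE p50
#> 2          15         44.2 FALSE       2766 FALSE p50
#> 3          25         45.0 FALSE       2715 FALSE p50
#> 4          35         47.6 FALSE       2881 FALSE p50
autoplot(polar)
```

Each row is the distance at which a move along that bearing reaches 50%
detection probability on *this* synthetic landscape; bins aligned with
strong isotopic gradients need less movement than bins running along the
isoclines. `overlay_reported_distances(polar, reported_km)` then compares
distances animals are reported to have moved against the most favourable
bin. `classify_movement(hair, segment_sd)` makes the per-hair moved /
not-moved call.

See `vignettes/isoscape-movement-methods.Rmd` for the full model
descriptions, identifiability analysis, and the generator's scope.

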