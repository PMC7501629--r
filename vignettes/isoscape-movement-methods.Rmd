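---
title: "Methods: sulfur isoscapes, hair calibration, and movement detectability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sulfur isoscapes, hair calibration, and movement detectability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isomove)
```

# The problem

Grazing animals record where they have fed: sulfur entering a plant from
the underlying soil carries an isotopic signature (δ³⁴S, the ³⁴S/³²S ratio
in per mil relative to V-CDT) that varies across a landscape with geology,
and keratin laid down in a continuously growing tail hair preserves the
signature of the diet at the time each section grew. Reading a hair from
root to tip therefore reads a time series of feeding locations — *if* three
quantitative problems are solved:

1. **Isoscape construction** — predict local grass δ³⁴S anywhere on the
   landscape, with honest uncertainty, from a finite set of grass plots;
2. **Tissue calibration** — map grass δ³⁴S to hair δ³⁴S, accounting for
   trophic fractionation, individual animals' offsets, and the fact that
   the local grass value is itself measured with error;
3. **Detectability** — decide how far an animal must travel, and in which
   direction, before its hair can *statistically* betray the movement,
   given every propagated source of uncertainty.

`isomove` implements all three stages plus a synthetic-data generator that
reproduces the statistical structure the analysis assumes, so the whole
pipeline is testable end to end without any field data.

# The isoscape model

Grass δ³⁴S at plot *i* is modelled as a penalized additive (GAM) regression

$$\delta^{34}S_{L,i} = \mathbf{x}_i^\top\boldsymbol\gamma
  + f(\mathrm{east}_i, \mathrm{north}_i) + e_i,
  \qquad e_i \sim N(0, \sigma^2),$$

where $\mathbf{x}_i$ holds an intercept and dummy-coded lithology classes
(reference-level coding, so each coefficient is a contrast against the
reference rock type) and $f$ is a tensor-product smooth over the planar
coordinates with one roughness penalty per margin. Fitting, smoothness
selection (REML by default, GCV behind a flag) and prediction standard
errors are delegated to mgcv — the de facto standard for this model class —
behind the package's interface; `build_design()` exposes the marginal
B-spline bases and per-margin penalty matrices for inspection. Candidate
formulas are compared with AIC and Akaike weights
($w_i = e^{-\Delta_i/2}/\sum_k e^{-\Delta_k/2}$) in `select_isoscape()`.

`predict_isoscape()` returns the mean surface and a per-cell SD, σ_L. Two
conventions exist for σ_L and both are available: the default is the
standard error of the fitted mean surface,
$\sqrt{\mathrm{diag}(X \Sigma X^\top)}$, which is the convention that
yields σ_L magnitudes near 1 ‰ at survey-sized samples; `include_residual = TRUE` adds the
residual variance, describing a *new grass observation* rather than the
surface. The prediction grid inherits the lithology raster's resolution.

Two structural facts worth knowing:

* The tensor smooth's penalty null space is bilinear —
  span{1, x, y, xy} — so as the smoothing parameters grow the smooth
  collapses to a bilinear, not strictly planar, surface. On planar data
  the two coincide, which is how the infinite-smoothing limit is tested.
* With a noise-free response, REML's scale estimate degenerates and its
  optimiser can fail; `fit_isoscape()` falls back to the well-defined
  infinite-smoothing limit (fixed large smoothing parameters) in that
  case.

# The errors-in-variables calibration

Tail-hair segment *i* of animal *j* is linked to the *latent* local grass
value $M_{L,j}$:

$$\delta^{34}S_{T,i,j} \sim N(\alpha_j + \beta M_{L,j}, \sigma_\epsilon),
\qquad
\delta^{34}S_{L,j} \sim N(M_{L,j}, \sigma_M),
\qquad
\alpha_j \sim N(\alpha, \sigma_\alpha).$$

The slope β captures dietary fractionation scaling; α the baseline
grass-to-keratin offset; σ_ε segment-to-segment noise within a hair; σ_α
between-animal offset spread; σ_M how noisily a single pooled grass sample
represents the latent local value. Priors are weakly informative: t(3)
with scale 10 on β and on the *centered* intercept, half-t(3) with scale
2.5 on σ_ε and σ_α, and — crucially — $\sigma_M \sim N(\sigma_L, 0.25)$
truncated positive, centered on the isoscape's mean prediction SD.

**Identifiability.** Integrating the latents out shows the per-animal
summary $(\bar T_j, L_j)$ is bivariate normal with
$\mathrm{Var}(\bar T_j) = \beta^2 s^2 + \sigma_\alpha^2 +
\sigma_\epsilon^2/n_j$, $\mathrm{Var}(L_j) = s^2 + \sigma_M^2$ and
$\mathrm{Cov} = \beta s^2$, where $s$ is the spread of the latent grass
values. Three moment equations, four unknowns: the model has a
one-dimensional ridge along which a smaller β trades off against a larger
σ_α and smaller σ_M. The σ_M prior is what selects a point on that ridge —
it is not a nuisance detail but the device that converts the isoscape's
uncertainty estimate into an attenuation correction. Consequently (a)
parameter-recovery experiments must center that prior at the generative
σ_M, exactly as the real analysis centers it at the isoscape's σ_L, and
(b) the latent values need an exchangeable structural prior
$M_{L,j} \sim N(\mu_M, \sigma_{land})$ with $\sigma_{land}$ estimated
(half-t(3), scale 10): with a flat prior on each $M_{L,j}$ the
marginalized likelihood reduces to a naive regression of hair on observed
grass and the posterior sits at the attenuated slope.

**Sampling.** The posterior is sampled with JAGS. A naive encoding that
samples all latents mixes extremely poorly along the ridge (autocorrelation
times of thousands of iterations), so the model is encoded in collapsed
form: per animal, the bivariate normal above plus a gamma (scaled χ²) term
for the within-hair residual sum of squares — an exact marginalization,
not an approximation — and the sampler walks only the hyperparameters,
with the intercept parameterised on the centered scale. Kept draws of
$M_{L,j}$ and $\alpha_j$ are then recovered by exact conjugate bivariate
normal sampling given each hyperparameter draw, so the returned joint
posterior is that of the full displayed model. At the default protocol —
3 chains × 10,000 iterations, 5,000 warmup, thinned to 3,000 total kept
draws — all parameters reach split-Rhat ≤ 1.01 and effective sample sizes
in the thousands on design-sized data (46 animals × 10 segments).
`convergence_check()` recomputes split-Rhat (implemented directly: each
chain is halved before the between/within comparison) and ESS per
parameter and fails loudly.

All hair segments are regressed against the single local grass value by
default; `segments = "root"` restricts to the most recent segment. The
"3,000 posterior samples" convention is read as a total across chains.

`variance_partition(σ_ε, σ_α)` returns
$\sigma_\epsilon^2/(\sigma_\epsilon^2+\sigma_\alpha^2)$, the segment-level
share of hair variance. `predict_tail()` pushes a new location's grass
distribution $N(\mu_L, \sigma_L)$ through the posterior draw by draw —
new intercept, latent grass value, segment noise — to give the full
posterior-predictive hair value.

# Hair timelines and movement calls

`segment_hair()` converts hair length to dated half-open windows at a
constant growth rate (defaults: 8 mm segments, 0.76 mm/day, so one segment
spans 10.526 days and a 10-segment adult hair spans 105.26 days; display
conventions truncate or round, and the exact value is always carried).
Segment 1 is the root, i.e. days [0, 10.526) before sampling; leftover
hair shorter than one segment is discarded, as in sectioning practice.

`classify_movement()` tests every segment pair (or adjacent pairs) with
$z = |\Delta\delta^{34}S| / (\sigma\sqrt2)$ and a familywise correction
(Bonferroni by default) at level α = 0.05: a conservative yes/no movement
call driven by within-hair variation. The call is invariant to adding a
constant to the series, symmetric under reversal, and monotone in the
noise SD.

# Movement-detection power analysis

For a random pair of points on the isoscape, the package asks: would one
animal's hair differ detectably between the two? The two endpoints share
the animal's intercept and the slope draw (the comparison is within one
hair), so the predictive difference per posterior draw is
$D \mid \theta \sim N(\beta\,\Delta\mu,\;
\beta^2(\sigma_{L,1}^2+\sigma_{L,2}^2) + 2\sigma_\epsilon^2)$, and mixing
over draws gives closed-form mean and variance (the Gaussian predictive
noise is Rao-Blackwellised rather than simulated, so 50,000 pairs cost a
vectorised pass, not 50,000 simulations). A two-sided z-test at α = 0.05
flags the pair; no multiple-testing correction is applied across pairs
because each pair stands for its own hypothetical animal.

`detection_polar()` folds pair bearings to [0°, 180°) (pairs are
undirected; the curve is mirrored back), bins them (36 bins of 10° by
default), and estimates a per-bin detection distance. The default
estimator fits a logistic regression of significance on distance and
reports the 50%-detection distance; under perfect separation — a sharp
threshold, as on noise-free gradients — the diverged fit's
$-\hat b_0/\hat b_1$ still sits at the threshold and is used deliberately.
A literal "mean distance among significant pairs" estimator
(`"mean_sig"`) is also shipped; it is window-dependent (it grows with the
sampled domain) but robust, and bins where the logistic is unusable fall
back to it with a warning. Bins with no attainable detection are censored
at the largest sampled pair distance. On a point-mass posterior and a
linear gradient of g ‰/km the closed form
$d^* = z_{0.975}\sqrt2\,s/(\beta g)$ (s the per-endpoint predictive SD)
is available as an oracle; the test suite checks agreement within 10%,
with the sampled domain sized ~8 d* so pairs span both sides of the
threshold in every bearing bin.

One propagation subtlety is documented rather than resolved: full
posterior-predictive propagation of β, σ_L at both endpoints and σ_ε gives
per-point predictive SDs somewhat larger than the naive plug-in
$\sqrt{\beta^2\sigma_L^2 + \sigma_\epsilon^2}$ evaluated at point
estimates; the package implements the full propagation.

# The synthetic-data generator

`make_landscape()` builds the ground truth the pipeline is exercised on:
a base level plus additive offsets on contiguous lithology patches
(Voronoi tessellation of a few seed points per class, mimicking a geology
map) plus a stationary Gaussian random field with squared-exponential
correlation, synthesised spectrally on the grid torus (circulant
embedding), which gives the exact marginal SD requested. Defaults — a
60 × 60 grid of 2.24 km cells (5 km² pixels), 4 lithology classes with
offsets of a few ‰, field SD 1 ‰, range 25 km, base level 7 ‰ — are chosen
to resemble a volcanically heterogeneous savanna system: grass values
spanning roughly +3 to +13 ‰ with geology as the dominant driver.

`sample_grass()` emulates plot pooling: each site's value is the mean of
five quadrat subsamples, so pooled noise is quadrat_sd/√5. The emulated survey
design pools 5 quadrats per plot and collects 116
landscape plots; the within-plot quadrat SD is not reported anywhere, so
`quadrat_sd` is a free knob with default 0.5 ‰ — small relative to the
landscape signal, as pooling is intended to achieve.

`simulate_herd()` is the generative twin of the calibration model:
per-animal intercepts, piecewise-constant movement histories mapped onto
segment windows, and the linear grass-to-hair map with segment noise. Day
weighting enumerates whole days (day *d* is the interval [d, d+1) before
sampling) and averages the true grass value over the days in each segment
window; a move "at day 53" therefore lands cleanly between segments 5 and
6 even though the continuous boundary is at 52.63 days. This
discretisation is the package's convention; at one-day resolution it is
indistinguishable from continuous weighting for any realistic growth
rate.

What the generator deliberately does *not* emulate: diet-to-keratin
turnover lag (incorporation is instantaneous), seasonal change in the
isoscape itself, non-Gaussian grass noise, spatial autocorrelation in
isoscape residuals, and real covariates (rainfall, vegetation index, soil
chemistry) — the smooth field stands in for all continuous drivers.
Passing tests therefore demonstrate correctness of the *statistical
machinery* under the stated model, not robustness to these real-data
departures.

# Numerical and design choices

* Coordinates are planar km with Euclidean distances; the target systems
  are small enough that a projected plane suffices. Bearings are degrees
  clockwise from north.
* MCMC determinism: every chain gets an explicit RNG seed derived from the
  user seed; the latent back-fill uses a separately derived seed. Identical
  seeds give bit-identical posteriors.
* The pipeline (`run_pipeline()`) forks per-stage seeds deterministically
  from one global seed, hashes every artifact (MD5), logs one line per
  stage, and on resume skips stages whose recorded input and output hashes
  still match.
* Problem sizes in the shipped tests: landscapes up to 250 × 200 cells for
  field-statistics checks; 46 animals × 10 segments at the default
  calibration parameters for recovery (10 replicate fits at the full MCMC
  protocol); 50,000 pairs for power-analysis checks; 10,000 simulations
  for familywise-error calibration. These sizes make every Monte-Carlo
  tolerance in the suite comfortably larger than its Monte-Carlo error.
* Degenerate inputs have defined behaviour rather than crashes: constant
  responses (infinite-smoothing fallback), single-segment animals (the
  RSS term is dropped), two-animal datasets (wide posteriors), flat
  isoscapes (all polar bins censored), zero-distance pairs (p = 1).

# Limitations

* σ_L from the GAM is a confidence SD of the mean surface; if the
  downstream question concerns a new grass sample rather than the surface,
  use `include_residual = TRUE` consistently in both the calibration's
  `sigma_L` argument and the power analysis.
* The calibration's β is prior-identified through σ_M (see above); with a
  badly wrong σ_L input the slope will be correspondingly biased. This is
  a property of the model class, not of the implementation.
* The movement classifier controls familywise error per hair, not
  per-herd; screening many animals at α = 0.05 each will produce false
  movers at the usual rate.
* Lithology coefficients are plain dummy contrasts in ‰; analyses that
  scale covariates differently will report coefficients on a different
  scale than this package.
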