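---
title: "Seasonal RSF habitat mapping: models, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seasonal RSF habitat mapping: models, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`rsfmap` implements a seasonal habitat-selection modelling chain for greater
sage-grouse: used-available telemetry designs, weighted logistic mixed
models with two-step AICc selection and model averaging, cross-site
meta-analysis by hydrographic subregion, and the derived habitat selection
(HSI), habitat category, and habitat management (HMI) surfaces. This
vignette records the statistical model, the package's own design decisions
where the procedure left choices open, what the synthetic data generator
does and does not emulate, and the numerical conventions that make the
pipeline exactly testable.

## The estimation model

Used locations are contrasted with five available locations apiece, drawn
uniformly from the site's availability extent (the minimum convex polygon of
the site's locations dilated by 1,451 m, the average maximum daily movement).
The used-available table is fit as a weighted Bernoulli-logit mixed model

$$\mathrm{logit}\, P(y_i = 1) = \alpha + \beta^\top x_i + b_{\mathrm{bird}(i)} + b_{\mathrm{year}(i)},$$

with crossed Gaussian random intercepts and prior weights 1.0 (used) and
0.2 (available) so the two classes carry equal mass; under the exponential
RSF interpretation $\exp(\beta^\top x)$ is the relative selection strength.
Fitting is Laplace-approximate maximum likelihood via `glmmTMB`. The choice
of backend is a contract, not an implementation detail: `lme4::glmer`, the
field's usual tool, fails its PIRLS step-halving with the fractional prior
weights this design requires, while `glmmTMB` maximizes the identical
weighted Laplace ML objective and passes the balance check (an
intercept-only fit on a 5:1 weighted table returns an intercept at zero).
When both variance components collapse to the zero boundary — which is
common and, in the synthetic pipeline, expected, because constant per-draw
intercepts cancel out of the cellwise sampling law — the model is refit as a
weighted logistic GLM with bird-clustered robust (sandwich) standard errors.
That fallback is the same maximized likelihood restricted to the boundary;
its parameter count still includes the two variance components so AICc
comparisons across a model set remain coherent.

Covariates are z-scored per site-season on the availability rows, and
coefficients are reported on that standardized scale (the transformation is
stored on the fit and inverted automatically in prediction). Two-step
selection: (1) per covariate family, the best of the candidate scales/forms
by AICc is carried forward only if it beats the random-effects null by at
least 2.0 units (ties break to the smaller radius, i.e. the first candidate
in the declared order); (2) after an iterative |r| >= 0.65 screen that drops
the higher-AICc member of the currently worst pair, all two-covariate
additive models are fit, averaged with Akaike weights, and covariates whose
95% unconditional CI (Buckland SE, 1.96 multiplier) overlaps zero are
excluded. Averaging is *natural* (each term averaged only over models
containing it, weights renormalized); the zero-substituted "full average"
convention would shrink every estimate toward zero by the term's summed
Akaike weight, and since each two-covariate model omits most retained
covariates, that shrinkage would be severe and arbitrary here. Non-converged
models are dropped from the set with their weights renormalized.

The null model for the 2.0-unit rule refits the random-effect variances for
each site-season rather than fixing them, so the comparison is between
maximized likelihoods of nested specifications.

## Meta-analysis

Site-level coefficients are pooled per covariate, season and group (mesic,
xeric, combined) by inverse-variance weighting. Heterogeneity uses Cochran's
$Q$, $I^2 = \max(0, (Q - df)/Q)$ in percent (binned low < 25%, moderate
25-75%, high > 75%) and the DerSimonian-Laird $\tau^2$; pooled estimates and
CIs are reported from the random-effects model (fixed-effect results are
emitted alongside), with 95% intervals driving the consistency flag and 85%
intervals provided for forest plots. Sites whose chosen scale differs are
pooled per covariate *family* name, as the pooling operates on standardized
effects per family. The test suite cross-checks every formula against
`metafor::rma` (FE and DL) at 1e-10.

## Mapping conventions

"Equivalent to a logistic transformation" is implemented as the inverse
logit of the fixed-effects linear predictor (random effects at zero); a
linear min-max stretch is available behind `hsi_method = "minmax"`. Site
HSIs are averaged cellwise with equal site weights (overlap-area weighting
was considered and rejected: it would let large buffered MCPs dominate
exactly where extrapolation is least trustworthy), relativized by the
maximum averaged value within each subregion (so each subregion's maximum is
exactly 1), multiplied across the three seasons into the annual composite,
and masked 50 m around roads, lakes and urban areas. By default the
scenario applies coefficients region-wide (the region-wide extrapolated map
convention); with `extrapolate = FALSE` cells outside every buffered MCP
stay nodata. Category bins at mean − 0.5/1/1.5 SD of the classification
values are lower-closed half-open intervals, high closed at 1, computed per
subregion from the 10% classification birds' HSI values.

The management crossing rule is configuration, not inference: the default
maps (high|moderate HSI, high AUI) to core, good-habitat/low-AUI or
low-habitat/high-AUI to priority, low/low to general, and nonhabitat to
nonhabitat, with the AUI band split at 0.25. The rule and threshold are
arguments of `management_categories()`; the defaults are illustrative of the
four named classes rather than prescriptive.

Per-category validation agreement uses $\kappa = (p - e)/(1 - e)$, the
unique chance-corrected coefficient computable from an observed share and an
areal expectation; published per-class kappas built from full confusion
matrices are not comparable and are not targets.

## The synthetic generator

The generator's job is to produce data with exactly the statistical
structure the pipeline assumes, with known truth. Continuous layers are
Gaussian-smoothed white noise on a torus (stationary to the border) with a
declared practical correlation range (the lag at which correlation falls to
0.05), mapped through the normal CDF to percent covers; land cover
thresholds a latent field; springs/streams/meadows/roads/lakes/urban are
seeded point, line and patch processes. Point features are placed over a
margin-expanded extent (2 km) so distance covariates carry no edge artifact
inside the mapped region. Used locations are drawn per bird from the site
rectangle with cell weights $\exp(\beta_{season}^\top x + b_{bird} +
b_{year})$ on globally standardized truth covariates, snapped to cell
centers so the sampling law is exactly enumerable; one location per bird-day.

The default scenario (`rsf_scenario()`) declares the study conditions:
twelve rectangular sites on one 910 x 688-cell landscape at 90-m resolution
— ten modelled sites (28 birds x 75 locations, about 2,000 locations per
site; five per subregion) and two small sites (8 x 25) that fail the
20-bird/100-location screen and become the outside-RSF validation set. The
90-m cell size with 18-km sites keeps every site large relative to both the
1,451-m availability buffer and the covariate correlation ranges
(300-700 m), which is what makes the buffered-MCP availability contrast an
approximately unbiased estimator of the generating coefficients; at desk
scale this is the regime the real multi-kilometre management units occupy.
Truth acts on herbaceous and pinyon-juniper cover at the 439.5-m radius,
exponential-decay spring proximity (1,000-m constant, the package default —
no decay constant is prescribed anywhere, so one was fixed once at the scale
of daily movements), and elevation. Herbaceous selection is +0.5 in the
mesic and −0.5 in the xeric subregion in all seasons — a deliberately
stylized sign flip so subregion grouping carries unambiguous signal —
while pinyon-juniper avoidance is stronger in the xeric subregion (−0.9
versus −0.4), matching the observed pattern that conifer avoidance
intensifies in drier regions. Random-intercept SDs are 0.3 (bird) and 0.2
(year); these cancel from the cellwise sampling law (they shift a bird's
whole utility surface by a constant), so boundary variance fits downstream
are the correct, expected outcome rather than a failure.

What the generator does *not* emulate: movement autocorrelation beyond
daily thinning, GPS fix error, seasonal range shifts within birds,
realistic Great Basin vegetation mosaics, and per-bird availability
differences. Passing recovery tests therefore demonstrates correctness of
the estimation machinery under the design's own assumptions, not robustness
to the field realities those omissions represent.

## Numerical choices

* Circular windows include cells whose center distance is <= radius (with a
  1e-9 tolerance); at the movement radii on 30- or 90-m grids no ties can
  occur. A radius of one cell therefore covers the 5-cell discrete plus.
* Focal statistics run through zero-padded FFT cross-correlation with
  nodata excluded from numerator and denominator; class-fraction numerators
  and window counts are rounded to exact integers. TPI excludes the center
  cell from the surrounding mean (the literal reading of "surrounding").
* Distances: point features are measured exactly from cell centers; line
  and patch features are rasterized and measured center-to-center with an
  exact Euclidean distance transform (`EBImage::distmap`, verified against
  brute force). Linear distances are reported in km and elevation in km so
  coefficients stay O(1).
* Buffered MCPs discretize each vertex circle at 96 points; the resulting
  area error is below the 1% tolerance the tests use against the exact
  convex-dilation formula (hull area + perimeter x buffer + pi buffer^2).
* The winter season-year label keeps 16 Oct-31 Dec with the starting year
  and assigns 1 Jan-15 Mar to the previous year, so one biological winter
  is one random-effect level.
* The 80/10/10 bird split uses largest-remainder rounding after a seeded
  shuffle: deterministic, within one bird of the targets for any n.
* Every stage takes an explicit integer seed derived from the single run
  seed by fixed offsets; equal seeds give bit-identical landscapes,
  telemetry, availability samples and fits.

## Problem sizes

The default scenario was sized so a complete pipeline run (landscape,
~21,000 locations, 30 site-season model sets of ~16 weighted GLMMs each,
meta-analysis, mapping, validation, HMI) completes in about six minutes on
one CPU, and the full test suite in roughly ten. The recovery check treats
the ~100 retained site-season coefficients of one run as its seeded
replicates — each site fit is independently seeded — comparing
model-averaged estimates against the generating truth for estimates whose
selected scale is the generating column (a mis-selected scale estimates an
attenuated projection, which is a scale-identification question, reported
separately as the selection rate, not an estimation error).

## Known limitations

* Availability beyond the true range: a buffered MCP always contains a ring
  the birds never used; on small landscapes relative to the buffer this
  biases coefficients (the package's tests run in the large-site regime
  where it does not). Real analyses share the property.
* Two-covariate model sets mean each averaged coefficient is estimated in
  the presence of at most one other covariate; with correlated predictors
  the averaged estimates become KL projections rather than partial effects.
  The |r| >= 0.65 screen limits, but does not remove, this.
* The per-category kappa is a share-versus-area agreement coefficient, not
  Cohen's multi-class kappa from a confusion matrix; the two are not
  interchangeable.
* I-squared with five sites per group is noisy; its low/moderate/high bins
  should be read as descriptive labels.
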