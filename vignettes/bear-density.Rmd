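---
title: "Dual density estimation for bears: SECR and RSF extrapolation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual density estimation for bears: SECR and RSF extrapolation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ursadens)
```

`ursadens` estimates bear density from non-invasive genetic sampling at
bait-free rub objects by two routes, and compares them: spatially explicit
capture–recapture (SECR) with covariate models on detection and density, and
a resource-selection-function (RSF) extrapolation that distributes a
reference-area abundance over habitat-quality bins. This vignette is the
package's account of the models, their assumptions, the tunable parameters,
and the design decisions taken where the methods literature leaves choices
open.

## The SECR observation model

Each animal has a latent activity center $\mathbf{x}$. A detector at
distance $d$ from that center accumulates detection hazard per occasion

$$\lambda(d) = \lambda_0 \exp\!\left(-\frac{d^2}{2\sigma^2}\right),$$

the *hazard half-normal* form, and the per-occasion detection probability is
$g(d) = 1 - \exp(-\lambda(d))$. We parameterize with $\lambda_0$ (the
cumulative hazard of detection at the center, detections per occasion)
rather than $g_0$ because hazards add across effort and relate more directly
to home-range activity. $\sigma$ (km) sets the spatial scale over which
detection declines.

Log-linear submodels structure all three parameters:

* $\ln \lambda_0$: detector type (`traptype`: rub tree / fenceline /
  opportunistic), a trap-specific behavioural step `bk` (a permanent,
  within-session change after the individual's first detection at that
  site), a linear time trend `T` (0-based occasion index), grizzly-bear
  presence on the previous occasion (`gb`), and 7-level habitat `cover` at
  the detector;
* $\ln \sigma$: `traptype`, `T`, `gb`;
* $\ln D$ over the habitat mask: land tenure (reference level = protected),
  hunter harvest, ln-distance to tertiary roads and water, canopy, NDVI,
  road density, recent burn.

The full likelihood marginalizes the activity center over a gridded habitat
mask: with per-cell density $D(\mathbf{x})$, cell area $a$,
$\Lambda = \sum_m D(\mathbf{x}_m)\,a$ and
$\bar p = \sum_m p_\cdot(\mathbf{x}_m) D(\mathbf{x}_m) a / \Lambda$ (where
$p_\cdot$ is the probability of being detected at least once, evaluated at
the naive `bk = 0` parameters),

$$-\log L = \Lambda \bar p \; - \; \sum_{i=1}^{n} \log \sum_m
\Pr(\omega_i \mid \mathbf{x}_m) D(\mathbf{x}_m)\, a \; + \; \log n!$$

for a Poisson number of centers. The binomial alternative replaces the count
term with a binomial form of continuous size $N = \Lambda$ via gamma
functions; it is selectable (`distribution = "binomial"`) and gives nearly
identical density estimates on our simulations. Poisson is the default
because it is the simpler generative match for the synthetic worlds and for
the enumeration oracle used in testing. The binomial size is mask-wide
rather than per-region; with log-link density models the distinction only
matters in the far tails.

Individuals never detected enter only through $\Lambda \bar p$; detected
histories multiply per-(detector, occasion) Bernoulli terms whose hazard
carries the individual's `bk` state (detected at that site on an *earlier*
occasion). Undetected animals have `bk = 0` throughout, which is why
$p_\cdot$ uses naive parameters.

### Mask geometry

The area of integration is a square grid of centroids at `spacing` km
(2.5 km is the field convention, and the pipeline default) including every
cell within `buffer` km of a detector. The default buffer is three times the
root pooled spatial variance of detections,

$$\mathrm{RPSV} = \sqrt{\frac{\sum_i \sum_j \left[ (x_{ij} - \bar x_i)^2 +
(y_{ij} - \bar y_i)^2 \right]}{2\left(\sum_i n_i - m\right)}},$$

pooling over the $m$ individuals with $n_i \ge 2$ detections. RPSV is only
*named* in the SECR literature we follow; the pooled-variance form above
(degrees of freedom $\sum n_i - m$, deviations about each individual's mean
detection location, the factor 2 reflecting the two coordinates) is the
standard construction and is documented here as this package's definition.
Buffers are computed per sex, since male bears range farther. When the
buffer overshoots the mapped covariate grids, `clip_mask()` restricts the
mask to mapped habitat.

Opportunistic hair samples have no fixed traps: each sample is snapped to
the centroid of a 7 × 7 km grid cell (half-open cells, configurable origin
defaulting to the extent's minimum corner), each nonempty cell becomes an
`opp` detector active only on the final occasion, and duplicate
(individual, cell, occasion) records collapse to one binary detection.
Effort within an opportunistic cell is assumed uniform.

### Fitting, model selection, and reporting

Fitting maximizes the log-likelihood on the log-link working scale with
BFGS from default starts ($\ln\sigma$ at $\ln \mathrm{RPSV}$,
$\ln\lambda_0$ at $\ln(-\ln(1-r))$ with $r$ the naive per-occasion capture
rate, $\ln D$ at $\ln(n/\text{mask area})$, other coefficients 0) plus two
jittered restarts. Convergence is BFGS's own relative-tolerance criterion
(`reltol = 1e-10`); the gradient norm at the optimum is stored in the fit
for inspection rather than enforced against a fixed threshold, because
finite-difference gradients of a likelihood of this magnitude cannot
meaningfully be driven below machine-scaled noise. Standard errors come from
the inverted numerical Hessian; a singular Hessian flags the fit and leaves
SEs absent rather than failing silently. Density CIs are lognormal,
coefficient CIs Wald. Ties in AICc go to the model with fewer parameters.

Model selection is two-step, for tractability: step 1 screens observation
models (17 default candidates) with $D \sim 1$; step 2 carries the winning
observation model and screens single-covariate density models (8 defaults,
plus $D \sim 1$ so a structured density must earn its place). AICc uses
$n$ = number of detected individuals — validated against printed
model-selection tables, e.g. $LL=-1750.67, K=8, n=126 \rightarrow 3518.57$.

Abundance within a region is the discrete sum $\sum D(\mathbf{x})\,a$ over
its mask cells; interval estimates come from 1,000 seeded multivariate
normal draws of the density coefficients from their estimated covariance.
The relative SE of expected abundance $\Lambda$ is delta-method.

## The RSF route

Rub-object surveys follow roads, trails and fencelines, so rub locations
are a biased sample of habitat. A *global placement RSF* quantifies that
bias: all rub locations (used) against 20:1 uniform random points
(available) inside the minimum convex polygon of rub objects buffered by
2.4 km (an average daily bear movement). The buffered-MCP geometry is exact:
the hull is convex, so the dilation has area
$A_{\text{hull}} + P b + \pi b^2$ and containment is a distance test.

Sex-specific RSFs then compare detector locations where a sex was detected
(used) with the full detector array (available), an exponential RSF
$w(\mathbf{x}) = \exp(\beta_1 x_1 + \dots + \beta_n x_n)$ fitted by
logistic regression with continuous covariates standardized on the pooled
design (constants stored and reapplied at prediction; the intercept is
excluded from the score as it only encodes the sampling ratio). AIC picks
among candidate formulas. The 11 default candidates (`rsf_candidates()`)
are a documented, configurable set over the synthetic covariates — they are
deliberately *not* a claim about any published candidate set, whose
formulas live outside the main methods literature we re-implement.

Scores over cells are scaled by their maximum into $(0,1]$ — max-scaling
makes every later quantity invariant to constant rescaling of the raw
scores — and cut into 10 equal-width bins with midpoints
$w(x_i) = 0.05, 0.15, \dots, 0.95$. Equal-width (not quantile) bins were
chosen because the bin midpoint then estimates a relative probability of
use, which the extrapolation formula requires; this choice is flagged as a
convention. The lowest three bins are dropped from the area of inference
when a natural break separates rarely used habitat (the default
`drop_lowest = 3` is configurable).

With bin areas $A(x_i)$, relative probability of use
$$U(x_i) = \frac{w(x_i) A(x_i)}{\sum_j w(x_j) A(x_j)},$$
a reference area assumed at carrying capacity with abundance $\hat N$
(reference density × reference area; defaults per sex from an independent
park estimate: males 48.3/1,000 km², 95% CI 40.2–57.3; females 72.3, 95% CI
60.3–87.5) distributes as $\hat N_i = \hat N U(x_i)$, giving bin densities
$\hat D_i = \hat N_i / A(x_i)$ inherited by every target cell of that bin.
Interval surfaces substitute the reference CI bounds for $\hat N$ — the
extrapolation inherits *only* the reference estimate's uncertainty, not the
RSF's, a known limitation of the method.

Predictive ability is assessed by k-fold cross-validation (10 folds × 10
repeats by default): refit on training folds, re-bin, and compute
Spearman's rank correlation between bin rank and the frequency of withheld
used points per bin, averaged as $\bar r_s$. Frequencies are area-adjusted
before ranking (the bins have very unequal areas; `area_adjust = FALSE`
gives raw frequencies). Note that when withheld points concentrate in few
bins the remaining bins tie at zero and the attainable $\bar r_s$ is well
below 1 even for a perfect model; $\bar r_s$ is a comparative, not an
absolute, score.

## The synthetic world

The generator produces the structures the analysis assumes, under known
parameters, so every estimator can be tested for recovery:

* a planar rectangular landscape (km, Euclidean distances, no CRS — the
  geometry of the problem is planar and CRS handling is out of scope),
  gridded at 2 km, with a contiguous three-band tenure mosaic (private /
  Crown / protected at 0.52 / 0.34 / 0.14, the study-area shares), a smooth
  0–1 productivity field (NDVI analog), canopy 0–100, one circular recent
  burn, block-wise constant harvest density that is zero on protected land,
  ln-distances to synthetic road and stream segments, and road density in a
  7-km radius;
* rub and fence detectors placed with optional bias toward the linear
  features (as real rub surveys are), opportunistic detectors tiling the
  extent at 7-km centroids, active only on the last occasion; fence
  detectors are treated as points, since no discretization convention for
  fence lines into detectors is established;
* activity centers from an inhomogeneous Poisson process with cell-wise
  log-linear intensity (Poisson, not fixed-N: the simplest process
  consistent with a log-linear intensity; the fitter supports both count
  distributions);
* binary detections per (animal, detector, occasion) from the same hazard
  half-normal model the fitter assumes, with trap-type/time/grizzly effects
  and a permanent within-session `bk` step; animals with empty histories
  are dropped but counted in attributes.

Everything is a deterministic function of configuration plus seed.

What the generator does *not* emulate: genotyping error and partial
individual identification, home-range drift and closure violation across a
long season, non-Euclidean space use, realistic road networks, multi-year
dynamics. Passing recovery tests therefore demonstrates correctness of the
estimator under its own assumptions — not robustness to the ways real
hair-snag data violate them.

## Numerical choices and problem sizes

* Likelihood evaluation is vectorized over a (detector × occasion) × cell
  hazard matrix; `log(1-p) = -λ` keeps the survivor terms exact, and
  `log(-expm1(-λ))` is used for detection terms. Non-finite likelihoods are
  returned as a large barrier value to the optimizer.
* Simulation studies in the test suite use desk-scale designs chosen as the
  smallest that make the statistical claims meaningful: homogeneous-density
  recovery uses 100 traps × 7 occasions at $D = 0.05$ bears/km²,
  $\lambda_0 = 0.1$, $\sigma = 2$ km over 50 replicates (mask spacing
  2.5 km); selection consistency uses 20 replicates of a 36 × 36 km
  landscape with log-density tenure contrasts of $-1$ (Crown) and $-0.45$
  (private) relative to protected — the magnitudes the field study itself
  estimated — a trap-type detection contrast, uniformly placed detectors,
  and surveys sized to detect on the order of 140 individuals; the
  end-to-end fixture uses a 28 × 28 km world, 45 systematic detectors and
  5 occasions.
* The σ–λ₀ compensation property is demonstrated on a dense,
  near-saturated array, the regime in which the trade-off provably leaves
  density almost untouched; on sparse arrays density does react to a forced
  σ, which is why the package never fixes σ in ordinary fits.
* Degenerate inputs fail loudly by design: no multi-detection individual
  (RPSV undefined), detections where usage is zero, mask cells without
  covariate values, complete separation or rank deficiency in RSF designs,
  all-zero RSF scores, AICc with $n \le K + 1$.

## A short tour

```{r tour, eval = FALSE}
cfg <- run_config(
  sim = sim_config(extent = c(28, 28), spacing = 2, n_rub = 35, n_fence = 10,
                   opp_cell_size = 7, n_occasions = 5, seed = 11),
  truth = list(
    F = true_params(beta_d = c("(Intercept)" = log(0.10)),
                    lambda0 = 0.4, sigma = 2, sex = "F"),
    M = true_params(beta_d = c("(Intercept)" = log(0.08)),
                    lambda0 = 0.4, sigma = 2.5, sex = "M")),
  mask_spacing = 2, seed = 5)
res <- run_pipeline(cfg, out_dir = "run1")
res$report          # SECR and RSF densities side by side, per sex x tenure
res$sex_ratios      # F/M abundance ratios per region and method
autoplot(res$secr$F$best_fit)
plot_method_comparison(res$report)
```

## Known limitations

* The SECR likelihood is single-session; multi-year data are analysed
  year by year (as the motivating study did), not with open-population
  models.
* RSF extrapolation intervals ignore RSF-coefficient uncertainty.
* The opportunistic occasion inherits the hazard model with its own trap
  type and uniform within-cell effort; if real opportunistic effort is
  spatially structured within cells, $\lambda_0^{\text{opp}}$ absorbs it
  only on average.
* `bk` resets between sessions and is permanent within one; transient
  behavioural responses are not modelled.
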