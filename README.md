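# ursadens

Density estimation for bears from non-invasive genetic sampling at
bait-free rub objects, by two complementary routes:

1. **Spatially explicit capture–recapture (SECR)** with a hazard
   half-normal detection function, full likelihood, covariate models on
   detection and density, two-step AICc model selection, density-surface
   prediction and region abundance by discrete summation.
2. **Resource-selection-function (RSF) extrapolation**: used–available
   logistic regression, 10-bin reclassification of scaled RSF scores, and
   distribution of a reference-area abundance over bins by relative
   probability of use.

The package is aimed at wildlife biologists and quantitative ecologists who
want both estimators, and the comparison between them, in one tidy,
scriptable workflow — plus a synthetic-data module that simulates
landscapes, detector arrays and capture histories with known parameters, so
every estimator ships with recovery tests.

## The models in brief

**SECR.** An animal with activity center $x$ is detected at a detector at
distance $d$ on one occasion with probability
$g(d) = 1 - \exp(-\lambda(d))$, where
$\lambda(d) = \lambda_0 \exp(-d^2 / 2\sigma^2)$ is the cumulative detection
hazard. Log-linear submodels act on $\lambda_0$ (trap type, a trap-specific
behavioural step `bk`, a time trend `T`, grizzly presence `gb`, habitat
cover), on $\sigma$, and on density $D$ over a gridded habitat mask
(buffer = 3 × RPSV of the detections, 2.5-km spacing by convention). The
full likelihood marginalizes activity centers over the mask with either a
Poisson or binomial number of centers; model selection uses
$\mathrm{AICc} = -2LL + 2K + 2K(K+1)/(n-K-1)$ with $n$ = detected
individuals. Abundance per land-tenure region is $\sum D(x)\,a$ over the
region's mask cells.

**RSF.** An exponential RSF
$w(x) = \exp(\beta_1 x_1 + \cdots + \beta_n x_n)$ is fitted by logistic
regression of used vs available covariate rows (continuous covariates
standardized). Scores are max-scaled into $(0,1]$, cut into 10 equal-width
bins with midpoints $w(x_i)$ and areas $A(x_i)$, and the relative
probability of use is $U(x_i) = w(x_i)A(x_i) / \sum_j w(x_j)A(x_j)$. A
reference area assumed at carrying capacity, with abundance $\hat N$,
yields bin abundances $\hat N_i = \hat N U(x_i)$ and densities
$\hat N_i / A(x_i)$ extrapolated across the area of inference; k-fold
Spearman cross-validation ($\bar r_s$) scores predictive ability.

See the methods vignette (`vignettes/bear-density.Rmd`) for assumptions,
parameter defaults and design decisions.

## Worked example

Simulate a two-sex world, run both estimators end to end, and compare:

```r
library(ursadens)

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
dplyr::filter(res$report, method == "SECR")
#> # A tibble: 6 × 10
#>   method sex   region     area N_hat    lo    hi density lo_density hi_density
#>   <chr>  <chr> <chr>     <dbl> <dbl> <dbl> <dbl>   <dbl>      <dbl>      <dbl>
#> 1 SECR   F     crown       280 27.2  19.0   38.8    97.2       67.7       139.
#> 2 SECR   F     private     384 37.3  26.0   53.3    97.2       67.7       139.
#> 3 SECR   F     protected   104 10.1   7.04  14.4    97.2       67.7       139.
#> 4 SECR   M     crown       280 25.6  18.3   35.5    91.4       65.5       127.
#> 5 SECR   M     private     384 35.1  25.1   48.7    91.4       65.5       127.
#> 6 SECR   M     protected   104  9.51  6.81  13.2    91.4       65.5       127.
```

Each row is one (method, sex, tenure) cell: `N_hat` is abundance from
summing the fitted density surface over that tenure's mask cells (`lo`,
`hi` from 1,000 coefficient draws), and `density` is per 1,000 km². Here
the selected female model was homogeneous (`D ~ 1`), so the three female
densities coincide; the generating female density was 100 bears/1,000 km²
and the fit recovers 97.2 (95% CI 67.7–139).

```r
res$sex_ratios
#> # A tibble: 5 × 3
#>   method region    ratio
#>   <chr>  <chr>     <dbl>
#> 1 RSF    crown       1.5
#> 2 RSF    private     1.5
#> 3 SECR   crown       1.1
#> 4 SECR   private     1.1
#> 5 SECR   protected   1.1

glance(res$secr$F$best_fit)
#> # A tibble: 1 × 9
#>   model        distribution     n     K logLik  AICc Lambda   rse converged
#>   <chr>        <chr>        <int> <int>  <dbl> <dbl>  <dbl> <dbl> <lgl>
#> 1 D~1 l0~1 s~1 poisson         33     3  -397.  802.   74.7 0.192 TRUE
```

`sex_ratios` are female/male abundance ratios per region (the generating
F:M density ratio was 0.10/0.08 = 1.25). `glance()` gives the one-row fit
summary: 33 detected females, expected abundance 74.7 on the female mask,
relative SE 19%. `tidy()`, `autoplot()`, `plot_density_surface()` and
`plot_method_comparison()` work on the fitted objects. All artifacts
(detectors, captures, masks, surfaces, model tables, bin tables, GeoJSON
MCP, run log) are written to `out_dir` and are bit-stable for a given
config and seed.

Lower-level entry points: `rpsv()`, `build_mask()`, `attach_covariates()`,
`grid_opportunistic()`, `fit_secr()`, `run_two_step()`,
`predict_density()`, `region_abundance()`, `mcp_buffer()`,
`sample_available()`, `fit_rsf()`, `select_rsf()`, `bin_scores()`,
`expected_use()`, `extrapolate_density()`, `kfold_cv()`.

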