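---
title: "Statistical methods for grass leaf silicification analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for grass leaf silicification analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grassSi)
```

grassSi implements the statistical machinery for analysing grass leaf
silicon concentrations measured in globally replicated grassland
experiments that cross full NPK fertilisation with grazer-exclusion
fencing across sites spanning wide precipitation (365–1,898 mm/yr) and
temperature (0.3–22.1 °C) gradients. This vignette explains the models,
the synthetic-data generator that stands in for field data, the
numerical choices, and what the package's simulation experiments do and
do not establish.

## The mixed model

Leaf Si (% dry weight) is strongly right-skewed, so all models use the
natural log as the response (any fixed log base is equivalent up to
scaling of coefficients). The workhorse is the random-intercept linear
mixed model

$$\log \mathrm{Si}_{ij} = \mathbf{x}_{ij}^\top\beta + \alpha_j +
\varepsilon_{ij}, \qquad \alpha_j \sim N(0, \sigma^2_\alpha), \quad
\varepsilon_{ij} \sim N(0, \sigma^2_\varepsilon),$$

with a site random intercept $\alpha_j$ and fixed effects drawn from
the treatment flags (NPK, FENCE) and site covariates (MAP, MAT, PET,
sand, pH, organic matter, soil C, soil N, grazing index).
`fit_lmm()` maximises the restricted (default) or full likelihood by
profiling: given the variance ratio $\lambda =
\sigma^2_\alpha/\sigma^2_\varepsilon$, the GLS coefficients and the
residual variance have closed forms via the blockwise identity
$(I + \lambda J)^{-1} = I - \tfrac{\lambda}{1+\lambda n_j}J$, so the
optimisation is one-dimensional in $\log\lambda$ (`optimize()` over
$[-20, 13]$, with the boundary $\sigma^2_\alpha = 0$ checked
explicitly). The implementation agrees with `lme4::lmer` to at least
six decimals in coefficients, variance components and log-likelihood on
shared fixtures, and with an independent dense-matrix 2-D grid-search
oracle to $10^{-4}$ log-likelihood units; both checks are in the test
suite.

Conventions worth stating:

* **AIC always comes from the ML criterion** (the model is refitted by
  ML when coefficients are reported from REML), because candidate
  models differ in fixed effects. The parameter count is intercept +
  fixed terms + the two variance components.
* **Coefficient p-values** use residual degrees of freedom $n - p$;
  this is approximate (no Satterthwaite correction) and is documented
  as such.
* **Adjusted (least-squares) treatment means** are model predictions at
  each factor level with every other term at its observed average,
  back-transformed by plain exponentiation — i.e. geometric means on
  the concentration scale, with no lognormal bias correction — and
  delta-method standard errors.
* **Nakagawa–Schielzeth R²** takes $\sigma^2_f$ as the variance of the
  fixed-effect linear predictor over the observed design:
  $R^2_m = \sigma^2_f / (\sigma^2_f + \sigma^2_\alpha +
  \sigma^2_\varepsilon)$, and $R^2_c$ adds $\sigma^2_\alpha$ to the
  numerator.

Diagnostics follow standard practice: composite-hypothesis
Anderson–Darling normality (via nortest) and a Cook–Weisberg score test
for variance increasing with the fitted values (half the regression sum
of squares of squared standardised residuals on fitted values, referred
to $\chi^2_1$); the latter matches `car::ncvTest` exactly on `lm`
fixtures.

## Multimodel inference

`enumerate_candidates()` builds all subsets of the supplied main
effects (the intercept-only model is always a candidate) plus
whitelisted pairwise interactions, each interaction entering only
alongside both parents. `rank_models()` sorts by AIC and computes
$\Delta_i$ and Akaike weights $w_i = e^{-\Delta_i/2} / \sum_j
e^{-\Delta_j/2}$ **over exactly the set supplied** — the caller decides
whether weights refer to a full candidate set or a reported subset,
which matters when comparing against published tables whose weights
were computed over a larger unpublished set. Models with $\Delta < 2$
are flagged equivalent to the best; $\Delta > 7$ flags poor fit. AIC
ties break by fewer parameters, then model string.

## Threshold detection by regression tree

`grow_tree()` is a CART regression tree: greedy binary splits minimise
pooled within-node SSE, thresholds sit at midpoints between adjacent
sorted predictor values, and growth stops at `min_leaf` (default 7) or
when the relative SSE improvement, scaled by the root SSE, falls below
`cp_min` (default 0.01) — the rpart complexity-parameter convention.
Equal-gain ties break to the lowest predictor index, then the smallest
threshold. `prune_one_se()` computes the weakest-link cost-complexity
sequence, estimates each nested tree's error by k-fold cross-validation
(default 10 folds; fold assignment by seeded shuffling stratified by
site; each nested tree evaluated at the geometric mean of its cp
interval, the root at infinity), and selects the smallest tree whose CV
error is within one standard error of the minimum. The first split is
verified against a brute-force exhaustive-split oracle in the tests,
and first splits agree with rpart under shared settings.

Soil N enters the tree at the plot level when a plot-level `soil_n`
column is present (the generator emits one; soils in the emulated
design are measured per plot), otherwise the site value is used.

## The stoichiometric dilution null

Element concentrations are percentages of a closed composition, so any
increase in %C mechanically dilutes every other element. To ask whether
the Si ~ C slope is steeper than closure alone predicts,
`dilution_test()` replaces each sample's focal concentration with the
concentration of one of the five nonfocal elements of the same sample,
drawn uniformly and independently per sample, refits the same
random-intercept model of the response on %C, and repeats this R times
(default 999) to build a null slope distribution. Empirical p-values
use the add-one correction $p_\mathrm{lower} = (1 + \#\{b_\mathrm{null}
\le b_\mathrm{obs}\})/(R+1)$; the lower tail is the trade-off
direction, and both tails are reported. The observed slope is fitted on
the raw % scale by default (a `log_focal` flag is available). Null
replicates are fitted by a vectorised profile-REML path that shares the
design across replicates (a fixed log-ratio grid with parabolic
refinement, then an exact GLS solve per replicate); it matches the
one-at-a-time fitter to ~1e-4 on shared responses, far below the null
distribution's spread. Samples are canonically ordered internally, so
results do not depend on row order.

Two properties of this published procedure deserve emphasis:

* **Its null is exchangeability.** When the focal element truly follows
  the same dilution law as the nonfocal elements, the observed slope is
  one more draw from the null and p-values are uniform (verified by a
  KS test across seeded replicates).
* **It is anti-conservative under unequal element means.** The closure
  slope of an element is proportional to its own mean concentration,
  while the null distribution is centred on the *average* nonfocal
  slope. An element whose mean concentration exceeds the nonfocal
  average (leaf N or K against P, Ca, Mg, for instance) therefore
  rejects in the lower tail at well above the nominal rate even with no
  trade-off — in our simulations at realistic foliar means, roughly
  20% at $\alpha = 0.05$ with ~160 samples, worsening with sample
  size. The package implements the procedure as published rather than
  replacing it with a log-ratio analysis; calibration experiments
  therefore use the exchangeable configuration
  (`scenario_config("dilution_closure")`), and interpretation of
  single-element results on real data should bear this bias in mind.

## Per-site slopes and precipitation

`site_slopes()` fits ordinary least squares of raw %Si on %C within
each site (sites need at least 3 usable samples and non-constant C);
`slope_vs_map()` regresses those slopes on site MAP (or MAT/PET). A
positive MAP coefficient means the negative arid-site trade-off decays
toward zero with increasing precipitation. Second-stage inference
ignores first-stage estimation error by default, matching the approach
the package emulates; an inverse-variance weighted mode is provided as
an extension and reduces to OLS under equal slope SEs.

## Chemometric calibration

`kennard_stone()` is the deterministic max–min algorithm on Euclidean
distances between mean-centred spectra: start from the most distant
pair, repeatedly add the sample maximising its minimum distance to the
selected set. Ties break to the lowest sample index (published
implementations differ here, so the rule is explicit). `fit_pls()` is
NIPALS PLS1 on centred spectra; validation R² is the squared Pearson
correlation of predicted versus reference values (a 1 − SSE/SST variant
is available). PLS at full rank reproduces OLS predictions, and the
one-component coefficient matches its closed form, both under test.

`simulate_spectra()` builds NIR-like spectra from three latent
Beer–Lambert components (Gaussian absorption profiles, lognormal
concentrations) plus a random smooth baseline and instrument noise; the
reference concentration is linear in the latent amounts plus lab error.
One subtlety: a max–min calibration split removes the spectral extremes
from the validation pool, which retains only about two thirds of the
signal variance. The lab-error SD is therefore calibrated against that
restricted variance (restriction factor 0.67, measured once for this
concentration model at a 20% split), so the tuning target — external
validation R² ≈ 0.83 — refers to the quantity the
Kennard–Stone-then-validate pipeline actually reports.

## The synthetic-data generator

`generator_config()`/`generate_dataset()` emulate the study design: by
default 17 sites with MAP ~ U(365, 1898) mm and MAT ~ U(0.3, 22.1) °C,
2–5 blocks per site, the 2×2 NPK × FENCE factorial within each block,
one pooled grass sample per plot (the design's implied sampling unit).
Site covariates are drawn with simple dependencies (PET rising with
MAT, soil C ≈ 11 × soil N, organic matter from soil C); plot soil N
jitters around the site value (SD 0.02%).

Leaf Si is generated on the log scale:

$$\log \mathrm{Si} = \mu_0 + \beta_\mathrm{soilN}(\mathrm{N}_p -
\bar{\mathrm{N}}) + s\,[\mathrm{N}_p > \tau] + g(\alpha_j +
\varepsilon) + g\,\beta_\mathrm{NPK}\,\mathrm{npk} +
b(\mathrm{MAP})(C - \bar{C}),$$

then exponentiated and, like every other element, multiplied by the
closure factor $(100 - C)/(100 - \bar{C})$ so that rising leaf C
passively dilutes all constituents. The pieces and their defaults:

* $\mu_0 = \log 1.72$: control-plot geometric mean Si of 1.72% dw.
* $\beta_\mathrm{NPK} = -0.49$: the fertilisation effect on log Si.
* $b(\mathrm{MAP}) = -0.1486 + 7.83 \times 10^{-5}\,\mathrm{MAP}$: the
  within-site Si~C trade-off, ≈ −0.12 log-Si per %C at 365 mm and ≈ 0
  at 1,898 mm.
* Soil-N structure: a linear decline ($\beta_\mathrm{soilN} = -1.1$ per
  % N, centred) **plus a drop of $s = -0.65$ above the threshold $\tau =
  0.43\%$**, with the attenuation factor $g = 0.2$ multiplying the NPK
  effect, the site intercept and the residual at sites above $\tau$.
  The step deserves a note: attenuating a negative NPK effect *raises*
  the pooled mean above the threshold, partially cancelling the linear
  decline, and a purely linear trend puts a CART split near the middle
  of a uniform gradient rather than at the threshold. The pattern being
  emulated — Si varying widely right up to the threshold and sitting
  uniformly low and invariant above it — is a genuine mean
  discontinuity, which the step encodes explicitly.
* $\sigma_\alpha = 1.2$, $\sigma_\varepsilon = 0.85$ on log Si. With
  the defaults above, the NPK + soil N model's $R^2_m/R^2_c$ average
  about 0.23/0.67 at 17 sites, and the NPK coefficient's SE is ≈ 0.11 at the
  default design size (~240 plots) — the regimes the recovery
  experiments target.
* Macronutrients N, P, K, Ca, Mg: lognormal site and sample variation
  (SDs 0.25/0.35) around baseline means 1.5, 0.15, 1.5, 0.4, 0.2% dw,
  all times the closure factor.
* Leaf C ~ U(38, 48)% per sample.

Closure (element sum < 100%) is enforced by redrawing the stochastic
parts of any offending sample from the same RNG stream; if an extreme
site intercept alone makes closure impossible (possible in principle
with lognormal site effects, vanishingly rare under the defaults), the
site intercept is redrawn as well. Generation stays seed-stable; with
the default composition redraws essentially never trigger. Identical seeds give byte-identical tables.

What the generator does **not** emulate: species identities and
composition shifts, spatial structure within blocks, correlated climate
covariates beyond the simple dependencies above, measurement error in
the covariates, and missing data. Passing recovery tests on these data
shows the estimators and algorithms are correct and calibrated under
the design's assumptions, not that real field data satisfy those
assumptions.

## Scenario configurations and problem sizes

`scenario_config()` freezes the configurations used by the package's
standard simulation experiments (and by `scripts/acceptance.R`), chosen
from design-time power calculations:

* `npk_recovery` / `adjusted_means`: the default design with the soil-N
  attenuation disabled — these experiments probe the estimator, so the
  threshold mechanism that deliberately biases the pooled NPK effect is
  switched off. Adjusted-mean truth: control 1.72% dw, +NPK 1.27% dw.
* `tree_threshold`: 40 sites × 2 blocks. A 17-site gradient leaves
  adjacent-site soil-N spacings of ~0.05%, too coarse for a ±0.05
  threshold readout no matter how exact the tree; the denser gradient
  makes the experiment measure the algorithm rather than the grid.
  Small site effects (σ = 0.3) keep the threshold dominant.
* `dilution_closure` / `dilution_tradeoff`: 10 sites × 4 blocks with
  all six elements exchangeable (equal means, shared dilution law);
  the trade-off variant injects $b = -0.12 + 5 \times
  10^{-5}\,\mathrm{MAP}$ on Si only. Null distributions use R = 199 in
  the replicated rate experiments and R = 999 for single-dataset
  checks.
* `aridity_slopes`: 17 sites × 5 blocks with moderate noise
  (σ_site = 0.2, σ_resid = 0.3) so the second-stage MAP coefficient is
  detectable at the ≈ 0.9 power the experiment asserts.

Replication counts (100–200 replicates per experiment) keep the whole
suite within a few minutes on one CPU while holding Monte-Carlo error
on the asserted rates to a few percent.

## Known limitations

* Only a single site random intercept: no random slopes, no nested or
  crossed random effects (the species-level analysis that would need a
  second grouping factor is out of scope).
* p-values for fixed effects use the residual-df approximation.
* The dilution null is implemented as published; its unequal-means
  anti-conservativeness is documented above rather than corrected.
* The tree handles numeric predictors only — no surrogate splits,
  missing-value handling, or classification.
* PLS is single-response (PLS1) with mean-centring only; no SNV or
  derivative preprocessing.
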