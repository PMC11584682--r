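---
title: "Modelling powder blend properties from raw-material data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling powder blend properties from raw-material data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(powdermix)
```

## The problem

Formulating a tablet means blending an active pharmaceutical ingredient
(API) with excipients, and the blend's bulk behaviour — how fine it is, how
elongated its particles are, how densely it packs, and above all how well
it flows — decides whether it can be manufactured robustly. Measuring these
properties for every candidate blend consumes material and shear-cell time.
`powdermix` predicts them instead, from quantities measured once per raw
material: the number-based particle size distribution (PSD), the
aspect-ratio distribution (ARD), and the true and bulk densities, plus the
recipe (mass fractions).

The pipeline is hybrid. Distributions and densities mix analytically;
tapped density and the flow function coefficient (FFC) — for which no
usable mechanistic rule exists — are regressed on features derived from the
analytic predictions, so the whole chain still runs on raw-material data
alone.

## The probabilistic distribution mixture model

A blend's number-based PSD is a finite mixture of the component PSDs,

$$n_{\mathrm{mix},i} = \sum_{j=1}^{K} \lambda_j\, n_{j,i},
  \qquad \sum_j \lambda_j = 1,$$

where $\lambda_j$ is the probability that a particle picked from the blend
belongs to component $j$. Modelling particles as spheres of diameter
$d_{j,i}$ (with a per-component shape correction factor $\varphi_j$
absorbing the error of that assumption), the particle count of component
$j$ is proportional to its bulk volume divided by a mean per-particle
volume, which gives

$$\lambda_j \propto \frac{C_j}{\rho_{t,j}\,\varphi_j}
  \sum_{i} \frac{1}{d_{j,i}^{3}},$$

with $C_j$ the mass fraction and $\rho_{t,j}$ the true density. Two
readings of the size sum coexist:

* **default** — the unweighted sum $S_j = \sum_i 1/d_{j,i}^3$ over the
  size classes the component actually occupies ($n_{j,i} > 0$), i.e. the
  classes an instrument would export for that material. Summing over an
  entire shared grid instead would make $S_j$ identical for every
  component and erase the size information entirely, which is clearly not
  the model's intent.
* **frequency-weighted** (`use_frequency_weighting = TRUE`) —
  $S_j = \sum_i n_{j,i}/d_{j,i}^3$, the reading in which the mean particle
  volume is averaged over the component's own distribution. For components
  with full support on a shared grid the default degenerates to
  mass-over-volume weights and this variant is the one that retains size
  sensitivity; both are exposed and tested.

The ARD mixes the same way but with weights
$w_j \propto C_j/\rho_{t,j}$ — the component's solid volume share. We
normalize the weights so the mixed ARD is again a frequency distribution;
without the normalizer the output would not sum to one.

`convert_basis()` moves between number- and volume-based distributions via
the cube law $v_i \propto n_i d_i^3$; the round trip is the identity to
numerical precision.

### Shape correction factors

$\varphi_j$ defaults to 1 and is fitted per mixture for selected
components (`fit_shape_correction()`) by Levenberg–Marquardt least squares
(via `minpack.lm`), minimising the RMSE between predicted and measured
blend PSD. The factor is parameterized as $\varphi = e^{\theta}$ so it
stays positive without box constraints, started at $\varphi = 1$.
Non-convergence is reported in the result (`converged = FALSE`), not
thrown.

### Percentiles

Percentiles (D10/D50/D90) interpolate the cumulative curve linearly over
class midpoints using the mid-mass convention: class $i$ carries
cumulative mass $\mathrm{cum}_i - f_i/2$ at its midpoint, and only
non-empty classes are interpolation nodes. This makes a monodisperse
distribution return its single class value for every $q$, and a symmetric
two-class distribution on $(1, 2)\,\mu m$ return $D50 = 1.5\,\mu m$.
Queries beyond the first/last node clamp to that node (leftmost class on
flat segments). The mass-weighted average of component percentiles
(`baseline_percentile_mixture()`) is retained as the classic comparator.

### Regridding

Mixing requires one shared grid. `regrid()` interpolates the cumulative
distribution at the source class edges onto the target class edges and
differences. This is exact overlap integration for a piecewise-uniform
density; it is lossless exactly when the target class edges are a subset
of the source edges (or vice versa), e.g. when a fine uniform grid
subdivides a coarse one. For non-nested grids the kinks of the piecewise
linear cumulative fall between nodes and the round-trip error is of the
order of the local density change times the fine class width (about
$10^{-4}$–$10^{-3}$ for 1001 log-spaced classes) — adequate for
harmonising instrument exports, and the reason harmonization is an
explicit, logged step rather than something done silently on read.

## Density mixture rules

True density obeys a mass balance: converting mass fractions to volumes
gives the mass-weighted harmonic mean
$\rho_{t,\mathrm{mix}} = \left(\sum_j C_j/\rho_{t,j}\right)^{-1}$
(the reference rule), with mass-weighted arithmetic and geometric means as
comparators — always ordered harmonic $\le$ geometric $\le$ arithmetic.
Bulk density has no exact balance; the mass-weighted arithmetic mean is
the reference, with mass-and-true-density-weighted and
particle-volume-weighted alternates. `compare_density_rules()` ranks rules
by RMSE/R² against measurements.

## Feature space and regressors

The 1001-class predicted distributions are compressed by PCA
(`fit_distribution_pca()`): column-mean centering only, no variance
scaling — all classes already share one normalized frequency scale, and
scaling would inflate empty tail classes. Loading signs are fixed so each
loading's largest-magnitude element is positive, making score files
platform-reproducible. Three components are retained by default.

Feature layouts are fixed per target:

| target | features |
|---|---|
| tapped density | PSD PC1–3, ARD PC1–3, $\rho_{t,\mathrm{mix}}$, $\rho_{b,\mathrm{mix}}$ |
| FFC | PSD PC1–3, $\rho_{t,\mathrm{mix}}$, $\rho_{b,\mathrm{mix}}$, consolidation pressure $P_c$ |

Shape scores are excluded from the FFC model, having shown only marginal
influence on flowability.

### Response scaling

FFC spans roughly 1–35 but its decision-relevant structure is near the
flow-class boundaries (cohesive $<4 \le$ easy-flowing $<10 \le$
free-flowing). Training uses

$$u = 1 - 2^{-y/\beta}, \qquad \beta = 4,$$

which maps $[0,\infty)$ onto $[0,1)$ with the cohesive boundary $y = 4$ at
exactly $u = 0.5$: cohesive and non-cohesive powders each occupy half the
scaled domain and carry comparable weight in the squared loss. Predictions
are clipped to $u \le 1 - 10^{-9}$ (FFC $\approx 120$ at $\beta = 4$)
before the inverse $y = -\beta \log_2(1-u)$, keeping them finite.
Tapped-density responses train untransformed.

### Families, splitting, validation

Four families share one training surface: random forest
(`randomForest`, 500 trees), classic gradient boosting and
regularized extreme gradient boosting (both on the `xgboost` backend —
the classic configuration disables the regularization penalty and
subsampling and uses depth-3 trees at learning rate 0.05, the extreme
configuration keeps them), and RBF support-vector regression (`e1071`,
standardized features). Defaults are deliberately plain; the comparison
harness, not the defaults, is the contract, and everything is overridable
via `hyperparameters`.

Splitting is always grouped by formulation (`split_by_formulation()`):
all pressure replicates of a blend travel together, so test blends are
genuinely unseen recipes. `leave_api_out_cv()` goes further, holding out
every blend sharing an API identity, which probes transfer to a chemically
new active. Fold RMSEs are reported on the scaled $u$ domain (where the
loss lives) and on the FFC scale, both labelled, since the two are not
comparable.

## Uncertainty quantification

Two interval constructions:

* **Ensemble interval** — for a random forest, the point prediction is
  the mean of the per-tree predictions and the standard error is
  $E_s = \sqrt{\operatorname{Var}(\text{trees}) + \mathrm{MSE}}$, with the
  population variance (divide by the number of trees) and the forest's
  out-of-bag MSE as the residual-variance estimate;
  $\gamma = \hat y \pm Z_{1-\alpha/2} E_s$.
* **Leverage interval** — the regression prediction interval
  $\hat y \pm t_{\alpha/2,\,n-1}\, S \sqrt{1 + 1/n + h(x)}$ with leverage
  $h(x) = (x-\bar X)\, S_{XX}^{-1} (x-\bar X)^{\top}$ computed from the
  unbiased training-feature covariance (Moore–Penrose pseudo-inverse with
  a warning when singular). The degrees of freedom are exposed explicitly
  through `n`.

The relative standard deviation, RSD = interval width / point prediction,
flags predictions in data-sparse regions: leverage grows with Mahalanobis
distance from the training mean, which is why free-flowing powders —
rarer in typical datasets — come back with wider, less certain intervals.
For FFC the interval is built on the $u$ domain and both bounds are mapped
back through the monotone inverse transform, preserving coverage.

## The synthetic data generator

No public blend dataset with this characterisation depth exists, so
`generate_blend_dataset()` emulates one: log-normal number-based PSDs
discretized on a log-spaced 1001-class grid over 0.5–500 µm (log-spacing
mirrors optical-microscopy size classing), beta-shaped ARDs on (0, 1],
true densities uniform in 1.29–1.97 g/cm³, bulk in 0.33–0.69 g/cm³, and
five consolidation pressures spanning 0.79–13.26 kPa. Blends cycle through
placebo and four APIs at 5–50 % drug loading with 2–3 fillers.

Mixture PSDs, ARDs and densities are ground-truthed by the package's own
forward models with known shape factors — bit-exact self-consistency is
what makes the φ-recovery and regression-recovery tests meaningful.
Tapped density and FFC have no analytic truth, so they come from declared
response models whose only contract is smoothness, positivity and
flow-class coverage:

* tapped $= \rho_b / (0.8 + 0.002\, D50 + \varepsilon)$,
  $\varepsilon \sim N(0, 0.01)$;
* FFC $= 1.2\sqrt{D50} + 1.1 P_c + 12\,\rho_b/\rho_t - 8.5$, floored at
  0.3, plus $N(0, \sigma)$ with $\sigma = \mathrm{sd}(\text{signal})/\mathrm{snr}$
  (default snr = 5). The coefficients were set once from the analytic
  ranges of the three terms so that the five default pressure levels sweep
  a typical blend across all three flow classes.

What the generator does **not** emulate: instrument artefacts
(agglomerates, dispersion-pressure effects), inter-component interactions
(the forward model is exactly the package's own mixture model, so tests
confirm internal consistency, not the physics of real blending), and
measurement-replicate structure. Passing recovery tests therefore shows
the pipeline is implemented correctly and identifiable at realistic noise,
not that real blends obey these equations.

## Numerical choices and degenerate inputs

* Frequencies must sum to 1; raw sums within $10^{-3}$ of 1 (instrument
  rounding) are silently renormalized, larger deviations are refused.
* Strictly positive, strictly increasing grids are enforced; aspect-ratio
  midpoints must lie in (0, 1].
* Membership weights require at least one positive mass fraction and
  positive diameters; pure formulations reproduce the component
  distribution bit-exactly.
* Percentile ties on flat cumulative segments resolve to the leftmost
  class value.
* A constant measured vector makes R² undefined; it is reported as `NaN`
  with a warning, never silently dropped.
* Training is deterministic given `seed`; manifests record seed, sizes
  and hyperparameters.

## Problem sizes used in the test-suite

Unit tests run on reduced grids (101/51 classes) and 12–25 blends so the
suite stays fast; the headline recovery checks use the full 1001-class
convention with 50 blends × 5 pressures (the regression criterion) and
100 noise-free blends for the asymptotic recovery check, where the limit
is the PC-score encoding of D50 rather than regressor convergence. These
sizes are the package's choices for a convincing-but-economical
demonstration, and all of them are regenerated in code at test time.

## Known limitations

* The probabilistic PSD model assumes independent, non-interacting
  particle populations; agglomeration and segregation are out of scope,
  as are pairwise dependencies between shape correction factors.
* The default size term of the membership weights loses discrimination
  for components whose PSDs share identical support; use the
  frequency-weighted variant in that regime.
* Tapped density can only be predicted when training measurements are
  supplied; the package deliberately asserts nothing about
  tapped ≥ bulk for model outputs.
* Leverage intervals assume approximately homoscedastic residuals and an
  informative residual-sd estimate; with strongly heteroscedastic data
  the nominal level is only indicative.
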