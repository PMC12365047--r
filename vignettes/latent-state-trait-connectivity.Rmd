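---
title: "Latent state-trait models for test-retest functional connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent state-trait models for test-retest functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lstconn)
```

## The measurement problem

Resting-state functional connectivity (RSFC) is measured per *edge* - an
unordered pair of brain parcels - as the Fisher-z transformed Pearson
correlation between the two parcel time series during one scan. Edge values
fluctuate from scan to scan and day to day, so a single measurement mixes
three very different sources of variance:

* a stable, person-specific **trait** component,
* **occasion (state)** components specific to the measurement day, and
* **random error** within a scan.

A typical test-retest design acquires four resting scans over two days (two
scans per day, with counterbalanced phase-encoding order), giving four
indicators Q1..Q4 per edge: Q1, Q2 on day 1 and Q3, Q4 on day 2, with Q1 and
Q3 the first scan of their day. Psychological phenotypes bring the same
problem at the item/subscale level: observed scores are congeneric
indicators of a latent construct, measured with error. Ignoring either error
source attenuates brain-phenotype correlations and inflates the sample sizes
needed to detect them.

## Measurement models

`lstconn` fits five small structured covariance models by maximum
likelihood. All latent variances are fixed to 1 and loadings are
equality-constrained within factor type, so each family is identified by a
handful of parameters:

* **single-trait** (`single_trait`): one common factor,
  $\Sigma_{ij} = \lambda^2$ for $i \neq j$, $\lambda^2 + \theta_i$ on the
  diagonal. With four indicators and equal loadings: df = 5. A baseline with
  no state structure.
* **multistate single-trait** (`msst`): one state factor per day
  ($S_d$, unit variance) and a second-order trait factor,
  $S_d = \lambda_t T + \zeta_d$. Implied moments: same-day covariance
  $\lambda_s^2$, cross-day $\lambda_s^2 \lambda_t^2$; df = 4. The
  single-trait model is the $\lambda_t = 1$ restriction, so the two are
  compared by a 1-df likelihood-ratio test (critical value 10.83 at
  p = .001).
* **msst + method factors** (`msst_method`): two orthogonal order factors
  (first/second scan of a day) with one shared loading $m$; adds $m^2$ to
  same-order pairs; df = 3.
* **bi-factor** (`bifactor`): general factor plus orthogonal day factors;
  same-day $g^2 + s^2$, cross-day $g^2$; df = 4. At interior optima it is
  covariance-equivalent to the msst family via $g = \lambda_s\lambda_t$,
  $s^2 = \lambda_s^2(1 - \lambda_t^2)$, which the test suite exploits as a
  cross-check on the optimizer.
* **congeneric** (`congeneric`): one factor, free loadings $\nu_j$ and
  residuals per indicator; used for phenotype scales (at least three
  indicators).

```{r}
spec <- build_rsfc_model("msst")
implied_covariance(spec, c(lambda_s = 0.8, lambda_t = 0.9, theta1 = 0.36,
                           theta2 = 0.36, theta3 = 0.36, theta4 = 0.36))
```

### Estimation

`ml_fit()` minimizes the normal-theory discrepancy
$F_{ML} = \log|\Sigma(\theta)| - \log|S| + \mathrm{tr}(S\Sigma(\theta)^{-1}) - p$
with $\chi^2 = (n-1)F_{ML}$ at the optimum. Numerical choices, stated so
results are bit-reproducible:

* box constraints: residual variances $\ge 10^{-6}$; loadings within
  $[-2, 2]$ after internal rescaling of the data (blocks with
  equality-constrained loadings are rescaled by one common factor so the
  constraint is preserved; free-loading indicators individually - the
  discrepancy is invariant and estimates are mapped back exactly);
  the second-order loading $\lambda_t \in [0, 1.2]$, deliberately wider than
  1 so the "second-order loading > 1" exclusion rule can actually trigger;
* sign indeterminacy resolved by constraining the first loading of each
  factor to be non-negative;
* three deterministic starts (moment-based, flat 0.5, perturbed
  moment-based); ties broken by lowest discrepancy, then smallest parameter
  norm;
* L-BFGS-B with at most 500 iterations per start; non-positive-definite
  candidates are repelled by a smooth barrier; non-convergence is reported
  as `converged = FALSE`, never an error, and all downstream stages exclude
  such fits with a logged reason;
* solutions within $10^{-3}$ (standardized scale) of a box edge carry
  `boundary = TRUE`;
* the baseline for CFI is the independence model; SRMR includes the
  diagonal residuals; $\chi^2$ uses the $(n-1)$ multiplier. Plain ML is
  used throughout: the synthetic data are exactly multivariate normal, so
  robust (scaled) statistics would add complexity without changing any
  conclusion at this scale.

### Selection and decomposition

`select_model()` applies the conventional cutoffs SRMR < 0.08, RMSEA < 0.08,
CFI > 0.90 plus the loading windows for the msst family (standardized
first-order loading in [0.40, 0.90], second-order in [0.70, 1.00]), and
returns machine-readable failure reasons. `decompose_variance()` splits each
indicator's variance into common consistency
$\lambda_s^2\lambda_t^2/\sigma_i^2$, occasion specificity
$\lambda_s^2(1-\lambda_t^2)/\sigma_i^2$ and random error
$\theta_i/\sigma_i^2$; without method factors the three shares sum to 1.
`omega_reliability()` is $(\sum\nu_j)^2 / ((\sum\nu_j)^2 + \sum\theta_j)$.

An open structural question is whether the day-factor disturbances should be
freely estimated; because the model description standardizes all latent
variances to 1, the day factors here have unit variance by construction,
which also makes $\lambda_t$ directly interpretable as a standardized
second-order loading.

## Association and prediction

`corrected_correlation()` joins the msst measurement model for one edge with
the congeneric model for one scale; the corrected association is the
correlation $\psi$ of the two latent disturbances. Covariates (age, sex,
mean motion) enter as exogenous regressors on both latent factors - the
standard latent-regression wiring; their covariance block is fixed at the
sample values. The uncorrected association is the covariate-partialled
correlation of the 4-scan mean z with the unit-weighted sum score.
`improvement_factor()` regresses corrected on uncorrected correlations
across edges (with intercept; only the slope is reported, since a
through-origin fit is not implied by near-linearity), and
`required_n()`/`sample_size_ratio()` translate both into sample-size
requirements via the two-sided Fisher-z approximation
$N = \lceil ((z_{1-\alpha/2} + z_{power})/\mathrm{atanh}\,r)^2 + 3 \rceil$
(defaults $\alpha = 0.05$, power 0.80; the formula choice is ours and is
configurable).

`split_half_experiment()` evaluates four ridge-regression variants (average
scores vs regression factor scores of edges as predictors, crossed with sum
scores vs Bartlett factor scores of the phenotype as targets) under repeated
split-half cross-validation, fitting all measurement models in the training
and test halves independently. Edges whose measurement model is not
established in either half are zero-imputed; validity coefficients are
computed and gated (default 0.80) as a reported flag - exclusion by validity
operates through the network filter, with `validity_action = "exclude"`
available. Ridge uses the closed form on training-standardized predictors
with the penalty selected by 5-fold inner CV over nine log-spaced points in
$[10^3, 10^7]$ (the grid resolution is our choice within that range).

`operative_pipeline()` implements conditional-normal ("operative")
prediction $\hat y = \hat\mu_y + \hat\Sigma_{xy}^{\top}
\hat\Sigma_{xx}^{-1}(x_0 - \hat\mu_x)$ from the joint model with a saturated
mean structure (indicator means free, hence equal to sample means), summed
to a predicted scale score per edge and collapsed across edges by a ridge
trained on the training split, under 10-fold family-aware cross-validation
(whole families assigned greedily to folds, largest first, into the
currently smallest fold). With saturated moments, operative prediction
reduces exactly to ordinary least squares - a property the tests verify to
$10^{-8}$.

## The synthetic-data generator

The generator is the package's study bench: every latent quantity is
recorded, so recovery can be tested against known truth. Per edge,
$S_d = \lambda_t T + \zeta_d$ with $\mathrm{Var}(\zeta_d) = 1 - \lambda_t^2$
and $Q_i = \lambda_s S_{day(i)} + m\,O_{order(i)} + \varepsilon_i$; per
scale, congeneric items $\nu_j \eta + e_j$. All latents are Gaussian (the
model itself assumes multivariate normality, so no heavy-tail option is
provided). A single standard-normal driver shared by edge traits and
phenotype factors induces corr$(T_e, \eta) = \rho$ for every pair while
keeping all latents standard normal; a side effect is that edge traits
correlate with each other at $\rho$, which is itself realistic. Families,
age, sex, a synthetic mean-motion summary, and a 50% phase-encoding
counterbalance fraction are attached; covariates are independent of the
latents unless effects are configured (their generative form is not
prescribed by the design, so they default to zero). Network labels come
from the seven-network + subcortex vocabulary, with regime defaults
(sensorimotor: higher state share; limbic/subcortex: weak loadings, the
edges whose models tend to fail) set in `default_edge_params()`.

`generate_timeseries()` emulates the raw input of the connectivity stage:
per scan, parcel series are multivariate normal with pairwise correlations
`tanh(z)` of that scan's indicator value, plus an optional shared "global"
component and artifact noise on motion-spike volumes, with per-volume RMSD
values carrying spikes above 0.25 mm at a configured rate. What the
generator does **not** emulate - hemodynamics, spatial autocorrelation,
atlas geometry, non-normal tails, missingness - bounds what passing tests
show about real data: they validate the statistical machinery under the
model's own assumptions, not robustness to their violation.

### Fixed study conditions used by the acceptance checks

* Parameter recovery: 200 edges, $n = 400$, $\lambda_s \in \{0.6, 0.8\}$,
  $\lambda_t \in \{0.8, 0.9\}$, $\theta = 0.36$ (a realistic error share;
  note the Fisher information at these truths puts the best attainable MAE
  for $\hat\lambda_s$ near 0.02 at this sample size).
* Disattenuation: $\rho = 0.3$, 4-scan-mean reliability 0.75
  ($\lambda_s = 0.8, \lambda_t = 0.9, \theta = 0.448$), $\omega = 0.75$
  (7 items, $\nu = 0.7$, residual 1.1433), $n = 861$, 200 edges; classical
  theory predicts uncorrected $\approx 0.225$ and improvement factor
  $\approx 1.33$.
* Null calibration: 2000 replicates of the 1-df LRT at $n = 400$ under
  single-trait truth.
* Prediction contrast: 800 unrelated subjects (from 1600 in 800 families),
  40 edges, $\lambda_s = 0.55$, $\lambda_t = 0.9$,
  $\theta = (0.2, 1.6, 0.2, 1.6)$, $\rho = 0.5$, 10 split-half repeats. The
  strong first/second-scan error contrast is the point: unit-weight
  averages cannot downweight the noisy scans, model-based factor scores
  can; with homoscedastic residuals the two predictors coincide after
  standardization and no method could differ.

Problem sizes throughout (hundreds of edges, a few thousand subjects) are
chosen as desk-scale stand-ins for the full 93,096-edge analyses; every
statistic is defined per edge, so scale changes nothing but runtime.

## Worked example

```{r, eval = FALSE}
ep <- default_edge_params(50, seed = 1)
sp <- default_scale_params("cognition", n_indicators = 7, seed = 1)
pop <- generate_population(400, ep, sp, rho = 0.3, seed = 1)
panel <- generate_edge_panel(pop, seed = 2)
phen <- generate_phenotype(pop, seed = 3)

fits <- fit_edge_panel(panel, "msst")
head(fits[, c("edge_id", "lambda_s", "lambda_t", "pass",
              "common_consistency", "occasion_specificity", "random_error")])

assoc <- associate_edges(panel, phen$items$cognition, scale_id = "cognition")
improvement_factor(assoc)
```

## Known limitations

* The engine covers exactly the model families above - no general SEM
  syntax, missing-data FIML, ordinal indicators, or robust standard errors.
* Corrected correlations are point estimates; no standard errors or
  confidence intervals are attached (exclusion rules stand in for
  significance screening, as in the source analyses).
* The improvement-factor regression is descriptive OLS across edges whose
  errors are not independent (edges share subjects); its slope is a summary,
  not an inferential quantity.
* Family-aware folding balances fold sizes greedily; with very unequal
  family sizes folds can differ by a few subjects.
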