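---
title: "Causal networks and feedback loops from monthly plankton monitoring series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal networks and feedback loops from monthly plankton monitoring series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccmnet)
```

## The problem

Whether biodiversity drives ecosystem functioning in natural communities —
or the other way round, or both at once through nutrient feedbacks — cannot
be settled by correlation: in nonlinear ecosystems, associations between
state variables appear, vanish and change sign as the system moves around
its attractor. `ccmnet` implements a pipeline for resolving such questions
from long-term monthly monitoring data with convergent cross-mapping (CCM),
a causal-inference method for nonlinear dynamical systems built on Takens'
state-space reconstruction. The target system is the
diversity–biomass–environment network of lake and marine phytoplankton:
species richness (BD), community biomass via chlorophyll-a (EF), nitrate,
phosphate, and water temperature, where temperature is *exogenous* — it
forces the biota but is not fed back upon — while the nutrients are
*endogenous* and can sit inside feedback loops.

The pipeline has five stages, each an exported module:

1. **Preprocessing** — irregular observations to stationary monthly
   anomalies (`aggregate_monthly`, `detrend_linear`, `deseasonalize`,
   `rescale`, `preprocess`).
2. **EDM core** — delay embedding, simplex cross-mapping and library-size
   skill curves (`embed_series`, `cross_map`, `skill_curve`).
3. **Per-link CCM protocol** — embedding-dimension and lag selection,
   convergence testing, significance, bootstrap standard errors
   (`quantify_link` and friends).
4. **Network assembly** — standardized linkage strengths and Neutel loop
   weights for pairwise and triangular feedbacks (`build_site_network`,
   `standardize_network`, `pairwise_loop`, `triangular_loops`).
5. **Cross-system comparison** — redundancy analysis, permutation tests,
   stepwise regression, rank tests (`assemble_cross_system_table`,
   `rda_analysis`, `paired_permutation_test`, ...).

Because real long-term monitoring archives are not redistributable, the
package ships seeded generators with *known* causal structure
(`simulate_coupled_logistic`, `simulate_mock_ecosystem`, `simulate_study`)
against which every stage is validated.

## Preprocessing model

A monthly series $O(t)$ is reduced to a stationary anomaly in three steps,
in this order:

1. **Detrend**: residuals of an OLS regression of $O$ on the month index
   $t = 0, 1, 2, \dots$ Missing months are excluded from the fit and stay
   missing — gaps are never interpolated, because interpolation fabricates
   dynamics that the state-space analysis would read as signal.
2. **Deseasonalize**: $D(t) = (O(t) - \mu_{m(t)}) / \sigma_{m(t)}$, where
   $\mu_m, \sigma_m$ are the mean and sample standard deviation of all
   values observed in calendar month $m$. A month with zero variance gets
   anomaly 0 (the vanishing-variance limit), with a warning.
3. **Rescale**: z-score to zero long-term mean and unit sample variance.

Two conventions deserve note. First, the sample ($n-1$) standard deviation
is used throughout. Second, inside `preprocess()` the trend is estimated
*jointly with calendar-month intercepts* (`detrend_linear(seasonal_intercepts
= TRUE)`): a seasonal cycle is generally not orthogonal to time over a
finite record, so a plain value-on-time slope absorbs part of the
seasonality and leaks a small spurious trend into the anomalies. With
monthly intercepts the pipeline is *exactly* invariant to adding any linear
trend plus any fixed 12-periodic signal — the operational meaning of
"removing the trend and accounting for seasonality". The plain regression
remains available (and is the default of the exported `detrend_linear`) for
step-by-step use.

Deseasonalization needs at least two observations in every represented
calendar month; series shorter than two years cannot be processed.

## Cross-mapping and the per-link protocol

To test whether $Y$ causally forces $X$, CCM asks the *effect's* history to
reconstruct the *cause*: the delay embedding
$(X(t), X(t-\tau), \dots, X(t-(E-1)\tau))$ (monthly $\tau = 1$) is searched
for the $E+1$ nearest neighbours of each prediction point, their target
values are combined with exponential weights $w_i = e^{-d_i/d_{\min}}$
(simplex projection), and the skill $\rho$ is the Pearson correlation
between estimates $\hat Y$ and observations. Causality is inferred from
*convergence*: $\rho(L)$ must increase as the library of embedded points
grows from $L_0 = E$ to $L_{\max}$ (all valid vectors).

Per directed link the protocol is:

- **Embedding dimension** $E \in \{2, \dots, 20\}$, chosen by hindcast
  cross-mapping ($X(t)$ projecting one step backward to $Y(t-1)$), per
  ordered pair.
- **Cross-map lag** $k \in \{0, 1, 2, 3\}$ months, mapping $X(t+k)$ to
  $Y(t)$, to admit lagged causal effects on the timescale of phytoplankton
  dynamics.
- **Convergence**: a one-sided Kendall rank test for an increasing trend of
  $\rho(L)$, *and* Fisher's $\Delta\rho$ $Z$ test comparing
  $\rho(L_{\max})$ against $\rho(L_0)$, both at $\alpha = 0.05$. A link is
  significant only if both pass with positive trend and positive gain.
- **Linkage strength** $LS = \max(\rho(L_{\max}), 0)$; negative skill
  carries no causal information (the raw value is retained in the result).
- **Uncertainty**: the standard error of $LS$ from 500 bootstrap resamples
  of the library of embedded points (library size preserved, prediction set
  fixed).

### Guarding the null: four numerical choices

Monitoring anomalies are serially autocorrelated, and a convergence test
naive to that fact detects "causality" between independent AR(1) series
most of the time. Four choices keep the false-positive rate near nominal
while leaving genuine links untouched; each is configurable in
`ccm_config()`:

- **Cross-validated skill curves.** For $L < L_{\max}$ the library subsets
  predict only *out-of-library* points. If instead all points are predicted,
  the leave-one-out estimate at an in-library point is built from the other
  library targets and is explicitly anti-correlated with its own target;
  at $L_0 = E$ this biases $\rho$ negative, so every null curve drifts
  upward and "converges". At $L_{\max}$ the full library is used once with
  leave-one-out prediction over all points.
- **Temporal exclusion radius** (`exclusion_radius`, default 3 months).
  Library points within this window of a prediction point are never
  neighbours; otherwise serial correlation makes temporally adjacent points
  the nearest neighbours and their targets leak autocorrelation — not
  dynamics — into the skill.
- **Same-calendar-month exclusion** (`seasonal_exclusion`, default on).
  Month-wise standardization estimates each month's climatology from a few
  decades of values, so every deseasonalized series keeps a small fixed
  per-calendar-month offset (the estimation error, about
  $\sigma/\sqrt{n_{years}}$). Neighbours an exact multiple of 12 months
  away share that offset, and two independent seasonal series would
  cross-map each other through the shared calendar alone; such neighbours
  are therefore never used.
- **Effective sample size in the Fisher test.** The $Z$ statistic needs the
  information content of each correlation; for autocorrelated series the
  number of prediction points overstates it. Sample sizes are divided by
  the standard cross-correlation factor
  $1 + 2\sum_k r_X(k) r_Y(k)$ (`effective_sample_size()`).
- **Parsimonious model selection.** An exact argmax over 19 embedding
  dimensions and 4 lags maximizes the very statistic that becomes
  $\rho(L_{\max})$; under the null this inflates it by roughly +0.15 and
  manufactures convergence. The hindcast exists to prevent overfitting
  when the series are unrelated, so the selection honours that intent with
  a standard-error rule: the smallest $E$ (and smallest $k$) whose
  skill lies within `se_mult` ESS-corrected standard errors (Fisher-z
  scale) of the best is chosen (`se_mult`, default 2; 0 restores the plain
  argmax).
  When nothing distinguishes candidates beyond noise, the most parsimonious
  reconstruction wins; for truly causal pairs the skill differences dwarf the
  margin and the near-argmax is selected.

With these settings, the two-species benchmark (below) yields 100%
detection of the forced direction, 0% of the reverse, and ~7% per-direction
significance on independent AR(1) pairs at $\alpha = 0.05$ — against 50–90%
for the naive combination.

Degenerate cases: coincident embedded points share weight equally (the
$d_{\min} = 0$ limit); distance ties break to the earliest time index; a
library smaller than $E + 1$ uses all available neighbours with a warning;
self-links ($Y \equiv X$) are flagged and never significant.

## Networks and loop weights

Within one site, every ordered pair among the five variables is quantified
(20 links). Strengths are standardized *within the site*,
$SLS = LS/\max(LS)$, so the strongest link has $SLS = 1$ and sites with
different noise levels or record lengths remain comparable; no cross-site
pooling of skills occurs. The denominator is the maximum over all 20
quantified links (configurable to significant links only). Links *into*
temperature are quantified — they are the pipeline's own false-positive
diagnostic — but flagged and excluded from feedback loops, since an
exogenous forcing cannot take part in a feedback.

Feedback loops are weighted by the geometric mean of their member $SLS$
(Neutel's loop weight): $\sqrt{SLS_{A\to B} \cdot SLS_{B\to A}}$ for a
pairwise loop, the cube root of the product for the four triangular
diversity–biomass–nutrient feedbacks — Type I
(richness→biomass→nutrient→richness, containing the BD→EF link) and
Type II (biomass→richness→nutrient→biomass, containing EF→BD), each with
nitrate or phosphate. A loop is called significant when every member link
is individually significant — the only rule composable from per-link tests.

## Cross-system comparison

Site-level module strengths (links into biomass, links into richness,
pairwise loop weights, triangular loop weights) are related to site
characteristics (depth, area, long-term means of richness, temperature,
PO4, NO3, biomass; depth, area, biomass and nutrients log10-transformed,
all predictors z-scored). The ordination is a redundancy analysis computed
from first principles — center the responses, regress on the predictors,
eigen-decompose the fitted values — with the explained-variance fraction as
test statistic and significance from 10,000 row permutations of the
predictor block ($p = (1 + \#\{\text{perm} \ge \text{obs}\})/(1 +
n_{perm})$; all permutation p-values in the package carry this +1
correction). In the univariate-response case the explained variance reduces
exactly to the OLS $R^2$, which the test suite verifies against both a
direct regression and the vegan implementation.

Supporting statistics: site-paired permutation tests on mean differences
(sign-flip null, two-sided, with exact $2^n$ enumeration available for
small $n$), bidirectional AIC stepwise regression on standardized
predictors (overall $F$ on $(k, n-k-1)$ degrees of freedom), tie-corrected
Kruskal–Wallis comparison across feedback types, and Pearson (optionally
Spearman) correlation with a permutation p-value. These analyses describe
where in environmental space a module prevails; they make no causal claim
about the cross-site gradients themselves.

## What the generators emulate — and what they do not

`simulate_coupled_logistic` is the canonical CCM benchmark: coupled
logistic maps $x_i(t+1) = x_i(t)(r_i - r_i x_i(t) - \sum_{j\ne i}
\beta_{ij} x_j(t))$, with the literature's default forcing $\beta = 0.1$
and growth rates $r = (3.8, 3.5)$. The coupling matrix *is* the ground
truth: edge $j \to i$ iff $\beta_{ij} \ne 0$.

`simulate_mock_ecosystem` is a stylized five-variable lake: temperature is
a seasonal sinusoid plus an AR(1) anomaly (coefficient 0.6, innovation sd
0.8 °C) whose standardized value forces the biota; richness, biomass and
nutrients follow coupled logistic dynamics in which nutrients are
replenished logistically toward capacity (loading) and depleted through the
biomass coupling. Each month is the composition of two growth substeps —
plankton generations are much shorter than a month, and a single map step
would imprint a deterministic month-to-month alternation on the anomalies
that real monitoring series do not show. The default network contains the
Type I cycle richness→biomass→NO3→richness, a biomass↔PO4 pairwise
feedback, and temperature forcing of biomass — six edges, none into
temperature. Process noise (map-scale sd 0.04) keeps the coupled system off
a synchronized attractor: with fully deterministic moderate-to-strong
coupling, every variable's embedding reconstructs every other variable and
direction is undecidable — the generator is tuned to the weak-to-moderate
interaction regime where CCM is informative. States map affinely to natural
units (species counts, µg/L chlorophyll, µmol/L nutrients, °C), which the
z-scoring analysis never sees.

One honest limit surfaced by this design: biomass carries three drivers
(richness, PO4, temperature), and their cross-map detectabilities behave
like a shared budget — strengthening one driver's coupling raises its
detection rate at the expense of the others'. Detecting a moderate
stochastic exogenous driver through a noisy chaotic intermediate is the
hardest case; at 40-year records the pipeline recovers the endogenous
network reliably while the temperature edge is found in only a minority of
runs.

`add_observation_layer` then adds what the preprocessing removes: linear
trends, fixed seasonal cycles, i.i.d. observation noise (default 10% of
each variable's dynamic sd in `simulate_study`), and missing months
(default 2%, masked completely at random with a deterministic count).
`simulate_study` draws 19 sites with 16–41 year records, site couplings
arranged along a latent gradient (stronger diversity→biomass coupling,
weaker nutrient limitation at the "oligotrophic" end), and a metadata table
for the cross-system layer.

What passing tests on these generators shows: the pipeline recovers known
directed structure from realistic record lengths, seasonality, noise and
gaps, with calibrated false-positive behaviour. What it does not show: the
generators have no mechanistic realism (no Monod kinetics, no
stoichiometry, no grazers), missingness is random rather than seasonal
(winter gaps in real monitoring are not random), and real observation error
is neither Gaussian nor homoscedastic. Results on real archives depend on
those differences.

## Problem sizes and determinism

Library-size curves use a 20-point grid with 100 random subsets per size
(`n_L`, `n_subsamples`); benchmark validation uses 400-step series and the
mock ecosystem 40-year (480-month) records, matching the span of the
monitoring archives emulated. The validation suite and the acceptance
script run 30 seeds per stochastic property; the end-to-end reproducibility
check runs the full 19-site study at a reduced configuration (library grid
of 8, 20 subsets, $E \le 6$) so that a complete double run stays in the
minutes range. Every stochastic step — simulation, observation masking,
library subsampling, bootstrap, permutation — draws from R's RNG under a
seed threaded through the call tree, so a run configuration reproduces its
outputs bit-for-bit.

## Known limitations

- Cross-map skill carries no sign: the pipeline cannot distinguish
  facilitation from suppression in a feedback.
- Monthly resolution only; multi-scale analysis would require regular
  sub-monthly sampling.
- Heavily gapped series (deseasonalization needs ≥ 2 observations per
  calendar month; links need ≥ 30 common months) are rejected rather than
  imputed.
- Exogeneity is declared, not inferred: the false-positive diagnostic on
  links into temperature measures, but does not enforce, the assumption.
- The convergence criteria remain anticonservative for very strongly
  coupled (synchronized) systems; this is intrinsic to CCM, not to the
  implementation.
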