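---
title: "Coupling coordination between tourism development and ecosystem service value: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupling coordination between tourism development and ecosystem service value: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccdesv)
```

## The problem

Urban agglomerations that lean on tourism face a two-way dependency: the
tourism economy draws on the quality of the surrounding ecosystems, while
urban and touristic expansion converts the very land that supplies those
ecosystem services. `ccdesv` quantifies how *coordinated* the two
subsystems are over a panel of cities and years, in four stages:

1. **Ecosystem service value (ESV)** from land-use composition, by the
   equivalent-factor method;
2. a **composite tourism-quality index** from a multi-indicator panel,
   weighted by the entropy-weight method (EWM);
3. the **coupling coordination degree (CCD)** of the two subsystem
   scores, classified on a three-stage, nine-type ladder;
4. **panel regression** of the CCD on candidate drivers, with the
   standard pooled / fixed-effects / random-effects selection battery.

Because the real inputs of such studies (statistical yearbooks, land-cover
classifications, nighttime lights) are external data products, the package
ships a synthetic-data module that generates structurally faithful
city-year panels with known ground truth, so every stage is testable end
to end.

## ESV by equivalent factors

The base value is one seventh of the per-hectare economic value of grain
production, `Ea = (1/7) P Q / S` (P: grain price in yuan/kg; Q: yield in
kg; S: sown area in ha), rescaled to the study region by the correction
coefficient `lambda`, the ratio of regional to national per-hectare grain
yield. The defaults are `P = 3.05`, `Ea = 2418.58` yuan/ha and
`lambda = 0.968`. Note that `2418.58 * 0.968 = 2341.19`, whereas regional
applications often quote a corrected value of 2341.52 — consistent with a
lambda rounded from roughly 0.96814. The package stores the printed
inputs and uses the arithmetic product; both are visible in the
configuration.

Each (land-use class, service) pair carries a unit value VC in
yuan/ha/yr. The default 11-service x 7-class table is embedded verbatim
as canonical constants, because the underlying equivalent factors e_ij
are not separately published; an optional builder accepts a user
equivalent-factor matrix and computes `VC = e * Ea * lambda`. Two
conventions worth flagging:

* construction land is a *net consumer* of water supply, gas regulation
  and purification, so its unit values (and its per-hectare total,
  -28145.07 yuan) are negative; negative ESV is propagated, never floored
  at zero. The per-hectare total of construction land is reported as the
  column sum -28145.07, one cent below the commonly printed rounded total
  of -28145.06.
* totals are exactly additive: per-class and per-service contributions
  each sum to the total ESV (`total_esv()` is linear and homogeneous in
  areas, which the tests exercise on random tables).

## Entropy-weight composite index

Indicators are min-max standardised with direction: benefit indicators as
`(x - min)/(max - min)`, cost indicators (the air-pollution column) as
`(max - x)/(max - min)`. The extremes are taken over the **pooled**
city-year panel: the study compares one index across cities *and* years,
so a single scale is the defensible default (`weight_scope = "per_city"`
is available but not endorsed, since per-city extremes destroy cross-city
comparability).

Weights come from Shannon entropy over observation proportions
`Y_ij = y_ij / sum_i y_ij`, with `e_j = -(1/ln m) sum Y ln Y` (and the
standard `0 ln 0 = 0` limit — unavoidable, as the minimum of each column
standardises to exactly zero), utility `d_j = 1 - e_j` and weights
`W_j = d_j / sum d_j`. A constant column has undefined entropy terms; it
carries no information, so it is assigned `e = 1`, weight 0 and a
warning. One weight vector is computed for the whole study period and
reused for every year. The composite score is the weighted sum
`S_i = sum_j W_j y_ij`, which lies in [0, 1] by construction.

## Coupling coordination degree

With tourism score `f` and normalised ESV `g`:

* coupling degree `C = 2 sqrt(f g) / (f + g)`;
* comprehensive index `T = alpha f + beta g`, default
  `alpha = beta = 0.5` (the subsystems treated as equally important);
* coordination degree `D = sqrt(C T)`.

Two readings circulating in the CCD literature deserve comment. The
two-subsystem coupling degree is sometimes typeset in a way that reads as
`2 f g / (f + g)^2`; that form has a maximum of 0.5 and cannot reach the
upper rungs of the standard classification, so the package adopts the
radical form, which satisfies `C` in [0, 1] with `C = 1` exactly at
`f = g > 0`. Likewise `D` is sometimes written as the bare product
`C x T`; the package defaults to `D = sqrt(C T)` — the convention under
which D spans [0, 1] and all nine ladder rungs are reachable — and keeps
the literal product behind `analysis_config(ccd_form = "product")`.

Degenerate input `f = g = 0` would make C's limit along the diagonal 1;
a dead pair of subsystems is not meaningfully "coordinated", so the
package defines `C = 0` there and warns.

How to place ESV on the [0, 1] scale next to the tourism score is itself
a modelling choice rarely stated explicitly; the package min-max rescales
the pooled ESV series by default (mirroring the indicator
standardisation), with a per-city option.

The classification ladder is printed in the literature with gapped
interval labels (0.40-0.49 / 0.50-0.59, etc.); implemented literally
those labels leave values such as 0.495 unclassified. The package uses
half-open deciles `[lower, upper)` with the top rung closed at 1, so
every D receives exactly one of the nine labels and a boundary value
like 0.20 belongs to the rung it opens.

## Panel inference on the drivers of coordination

The driver model is `D_it = b0 + b1 ED + b2 IS + b3 GER + b4 UE + u_i +
e_it` (economic development, industrial structure, government
environmental regulation, urban expansion; `u_i` a city effect). Three
estimators are implemented on balanced panels only — the study design is
balanced, and silent handling of unbalanced input hides data errors, so
unbalanced panels are an explicit error:

* **pooled OLS**;
* **within (fixed effects)**: city-demeaned OLS; time-invariant
  regressors are refused by name;
* **Swamy-Arora random effects**: feasible GLS with `sigma_eps^2` from
  the within residuals, `sigma_u^2` from the between regression
  (negative estimates truncated to zero with a warning) and
  quasi-demeaning `theta = 1 - sqrt(sigma_eps^2 / (sigma_eps^2 + T
  sigma_u^2))`.

Selection follows the standard battery: F test of the city intercepts
(FE vs pooled; df `(N-1, NT-N-k)`, hence `(8, 95)` on a 9 x 12 panel
with four drivers), the Breusch-Pagan LM test for `sigma_u^2 = 0` (1
df), and the Hausman test comparing FE and RE slopes (df = number of
compared coefficients; a non-positive-definite variance difference — a
finite-sample artefact — is inverted by pseudo-inverse with a warning).
The decision rule: significant Hausman selects FE; otherwise significant
LM selects RE; otherwise significant F selects FE; otherwise pooled.

Since no single "R-squared" is canonical for GLS, the RE fit reports the
squared correlation of fitted and observed response as its headline
value and also emits within and between flavours. Significance markers
default to `*` p < 0.05, `**` p < 0.01, configurable. Collinearity
diagnostics report `VIF = 1/(1 - R^2_k)` and tolerance per driver;
perfect collinearity is reported as an infinite VIF rather than an
exception.

## The synthetic data generator

`synthetic_spec()` defaults describe the study shape: 9 cities observed
2011-2022.

* **Land use**: year-0 compositions are Dirichlet draws (concentration
  300) around mean shares (cropland 0.25, forests 0.35, grassland 0.05,
  water 0.12, wetlands 0.03, construction 0.17, unused 0.03 — a
  coastal-delta mix); each year a fraction `construction_drift = 0.01`
  of the cropland + water share transfers to construction land,
  emulating urban encroachment. Compositional noise (sd 0.02) is applied
  on the log-ratio scale and renormalised, keeping shares in the simplex
  without clipping; every row sums exactly to the city area (600,000
  ha).
* **Indicators**: 21 columns, one cost-type (an air-pollution
  analogue); each loads on a latent per-city quality `q_i ~ U(0.2,
  0.8)` (stored as ground truth) plus a mild common year trend and
  observation noise (sd 0.05).
* **Drivers**: four regressors with pairwise correlation 0.3 and
  response `D = 0.4 + 0.069 ED + 0.128 IS + 0.035 GER - 0.279 UE + u_i +
  e_it`, with `sigma_u = 0.1`, `sigma_eps = 0.05`. The slopes are set to
  the point estimates reported for this driver set in the regional
  tourism-ESV literature, so recovery simulations run at empirically
  plausible effect sizes.

One master seed drives everything through per-stage sub-streams
(`substream_seed()`), so each generator is a pure function of its spec
and can be regenerated independently; generators also restore the
caller's RNG state.

What the generator does **not** emulate: realistic magnitudes of tourism
revenue or land areas, spatial autocorrelation between neighbouring
cities, measurement error correlated across indicators, or drivers that
feed back on land use. Passing tests therefore demonstrate the
*correctness of the computations* and the statistical calibration of the
estimators under a well-specified DGP — not that any substantive
regional finding generalises.

## Numerical choices and problem sizes

* Gap filling: interior gaps by linear interpolation in year order;
  leading/trailing gaps take the nearest observed value (no
  extrapolation), each fill logged. The operation is idempotent and
  range-preserving.
* Ties in year order are impossible after the duplicate-key check;
  monetary values are carried in nominal yuan (no deflation hook is
  applied by default).
* Estimator validation uses dense-matrix oracles (normal equations; full
  Omega GLS) on small fixtures at 1e-10 tolerance.
* Monte-Carlo checks run at sizes chosen to make the asymptotics
  informative while keeping the suite quick: RE recovery at N = 50,
  T = 12 with 200 replicates (each coefficient's mean within 2
  Monte-Carlo SE of truth), and Hausman size at N = 30, T = 8 with 500
  replicates under the exchangeable-effects null (empirical size
  observed ~0.08 at the 0.05 level — mild finite-sample liberality is
  expected for the Hausman statistic at these dimensions).

## Known limitations

* The embedded unit-value table is region-specific; applying it
  elsewhere requires a user equivalent-factor matrix and local grain
  economics.
* Entropy weights are data-driven and scale-free but not stable under
  panel extension: adding a year changes the pooled extremes, hence all
  scores. This is inherent to EWM, not an implementation artefact.
* The CCD is a descriptive composite; neither C nor D has an inferential
  distribution, and the classification ladder's thresholds are
  conventional.
* Only exchangeable (random-intercept) heterogeneity is modelled; no
  spatial or dynamic panel structure.
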