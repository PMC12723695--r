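# ccdesv

Coupling coordination between tourism development and ecosystem service
value (ESV) on city-year panels.

Regions that build their economy on tourism depend on the very
ecosystems that urban and touristic expansion erodes. `ccdesv` is for
sustainability analysts who want to quantify that tension: it measures
how *coordinated* a composite tourism-quality index and the monetised
value of ecosystem services are across cities and years, and which
factors drive the coordination.

## The methods

**ESV by equivalent factors.** Each land-use class *i* and service
category *j* carries a unit value VC<sub>ij</sub> (yuan/ha/yr), a
multiple of a base value Ea = (1/7)·P·Q/S (one seventh of the
per-hectare economic value of grain production), regionally corrected by
λ. Total value is ESV = Σ<sub>i</sub> VC<sub>i</sub>·A<sub>i</sub> over
class areas A<sub>i</sub>. The default 11-service × 7-class unit-value
table is embedded; construction land is a net service consumer with a
negative per-hectare total.

**Entropy-weight composite index.** Indicators are min-max standardised
with direction (y<sub>ij</sub> ∈ [0,1]), weighted by information
utility W<sub>j</sub> = (1−e<sub>j</sub>)/Σ(1−e<sub>j</sub>) where
e<sub>j</sub> is the Shannon entropy of each indicator's observation
proportions, and combined as S<sub>i</sub> = Σ<sub>j</sub>
W<sub>j</sub>y<sub>ij</sub>.

**Coupling coordination degree.** For subsystem scores f (tourism) and
g (normalised ESV): C = 2√(fg)/(f+g), T = αf + βg (default α = β =
0.5), D = √(C·T), classified onto a three-stage, nine-type ladder
(severe disorder … excellent coordination).

**Panel inference.** D<sub>it</sub> = β₀ + β₁ED + β₂IS + β₃GER + β₄UE +
u<sub>i</sub> + ε<sub>it</sub>, estimated by pooled OLS, the within
(fixed-effects) estimator and Swamy–Arora feasible-GLS random effects,
selected by the F / Breusch–Pagan LM / Hausman battery, with VIF
collinearity diagnostics.

A synthetic-data module generates structurally faithful land-use,
indicator and driver panels (9 cities × 2011–2022 by default) with known
ground truth, so the whole pipeline runs and is validated without any
external yearbook or land-cover data.

## Worked example

```r
library(ccdesv)

# value one year of land use for a single city (areas in hectares)
lu <- landuse_table(data.frame(city = "gz", year = 2020,
  cropland = 120000, forests = 210000, grassland = 30000,
  water_bodies = 70000, wetlands = 18000, construction_land = 140000,
  unused_land = 12000))
total_esv(lu)$esv_total
#> [1] 32607189900        # ~32.6 billion yuan/yr

# entropy weights on a tiny two-indicator example
entropy_weights(cbind(a = c(0, 0.5, 1), b = c(1, 0, 1)))
#>   indicator entropy utility weight
#> 1         a  0.5794  0.4206 0.5326
#> 2         b  0.6309  0.3691 0.4674

# full synthetic pipeline: land use -> ESV, indicators -> index,
# coupling -> classified D, drivers -> panel model
res <- run_all(synthetic_spec(seed = 3))
head(as.data.frame(res$ccd), 4)
#>      city year         f         g         C         T         D        stage                  type
#> 1 city_01 2011 0.2309953 0.7305682 0.8544448 0.4807817 0.6409379 Coordination Elementary coordinate
#> 2 city_01 2012 0.1991113 0.6661821 0.8418040 0.4326467 0.6034929 Coordination Elementary coordinate
#> 3 city_01 2013 0.2163946 0.6695663 0.8592814 0.4429804 0.6169642 Coordination Elementary coordinate
#> 4 city_01 2014 0.1986063 0.6240342 0.8558953 0.4113203 0.5933355       Run-in       Bare coordinate

res$battery
#> Panel model selection
#>   F test (FE vs pooled):  F(8, 95) = 20.264, p = 1.518e-17
#>   BP-LM test (RE vs pooled): chi2(1) = 189.484, p = 4.121e-43
#>   Hausman test (FE vs RE): chi2(4) = 7.359, p = 0.1181
#>   recommended model (alpha = 0.05): random
```

Per city-year, `f` is the entropy-weighted tourism score, `g` the
min-max-rescaled ESV, `C` how balanced the two are, `T` their weighted
level and `D` the coordination degree with its ladder label. The test
battery here finds strong city effects (F, LM) that are uncorrelated
with the drivers (Hausman), so the random-effects model is recommended —
`summary(res$fit)` prints its coefficient table and variance components.

`ccd_panel()` is the model-fitting front end
(`ccd_panel(D ~ ED + IS + GER + UE, data, model = "random")`) with the
usual `coef`, `summary`, `predict`, `residuals`, `simulate` and `vcov`
methods; `vignette("coupling-coordination")` documents the methods,
defaults and design choices.

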