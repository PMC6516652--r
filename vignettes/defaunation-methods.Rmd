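---
title: "Modelling and mapping hunting-induced defaunation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and mapping hunting-induced defaunation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(defaunatr)
```

## The problem and the model

Hunting depletes tropical mammal populations without leaving a signal
that satellites can see. The quantitative handle is the local contrast:
a species' abundance in a hunted site, X_h, against a matched unhunted
control, X_c, summarised as the log response ratio RR = ln(X_h / X_c).
Two regimes coexist in such data: graded declines (RR < 0, occasionally
increases RR > 0) and complete local extirpations (X_h = 0), for which
the log ratio is undefined. `defaunatr` therefore fits a two-stage
hurdle mixed model:

* **Binomial stage** — persistence (1) versus extirpation (0) on a
  logit link,
  `logit P(persist) = Xβ + u_country + u_study + u_species`;
* **Gaussian stage** — the nonzero RRs,
  `RR = Xβ + u_country + u_study + u_species + ε`, ε ~ N(0, σ_e²).

Crossed random intercepts absorb country-level policy and culture,
study-level methodology, and species identity. Fixed effects are drawn
from: distance to hunters' access points (km), human population density
(ind/km²), stunting prevalence (proportion, a spatial poverty proxy),
travel time to major towns (min), livestock biomass (kg/km²),
protection status, ln body mass (kg), diet guild, and the
mass-by-distance interaction. Estimation is by `lme4` (Laplace
approximation for the binomial marginal likelihood; adaptive
Gauss-Hermite quadrature is available for single-factor layouts and is
cross-checked in the tests against an independent quadrature oracle).
ML fits feed model selection; REML refits give the reported
coefficients.

Model choice is all-subsets BIC (interaction only when both mains are
present), with k counting fixed coefficients plus one variance
component per random factor (plus σ_e² for the Gaussian stage) — the
source analysis is silent on this count, so it is fixed here and
documented to keep BIC values auditable. Models within ΔBIC ≤ 2 of the
best are "supported"; within that set the fewest-parameter model wins,
ties broken by declaration order.

## From fitted stages to maps

Per species and grid cell the two stages are combined as

    DI_s = 1 − p_persist · min(exp(RR_hat), 1),   clipped to [0, 1].

The combination rule is this package's own (the upstream method states
only that extirpation probability and declines were "simultaneously
accounted for"): extirpation contributes total loss with probability
1 − p_persist, and conditional on persistence the expected abundance
ratio scales the remainder. Capping exp(RR_hat) at 1 keeps predicted
abundance increases from reading as negative defaunation; the cap is a
flag (`cap_increase`) so the uncapped variant remains available. No
lognormal back-transform correction (+σ²/2) is applied to exp(RR_hat):
the index deliberately mirrors the plain "reverse of exp(RR)"
definition; a bias-corrected variant would change DI_s by a constant
factor exp(σ_e²/2) and is left off by default.

Projections are population-level where data end: species and country
random intercepts are added when the level was observed during fitting
and contribute 0 otherwise. That is the only defensible choice when
projecting ~13× more species than were ever observed. The composite
index is the per-cell mean of DI_s across the S in-range species;
size-class (<1, 1–20, >20 kg) and guild composites reuse the same
aggregation with filters. Hotspots are cells where at least one third
of species exceed DI_s = 0.7 (strict). MESS (minimum over variables of
the Elith percentile similarity, strictly-below tie convention) flags
cells outside the socioeconomic domain of the fitting records; the
domain-restricted summaries mask cells with similarity < 0. Overlay
summaries use strict DI > 0.1 for "defaunated", inclusive HF ≤ 2 for
wilderness, and a per-cell 95% CI that treats cells as independent — a
documented simplification, since spatial autocorrelation makes these
intervals optimistic.

## Numerical choices

* **Internal standardization.** Both stages are optimized on z-scored
  continuous covariates and the coefficients and covariance are mapped
  back to the raw scale by the exact linear transform between the two
  model matrices (`X_std = X_raw M`). The likelihood, variance
  components, random intercepts and predictions are invariant; what
  changes is optimizer behaviour — raw-scale fits routinely trip
  lme4's gradient check with false-positive convergence warnings.
  Selection still standardizes explicitly (comparable coefficient
  scales); prediction uses raw-scale coefficients throughout.
* **Convergence.** A stage is `converged` only if the optimizer
  reported success and no lme4 convergence code was raised; failures
  are returned flagged, never silently, and model selection drops and
  logs them. Singular fits (a variance hitting 0) are reported but
  kept, matching standard mixed-model practice.
* **"Pinned" variances.** With `random = character(0)` both stages
  reduce exactly to glm/lm. With variances merely *generated* as 0 the
  estimates converge to the fixed-only fits but need not match to
  machine precision, since a free variance component may sit at a small
  positive optimum in finite samples.
* **REML values are parameterization-dependent.** The REML criterion
  changes under reparameterization of X (only ML fits enter BIC; the
  `bic()` function refuses REML fits).
* **Thresholds.** Strict inequalities at DI 0.1 and 0.7 and MESS 0;
  inclusive at HF ≤ 2; category bounds low ≤ 0.1 < moderate ≤ 0.7 <
  high.

## The synthetic world

`synthetic_config()` states the world once: 150 studies in 25
countries, 290 species, 20 records per study (n = 3,000, matching the
order of the empirical database's 163/296/3,281), extirpation in
roughly one record in five (the empirical database saw one in eight), distances uniform over 0–40 km (hunters
rarely operate beyond ~20 km; the upper half keeps remote cells
represented), body masses log-uniform over 0.018–3,940 kg (the
empirical span), HPD lognormal, stunting Beta(2, 4), protection ~
Bernoulli(0.3). True effects follow the fitted signs — persistence and
RR improve with distance, worsen with density and poverty, large-bodied
species fare worse but recover faster with remoteness — at magnitudes
chosen a priori so each coefficient carries ~5–20 SE of signal at
n = 3,000. Landscapes are 48×48 km at 1 km: settlement points (a fifth
urban, hence excluded from the distance layer), smooth lognormal/Beta
socioeconomic fields matched to the record marginals so MESS is mostly
positive by construction, blocky protected areas, Voronoi countries
drawn from the database country pool, rectangular species ranges.

What a green test establishes — and what it does not: the generator
shares the model family with the estimator, so recovery tests validate
the estimation and projection machinery, not the model's adequacy for
real hunting data. Real databases bring selection effects, spatially
autocorrelated effort, non-Gaussian RR tails and time-lagged declines,
none of which are emulated; headline empirical numbers (mean DI 0.13,
47% of forest defaunated, etc.) depend on the full field database and
global rasters and are out of desk-scale reach by design.

## Cross-validation design

Folds are record-level by default with a documented seed; study-level
grouping (`grouping = "study"`) is offered because record-level folds
leak study random effects between train and test, flattering accuracy.
Observed categories come from observed DI (extirpation = 1, otherwise
1 − exp(RR) floored at 0); predicted categories from the combined
hurdle prediction. The pseudo-R² squares the Pearson correlation of
pooled predicted and observed DI, extirpations included; a degenerate
(constant) predictor reports 0 with an explicit flag.

## Known limitations

Laplace-approximate Wald intervals for the binomial stage are
anticonservative in this crossed design: measured coverage is roughly
0.77-0.83 (nominal 0.95) for every binomial coefficient, because with
~10 binary observations per species the species variance is shrunk to
the singular boundary in most fits, deflating the fixed-effect SEs.
Point estimates are essentially unbiased (the 20-replicate bias checks
pass with wide margin); it is the interval calibration that suffers.
Adaptive quadrature would fix it but exists only for single-factor
layouts. Treat binomial-stage Wald CIs as optimistic. Spatially correlated hunting
pressure, time dynamics, dispersal, and curved-earth geometry are out
of scope; CIs over cells assume independence; the country of a border
cell is whatever the single-valued country grid says.
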