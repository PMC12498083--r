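---
title: "Methods: multimodel ISAR analysis for postglacial lake fish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodel ISAR analysis for postglacial lake fish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lakesar)
```

## The scientific problem

The island species–area relationship (ISAR) — richness $S$ as a function of
insular area $A$ — is the backbone of island biogeography. Postglacial
peri-Alpine lakes (Rhine, Rhône, Po and Danube catchments) form a young,
fish-rich "archipelago" in which the shape of the ISAR, and the way human
introductions and extirpations have reshaped it, can be examined. `lakesar`
implements that analysis end to end:

1. a catalogue of SAR functional forms fitted by **Poisson maximum
   likelihood** on the untransformed richness scale and ranked by **AICc**;
2. **community scenarios** separating the pre-1900 native fauna from
   human-modified communities;
3. a **passive-sampling (rarefaction) null model**;
4. a stochastic **colonisation–speciation–extinction simulator** of ISAR
   emergence through time;
5. a **synthetic-data generator** so that every stage runs, and is tested,
   without external data.

## The model catalogue

`sar_models()` returns 24 enabled forms (out of 25 defined): 20 smooth
curves covering linear, convex, asymptotic and sigmoid shapes — among them
the power model $S = cA^z$, the rational function
$S = (c + zA)/(1 + dA)$ with asymptote $z/d$, the persistence functions
$cA^z e^{-dA}$ and $cA^z e^{-d/A}$, Monod, Gompertz, Lomolino, cumulative
Weibull and beta-P — plus 4 piecewise (threshold) forms. The logistic-in-area
form is defined but disabled by default, since its sigmoid niche is covered
by the Gompertz, Morgan–Mercer–Flodin and extreme-value forms; membership is
a configuration choice (`models.yaml`, see `inst/extdata/models.yaml`), not
a hard-coded list.

Each form carries an analytic asymptote rule (`sar_asymptote()`): `z/d` for
the rational function, the upper parameter `d` for the saturating forms,
the attained maximum $c(z/d)^z e^{-z}$ for the hump-shaped persistence
function 1, and `Inf` for the unbounded class (power, extended power,
Gleason, Kobayashi, linear, persistence 2).

### Piecewise forms and the predictor scale

The four threshold forms (continuous one-threshold, left-horizontal,
discontinuous, continuous two-threshold) take $x=\ln A$ as predictor with
the mean kept on the natural richness scale. Breakpoint SAR practice places
thresholds on log area; the Poisson likelihood needs untransformed means,
and this combination satisfies both. A `log_area = FALSE` switch in
`sar_models()` retains raw-area thresholds for sensitivity analysis.
Thresholds are free parameters, optimised jointly with the segment slopes,
and are started (and bounded) inside the interior 5–95% quantile range of
$\ln A$ so segments always contain data.

### Parameter bounds

No published bound set exists for this analysis, so bounds are derived from
a data summary by parameter *role*: richness-scale parameters in
$(10^{-6}, 2S_{\max}]$, asymptotes in $(10^{-6}, 5S_{\max}]$, power-law
exponents in $(-5, 5]$, per-km² rates in $(10^{-8}, 5]$, area-scale
constants (e.g. the Monod half-saturation) in $(10^{-8}, 2A_{\max}]$,
dimensionless shapes in $(10^{-8}, 20]$. The role-based extension matters
because not every parameter lives on the richness scale: bounding the Monod
half-saturation constant by richness would exclude its optimum whenever
areas span hundreds of km². Per-model overrides are available through the
YAML config.

## Fitting and ranking

The likelihood is the product of Poisson probabilities of the observed
richness values with mean $f(A_i;\theta)$. Fitting
(`sar_fit()`) runs a derivative-free simplex search from 10 seeded random
starting vectors; box bounds are enforced exactly by optimising on a
logistic-transformed scale. Numerical choices:

* convergence tolerance $10^{-8}$ (relative, on the log-likelihood), at
  most 5000 evaluations per start, plus one simplex restart from each
  solution to guard against premature collapse;
* means are clamped below at $10^{-10}$ before the log; a parameter vector
  giving a *negative* mean at any observed area is infeasible
  (log-likelihood $-\infty$), with a finite graded penalty used inside the
  optimiser so the simplex can recover;
* ties in the ranking break by AICc, then fewer parameters, then model
  name — a total, reproducible order;
* $AICc = -2\log L + 2k + 2k(k+1)/(n-k-1)$ with $n$ the number of lakes in
  the fitted subset (so $n$ shrinks in the leave-one-catchment-out
  analysis), and Akaike weights $w_i \propto e^{-\Delta_i/2}$;
* models for which no start is feasible, or with $n \le k+1$ (AICc
  undefined), are excluded from the ranking with a recorded reason, never
  silently dropped, and never abort the table.

Model `i` of the catalogue uses seed `seed + i - 1`, making the entire
ranking table bitwise reproducible.

`fit_linear_power()` is the separate log–log ordinary-least-squares fit of
$\ln S = c + z\ln A$ used for slope/intercept comparisons between
catchments and scenarios; the reported intercept is on the natural-log
scale (back-check: $e^{2.06}\cdot 536^{0.25}\approx 38$, the richness of
the largest lake at the largest area). Zero-richness lakes are excluded
from that fit with a warning and a count — they cannot occur in the real
system but do in simulations.

## Community scenarios

With `Ext` the extirpated records and `Int` the introduced + translocated
ones, the four communities are `OC` (natives including extirpated — the
pre-1900 baseline), `OC_plus_Int` = `OC ∪ Int`, `OC_minus_Ext` =
`OC \ Ext`, and the current community `CC` = `(OC ∪ Int) \ Ext`. A species
translocated into a lake and later extirpated there counts in neither `OC`
(not native) nor `CC` (extirpated) — the rule is explicit because synthetic
data can produce such records even though the real data do not.
Translocated and introduced species are pooled in the `+Int` operation.
`compare_scenarios()` refits every scenario with the same catalogue and
seed as the baseline, so differences in the best model, slope and intercept
are attributable to the community change alone.

## Passive-sampling null model

The null asks whether the ISAR could arise from random accumulation of
occurrences alone. The regional pool holds each species' number of occupied
lakes; a lake of area $A_i$ receives
$n_i \propto A_i$ draws (largest-remainder rounding, total effort equal to
the total observed occurrence count — the canonical passive-sampling
effort model, chosen because the exact published design is not specified in
the main text; both the pool and the effort are arguments of
`passive_sampling_core()` for sensitivity analysis). Expected richness
under the null is the hypergeometric rarefaction formula
$E[S(n)] = \sum_j [1 - \binom{N-N_j}{n}/\binom{N}{n}]$, evaluated in log
space; a Monte-Carlo envelope (2.5%/97.5% quantiles, $\ge 200$ replicates)
flags lakes whose observed richness exceeds the upper bound. On
archipelagos generated *by* passive sampling the flag rate stays at or
below the nominal 5%.

## The colonisation–speciation–extinction simulator

`simulate_lake()` is an exact event-driven (Gillespie) birth–death process
per lake: each of the $M$ absent mainland species immigrates at rate
$\gamma$; every resident lineage goes extinct at rate
$\mu(A)=\mu_0 A^{-x}$; anagenesis ($\lambda_a$) converts an immigrant
population into an endemic species, freeing its mainland source to
recolonise; cladogenesis ($\lambda_c$) splits a lineage into endemics. An
optional cap $K$ scales immigration and speciation by $\max(0, 1-S/K)$.
Lakes evolve independently (no inter-lake dispersal) — the simplest model
in which an archipelago-level ISAR can emerge from area-dependent
extinction; this is a known limitation, not an oversight.

Defaults ($M=100$, $\gamma=0.01$, $\lambda_c=\lambda_a=0.1$, $\mu_0=1$ per
lineage per My, $x=0.25$, no cap) are documented package defaults on
ecologically plausible scales for temperate freshwater fish; they are
deliberately generic — the simulator is a reusable instrument, and no claim
is made that these equal any previously used calibration.
`zslope_vs_age()` sweeps system age and reports when the mean log–log
slope first reaches a target steepness (default $z = 0.25$). Under the
defaults the slope is indistinguishable from zero at the 15 ky postglacial
age and only becomes substantial on million-year scales — steep ISARs need
either far more time or much faster rates than the defaults.

## The synthetic-data generator

`generate_dataset()` emulates the statistical structure the analysis
assumes: 79 lakes in four catchments; areas log-uniform on 0.05–600 km²
(four orders of magnitude); depth log-normally correlated with area; native
richness Poisson around a rational curve with parameters (7.23, 1.44,
0.04); native identities drawn from a 75-species pool with geometric
incidence weights (nested occupancy, the skew rarefaction needs); endemics
zero-inflated and depth-driven, so most lakes have none and deep lakes host
up to ~10; introductions Poisson with mean proportional to native richness
(absolute counts rise with area, proportions do not); extirpations rare
(0–4 per lake) and area-independent.

Two deliberate distortions of realism: richness is truncated at $\ge 1$
(the real system has no fishless lakes), which biases the mean upward at
tiny areas — parameter-recovery experiments therefore use
`truncate = FALSE`; and species identities are exchangeable within the
weight structure — no attempt is made to clone the real species lists.
Passing tests on these data show that the *pipeline* recovers what it
generates under the assumed structure (Poisson noise, nestedness,
depth-driven endemism); they cannot certify the field accuracy of the
published numbers, which requires the real supplementary tables (convert
them with `convert_supplementary()`; the package reads CSV exports of the
published sheets, and the acceptance tests then run the full comparison).

## Problem sizes used by the test suite

Simulation-backed checks run at sizes chosen to keep the default suite
fast while leaving the statistical conclusions unambiguous: parameter
recovery at $n=500$ lakes with 200 replicates (median relative error per
rational-curve parameter $\le 10\%$); model-class recovery over 20
full-catalogue replicates; immigration-only closed-form check over 2000
simulated lakes; null-model calibration over 10 archipelagos of 79 lakes
with 500 Monte-Carlo replicates each; slope-through-time sweeps with 20–30
replicate archipelagos per age. Enlarging any of these only narrows the
Monte-Carlo error around the same conclusions.

## Known limitations

* Poisson errors assume no overdispersion in richness; the multimodel
  machinery would carry over to a negative-binomial likelihood, which is
  not implemented.
* No confidence intervals on nonlinear parameter estimates and no model
  averaging of predictions — ranking and weights only.
* The piecewise threshold forms can have multimodal likelihoods when data
  cluster near candidate thresholds; 10 starts with interior-quantile
  threshold initialisation handled every case encountered, but pathological
  configurations may need more starts.
* The supplementary-sheet converter reads CSV exports, not spreadsheets
  directly.
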