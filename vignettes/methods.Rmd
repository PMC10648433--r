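---
title: "Modeling partial meat replacement with walnuts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling partial meat replacement with walnuts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutshift)
library(dplyr)
```

nutshift models what happens to a population's nutrient intake, diet
quality, and food spending when part of its meat consumption is replaced by
walnuts. The substitution is applied to 24-hour dietary-recall microdata at
four escalating doses — 1, 2, 3 and 4 oz equivalents of meat per day
replaced by 0.5, 1, 1.5 and 2 oz of walnuts respectively, the 2:1 ratio
following the USDA Protein Foods convention that 1 oz of cooked meat and
0.5 oz of nuts are both one oz equivalent. Downstream, the package
estimates usual (long-run) nutrient-intake distributions with a
measurement-error model, scores diet quality with the Healthy Eating Index
2015 (HEI-2015), quantifies uncertainty with balanced repeated replication
(BRR), and prices the swap with a CPI-adjusted food-cost model.

This vignette explains each model, its assumptions and tunable parameters,
what the synthetic-cohort generator does and does not emulate, and the
numerical choices made where the design was genuinely open.

## The substitution engine

Meat is defined as the sum of the meat, cured-meat and organ-meat
food-pattern (FPED-style) categories; poultry is excluded. For a recall day
with `a` oz eq of meat available and dose `d`, the engine removes
`r = min(d, a)` oz eq — a person reporting less meat than the dose is only
modified up to their reported level, and a zero-meat day is untouched — and
adds `w = 0.5 r` oz of walnuts. Nutrient changes are
`w * walnut_per_oz - r * meat_per_oz` with the per-ounce composition
vectors from USDA data (walnuts: 185 kcal, 4.32 g protein, 1.9 g fiber,
2.57 g ALA, 44.8 mg magnesium, ...; meat: 49 kcal, 7.1 g protein, 20 mg
cholesterol, 0.6 µg B12, ...). Three design choices deserve a note:

* **Proportional removal.** The source data never says which meat items
  leave the plate first, so the three meat sub-categories are shrunk
  proportionally. This is order-free and deterministic.
* **Per-day application.** Each recall day is modified independently,
  because the usual-intake model is re-estimated on the modified
  person-days; the modified diet, including its energy, is the analysis
  unit (the energy covariate below uses the modified day's energy).
* **Unlisted components subtract zero.** The meat vector carries no fiber,
  copper, folate, vitamin E or LA; those nutrients are only ever added by
  walnuts. The composition profile is a data object
  (`food_composition_profile()`), so alternative vectors can be swapped in.
* **The cap is applied uniformly.** The source procedure states the
  cap-at-reported-meat rule explicitly only for the cost analysis; we apply
  it to the nutrient model as well (a `cap = FALSE` switch exposes the
  uncapped variant), since modeling the removal of meat nobody reported
  eating has no physical interpretation.

Group bookkeeping: `w` oz of walnuts is `r` oz eq of nuts and seeds, so
total protein-food oz equivalents are invariant under the swap, and the
seafood-and-plant-proteins component gains `r` oz eq.

## Usual-intake estimation

Two recalls per person are too few to read off anyone's long-run intake:
day-to-day (within-person) variation inflates the spread of observed
intakes. The amount model separates the two variance sources the way the
NCI method's Mixtran/Distrib macros do for daily-consumed nutrients,
re-implemented here as a one-part model (every nutrient in scope is
consumed near-daily, so the episodic two-part extension is out of scope):

1. **Transform.** Daily amounts `y > 0` are Box-Cox transformed,
   `g(y; λ) = (y^λ − 1)/λ` (log at `λ = 0`).
2. **Mixed model.** `g(y_ij) = x_ij'β + u_i + e_ij` with a person random
   intercept `u_i ~ N(0, σ_u²)` and residual `e_ij ~ N(0, σ_e²)`, fitted by
   maximum likelihood (`lme4::lmer`). Covariates: recall sequence (day 1
   vs 2), weekday (Mon–Thu vs Fri–Sun), 7-level age category, gender,
   4-level race, and daily energy (per 1000 kcal). Covariates that are
   constant in a data set are dropped automatically so small fixtures stay
   full-rank. Persons contributing a single day still inform `β` and the
   variance total; `σ_e²` is identified by the persons with both recalls
   (all-single-day data are rejected).
3. **Exponent selection.** `λ` is chosen on a grid (default
   `seq(0, 1, by = 0.05)`) by the profile likelihood including the Jacobian
   term `(λ − 1) Σ log y`. The NCI macros' search strategy is not public;
   the grid is a configurable argument.
4. **Back-transformation.** A person's usual intake is
   `T = E_e[g^{-1}(x'β + u + e)]`, computed by 9-point Gauss–Hermite
   quadrature over the residual (the macros' documented practice). The
   population distribution of `T` is built by drawing `n_pseudo`
   (default 100) random intercepts per person with covariates fixed at
   their day-1 values, then weighting pseudo-persons by survey weights.
   When `λ > 0` the inverse transform is clamped at zero below the image
   of `g`; with the default configurations this branch is never exercised.

Adequacy is summarized by the EAR cut-point method (fraction of the
usual-intake distribution below the Estimated Average Requirement) and the
fraction above the Adequate Intake for nutrients with an AI
(`dri_reference()` ships gender-and-age-banded EAR/AI values for magnesium,
B12, iron, potassium, fiber and ALA in the package's fixed units).

A caution on variance components: `σ_u²` and `σ_e²` are reported on the
selected transformed scale, so fits at different `λ` are not directly
comparable; `normalized_variance_components()` divides by `G^{2λ}` (G the
geometric mean of the amounts), yielding squared coefficients of variation
that are comparable across exponents.

## HEI-2015 and the population-ratio method

The 13 HEI-2015 components are scored piecewise-linearly between a
zero-score and a full-score standard on a density basis (amounts per 1000
kcal, percent of energy with 16 kcal per tsp of added sugars and 9 kcal per
g of saturated fat, or the (MUFA+PUFA)/SFA ratio), clamped to
`[0, max points]`; the standards are shipped as data (`hei_standards()`) so
a revised index can be substituted. The population score uses the
population-ratio method: survey-weighted mean constituent amounts are
computed first and the scoring curve is applied to those means — a ratio of
means, which differs from the mean of per-person scores whenever the
scoring curve is nonlinear across people (the package's tests demonstrate
the gap). Scoring uses day-1 recalls only.

For modeled diets the constituents are adjusted per person with the
published per-ounce addition/subtraction values (walnut add: 2.53 g MUFA,
13.4 g PUFA, 1.74 g SFA, 185 kcal, 2 oz eq total protein, 2 oz eq
seafood-and-plant proteins, 0.567 mg sodium; meat subtract: 0.87, 0.12,
0.76 g, 49 kcal, 1, 1 oz eq, 127 mg sodium), kept verbatim — including two
oddities. First, the meat subtraction lists 1 oz eq of seafood-and-plant
proteins although meat is not normally part of that component; applied
literally it exactly cancels the walnut addition (`w·2 − r·1 = 0`). We
preserve the published arithmetic by default and expose
`literal_seafood_plant = FALSE` for the non-literal variant; we do not
guess intent. Second, walnut sodium is three orders of magnitude below meat
sodium (0.567 mg vs 127 mg per oz); the asymmetry is preserved as printed.
With the literal default, the dose response of the total score is driven by
the fatty-acid ratio and sodium components.

## Survey weights and BRR variance

Every population quantity supports an arbitrary statistic-under-weights
contract: `brr_interval(design, statistic)` evaluates the statistic under
the base weights and under each of `R` replicate weight vectors and forms
Fay's variance `Σ_r (θ_r − θ)² / (R (1−F)²)`, with a normal-theory 95%
multiplier of 1.96 (the df treatment of the original analyses is not
stated; 1.96 is the transparent choice). Significance between a current and
a modeled estimate uses the strict non-overlapping-CI rule — intervals
sharing a boundary are *not* significant.

The synthetic design builds replicates by balanced half-samples: persons
are assigned round-robin to `R` strata and to one of two half-samples
within each stratum; a Sylvester–Hadamard matrix flips half-samples across
replicates, scaling selected weights by `2 − F` and the complement by `F`
(default `F = 0.3`, `R = 32`, echoing the tens-of-replicates convention of
dietary-survey BRR; with few replicates the fixed 1.96 multiplier visibly
under-covers). The replicates satisfy the variance formula's contract; they
make no claim to reproduce any real survey's PSU structure. Measured over
500 independent synthetic cohorts, the 95% interval for a weighted mean
covers the true value about 92% of the time — the small shortfall is the
finite-replicate degrees of freedom under the fixed multiplier.

For usual-intake means the replicate evaluations reweight the pseudo-person
distribution with the fitted model held fixed; refitting the mixed model
under every replicate would propagate model-fit uncertainty too, at roughly
`R` times the cost. The resulting intervals are therefore slightly
anticonservative, which should be kept in mind when reading the
non-overlap flags on small effects.

## The cost model

Base-year prices per 100 g are inflated per food category by CPI ratios,
missing codes borrow their category's median price (flagged as imputed),
day-1 cost is `Σ grams/100 × price`, and the replacement applies
`−r × meat_price/oz + 0.5 r × walnut_price/oz` (walnuts priced per ounce of
food, not per oz eq). The cost replacement uses the same meat definition as
the nutrient model (meat + cured + organ, no poultry), although the source
category taxonomy for pricing lumps cured meats with cured poultry;
restricting the replacement to the same meat set keeps the two stages
consistent. Zero-meat days keep their expenses constant.

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` produces cohorts shaped like a two-recall national
survey of no-nut consumers: demographic strata in nationally representative
proportions; two non-consecutive recalls with 79% day-2 completion (missing
day 2 is represented as absence, never as zeros, since zeros would bias the
amount model); skewed positive amounts from the same two-level Box-Cox
model the estimator assumes; protein-food composition drawn from
stratum-specific Dirichlet shares calibrated so meat is roughly half of
protein-food oz equivalents (totals: boys 4.86, girls 3.81, men 6.97,
women 5.05 oz eq/day); small strata of walnut consumers, other-nut
consumers, pregnant/lactating women, under-4s, unreliable recalls,
implausible energies and missing protein data so each exclusion rule has
work to do; base weights plus Hadamard-balanced Fay replicate weights; and
a price table whose meat and walnut prices equal USD 0.38/oz and 0.26/oz
after inflation adjustment.

One deliberate departure from a fully independent channel-per-nutrient
design: each nutrient is generated as a positive *non-meat background* plus
the meat composition contribution of the day's drawn meat oz equivalents
(`meat_coupling = TRUE`). This makes the cohort internally coherent — B12,
cholesterol and zinc really do come partly from the meat that the
substitution removes — and guarantees modeled diets stay strictly positive,
so the Box-Cox model can be re-estimated on them. The ground-truth record
(`$truth`) accounts for the coupling analytically: per-person true usual
intakes integrate the residual by quadrature, and population truth is
computed by Monte Carlo from the generating parameters (60,000 draws by
default). Setting `meat_coupling = FALSE` gives the pure two-level model,
which is the right reference when checking recovery of the variance
components themselves.

Known limitations, hence what passing tests do and do not show: channels
are mutually independent given the meat draw (no fruit-fiber correlation,
no energy adjustment structure); food-group amounts have no zero-inflation
(no never-consumers of dairy or whole grains); food records partition day
totals grams-proportionally rather than by a food taxonomy; and weekday
effects are a single binary shift. Passing the pipeline on these cohorts
demonstrates the estimators are correct under their assumed model and
calibration — it does not validate the substitution's conclusions on real
survey data.

Seeding is one-stream-per-purpose (demographics, amounts, missingness,
weights, food records, prices, truth), each derived from the master seed,
so adding a stage never perturbs earlier draws and every run is exactly
reproducible from `sim_config(seed = ...)`.

## Numerical choices and degenerate inputs

* Energy screens use day-1 energy (day 1 is always present); 500 and
  5000 kcal themselves are retained — exclusion is strictly below/above.
* Exclusion rules run in a fixed order and record the first matching
  reason, so the exclusion log is a partition of the excluded set.
* Zero total protein makes shares undefined; they are reported as `NA`.
* Zero SFA makes the fatty-acid ratio infinite; it scores full points.
* HEI densities are undefined at non-positive energy — an error, not `NA`.
* Weighted quantiles invert the weighted empirical CDF (left-continuous).
* Classic BRR (`F = 0`) zeroes half the weights; `weighted_mean` accepts
  zero weights with a positive sum for exactly this reason.
* Degenerate generator settings (`σ_u = σ_e = 0`, `λ = 1`) reproduce the
  linear predictor exactly and are covered by tests.

## Problem sizes used by the test suite

The suite exercises the full pipeline at sizes chosen to make every
stochastic assertion stable under its fixed seed: parameter recovery runs
50 replicates of n = 1000 persons (magnesium channel only); BRR coverage
runs 200 cohorts of n = 250; the qualitative dose-response integration test
uses one n = 500 cohort with eight nutrients and all four doses; module
tests use cohorts of 25–300 persons. `scripts/acceptance.R` re-runs the
same computations at comparable sizes from a caller-supplied seed.
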