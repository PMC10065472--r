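---
title: "Methods: simulating the dietary and mortality impact of 'high in' front-of-pack labels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating the dietary and mortality impact of 'high in' front-of-pack labels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Mandatory 'high in' front-of-pack labelling (FOPL) warns consumers when a
packaged food is high in sodium, sugars or saturated fat. Evaluations of
implemented warning-label policies (Chile's labelling law, randomized
marketplace experiments, meta-analyses of warning-label trials) report
percentage changes in the nutrient content of food and beverage *purchases*.
A macrosimulation transposes those purchase changes onto a population's
*intake* distribution and asks how many diet-related non-communicable-disease
(NCD) deaths would not have occurred in the baseline year had intakes been at
the counterfactual level.

`foplimpact` implements that pipeline end to end, with a synthetic-survey
generator standing in for restricted survey microdata so every stage is
testable offline:

1. **simulate** — two-day item-level 24-h recalls with survey and replicate
   weights, plus population/mortality stratum tables;
2. **estimate** — usual (long-run average) nutrient intakes from the repeated
   recalls via a one-part measurement-error model;
3. **scenario** — food-class-specific percentage reductions applied at the
   item level, then full re-estimation;
4. **CRA** — a comparative risk assessment converting intake changes into
   deaths averted or delayed, with Monte Carlo uncertainty intervals.

## The synthetic-survey generator

`generate_recalls()` draws, for each respondent and nutrient, a daily total
on the log scale:

$$\log T_{ij} = \mu_{g(i)} + b_i + \beta_{wk}\,\mathrm{weekend}_{ij}
  + \beta_{seq}\,\mathbf{1}[j = 2] + \varepsilon_{ij},$$

with a person effect $b_i \sim N(0, \sigma_b^2)$ and day-to-day error
$\varepsilon_{ij} \sim N(0, \sigma_w^2)$. Group means $\mu_g$ per DRI age-sex
group are set so back-transformed means sit at realistic adult levels
(energy ~1,900–2,500 kcal/d, sodium ~2,400–3,200 mg/d, sugars ~80–95 g/d,
saturated fat ~20–26 g/d, men above women, a mild decline after age 50);
log-scale SDs of 0.25–0.45 match the between- and within-person variability
typical of 24-h recall data. A fraction of 0.35 of respondents receives a
second (telephone) recall, the design fraction of the survey being emulated.
Weekend days are drawn Bernoulli(2/7) — the emulated survey adjusts for
weekend but does not publish its weekend share, so this is a configuration
default, not a claim. Daily totals are apportioned over items by a Dirichlet
draw across sampled food categories scaled by category-specific relative
nutrient densities, producing item-level records for the food-class engine
without claiming any real survey's item distribution.

Generating on the log scale while the estimator searches a Box-Cox family is
deliberate: the estimator runs under mild transformation misspecification,
as it would on real data.

Replicate weights use a paired half-sample scheme: respondents are paired
within DRI group and per replicate one member of each pair is scaled by
$2-f$ and the other by $f$ (Fay coefficient $f$, default 0, i.e. classic
balanced repeated replication). The emulated survey names bootstrap balanced
repeated replication without publishing the scheme; the expected replicate
weight equals the survey weight, which the tests verify.

What the generator does *not* emulate: real food-composition correlation
structure between nutrients, differential non-response, intra-household
clustering, or genuine survey calibration margins. Passing tests therefore
demonstrate the statistical machinery — not that real-survey estimates would
be reproduced.

## Sample construction and misreporting

Exclusions run in a fixed order (breastfeeding → zero consumption →
underweight/missing anthropometrics) with a per-rule tally, so the
bookkeeping `kept = eligible − Σ removed` is exactly reproducible. BMI at
the threshold (18.5 kg/m²) is kept: the rule is a strict `<`.

Misreporting is classified from the ratio of reported energy intake to
predicted total energy expenditure (TEE), with Goldberg-type cutoffs. The
defaults (0.7, 1.42) and the Institute-of-Medicine-style adult TEE equation
at low-active physical-activity coefficients are package defaults — the
analysis this package operationalises cites its own misreporting procedure
without printing cutoffs, so these are documented configuration, not claims.
Ratios exactly at a cutoff are classified plausible.

Implausible day-level totals are removed per day (not per respondent) by an
absolute cap and a robust z-rule on the log scale (|z| > 4 against the
median/MAD), both configurable.

## The one-part usual-intake model

For nutrients consumed nearly every day, a one-part (amount-only) model
suffices. `fit_one_part_model()`:

- searches a Box-Cox exponent $\lambda$ over a grid (default 0 to 1 by 0.05)
  by profile likelihood, including the Jacobian term
  $(\lambda - 1)\sum \log y$ so likelihoods are comparable across the grid;
  ties break toward $\lambda = 1$ (less transformation);
- at each $\lambda$ fits, by maximum likelihood, a linear mixed model on the
  transformed scale with a person random intercept and fixed effects for
  age, sex, misreporting status, weekend and recall sequence (`lme4`).

Separating between- and within-person variance requires repeated measures;
with no second recalls the fit aborts with a non-identifiability error
rather than returning silently degenerate variances.

Usual intake per person back-transforms the conditional distribution of the
person effect. With $u \mid \text{data} \sim N(\hat u_i, v_i)$,

$$\widehat{T}_i = \int g^{-1}_{\sigma_e}(\mu_i + u)\,
  \phi(u; \hat u_i, v_i)\, du,$$

integrated by 9-node Gauss–Hermite quadrature, where $g^{-1}_{\sigma_e}$ is
the inverse Box-Cox with a within-person-variance adjustment — exact
(lognormal mean) at $\lambda = 0$, the identity at $\lambda = 1$, a
second-order Taylor correction otherwise. The prediction sets weekend to its
design share (2/7) and recall sequence to the first recall; age, sex and
misreporting status stay at observed values. Saturated fat as % of total
energy is computed per person as $100 \times 9 \times \text{satfat}/\text{energy}$
before aggregation.

Stratum estimates are survey-weighted means over persons (all adults and
each DRI group). Standard errors re-run the weighted aggregation under each
replicate weight set:

$$\widehat{\mathrm{Var}}(\hat\theta) = \frac{1}{R(1-f)^2}
  \sum_{r=1}^{R} (\hat\theta_r - \hat\theta)^2,$$

with 95% intervals $\hat\theta \pm 1.96\,\mathrm{se}$. The mixed model
itself is fit once on the full sample; replication covers the aggregation
stage. This keeps 500-replicate runs affordable and matches the convention
of replicating the estimator actually reported (weighted means).

Survey weights do not enter the mixed-model likelihood — they enter at
aggregation. Doubling all weights leaves every estimate unchanged
(tested). This is a deliberate simplification of survey-weighted mixed
modelling; on self-weighting synthetic designs it is exact.

## The counterfactual engine

Each item is classified into {food, beverage, snack food, alcoholic
beverage, meal replacement} via an editable `food_class_map()`; unmapped
codes are an error, never a silent default, and each map entry carries a
provenance note. Alcoholic beverages and meal replacements are exempt in
every scenario (they are regulated separately from the FOPL policy being
modelled). The real analysis's snack-food list lives in an unavailable
supplement; the shipped map covers the synthetic category table and is meant
to be replaced for real data.

The built-in library holds the published percentage changes: S1 (overall
Chilean-evaluation changes), S2 (the same split food vs beverage), S3
(snack foods and beverages only, the most conservative), S4 (meta-analytic
overall changes), and a WHO-criteria sensitivity scenario. Nutrient amounts
scale by $1 + \Delta/100$ at the item level — mathematically equivalent to
scaling daily totals for proportional changes, and it keeps the food-class
targeting exact.

Counterfactual calories are, conservatively, derived from the sugar and
saturated-fat changes only:

$$\text{kcal}_{cf} = \text{kcal}_{base} - (4\,\Delta\text{sugars} +
  9\,\Delta\text{satfat}),$$

applied at the person level with each person's own usual-intake deltas. The
WHO scenario instead uses `calorie_mode = "direct"`: item energy is rescaled
by its published percentage and re-estimated. Saturated-fat %TE always uses
the counterfactual energy consistent with the calorie mode. Reported means
round half-up to the conventions of the surveillance literature (integers
for kcal and mg sodium, one or two decimals for grams).

Counterfactual re-estimation is a full re-run of the one-part model per
nutrient on the adjusted records, with the same $\lambda$ grid, covariates
and weights as baseline. A baseline-vs-counterfactual difference is called
meaningful iff the two 95% intervals are disjoint as closed intervals
(touching endpoints are not meaningful).

## The comparative risk assessment

Three mediated pathways connect intake changes to mortality:

| exposure | mediator | slope parameter |
|---|---|---|
| energy (kcal/d) | BMI (kg/m²) | `energy_to_weight` / height² |
| sodium (mg/d) | systolic BP (mmHg) | `sodium_to_sbp` × 2.5 g salt/g sodium |
| saturated fat (%TE) | total cholesterol (mmol/L) | `satfat_to_chol` |

For disease $d$, stratum $s$ (sex × 5-year band) and factor $k$ with
log-linear relative risk $r$ per mediator unit and mediator slope $m_k$,

$$\text{ratio}_{d,s,k} = \frac{E_{cf}[r^{(x - x_{ref}) m_k}]}
  {E_{base}[r^{(x - x_{ref}) m_k}]}, \qquad
  \text{averted}_{d,s} = D_{d,s}\Big(1 - \prod_k \text{ratio}_{d,s,k}\Big).$$

Expectations integrate over the stratum's exposure distribution — lognormal
for energy and sodium (moment-matched to the stratum mean and SD of
person-level usual intakes), truncated normal for %TE — by adaptive
quadrature (`stats::integrate`); a fixed Gauss–Legendre path, tested to
agree to ~1e-8, is used inside the Monte Carlo loop. Counterfactual
distributions shift the mean by the estimated intake change, preserving
spread, form and truncation; lognormals are re-expressed by moment matching
to the shifted mean at the original variance.

**Truncation is load-bearing.** An exponential RR integrated over an
unbounded lognormal has no finite expectation, and even the numerically
finite tail can invert ratios when the matched counterfactual has a heavier
tail. Exposures are therefore truncated at physiological bounds (energy
500–6,000 kcal/d, sodium 200–12,000 mg/d, %TE 0–40), which bounds the
implied risk range and keeps ratios monotone in the shift.

DRI-group intake estimates bridge to 5-year mortality bands by midpoint:
each band takes the estimate of the DRI group containing its midpoint, with
no finer interpolation. The under-75 subtotal sums bands entirely below 75.

Epidemiological parameters ship as an editable YAML configuration
(`inst/extdata/cra_params.yaml`) holding illustrative literature-style
magnitudes: ~0.042 kg steady-state weight per kcal/day, ~2 mmHg per g salt,
~0.05 mmol/L cholesterol per %TE, and per-disease RRs per mediator unit with
lognormal uncertainty. They are defaults that make the model run and behave
plausibly, not estimates from any single source; production use should
substitute meta-analytic values. Consequently the synthetic pipeline's death
counts are demonstrations of the machinery, not reproductions of any
published national estimate — reproducing those would additionally require
the restricted survey microdata and the source model's exact parameters.

Attribution re-runs the model with one factor's shift active at a time;
single-factor totals need not sum to the joint total and the interaction
residual is reported. Uncertainty intervals redraw RRs (lognormal) and
mediator slopes (normal) per iteration and take empirical 2.5th/97.5th
percentiles (linear interpolation); the point estimate stays at central
parameter values. All Monte Carlo output is seeded and byte-reproducible.

## Numerical choices and degenerate inputs

- $\lambda$ grid [0, 1] step 0.05; ties toward 1. With low-variability data
  the Box-Cox family is nearly affine-equivalent and the choice of $\lambda$
  is immaterial; with recall-like coefficients of variation it is
  identifiable (the parameter-recovery tests exercise both).
- Gauss–Hermite 9 nodes (agreement with the lognormal closed form to
  <0.1% at the SDs arising here); Gauss–Legendre 60 nodes for exposure
  integrals.
- Zero within-person variance: usual intake collapses onto the observed
  person values. Zero exposure SD: ratios use the point-mass closed form
  $r^{\Delta m}$.
- BRR with a failing replicate drops it with a warning and adjusts $R$.
- Half-up rounding only at the reporting boundary, never inside
  computations.

## Problem sizes

The shipped analysis scripts and the acceptance checks use 2,000
respondents, 500 BRR replicates (on the aggregation stage) and 1,000 Monte
Carlo iterations; the parameter-recovery study uses 20 seeds at n = 2,000
with a coarsened $\lambda$ grid (0, 0.25, …, 1). These sizes give stable
estimates for every quantity reported while keeping a full run on a single
CPU in minutes; production Monte Carlo runs would use 10,000 iterations
(`monte_carlo_ui()`'s default).

## Known limitations

- Purchase-to-intake transposition is taken as given, as in the analyses
  being modelled; no substitution elasticities or reformulation dynamics.
- Mortality accounting is for the baseline year only — no time lags,
  life-tables or morbidity.
- The survey-weighting of the mixed model is approximate (weights at
  aggregation only).
- The CRA's steady-state energy→BMI mediation applied to between-person
  intake differences overstates implied BMI dispersion; truncation bounds
  the effect, but CRA magnitudes remain configuration-dependent.
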