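---
title: "Methods: dietary diversity, healthy aging, and their association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dietary diversity, healthy aging, and their association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietaging)
```

This vignette is the package's own account of what it computes and why the
open design choices were settled the way they were. The package follows a
cohort design with dietary exposure measured at two baseline waves
(2009 and 2011, three-day 24-hour recalls) and health outcomes measured at
one outcome wave (2015) in participants aged 60–80 at outcome.

## The dietary diversity score

The score counts, for each recall day, how many of eight guideline food
groups contributed any food: staple foods, vegetables, fruits, eggs,
aquatic products, meat and poultry, soybeans and nuts, dairy. Salt and oil
belong to the guideline's ten groups but are universal in this cuisine and
carry no diversity information, so they are excluded from scoring (they do
contribute energy). A valid day therefore scores 1–8; a day containing only
salt and oil would score 0 and is treated as an error rather than silently
kept.

Two decisions here were genuinely open:

* **Membership requires a positive amount.** A record with `amount = 0`
  (possible in inventory-style data) does not make its group "consumed".
* **Averaging is nested**: daily scores are averaged within each wave, and
  the one or two wave means are averaged unweighted. The source procedure
  describes per-wave averages first and cross-wave averaging second, which
  is only distinguishable from pooling all days when day counts differ
  between waves; `score_dds(..., averaging = "pooled")` exposes the pooled
  alternative for sensitivity use. Per-group consumption (grams per
  1000 kcal, computed day by day) is averaged by the same scheme so that
  exposure and consumption describe the same construct.

Energy adjustment divides a day's group grams by that day's energy intake
(`sum(amount * energy_density / 100)`) and multiplies by 1000. Whether the
energy adjustment should feed the DDS itself is moot: adjustment cannot
change presence/absence, so the scores coincide; the package computes DDS
from raw group presence.

## The healthy aging score

Four indices are each rescaled to [0, 1] by their full score and summed,
with cognition reversed, giving a 0–4 composite where 0 is healthiest:
limitations/5 + comorbidities/6 + (1 − cognition/27) + PSS/56.

* **Hypertension** counts toward comorbidity if previously diagnosed *or*
  measured SBP ≥ 140 and/or DBP ≥ 90 mmHg — a participant unaware of their
  hypertension is still hypertensive.
* **Cognition** totals 27 points. The component maxima are not printed in
  the source; the allocation 10 (immediate recall) + 10 (delayed recall) +
  5 (Serial 7s) + 2 (backward counting: 2 first try, 1 second, 0 fail) is
  the standard telephone-interview allocation and the only natural fit to
  a 27-point total. It is reconstructed, not verbatim.
* **PSS** items are coded never = 0 … very often = 4, forced by the printed
  0–56 range of 14 items (a 1–5 coding would give 14–70). "Don't know" is
  imputed to "sometimes" (= 2), the scale midpoint, *before*
  reverse-scoring; since 4 − 2 = 2 the midpoint is reversal-invariant, so
  the order of imputation and reversal cannot matter. The set of
  reverse-scored (positively stated) items defaults to the instrument
  standard {4, 5, 6, 7, 9, 10, 13} but is an argument of `score_pss()`
  because survey item order varies between instruments.
* Participants answering "don't know" to *any* limitation or comorbidity
  item, or to *all 14* stress items, are excluded by the cohort filter;
  encountering such answers inside the scoring functions is treated as a
  bug (an error), not as data.

## Cohort rules

Inclusion requires age 60–80 at the outcome wave and at least one baseline
dietary wave. Exclusions are applied sequentially in the declared order
(age; missing covariates; absent from the dietary survey; missing
aging-index items; "don't know" on limitation/comorbidity; all-"don't know"
stress), and the count removed at each step is recorded, so the flow can be
reported like a recruitment diagram. Income is exempt from the
missing-covariate rule: missing incomes are imputed with the median of the
same survey site at the same wave, then converted to tertiles within wave.

All rank-based splits (income tertiles, DDS tertiles, cognition and stress
tertiles, food-group tertiles) use one deterministic rule: cutpoints at the
⌊n/3⌋-th and ⌊2n/3⌋-th order statistics with boundary ties assigned to the
lower group. Fully tied vectors cannot be split and raise an error. For
food groups with many non-consumers (fruits, aquatic products, dairy) the
exposure is instead non-consumer / at-or-below the consumer median / above
it; exact-median consumers fall in "low" so the three categories are
exhaustive.

## The association models

Linear regression for HAS; cumulative-logit proportional-odds models for
the categorized components; a baseline-category multinomial model (fair as
reference) for self-rated life quality. Confidence intervals are Wald at
95% throughout — the convention of the standard fitting packages
(`MASS::polr`, `nnet::multinom`) whose output these tables mirror — and no
multiple-testing correction is applied. The proportional-odds assumption
is deliberately not tested or enforced. With only two observed outcome
levels the cumulative model *is* binary logistic regression, and the
package fits it as such rather than failing.

Outcome level order encodes direction: limitation, comorbidity and stress
categories run from none to most, so an odds ratio below 1 means healthier;
cognition tertiles run from low to high function, so there an odds ratio
above 1 means healthier.

The trend test assigns each exposure category the within-category median of
the underlying continuous exposure and refits the model with that single
numeric regressor; its Wald p-value is the p-trend. With two categories
this reduces exactly to the dummy-coded Wald test (the regressor is an
affine transform of the dummy), which the tests verify.

Subgroup analyses stratify on age (≤ 60 vs > 60 years), gender, region,
BMI (< 24 vs ≥ 24), smoking and alcohol; interaction is tested by a
likelihood-ratio test between the adjusted model with and without
exposure-by-stratifier terms. Two conventions are worth stating: the
within-stratum models adjust for all covariates *except* the stratifying
one (and its continuous parent, e.g. BMI for the BMI groups); and the age
cut is applied exactly as stated even though the cohort window starts at
60, so the lower age stratum consists of the 60-year-olds only.

## The synthetic cohort generator

`simulate_cohort()` exists so that every stage — schema validation,
filtering, scoring, and all three model families — can be exercised with
known truth and no access to restricted survey data. It emulates the
*structure* of the real cohort: two baseline waves with a configurable
single-wave fraction (default 0.352, the observed share), three recall
days per wave, about twelve survey sites carrying log-normal income
structure (which makes site-median imputation meaningful), covariate
margins near the published baseline table, and an outcome questionnaire
with the exact item layout the scoring functions expect.

Effects are planted on four latent component propensities. A participant's
"unhealth shift" is linear in their realized DDS (the value the analysis
pipeline itself computes from the generated records), in education, income
tertile and age; one quarter of the shift goes to each component
propensity, and each questionnaire component is drawn with that propensity
as its per-item success probability (binomially for limitation counts,
disease counts and the cognition components; as a graded 0–4 response per
stress item). Because the conditional mean of every component is exactly
linear in the planted predictors, the covariate-adjusted linear model of
the composite is correctly specified, and the parameter-recovery check
tests estimation rather than discretization artifacts. Three details keep
that exact:

* the income tertile entering the outcome model is computed *after* the
  same site-median imputation the analysis applies;
* the stress-item slope is scaled by 1/(1 − p_dk) so that "don't know"
  imputation at scoring time does not attenuate the planted effect;
* propensities are clamped to [0.005, 0.995]; with the default baselines
  (0.25, 0.30, 0.55, 0.30) and noise SD 0.07 the clamp binds for well
  under 1% of draws, a bias far below the Monte-Carlo resolution of the
  validation.

Confounding is planted through education and income, which shift both the
food-group consumption probabilities (via a latent socioeconomic factor)
and the outcome propensities in opposite directions, so crude estimates
exceed adjusted ones in magnitude — the qualitative attenuation pattern a
real analysis shows. Self-rated life quality is drawn from a multinomial
logit in the participant's *realized* HAS (planted log odds per HAS unit:
−1.0 for good, +1.4 for bad, fair as reference), so the life-quality model
is also correctly specified.

Food amounts are log-normal with medians anchored loosely to published
consumption levels (staple ~400 g/day raw, vegetables ~240 g, dairy rare
at ~12% daily probability, etc.). These are order-of-magnitude choices:
the generator reproduces the data *structure* and the planted effects, not
the marginal distributions of any real population, nor geographic realism,
nor survey weights. Passing tests therefore show the pipeline is correct
and calibrated under its assumptions — not that any real-data coefficient
is reproduced; the published headline coefficients derive from restricted
data and are out of reach by design.

All randomness flows from a single seed in a fixed draw order (sites,
participants, wave membership, dietary records, propensities, items, life
quality), so equal configs give byte-identical output files; this is
asserted at file-hash level.

## Validation problem sizes

The test suite validates at sizes chosen to balance Monte-Carlo resolution
against run time: parameter recovery and CI coverage with n = 5000 over
100 seeded replicates (planted −0.05 HAS per DDS point; bias within 2
Monte-Carlo SEs, coverage within [90%, 99%]); interaction-test size with
200 null replicates at n = 2000 (rejection rate within the binomial 95%
band around 0.05); trend-test null uniformity with 1000 replicate
p-values at n = 240 (Kolmogorov–Smirnov p > 0.01); and a 1000-vector
brute-force oracle for stress scoring. The 12-participant worked example
(`generate_worked_example()`) pins every score to a hand-computed fraction
at 10⁻⁹.

## Known limitations

* The cognition point allocation and the stress-item reversal set are
  reconstructions (standard, but not printed in the source); both are
  configurable where feasible.
* Exposure averaging treats the two baseline waves as exchangeable; no
  secular trend between 2009 and 2011 is modeled.
* The generator's food amounts and covariate margins are coarse anchors;
  do not use it to study distributional properties of real diets.
* No survey weights, no imputation beyond income, no causal or mediation
  analysis — matching the scope of the analysis it implements.
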