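---
title: "Modelling calcium fortification of flour from dietary recall surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling calcium fortification of flour from dietary recall surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calfort)
```

## The problem

Calcium intake is far below requirements in much of the world, and flour is
one of the few food vehicles reaching most of a population daily. Before a
country mandates fortification it needs to know two things for every
life-stage group: how much the prevalence of *inadequate* intake (usual
intake below the Estimated Average Requirement, EAR) would fall, and whether
any group would be pushed over the Tolerable Upper Intake Level (UL). Both
questions are about the distribution of *usual* (habitual) intake, which a
single 24-hour recall does not measure directly: one observed day mixes
stable between-person differences with large day-to-day noise, so the
one-day distribution is too wide and both tail prevalences are
overestimated.

`calfort` implements the full planning pipeline: per-day aggregation of
recall records into calcium and fortifiable-flour totals, a measurement-error
adjustment recovering the usual-intake distribution, the EAR cut-point
method for prevalence, a deterministic fortification scenario (default 156
mg calcium per 100 g flour, the UK mandatory level for white wheat flour,
applied here to all flour types jointly), and the target-prevalence /
initial-gap rule used to size a fortificant dose.

## The measurement-error model and the adjustment

Let $U_i$ be subject $i$'s usual daily calcium intake and $D_{ij}$ the
intake observed on recall day $j$. On a transformed scale (natural log with
a +1 mg offset by default) the model is the classical one-way
random-effects decomposition

$$t_{ij} = \log(D_{ij}+1) = \mu_g + b_i + \varepsilon_{ij},
\qquad b_i \sim (0, \sigma^2_B),\ \varepsilon_{ij} \sim (0, \sigma^2_W),$$

with $\sigma^2_B$ the between-person and $\sigma^2_W$ the within-person
(day-to-day) variance. With at least some subjects observed on two
non-consecutive days, `estimate_variance_components()` estimates
$\sigma^2_W$ as the (survey-weighted) mean of per-subject sample variances
and $\sigma^2_B$ as the weighted variance of subject means minus
$\sigma^2_W/\bar{k}$ ($\bar{k}$ = mean days per subject), floored at zero.
Any two distinct day indices count as a repeat; consecutive-day correlation
corrections are out of scope.

`adjust_distribution()` then shrinks each subject's transformed day-1 value
toward the weighted group mean:

$$t_i' = m + (t_i - m)\sqrt{\tfrac{1}{1+r}}, \qquad r = \sigma^2_W/\sigma^2_B,$$

and back-transforms. This best-linear-shrinkage form is the simplest member
of the family of usual-intake estimators built on the variance ratio $r$;
it preserves the weighted mean on the transformed scale exactly, multiplies
the transformed-scale SD by exactly $\sqrt{1/(1+r)}$, and is strictly
monotone, so no subject is re-ranked. For surveys with a single recall day
the ratio must come from outside (`variance_ratio_spec(mode = "external",
ratio = ...)`). The shipped external default of 2.0 on the log scale is an
order-of-magnitude placeholder and warns whenever it is used: variance
ratios are nutrient- and survey-specific and should always be taken from a
comparable survey with repeats.

Two deliberate numerical choices: zeros are handled by the +1 mg offset
(zero recorded calcium over a full day is a recall artefact, not biology,
but must not crash the log), and when the estimated between-person variance
is zero the adjusted distribution is returned degenerate at the group mean
with a warning rather than failing.

### A known, quantified bias

The generator (below) makes daily intake mean-unbiased for usual intake on
the *raw* scale, $E[D_{ij} \mid U_i] = U_i$, which places the day-1 log-scale
mean at $\mu - \sigma^2_W/2$ rather than $\mu$. Because the adjustment
preserves the transformed-scale mean (a property we consider more
fundamental than raw-scale calibration, and test to $10^{-9}$), the
adjusted distribution inherits a downward shift of $\sigma^2_W/2$ on the
log scale. The induced error in tail prevalences is
$\Phi(z + \sigma^2_W/(2\sigma_B)) - \Phi(z)$ — under one percentage point in
the high-prevalence regime where fortification planning operates (e.g. at a
true prevalence of 97.6% with $\sigma_B = 0.5$, $\sigma_W = 0.4$ the bias is
about +0.8 points), but it can reach several points where the EAR falls on
the steep part of the distribution. Methods that calibrate the
back-transformation against the observed day mean remove this bias at the
cost of the transformed-scale mean identity; we document rather than hide
the trade-off.

## Adequacy metrics and the planning rule

`prevalence()` applies the EAR cut-point method with *strict* inequalities:
values exactly at the EAR count as adequate and exactly at the UL as safe.
The planning rule in `target_prevalence()` is a step function of the
current prevalence of inadequacy: above 50% the target is 50%, from 10% to
50% (both endpoints included — "above 50%" is read strictly, "between 10%
and 50%" inclusively; both conventions are unit-tested) the target is 10%,
below 10% it is 0%. `initial_gap()` then reports
$\max(0, \mathrm{EAR} - Q(\text{target}))$, the daily milligrams separating
the target percentile $Q$ of the usual-intake distribution from the EAR,
and `gap_to_level()` converts that into mg per 100 g of flour through the
group's mean flour intake.

Percentiles throughout are survey-weighted with linear interpolation: the
continuous extension of R's type-7 sample quantile to cumulative weights,
chosen because it reduces *exactly* to integer weight expansion, which
gives every weighted statistic a brute-force oracle.

## The fortification scenario

Fortifying at level $L$ mg/100 g adds $L/100 \times \text{flour}_{ij}$ mg to
each subject-day — deterministic, linear, and exactly additive in the mean
(`apply_fortification()`). The fortifiable flour of a food is the sum of
its flour-type fractions (a food of 30% rice and 40% wheat flour is 70%
fortifiable); tablet or pill supplements may contain starch but are never
fortified, while powder and liquid supplements count toward calcium.
`run_scenario()` re-runs the adjustment on the fortified daily intakes
*reusing the baseline variance components*: the added amount is a
deterministic function of the same day's flour, so the variability
structure is unchanged, and reuse makes post-fortification dominance
(post %<EAR ≤ pre, post %>UL ≥ pre) a theorem rather than a tendency —
both adjusted values move by $(1-\lambda)(m'-m) + \lambda(t_i'-t_i) \ge 0$
pointwise. Selective fortification is available by filtering flour types in
`fortification_spec()`.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` draws, per group: usual intake
$U_i \sim \mathrm{LogNormal}(\mu, \sigma_B)$ (right-skewed, as intake
distributions are); daily intakes
$D_{ij} = U_i \exp(\varepsilon_{ij} - \sigma^2_W/2)$,
$\varepsilon_{ij} \sim N(0, \sigma^2_W)$, so $E[D|U] = U$; flour consumption
as Bernoulli(consumer probability) with consumer-day amounts
$\mathrm{Gamma}$(shape, scale = mean/shape); one or two recall days, with an
optional partial second-day subsample; and uniform or log-normal survey
weights. Each day is split into 2–5 food items, one of which carries the
day's flour exactly through the shipped flour map. Ground truth
(`$truth`) is computed from the generating log-normal by closed-form CDF,
never by sampling, and the latent per-subject usual intakes are returned
for direct checks.

The seven `paperlike_presets()` are moment-matched to published group-level
summaries from seven national and subnational surveys (see
`survey_profiles()`): the usual-intake log-normal matches each group's
reported calcium mean and SD, the Bernoulli–Gamma flour model matches the
reported consumer share and flour mean/SD, and the survey design features
(single-day Argentina, partial Lao repeats, weighted Argentina/USA samples)
are mirrored. The default within-person log-SD is 0.4, a day-to-day
coefficient of variation of roughly 40%, typical of calcium. What the
presets do **not** emulate: real food-composition detail, seasonal and
weekday effects, intra-household correlation, and the surveys' actual
adjustment internals — so passing tests demonstrate that the pipeline's
estimators recover known truth under the assumed model, not that they
reproduce any published table. Published country results are treated as
approximate reference points only; the worked-example consistency check
uses the model-free additivity identity (baseline mean + 1.56 × mean flour
= post mean), which published Argentina rows satisfy to 0.14%.

## Default parameters at a glance

| Parameter | Default | Why |
|---|---|---|
| fortification level | 156 mg Ca / 100 g flour | the UK mandatory level for white wheat flour; a feasible benchmark |
| flour types fortified | all | planning upper bound; filter via `flour_types` |
| transformation | log, offset 1 mg | right-skewed intakes; finite at zero |
| external variance ratio | 2.0 (placeholder, warns) | must be survey-specific; never silent |
| `min_n` | 10 (warn-only) | groups this small are flagged, not dropped, mirroring surveys' minimum-n exclusions |
| within-person log-SD (generator) | 0.4 | day-to-day CV ≈ 40%, typical for calcium |

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run entirely on generated data:
recovery checks use groups of n = 1000 across 200 seeded replicates
(analytic truth 97.6% below the EAR), cut-point oracle checks use up to
10⁴-point instances, convergence of the generator's empirical truth is
checked at n = 10⁵, and monotonicity across 50 random two-group cohorts of
n = 80 per group. These sizes give Monte-Carlo noise comfortably below the
asserted tolerances (e.g. binomial SE ≈ 0.5 points at n = 1000 for a 97.6%
prevalence).

## Known limitations

* Point estimates only: no uncertainty intervals around prevalences or gaps.
* The adjustment is the simple one-ratio shrinkage — not a full two-part
  episodic model, no covariates, no heterogeneous within-person variance —
  and carries the quantified transformed-scale-mean bias above.
* Prevalence by the cut-point method assumes requirement and intake are
  independent and requirements symmetric; it is not the full probability
  method.
* No bioavailability, nutrient-interaction, or cost modelling: the scenario
  measures intake, not absorbed calcium.
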