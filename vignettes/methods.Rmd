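---
title: "Estimating BMI trends from heterogeneous surveys: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating BMI trends from heterogeneous surveys: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`bmitrends` estimates national, regional and worldwide trends in mean
body-mass index (BMI) and in growth-reference BMI categories from
study-level survey data that differ in coverage (national, subnational,
community), urbanicity (population-mixed, urban-only, rural-only), sample
size and reporting. This vignette is the package's own account of the
model, its assumptions, the tunable parameters, the synthetic-data
generator, and the numerical choices made where the design was genuinely
open.

## 1. Growth-reference classification

Children's and adolescents' BMI is classified against an age- and
sex-specific growth reference in the Box-Cox (LMS) parameterisation: at
each age and sex the reference stores a skewness power $L$, a median $M$
(kg/m$^2$) and a coefficient of variation $S$. A measurement is converted
to an SD score

$$
z = \frac{(\mathrm{BMI}/M)^L - 1}{LS} \quad (L \neq 0), \qquad
z = \frac{\log(\mathrm{BMI}/M)}{S} \quad (L = 0),
$$

which is strictly increasing in BMI, so z-score cutoffs correspond to
age/sex-specific BMI cutoffs (`lms_inverse()` places them on the BMI
scale). The shipped child/adolescent scheme cuts at $-2, -1, +1, +2$ SD:
moderate-and-severe underweight, mild underweight, healthy weight,
overweight (not obese), obesity. "More than $k$ SD" is strict, so a value
exactly at a cutoff belongs to the category nearer the median: $z = -2$ is
mild underweight and $z = +2$ is overweight-not-obese. The adult preset
(`scheme_adult_bmi()`) instead uses conventional lower-closed fixed-BMI
cutoffs (obesity at BMI $\ge 30$). Observations carry integer age in
completed years and are matched to the reference at the band midpoint in
months (`year * 12 + 6`); this is a repository convention chosen for
determinism — sources differ in how they report fractional age, and no
single reconstruction is possible from study-level data.

The package ships no copyrighted reference table. `generate_lms_reference()`
produces a deterministic synthetic stand-in with the qualitative shape of a
child/adolescent BMI reference (median rising through adolescence, mildly
negative $L$, widening $S$); any real table in the documented CSV format
can be supplied instead.

## 2. The hierarchical trend model

One fitted model owns exactly one outcome — mean BMI, or a single category
prevalence — and one sex; the five categories are modelled separately and
recombined only at reporting time. For observation $i$ from country $c$,
year $t$, age $a$:

$$
\eta_i = A_c + B_c (t - t_0) + \textstyle\sum_\ell u_\ell(t) + s_c(a)
 + \beta_{\mathrm{urb}}\, U_c(t) + \delta_{sn} \mathbb{1}[\text{subnat}]
 + \delta_{cm} \mathbb{1}[\text{community}] + \delta_{u/r}\, w_i + e_{s(i)},
$$

with $y_i \sim \mathcal N(\eta_i,\; \mathrm{se}_i^2 + \tau^2_{k(i)})$ on
the link scale (identity for mean BMI, logit for prevalences, with
delta-method standard errors $\mathrm{se}/(p(1-p))$ and $p$ floored at
0.005 — bounded outcomes need a link, and the logit keeps every posterior
prevalence in $(0,1)$).

* **Hierarchy.** $A_c$ and $B_c$ decompose as global + superregion +
  region + country Gaussian deviations, so sparse-data countries borrow
  strength from their region and the world, and a data-free country's
  trajectory shrinks to its region/global mean.
* **Nonlinear time.** Each level $\ell$ (global, each superregion, region,
  country) carries a second-order random walk $u_\ell(t)$ with
  level-specific precision $\kappa_\ell$, constrained to
  $\sum_t u(t) = 0$ and $\sum_t t\,u(t) = 0$ so it is identified against
  the hierarchical intercepts and slopes.
* **Age.** $s_c(a)$ is a cubic B-spline (5 interior knots by default,
  placed at quantiles of observed ages) whose coefficients are a global
  vector plus shrunken country deviations. The basis columns are centred
  over the estimation age grid, so the spline is orthogonal to the
  intercept. Two spline levels (global + country) rather than the full
  four-level chain: age patterns vary by country, and intermediate-level
  age deviations are unidentifiable at realistic data densities.
* **Study quality.** Fixed effects $\delta_{sn}, \delta_{cm}$ absorb
  systematic offsets of subnational and community samples; study random
  effects $e_s$ with coverage-class-specific SDs $\phi_k$ (prior scales
  increasing from national to community) let national data pull estimates
  harder than equally sized community data; extra variances $\tau^2_k$
  absorb residual overdispersion per class.
* **Urbanisation.** $U_c(t)$, the national proportion living in urban
  areas, enters as a global covariate (a single $\beta_{\mathrm{urb}}$;
  making it hierarchical is unidentified at desk scale). Urban-only and
  rural-only studies get fixed effects weighted by
  $w_i = u_{\text{study}} - U_c(t)$, where $u_{\text{study}}$ is 1 for
  urban-only and 0 for rural-only samples, so the adjustment scales with
  how unrepresentative the sample is of the country that year.

**Priors.** Half-normal priors on all SD components (weakly informative and
proper; scales in `prior_spec()`, e.g. 2/1/0.7 kg/m$^2$ for intercept
deviations by level and 0.3/0.6/1.0 for study-effect SDs by class),
$\mathcal N(0, 10^2)$ on the global intercept, slope and fixed effects, and
Gamma(1, $10^{-4}$) priors on the RW2 precisions. These are repository
defaults, not reproductions of any published analysis.

## 3. Sampler

`run_mcmc()` is a blocked Gibbs sampler with Metropolis steps:

1. **Joint Gaussian block** — hierarchical intercepts/slopes, all fixed
   effects, *and the study random effects* in one canonical-form draw. The
   coverage/urbanicity fixed effects and the study effects of the few
   studies that identify them are strongly correlated a posteriori;
   updating them in separate blocks mixes so slowly that interval coverage
   degrades, so they are drawn jointly (the cross-products are assembled
   by group sums, keeping the cost linear in the data).
2. **RW2 paths**, level by level and unit by unit, from their Gaussian
   Markov full conditionals; the two linear constraints are imposed by
   conditioning-by-kriging, after adding precision along the constraint
   directions (which leaves the constrained law unchanged) so the
   factorisation is full-rank even for data-free units.
3. **Spline coefficients**: the global vector, then per-country deviations
   (data-free countries draw from the prior).
4. **RW2 precisions** by conjugate Gamma updates; every SD component by
   adaptive random-walk Metropolis on the log scale (target acceptance
   0.44, Robbins-Monro adaptation frozen at the end of burn-in to preserve
   detailed balance).

Initialisation is weighted least squares on the linear hierarchy plus
spline under the prior ridge, zeros for RW2 and study effects, and
method-of-moments-scale variances; a non-finite posterior at initialisation
aborts with the offending component named. The default schedule is 10,000
iterations with 5,000 burn-in and no thinning (5,000 retained draws); the
sampler is deterministic given its seed, and split-chain scale reduction
and effective sample size for monitored scalars are reported in
`glance()`.

## 4. Post-processing

All derived quantities are computed draw-wise and summarised last, because
only the mean commutes with the nonlinear steps:

* **Rescaling**: the five separately modelled category prevalences are
  divided by their draw-wise sum so they sum to exactly 1 in each age,
  sex, country and year; per-draw scaling factors are returned for audit.
  Rescaling happens after prediction and before any standardisation or
  aggregation.
* **Age-standardisation**: weighted average over ages with
  standard-population weights (an input; `standard_population()` is a
  documented synthetic default declining gently with age, normalised to
  sum to 1).
* **Aggregation**: population-weighted averages of constituent country
  draws by year and age for regions and the world.
* **Counts**: age-specific prevalence times population, summed over ages;
  country counts add up to regional and world counts.
* **Summaries**: posterior means with 2.5th-97.5th percentile credible
  intervals (linear-interpolation quantile rule, R type 7); trend
  direction is the sign of the posterior mean change, and the posterior
  probability (PP) is the fraction of draws changing in that direction
  (exact zeros count half, so a flat trajectory reports PP = 0.5).
* **Change per decade** is the endpoint difference scaled to 10 years —
  for a linear trajectory this equals 10 times the annual slope; it is
  not a regression slope, and that choice is deliberate and documented.
* **Decomposition**: the change in affected counts between two years
  splits exactly into prevalence-at-baseline-population,
  population-at-baseline-prevalence, and interaction terms; shares are
  reported relative to the total and may be negative when components
  oppose.

## 5. The synthetic-data generator

`generate_world()` draws a ground-truth world from the model's own
generative structure, and `simulate_studies()` samples a study database
from it. The default desk-scale conditions — chosen once as what a
practitioner would call a realistic miniature of global anthropometric
surveillance, and small enough for minutes-scale fits — are:

* 2 superregions, 4 regions, 12 countries, years 1975-2016, ages 5-19 in
  1-year bands, one sex per world;
* baseline mean BMI 18 kg/m$^2$ at the window/age centre, global trend
  +0.03 kg/m$^2$ per year; intercept deviation SDs 0.8/0.5/0.4 kg/m$^2$
  and slope deviation SDs 0.015/0.010/0.008 by level; RW2 second-difference
  SDs of 0.003-0.004 (smooth multi-year departures of a few tenths of a
  unit); an age pattern rising about 0.33 kg/m$^2$ per year of age with
  small country-specific curvature;
* an urbanisation effect of 1 kg/m$^2$ per unit urban proportion;
  coverage biases $-0.2$ (subnational) and $-0.35$ (community); urbanicity
  effects 1.0 (urban) and 0.8 (rural); study-effect SDs 0.15/0.25/0.35 by
  class; individual-level SD 3 kg/m$^2$ for survey standard errors;
* studies arrive in about 20% of country-years, roughly half national,
  one sixth subnational and one third community — the approximate
  composition of pooled anthropometric databases — with per-band sample
  sizes of 200-1500. Prevalence worlds are generated on the logit scale
  to match the model's link.

What the generator deliberately does **not** emulate: real countries'
values, reporting heterogeneity beyond the schema (self-reported vs
measured anthropometry, differing category definitions), non-random
missingness correlated with the outcome, and within-study age-band
correlation of sampling errors. Passing recovery and calibration tests on
these worlds therefore shows the estimation machinery is correct and
calibrated *under the model's own assumptions*, not that those assumptions
hold for any real database.

## 6. Numerical choices and degenerate inputs

* Prevalence observations are clamped to $[0.005, 0.995]$ before the logit
  and delta-method transforms; predictions are clamped to
  $(10^{-6}, 1-10^{-6})$.
* Prevalence standard errors from degenerate samples are floored at
  $\sqrt{0.25/n} \times 0.05$ so $p \in \{0, 1\}$ cannot carry infinite
  weight; missing standard errors are imputed (binomial for prevalences,
  pooled-SD 3.5 kg/m$^2$ for means) and flagged in the issue report.
* Multi-year fieldwork is represented by the floor of the midpoint year;
  sex-combined rows are rejected for lack of a defensible weight.
* Time is centred at the window midpoint; ties in quantile computation are
  broken by stable sort; the RW2 prior rank is $T-2$ per unit.
* Fits refuse to predict outside the fitted year window or age grid:
  the model smooths and interpolates, it does not project.

## 7. Problem sizes used in the tests

The shipped test-suite and acceptance script run the package at the
desk-scale conditions above: one full desk-scale fit with 2,000 retained
draws for interval calibration; 20 replicate fits of a reduced world
(8 countries, 1997-2016, ages 5-19 every 2 years, 1,200 iterations) for
fixed-effect recovery; a one-country conjugate fixture checked against
the closed-form Gaussian posterior; and micro-worlds (3-4 countries, about
a decade, 2-3 ages) for the pipeline and determinism checks. These sizes
are the package's own choice of a reproducible desk-scale experiment;
estimates for the real world would use the full default schedule (5,000
retained draws) on the full database.

## 8. Known limitations

* The concrete model form (level-specific RW2, two-level spline, global
  urbanisation coefficient, additive class biases) is one committed
  interpretation of the estimation problem; other defensible variants
  exist and would change desk-scale estimates somewhat.
* Single-chain diagnostics (split-$\hat R$, ESS) catch gross
  non-convergence only; for publication-grade runs, fit with several seeds
  and compare.
* Ages 18-19 sit in both the child/adolescent and adult analyses of
  published work; here every configured run owns a single age range, and
  cross-range consistency is the user's responsibility.
* The rescaling audit (mean scaling factors) is reported but no automatic
  action is taken when category models disagree strongly; inspect
  `scaling_summary` in reports.
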