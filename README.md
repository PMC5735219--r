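# bmitrends

Hierarchical Bayesian estimation of body-mass-index (BMI) trends from
heterogeneous population surveys.

## The problem

Tracking how mean BMI and the prevalence of underweight, overweight and
obesity change over decades — by country, region and worldwide — has to be
done from whatever measured-anthropometry studies exist: national
examination surveys in some country-years, subnational or single-community
studies elsewhere, urban-only or rural-only samples, and long stretches
with no data at all. Naively pooling these sources confounds real trends
with changes in who was surveyed. `bmitrends` is for biostatisticians and
epidemiologists who need country-year-age estimates, with honest
uncertainty, from exactly this kind of patchwork.

## The model

Children's and adolescents' BMI is classified against an LMS growth
reference: `z = ((BMI/M)^L − 1)/(L·S)` (log form at `L = 0`), with
categories cut at −2, −1, +1, +2 SD of the reference median (obesity is
strictly more than +2 SD). Mean BMI and each category prevalence are then
modelled separately by a Bayesian hierarchical model: for a study
observation in country `c`, year `t`, age `a`,

```
eta = A_c + B_c (t − t0) + sum_l u_l(t) + s_c(a) + b_urb U_c(t)
      + d_sn + d_cm + d_{u/r} w + e_study,
y ~ Normal(eta, se² + tau²_class)        (logit link for prevalences)
```

where `A_c, B_c` decompose hierarchically over
global → superregion → region → country, `u_l(t)` are level-specific
second-order random walks (nonlinear time trends), `s_c(a)` is a
hierarchical cubic age spline, `U_c(t)` is the national urban-population
proportion, `d_sn`/`d_cm` adjust subnational and community samples,
urban-/rural-only studies are weighted by the study-minus-country
urbanisation difference `w`, and study random effects with
coverage-class-specific variances let national data pull harder than
community data. A blocked Gibbs/Metropolis sampler returns posterior
draws; post-processing rescales categories to sum to 1, age-standardises
with standard-population weights, aggregates countries
population-weighted, and reports means, 2.5–97.5% credible intervals,
trend posterior probabilities, affected counts and an exact decomposition
of count changes into prevalence, population and interaction components.

A synthetic-data module (`generate_world()`, `simulate_studies()`)
generates ground-truth worlds with this exact structure, so the whole
pipeline is testable without any external data.

## Worked example

Simulate a 6-country world, fit mean BMI, and summarise:

```r
library(bmitrends)

w   <- generate_world(n_countries = 6, n_regions = 3, years = 1990:2016,
                      seed = 42)
obs <- simulate_studies(w, seed = 43)
val <- validate_observations(obs, years = c(1990L, 2016L))
val$counts
#> # A tibble: 3 × 2
#>   disposition  rows
#>   <chr>       <int>
#> 1 accepted      510
#> 2 rejected        0
#> 3 imputed_se      0

spec <- model_spec(years = c(1990, 2016), iterations = 2000, burn_in = 1000)
fit  <- run_mcmc(build_model(val$observations, w$meta, spec), seed = 44)
glance(fit)
#> # A tibble: 1 × 9
#>   outcome  n_obs n_studies n_countries n_draws max_rhat min_ess mean_lp runtime_s
#>   <chr>    <int>     <int>       <int>   <int>    <dbl>   <dbl>   <dbl>     <dbl>
#> 1 mean_bmi   510        34           6    1000     1.10    10.6   1264.      20.2
```

Age-standardised country estimates and the world trend:

```r
dr  <- predict(fit)                                  # (draw, country, year, age)
sp  <- standard_population(w$ages)
est <- summarise_draws(age_standardise(unclass(dr), sp))
head(est, 4)
#> # A tibble: 4 × 5
#>   country year   mean lower upper
#>   <chr>   <chr> <dbl> <dbl> <dbl>
#> 1 C01     1990   19.0  18.4  19.6
#> 2 C02     1990   19.0  18.6  19.4
#> 3 C03     1990   18.7  18.0  19.4
#> 4 C04     1990   19.2  18.8  19.6

agg <- aggregate_draws(unclass(dr), w$meta$population, sex = "female")
change_per_decade(age_standardise(agg, sp), 1990, 2016)
#> # A tibble: 1 × 6
#>   group  mean lower upper direction    pp
#>   <chr> <dbl> <dbl> <dbl> <chr>     <dbl>
#> 1 World 0.572 0.354 0.795 increase      1
```

The world's age-standardised mean BMI rises by an estimated 0.57 kg/m²
per decade (95% CrI 0.35–0.80), and every posterior draw increases
(PP = 1) — as it should, since this synthetic world was generated with a
rising global trend. `plot_trend(est)`, `plot_age_pattern(fit)` and
`autoplot(dr)` draw the standard figures; `tidy(fit)` returns parameter
summaries.

`pipeline_simulate()` / `pipeline_fit()` / `pipeline_report()` (or
`pipeline_run()`, and the thin CLI in `inst/scripts/bmi-pipeline.R`)
orchestrate simulate → validate → fit → report with manifests and
digests for reproducibility.

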