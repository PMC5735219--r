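#' Default parameters for a synthetic world
#'
#' The generator draws a ground-truth world from the same generative
#' structure the hierarchical model assumes: hierarchical intercepts and
#' slopes, second-order random-walk (RW2) deviations at every level, a smooth
#' age pattern with country-level variation, an urbanisation covariate
#' effect, additive coverage and urbanicity biases, and study-level random
#' effects. Mean-BMI worlds live on the kg/m^2 scale; prevalence worlds are
#' generated on the logit scale and inverse-linked, matching the model's
#' link.
#'
#' @param outcome `"mean_bmi"` or `"prevalence:<category>"`.
#' @return Named list of generator parameters (documented in the methods
#'   vignette); override any element via the `params` argument of
#'   [generate_world()].
#' @export
world_params <- function(outcome = "mean_bmi") {
  if (identical(outcome, "mean_bmi")) {
    list(
      intercept = 18.0,            # kg/m^2 at the window/age centre
      slope = 0.03,                # kg/m^2 per year, global
      sd_alpha = c(superregion = 0.8, region = 0.5, country = 0.4),
      sd_beta = c(superregion = 0.015, region = 0.010, country = 0.008),
      rw_step_sd = c(global = 0.004, superregion = 0.003,
                     region = 0.003, country = 0.003),
      age_lin = 0.33, age_quad = 0.012,     # base age pattern, per year
      age_dev_sd = c(lin = 0.02, quad = 0.003),
      beta_urban = 1.0,
      delta = c(subnational = -0.2, community = -0.35,
                urban = 1.0, rural = 0.8),
      study_sd = c(national = 0.15, subnational = 0.25, community = 0.35),
      individual_sd = 3.0)
  } else {
    list(
      intercept = qlogis(0.08),    # logit scale
      slope = 0.02,
      sd_alpha = c(superregion = 0.5, region = 0.3, country = 0.25),
      sd_beta = c(superregion = 0.010, region = 0.006, country = 0.005),
      rw_step_sd = c(global = 0.002, superregion = 0.0015,
                     region = 0.0015, country = 0.0015),
      age_lin = 0.05, age_quad = 0.004,
      age_dev_sd = c(lin = 0.008, quad = 0.0015),
      beta_urban = 0.5,
      delta = c(subnational = -0.10, community = -0.15,
                urban = 0.5, rural = 0.4),
      study_sd = c(national = 0.10, subnational = 0.15, community = 0.20),
      individual_sd = NA_real_)    # prevalence SEs are binomial
  }
}

# RW2 path with steps of sd `step_sd`, projected onto the identifiability
# constraints sum(u) = 0 and sum(t*u) = 0 (OLS detrending).
rw2_path <- function(T, step_sd) {
  u <- numeric(T)
  if (step_sd > 0 && T >= 3) {
    for (t in 3:T) u[t] <- 2 * u[t - 1] - u[t - 2] + rnorm(1, 0, step_sd)
  }
  detrend_rw(u)
}

detrend_rw <- function(u) {
  t <- seq_along(u) - (length(u) + 1) / 2
  u <- u - mean(u)
  u - t * sum(t * u) / sum(t * t)
}

#' Generate a ground-truth synthetic world
#'
#' Draws country trajectories from the model's own generative prior:
#' countries are organised round-robin into regions and superregions, each
#' level contributes Gaussian intercept/slope deviations and an RW2 time
#' deviation, every country gets a smooth age pattern, an urbanisation series
#' and a population series. The default desk-scale world (2 superregions x
#' 4 regions x 12 countries, 1975-2016, ages 5-19, one sex) is small enough
#' for minutes-scale fits.
#'
#' @param n_superregions,n_regions,n_countries Hierarchy sizes.
#' @param years Integer vector of analysis years.
#' @param ages Integer vector of ages (completed years).
#' @param outcome `"mean_bmi"` or `"prevalence:<category>"`.
#' @param sex `"female"` or `"male"` (one sex per world; fits are by sex).
#' @param params Overrides merged over [world_params()].
#' @param seed Integer seed; the generator is a pure function of
#'   configuration and seed.
#' @return An object of class `bmi_world`: truth arrays (`eta` on the link
#'   scale and `truth` on the natural scale, country x year x age), per-level
#'   RW2 paths, fixed-effect truths, and `meta` (a [country_meta()] object).
#' @export
generate_world <- function(n_superregions = 2, n_regions = 4,
                           n_countries = 12, years = 1975:2016,
                           ages = 5:19, outcome = "mean_bmi",
                           sex = "female", params = list(), seed = 1L) {
  if (n_superregions < 1 || n_regions < n_superregions ||
      n_countries < n_regions) {
    stop_bad_arg("Need n_superregions <= n_regions <= n_countries, all >= 1.",
                 "bmitrends_config_error")
  }
  p <- modifyList(world_params(outcome), params)
  set.seed(as.integer(seed))

  countries <- sprintf("C%02d", seq_len(n_countries))
  regions <- sprintf("R%02d", rep_len(seq_len(n_regions), n_countries))
  region_names <- sprintf("R%02d", seq_len(n_regions))
  superregions <- sprintf("S%d", rep_len(seq_len(n_superregions), n_regions))
  region_map <- tibble(country = countries, region = regions,
                       superregion = superregions[match(regions,
                                                        region_names)])

  T <- length(years); A <- length(ages); C <- n_countries
  x <- years - mean(years)
  a_cent <- ages - mean(ages)

  # hierarchical intercepts and slopes
  a_sr <- rnorm(n_superregions, 0, p$sd_alpha[["superregion"]])
  a_rg <- rnorm(n_regions, 0, p$sd_alpha[["region"]])
  a_ct <- rnorm(C, 0, p$sd_alpha[["country"]])
  b_sr <- rnorm(n_superregions, 0, p$sd_beta[["superregion"]])
  b_rg <- rnorm(n_regions, 0, p$sd_beta[["region"]])
  b_ct <- rnorm(C, 0, p$sd_beta[["country"]])
  sr_of_region <- match(superregions, sprintf("S%d", seq_len(n_superregions)))
  reg_of_ctry <- match(regions, region_names)
  sr_of_ctry <- sr_of_region[reg_of_ctry]
  alpha <- p$intercept + a_sr[sr_of_ctry] + a_rg[reg_of_ctry] + a_ct
  beta <- p$slope + b_sr[sr_of_ctry] + b_rg[reg_of_ctry] + b_ct

  # level RW2 paths
  rw <- list(
    global = rw2_path(T, p$rw_step_sd[["global"]]),
    superregion = t(vapply(seq_len(n_superregions), function(i)
      rw2_path(T, p$rw_step_sd[["superregion"]]), numeric(T))),
    region = t(vapply(seq_len(n_regions), function(i)
      rw2_path(T, p$rw_step_sd[["region"]]), numeric(T))),
    country = t(vapply(seq_len(C), function(i)
      rw2_path(T, p$rw_step_sd[["country"]]), numeric(T))))
  rw_total <- matrix(rw$global, C, T, byrow = TRUE) +
    rw$superregion[sr_of_ctry, , drop = FALSE] +
    rw$region[reg_of_ctry, , drop = FALSE] +
    rw$country

  # age pattern: shared smooth curve plus small country deviations, centred
  base_age <- p$age_lin * a_cent + p$age_quad * a_cent^2
  base_age <- base_age - mean(base_age)
  dev_lin <- rnorm(C, 0, p$age_dev_sd[["lin"]])
  dev_quad <- rnorm(C, 0, p$age_dev_sd[["quad"]])
  age_effect <- outer(dev_lin, a_cent) + outer(dev_quad, a_cent^2)
  age_effect <- age_effect - rowMeans(age_effect)
  age_effect <- sweep(age_effect, 2, -base_age)

  # urbanisation series: rising logistic curves
  u0 <- rnorm(C, 0, 0.7)
  ur <- pmax(rnorm(C, 0.03, 0.01), 0.005)
  urban <- t(vapply(seq_len(C), function(c)
    plogis(u0[c] + ur[c] * x), numeric(T)))

  # populations: lognormal country sizes, mild growth, gently declining ages
  base_pop <- exp(rnorm(C, log(5e5), 0.8))
  growth <- rnorm(C, 0.012, 0.004)
  age_share <- (1 - 0.015 * (ages - min(ages)))
  age_share <- age_share / sum(age_share)
  population <- tidyr::expand_grid(country = countries, year = years,
                                   age = ages)
  ci <- match(population$country, countries)
  population$sex <- sex
  population$population <- base_pop[ci] *
    exp(growth[ci] * (population$year - years[1])) *
    age_share[match(population$age, ages)]
  population <- population[, c("country", "year", "sex", "age", "population")]

  eta <- array(0, dim = c(C, T, A),
               dimnames = list(country = countries, year = years, age = ages))
  for (t in seq_len(T)) {
    eta[, t, ] <- alpha + beta * x[t] + rw_total[, t] +
      p$beta_urban * urban[, t] + age_effect
  }
  link <- if (identical(outcome, "mean_bmi")) "identity" else "logit"
  truth <- if (link == "identity") eta else plogis(eta)

  meta <- country_meta(
    regions = region_map,
    urban = tibble(country = rep(countries, each = T),
                   year = rep(years, C),
                   urban_proportion = as.vector(t(urban))),
    population = population,
    years = range(years))

  structure(
    list(countries = countries, years = as.integer(years),
         ages = as.integer(ages), sex = sex, outcome = outcome, link = link,
         alpha = alpha, beta = beta, rw = rw, rw_total = rw_total,
         age_effect = age_effect, urban = urban, eta = eta, truth = truth,
         params = p, meta = meta, seed = as.integer(seed)),
    class = "bmi_world")
}

#' @export
print.bmi_world <- function(x, ...) {
  cat(sprintf(
    "<bmi_world: %d countries, %d-%d, ages %d-%d, outcome %s (%s), seed %d>\n",
    length(x$countries), min(x$years), max(x$years), min(x$ages), max(x$ages),
    x$outcome, x$sex, x$seed))
  invisible(x)
}

#' @method tidy bmi_world
#' @export
tidy.bmi_world <- function(x, ...) {
  grid <- tidyr::expand_grid(country = x$countries, year = x$years,
                             age = x$ages)
  grid$truth <- as.vector(x$truth[cbind(match(grid$country, x$countries),
                                        match(grid$year, x$years),
                                        match(grid$age, x$ages))])
  grid$sex <- x$sex
  grid$outcome <- x$outcome
  grid
}

#' Describe a synthetic study design
#'
#' Coverage mix defaults to the approximate composition of pooled
#' anthropometric databases (about half national samples, the rest split
#' between subnational and community samples); national studies are always
#' population-mixed, while subnational and community studies may be
#' urban-only or rural-only.
#'
#' @param coverage_mix Named proportions over national/subnational/community;
#'   must sum to 1.
#' @param urbanicity_mix Named proportions over mixed/urban/rural for
#'   non-national studies; must sum to 1.
#' @param p_study Probability that a given country-year contributes a study.
#' @param n_range Per-age-band sample-size range (uniform draw).
#' @param noise If `FALSE`, study effects and sampling noise are switched off
#'   (observations equal the study-level truth exactly).
#' @return A list of class `bmi_study_design`.
#' @export
study_design <- function(coverage_mix = c(national = 0.49, subnational = 0.16,
                                          community = 0.35),
                         urbanicity_mix = c(mixed = 0.5, urban = 0.25,
                                            rural = 0.25),
                         p_study = 0.2, n_range = c(200, 1500),
                         noise = TRUE) {
  if (length(coverage_mix) == 0L ||
      abs(sum(coverage_mix) - 1) > 1e-8 || any(coverage_mix < 0)) {
    stop_bad_arg("coverage_mix must be non-negative and sum to 1.",
                 "bmitrends_config_error")
  }
  if (abs(sum(urbanicity_mix) - 1) > 1e-8 || any(urbanicity_mix < 0)) {
    stop_bad_arg("urbanicity_mix must be non-negative and sum to 1.",
                 "bmitrends_config_error")
  }
  structure(list(coverage_mix = coverage_mix[COVERAGE_LEVELS],
                 urbanicity_mix = urbanicity_mix[URBANICITY_LEVELS],
                 p_study = p_study, n_range = n_range, noise = noise),
            class = "bmi_study_design")
}

#' Simulate a study database from a synthetic world
#'
#' Each sampled country-year contributes one study covering every age band of
#' the world. Observation values are the world's reference truth plus the
#' coverage fixed effect, the urbanicity effect weighted by the study-level
#' vs country-level urbanisation difference, a study-level random effect, and
#' sampling noise with a standard error derived from the band sample size.
#'
#' @param world A [generate_world()] object.
#' @param design A [study_design()].
#' @param seed Integer seed.
#' @return A validated observation tibble in the [read_observations()] schema.
#' @export
simulate_studies <- function(world, design = study_design(), seed = 1L) {
  set.seed(as.integer(seed))
  p <- world$params
  urban_by_year <- world$urban  # C x T
  rows <- vector("list", length(world$countries) * length(world$years))
  k <- 0L
  is_prev <- world$link == "logit"
  for (ci in seq_along(world$countries)) {
    for (ti in seq_along(world$years)) {
      if (runif(1) > design$p_study) next
      coverage <- sample(COVERAGE_LEVELS, 1, prob = design$coverage_mix)
      urbanicity <- if (coverage == "national") "mixed" else
        sample(URBANICITY_LEVELS, 1, prob = design$urbanicity_mix)
      u_c <- urban_by_year[ci, ti]
      w <- switch(urbanicity, mixed = 0, urban = 1 - u_c, rural = -u_c)
      bias <- switch(coverage, national = 0,
                     subnational = p$delta[["subnational"]],
                     community = p$delta[["community"]]) +
        switch(urbanicity, mixed = 0,
               urban = p$delta[["urban"]] * w,
               rural = p$delta[["rural"]] * w)
      e_s <- if (design$noise)
        rnorm(1, 0, p$study_sd[[coverage]]) else 0
      n_band <- round(runif(length(world$ages),
                            design$n_range[1], design$n_range[2]))
      eta_s <- unname(world$eta[ci, ti, ]) + bias + e_s
      if (is_prev) {
        p_cell <- plogis(eta_s)
        se <- sqrt(pmax(p_cell * (1 - p_cell), 1e-4) / n_band)
        value <- p_cell + if (design$noise)
          rnorm(length(se), 0, se) else 0
        value <- clamp(value, 1e-4, 1 - 1e-4)
      } else {
        se <- p$individual_sd / sqrt(n_band)
        value <- eta_s + if (design$noise) rnorm(length(se), 0, se) else 0
      }
      k <- k + 1L
      rows[[k]] <- tibble(
        study_id = sprintf("%s_%d", world$countries[ci], world$years[ti]),
        country = world$countries[ci],
        mid_year = world$years[ti],
        sex = world$sex,
        age_lower = world$ages, age_upper = world$ages,
        coverage = coverage, urbanicity = urbanicity,
        outcome = world$outcome,
        value = value, standard_error = se,
        sample_size = as.integer(n_band))
    }
  }
  if (k == 0L) {
    stop_bad_arg("Design produced no studies; raise p_study.",
                 "bmitrends_config_error")
  }
  dplyr::bind_rows(rows[seq_len(k)])
}

#' Plant schema violations in an observation table
#'
#' Used to exercise the validator: corrupts `n_bad` distinct rows with
#' violations the reader must reject, and reports which rows were corrupted.
#'
#' @param observations Observation tibble.
#' @param n_bad Number of rows to corrupt.
#' @param seed Integer seed.
#' @return List with `observations` (corrupted) and `bad_rows` (indices).
#' @export
corrupt_observations <- function(observations, n_bad, seed = 1L) {
  set.seed(as.integer(seed))
  n <- nrow(observations)
  if (n_bad > n) stop_bad_arg("n_bad exceeds row count.",
                              "bmitrends_value_error")
  bad <- sort(sample.int(n, n_bad))
  kinds <- sample(c("zero_se", "bad_sex", "bad_coverage", "old_year",
                    "zero_n", "inverted_ages"), n_bad, replace = TRUE)
  for (i in seq_along(bad)) {
    r <- bad[i]
    switch(kinds[i],
      zero_se = {observations$standard_error[r] <- 0},
      bad_sex = {observations$sex[r] <- "both"},
      bad_coverage = {observations$coverage[r] <- "unknown"},
      old_year = {observations$mid_year[r] <- 1900L},
      zero_n = {observations$sample_size[r] <- 0L},
      inverted_ages = {
        observations$age_lower[r] <- observations$age_upper[r] + 5L})
  }
  list(observations = observations, bad_rows = bad)
}

#' Deterministic synthetic growth reference
#'
#' Smooth closed-form L, M, S curves over the requested ages: the median BMI
#' rises through adolescence, the coefficient of variation widens slightly,
#' and the Box-Cox power is mildly negative (right-skewed BMI), one row per
#' 1-year band at the band-midpoint month. This is a synthetic stand-in with
#' the qualitative shape of a child/adolescent BMI reference, not a
#' reproduction of any published table.
#'
#' @param ages Integer ages in completed years (default 5-19).
#' @param sexes Which sexes to tabulate.
#' @return A growth-reference tibble (see [read_lms_reference()]).
#' @export
generate_lms_reference <- function(ages = 5:19,
                                   sexes = c("female", "male")) {
  if (length(ages) == 0L || any(ages < 2)) {
    stop_bad_arg("Invalid age range for a BMI reference.",
                 "bmitrends_config_error")
  }
  one_sex <- function(sex) {
    a <- as.numeric(ages) - 5
    male <- sex == "male"
    tibble(
      sex = sex,
      age_months = as.integer(ages) * 12L + 6L,
      L = round(-1.2 - 0.04 * a + ifelse(male, 0.05, 0), 4),
      M = round((if (male) 15.4 + 0.30 * a + 0.013 * a^2
                 else 15.2 + 0.32 * a + 0.012 * a^2), 4),
      S = round(0.085 + 0.003 * a + ifelse(male, 0.002, 0), 4))
  }
  dplyr::bind_rows(lapply(match.arg(sexes, several.ok = TRUE,
                                    choices = c("female", "male")), one_sex))
}

#' Simulate individual BMI measurements for one reference cell
#'
#' Draws z-scores from Normal(`mu_z`, `sigma_z`) and maps them through the
#' inverse LMS transform of the given reference row, so category counts
#' follow the corresponding normal-tail probabilities. Draws outside the
#' invertible z-range of the row (possible for extreme `sigma_z` with
#' non-zero L) are clamped to just inside it.
#'
#' @param n Number of individuals.
#' @param record One growth-reference row (list or single-row tibble with
#'   `L`, `M`, `S`).
#' @param mu_z,sigma_z Mean and SD of the true z-score distribution.
#' @param seed Integer seed.
#' @return Tibble with columns `z` and `bmi`.
#' @export
simulate_individuals <- function(n, record, mu_z = 0, sigma_z = 1,
                                 seed = 1L) {
  if (n < 1) stop_bad_arg("n must be >= 1.", "bmitrends_value_error")
  L <- record$L[[1]]; M <- record$M[[1]]; S <- record$S[[1]]
  if (!is.finite(M) || M <= 0 || !is.finite(S) || S <= 0) {
    stop_bad_arg("Invalid LMS record.", "bmitrends_domain_error")
  }
  set.seed(as.integer(seed))
  z <- rnorm(n, mu_z, sigma_z)
  if (abs(L) > 1e-12) {
    bound <- -1 / (L * S)
    z <- if (L * S > 0) pmax(z, bound + 1e-6) else pmin(z, bound - 1e-6)
  }
  tibble(z = z, bmi = lms_inverse(z, L, M, S))
}

#' Write a complete miniature input set
#'
#' Emits exactly the CSV schemas the readers consume: observations, region
#' map, urbanisation series, population table, growth reference, and a
#' standard-population weight table.
#'
#' @param world A [generate_world()] object.
#' @param observations Observation tibble for the world.
#' @param dir Output directory (created if needed).
#' @param force Overwrite an existing non-empty directory.
#' @return Invisibly, a named vector of written file paths.
#' @export
write_fixtures <- function(world, observations, dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force) {
    stop_bad_arg(sprintf("Directory '%s' is not empty (use force = TRUE).",
                         dir), "bmitrends_io_error")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    observations = file.path(dir, "observations.csv"),
    regions = file.path(dir, "regions.csv"),
    urban = file.path(dir, "urban.csv"),
    population = file.path(dir, "population.csv"),
    lms_reference = file.path(dir, "lms_reference.csv"),
    standard_population = file.path(dir, "standard_population.csv"))
  write_observations(observations, paths[["observations"]])
  readr::write_csv(world$meta$regions, paths[["regions"]])
  readr::write_csv(world$meta$urban, paths[["urban"]])
  readr::write_csv(world$meta$population, paths[["population"]])
  write_lms_reference(generate_lms_reference(world$ages),
                      paths[["lms_reference"]])
  readr::write_csv(standard_population(world$ages, world$sex),
                   paths[["standard_population"]])
  invisible(paths)
}
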