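test_that("world generation is a pure function of configuration and seed", {
  w1 <- tiny_world(seed = 21)
  w2 <- tiny_world(seed = 21)
  w3 <- tiny_world(seed = 22)
  expect_identical(w1$truth, w2$truth)
  expect_identical(w1$meta$urban, w2$meta$urban)
  expect_false(identical(w1$truth, w3$truth))
  o1 <- simulate_studies(w1, seed = 5)
  o2 <- simulate_studies(w1, seed = 5)
  expect_identical(o1, o2)
})

test_that("zero variances collapse every country onto the global line", {
  w <- generate_world(
    2, 4, 8, years = 2000:2010, ages = 8:12, seed = 3,
    params = list(
      sd_alpha = c(superregion = 0, region = 0, country = 0),
      sd_beta = c(superregion = 0, region = 0, country = 0),
      rw_step_sd = c(global = 0, superregion = 0, region = 0, country = 0),
      age_dev_sd = c(lin = 0, quad = 0),
      beta_urban = 0))
  for (c in 2:8) {
    expect_equal(w$truth[c, , ], w$truth[1, , ], tolerance = 1e-12)
  }
  # and the line is the configured global intercept/slope
  expect_equal(unname(w$alpha), rep(18, 8))
  expect_equal(unname(w$beta), rep(0.03, 8))
})

test_that("country slope dispersion matches the configured variance", {
  w <- generate_world(1, 1, 200, years = 2000:2005, ages = 10,
                      seed = 17)
  # single region/superregion: cross-country slope variance is the
  # country-level component alone
  sd_cfg <- world_params()$sd_beta[["country"]]
  v_hat <- var(w$beta)
  se_v <- sd_cfg^2 * sqrt(2 / (200 - 1))
  expect_lt(abs(v_hat - sd_cfg^2), 3 * se_v)
})

test_that("realised coverage mix matches the requested multinomial", {
  w <- generate_world(2, 4, 25, years = 1977:2016, ages = 10, seed = 23)
  obs <- simulate_studies(w, study_design(p_study = 1), seed = 24)
  studies <- obs[!duplicated(obs$study_id), ]
  n <- nrow(studies)
  mix <- c(national = 0.49, subnational = 0.16, community = 0.35)
  counts <- table(factor(studies$coverage, levels = names(mix)))
  for (k in names(mix)) {
    sd_k <- sqrt(n * mix[[k]] * (1 - mix[[k]]))
    expect_lt(abs(counts[[k]] - n * mix[[k]]), 3 * sd_k)
  }
})

test_that("noise-free national mixed studies reproduce the truth exactly", {
  w <- tiny_world(seed = 31)
  obs <- simulate_studies(
    w, study_design(coverage_mix = c(national = 1, subnational = 0,
                                     community = 0),
                    p_study = 1, noise = FALSE), seed = 32)
  ci <- match(obs$country, w$countries)
  ti <- match(obs$mid_year, w$years)
  ai <- match(obs$age_lower, w$ages)
  expect_equal(obs$value, w$truth[cbind(ci, ti, ai)], tolerance = 1e-12)
})

test_that("community bias shifts observations by the configured offset", {
  delta_cm <- 0.5
  w <- generate_world(1, 2, 6, years = 1990:2016, ages = 8:12, seed = 41,
                      params = list(delta = c(subnational = 0,
                                              community = delta_cm,
                                              urban = 0, rural = 0)))
  obs <- simulate_studies(
    w, study_design(coverage_mix = c(national = 0, subnational = 0,
                                     community = 1),
                    urbanicity_mix = c(mixed = 1, urban = 0, rural = 0),
                    p_study = 1), seed = 42)
  ci <- match(obs$country, w$countries)
  ti <- match(obs$mid_year, w$years)
  ai <- match(obs$age_lower, w$ages)
  dev <- obs$value - w$truth[cbind(ci, ti, ai)]
  # deviation = delta_cm + study effect + sampling noise
  n_study <- length(unique(obs$study_id))
  se_mean <- sqrt(w$params$study_sd[["community"]]^2 / n_study +
                    mean(obs$standard_error^2) / nrow(obs))
  expect_lt(abs(mean(dev) - delta_cm), 3 * se_mean)
})

test_that("individual z-draws hit the expected obesity tail", {
  ref <- generate_lms_reference()
  r <- lms_lookup(ref, "female", age_years = 10)
  ind <- simulate_individuals(20000, r, mu_z = 0, sigma_z = 1, seed = 51)
  frac <- mean(ind$z > 2)
  p <- pnorm(-2)
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / 20000))
  # sigma 0 collapses the sample
  ind0 <- simulate_individuals(10, r, mu_z = 0.3, sigma_z = 0, seed = 52)
  expect_equal(length(unique(ind0$bmi)), 1L)
  expect_identical(simulate_individuals(50, r, seed = 3),
                   simulate_individuals(50, r, seed = 3))
})

test_that("synthetic reference is valid and median-centred", {
  ref <- generate_lms_reference()
  expect_true(all(ref$M > 0) && all(ref$S > 0))
  # median BMI increases through adolescence
  for (sx in c("female", "male")) {
    expect_true(all(diff(ref$M[ref$sex == sx]) > 0))
  }
  # BMI at the median maps to z = 0, hence healthy weight at every age
  ind <- tibble::tibble(bmi = ref$M, sex = ref$sex,
                        age_months = ref$age_months)
  got <- classify_bmi(ind, ref)
  expect_true(all(got$category == "healthy_weight"))
})

test_that("emitted fixture files pass the readers with zero rejects", {
  w <- tiny_world(seed = 61)
  obs <- tiny_obs(w, seed = 62)
  dir <- withr::local_tempdir()
  paths <- write_fixtures(w, obs, dir, force = TRUE)
  expect_true(all(file.exists(paths)))
  val <- read_observations(paths[["observations"]], years = c(2000L, 2011L))
  expect_equal(sum(val$counts$rows[val$counts$disposition == "rejected"]), 0L)
  meta <- country_meta(paths[["regions"]], paths[["urban"]],
                       paths[["population"]], years = c(2000L, 2011L))
  expect_setequal(meta$regions$country, w$countries)
  ref <- read_lms_reference(paths[["lms_reference"]])
  expect_equal(nrow(ref), 2L * length(w$ages))
})
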