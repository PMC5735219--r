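test_that("workspace design matches an independently assembled dense design", {
  # 3-country toy: 2 regions, 1 superregion, hand-built observations
  regions <- tibble::tibble(country = c("AAA", "BBB", "CCC"),
                            region = c("R1", "R1", "R2"),
                            superregion = "S1")
  urban <- tidyr::expand_grid(country = c("AAA", "BBB", "CCC"),
                              year = c(2000, 2010))
  urban$urban_proportion <- c(0.5, 0.5, 0.2, 0.2, 0.8, 0.8)
  pop <- tidyr::expand_grid(country = c("AAA", "BBB", "CCC"),
                            year = 2000:2010, age = 10)
  pop$sex <- "female"; pop$population <- 100
  meta <- country_meta(regions, urban, pop, years = c(2000L, 2010L))
  obs <- tibble::tibble(
    study_id = c("s1", "s2", "s3", "s4"),
    country = c("AAA", "BBB", "CCC", "CCC"),
    mid_year = c(2002L, 2005L, 2008L, 2008L),
    sex = "female", age_lower = 10L, age_upper = 10L,
    coverage = c("national", "subnational", "community", "national"),
    urbanicity = c("mixed", "urban", "rural", "mixed"),
    outcome = "mean_bmi", value = c(18, 18.5, 17.2, 17.9),
    standard_error = 0.2, sample_size = 400L)
  spec <- model_spec(years = c(2000, 2010), ages = 10,
                     components = list(spline = FALSE))
  ws <- build_model(obs, meta, spec)
  expect_equal(ws$n, nrow(obs))

  # independent dense design: intercept/slope per level + covariates
  t0 <- mean(2000:2010)
  x <- obs$mid_year - t0
  u_c <- c(0.5, 0.2, 0.8, 0.8)  # country urban proportion at study year
  offs <- c(0, 1 - 0.2, 0 - 0.8, 0)
  oracle <- cbind(
    icpt = 1, a_s1 = 1,
    a_r1 = as.numeric(obs$country %in% c("AAA", "BBB")),
    a_r2 = as.numeric(obs$country == "CCC"),
    a_aaa = as.numeric(obs$country == "AAA"),
    a_bbb = as.numeric(obs$country == "BBB"),
    a_ccc = as.numeric(obs$country == "CCC"),
    slope = x, b_s1 = x,
    b_r1 = x * (obs$country %in% c("AAA", "BBB")),
    b_r2 = x * (obs$country == "CCC"),
    b_aaa = x * (obs$country == "AAA"),
    b_bbb = x * (obs$country == "BBB"),
    b_ccc = x * (obs$country == "CCC"),
    urb = u_c,
    delta_sn = as.numeric(obs$coverage == "subnational"),
    delta_cm = as.numeric(obs$coverage == "community"),
    delta_u = offs * (obs$urbanicity == "urban"),
    delta_r = offs * (obs$urbanicity == "rural"))
  # same column space, column-for-column after reordering
  got <- ws$X[, c("icpt_1", "a_sr_1", "a_reg_1", "a_reg_2", "a_ctry_1",
                  "a_ctry_2", "a_ctry_3", "slope_1", "b_sr_1", "b_reg_1",
                  "b_reg_2", "b_ctry_1", "b_ctry_2", "b_ctry_3", "urb_1",
                  "delta_sn_1", "delta_cm_1", "delta_u_1", "delta_r_1")]
  expect_equal(unname(got), unname(oracle))
})

test_that("coverage fixed effects shift otherwise identical observations", {
  w <- tiny_world()
  meta <- w$meta
  obs <- tibble::tibble(
    study_id = c("a", "b"), country = "C01", mid_year = 2005L,
    sex = "female", age_lower = 11L, age_upper = 11L,
    coverage = c("national", "subnational"), urbanicity = "mixed",
    outcome = "mean_bmi", value = 18, standard_error = 0.2,
    sample_size = 100L)
  spec <- model_spec(years = c(2000, 2011), ages = c(8, 11, 14),
                     components = list(spline = FALSE, study_re = FALSE))
  ws <- build_model(obs, meta, spec)
  state <- init_state(ws)
  state$theta[ws$col_group == "delta_sn"] <- -0.4
  eta <- model_eta(ws, state)
  expect_equal(eta[2] - eta[1], -0.4)
})

test_that("likelihood equals per-observation normal log densities", {
  f <- tiny_fit_cached()
  ws <- f$ws
  state <- init_state(ws)
  parts <- log_posterior(state, ws, terms = TRUE)
  eta <- model_eta(ws, state)
  sd_obs <- sqrt(ws$v + state$sds$tau[ws$class_i]^2)
  manual <- sum(dnorm(ws$y, eta, sd_obs, log = TRUE))
  expect_equal(parts$likelihood, manual)
  expect_equal(parts$likelihood + parts$prior, log_posterior(state, ws))
  # first 10 rows, fully by hand
  manual10 <- sum(vapply(1:10, function(i)
    dnorm(ws$y[i], eta[i], sd_obs[i], log = TRUE), numeric(1)))
  expect_equal(sum(dnorm(ws$y, eta, sd_obs, log = TRUE)[1:10]), manual10)
})

test_that("doubling standard errors changes the likelihood by the closed form", {
  w <- tiny_world()
  obs <- validate_observations(tiny_obs(w),
                               years = c(2000L, 2011L))$observations
  spec <- model_spec(years = c(2000, 2011), ages = c(8, 11, 14),
                     spline_knots = 2,
                     fit_variances = FALSE,
                     fixed_sds = list(tau = c(national = 0,
                                              subnational = 0,
                                              community = 0)))
  ws1 <- build_model(obs, w$meta, spec)
  obs2 <- obs; obs2$standard_error <- 2 * obs2$standard_error
  ws2 <- build_model(obs2, w$meta, spec)
  state <- init_state(ws1)
  l1 <- log_posterior(state, ws1, terms = TRUE)$likelihood
  l2 <- log_posterior(state, ws2, terms = TRUE)$likelihood
  eta <- model_eta(ws1, state)
  resid2 <- (ws1$y - eta)^2
  expected_drop <- sum(-log(2) + resid2 / (2 * ws1$v) -
                         resid2 / (2 * 4 * ws1$v))
  expect_equal(l2 - l1, expected_drop, tolerance = 1e-8)
})

test_that("prior-only states with invalid variances are rejected as -Inf", {
  f <- tiny_fit_cached()
  state <- init_state(f$ws)
  state$sds$alpha[["country"]] <- -1
  expect_identical(log_posterior(state, f$ws), -Inf)
  state <- init_state(f$ws)
  state$u$country[1, ] <- 1  # violates the sum-to-zero constraint
  expect_identical(log_posterior(state, f$ws), -Inf)
})

test_that("identical seeds give bitwise-identical draws", {
  f <- tiny_fit_cached()
  fit2 <- run_mcmc(f$ws, seed = 13)
  expect_identical(f$fit$draws, fit2$draws)
  fit3 <- run_mcmc(f$ws, iterations = 120, burn_in = 60, seed = 14)
  expect_false(identical(dim(f$fit$draws$theta), dim(fit3$draws$theta)))
})

test_that("retained RW2 draws satisfy both identifiability constraints", {
  f <- tiny_fit_cached()
  T <- f$ws$T
  tt <- seq_len(T) - (T + 1) / 2
  for (lev in names(f$fit$draws$u)) {
    arr <- f$fit$draws$u[[lev]]
    for (j in seq_len(dim(arr)[2])) {
      sums <- abs(arr[, j, ] %*% rep(1, T))
      slopes <- abs(arr[, j, ] %*% tt)
      expect_lt(max(sums), 1e-8)
      expect_lt(max(slopes), 1e-8)
    }
  }
})

test_that("logit-link fits keep every prevalence draw inside (0, 1)", {
  w <- tiny_world(seed = 44, outcome = "prevalence:obesity")
  obs <- validate_observations(tiny_obs(w, seed = 45),
                               years = c(2000L, 2011L))$observations
  spec <- model_spec(outcome = "prevalence:obesity", years = c(2000, 2011),
                     ages = c(8, 11, 14), spline_knots = 2,
                     iterations = 200, burn_in = 100)
  ws <- build_model(obs, w$meta, spec)
  expect_equal(ws$se, obs$standard_error /
                 (pmin(pmax(obs$value, 0.005), 0.995) *
                    (1 - pmin(pmax(obs$value, 0.005), 0.995))),
               tolerance = 1e-12)
  fit <- run_mcmc(ws, seed = 46)
  dr <- predict(fit)
  expect_true(all(dr > 0 & dr < 1))
})

test_that("prediction refuses to extrapolate beyond the fitted window", {
  f <- tiny_fit_cached()
  expect_error(predict(f$fit, years = 2012),
               class = "bmitrends_domain_error")
  expect_error(predict(f$fit, years = 1999),
               class = "bmitrends_domain_error")
  expect_error(predict(f$fit, countries = "ZZZ"),
               class = "bmitrends_lookup_error")
  dr <- predict(f$fit, countries = "C02", years = 2003:2005, ages = 11)
  expect_equal(dim(unclass(dr)), c(f$fit$n_draws, 1L, 3L, 1L))
})

test_that("single-sex and single-outcome contracts are enforced", {
  w <- tiny_world()
  obs <- tiny_obs(w)
  spec <- model_spec(years = c(2000, 2011), ages = c(8, 11, 14))
  expect_error(build_model(obs[obs$outcome == "nope", ], w$meta, spec),
               class = "bmitrends_value_error")
  mixed <- obs
  mixed$sex[1] <- "male"
  expect_error(build_model(mixed, w$meta, spec),
               class = "bmitrends_value_error")
})

test_that("fit summaries expose parameters and diagnostics tidily", {
  f <- tiny_fit_cached()
  td <- tidy(f$fit)
  expect_true(all(c("intercept_global", "slope_global", "beta_urban") %in%
                    td$term))
  expect_true(all(td$lower <= td$upper))
  gl <- glance(f$fit)
  expect_equal(gl$n_obs, f$ws$n)
  expect_equal(gl$n_draws, f$fit$n_draws)
})
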