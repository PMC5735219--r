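valid_row <- function(...) {
  row <- tibble::tibble(
    study_id = "s1", country = "C01", mid_year = 2000L, sex = "female",
    age_lower = 10L, age_upper = 10L, coverage = "national",
    urbanicity = "mixed", outcome = "mean_bmi", value = 18.2,
    standard_error = 0.1, sample_size = 500L)
  utils::modifyList(row, list(...))
}

test_that("a valid row is accepted and canonicalised", {
  val <- validate_observations(valid_row(sex = "F", coverage = "National"))
  expect_equal(nrow(val$observations), 1L)
  expect_equal(val$observations$sex, "female")
  expect_equal(val$observations$coverage, "national")
  expect_equal(nrow(val$issues), 0L)
})

test_that("invariant violations are rejected with machine-readable reasons", {
  cases <- list(
    list(row = valid_row(standard_error = 0), reason = "nonpositive_se"),
    list(row = valid_row(sex = "both"), reason = "unknown_sex"),
    list(row = valid_row(outcome = "prevalence:obesity", value = 1.4),
         reason = "value_out_of_range"),
    list(row = valid_row(mid_year = 1901L), reason = "year_out_of_window"),
    list(row = valid_row(age_lower = 12L, age_upper = 10L),
         reason = "bad_age_band"),
    list(row = valid_row(sample_size = 0L),
         reason = "nonpositive_sample_size"))
  for (case in cases) {
    val <- validate_observations(case$row)
    expect_equal(nrow(val$observations), 0L)
    expect_equal(val$issues$reason, case$reason)
  }
})

test_that("missing standard errors are imputed and flagged", {
  val <- validate_observations(valid_row(standard_error = NA_real_))
  expect_equal(val$observations$standard_error, 3.5 / sqrt(500))
  expect_equal(val$issues$reason, "imputed_se")
  expect_equal(val$issues$disposition, "accepted")
  vp <- validate_observations(valid_row(outcome = "prevalence:obesity",
                                        value = 0.1,
                                        standard_error = NA_real_))
  expect_equal(vp$observations$standard_error, sqrt(0.1 * 0.9 / 500))
})

test_that("a corrupted file yields exactly the planted number of rejects", {
  w <- tiny_world()
  obs <- simulate_studies(w, study_design(p_study = 1), seed = 12)[1:100, ]
  cor <- corrupt_observations(obs, n_bad = 7, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_observations(cor$observations, path)
  val <- read_observations(path, years = c(2000L, 2011L))
  expect_equal(sum(val$counts$rows[val$counts$disposition == "accepted"]), 93L)
  expect_equal(sort(val$issues$row[val$issues$disposition == "rejected"]),
               cor$bad_rows)
})

test_that("observations round-trip through write/read unchanged", {
  w <- tiny_world()
  obs <- validate_observations(tiny_obs(w),
                               years = c(2000L, 2011L))$observations
  path <- withr::local_tempfile(fileext = ".csv")
  write_observations(obs, path)
  back <- read_observations(path, years = c(2000L, 2011L))$observations
  expect_equal(as.data.frame(back), as.data.frame(obs), tolerance = 1e-12)
})

test_that("unknown columns and schema versions are hard errors", {
  row <- valid_row()
  row$mystery <- 1
  expect_error(validate_observations(row), class = "bmitrends_schema_error")
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(valid_row(), path)
  expect_error(read_observations(path, schema_version = 99),
               class = "bmitrends_schema_error")
})

test_that("urbanisation series interpolate linearly to integer years", {
  meta <- country_meta(
    regions = tibble::tibble(country = "AAA", region = "R1",
                             superregion = "S1"),
    urban = tibble::tibble(country = "AAA", year = c(1975, 1985),
                           urban_proportion = c(0.2, 0.4)),
    population = tibble::tibble(country = "AAA", year = 1980, sex = "female",
                                age = 10, population = 1000),
    years = c(1975L, 1985L))
  u1980 <- meta$urban$urban_proportion[meta$urban$year == 1980]
  expect_equal(u1980, 0.3)
  expect_equal(nrow(meta$urban), 11L)
})

test_that("duplicate or missing countries in metadata are hard errors", {
  regions <- tibble::tibble(country = c("AAA", "AAA"), region = "R1",
                            superregion = "S1")
  urban <- tibble::tibble(country = "AAA", year = c(1975, 2016),
                          urban_proportion = c(0.2, 0.4))
  pop <- tibble::tibble(country = "AAA", year = 1980, sex = "female",
                        age = 10, population = 1000)
  expect_error(country_meta(regions, urban, pop),
               class = "bmitrends_schema_error")
  expect_error(
    country_meta(tibble::tibble(country = c("AAA", "BBB"), region = "R1",
                                superregion = "S1"), urban, pop),
    class = "bmitrends_schema_error")
})

test_that("every generated country resolves to one region and superregion", {
  w <- generate_world(seed = 8)
  m <- w$meta$regions
  expect_equal(anyDuplicated(m$country), 0L)
  lookup <- unique(m[, c("region", "superregion")])
  expect_equal(anyDuplicated(lookup$region), 0L)
})

test_that("urbanisation offsets follow the study-minus-country rule", {
  meta <- country_meta(
    regions = tibble::tibble(country = "AAA", region = "R1",
                             superregion = "S1"),
    urban = tibble::tibble(country = "AAA", year = c(2000, 2010),
                           urban_proportion = c(0.6, 0.6)),
    population = tibble::tibble(country = "AAA", year = 2000, sex = "female",
                                age = 10, population = 1),
    years = c(2000L, 2010L))
  obs <- dplyr::bind_rows(
    valid_row(country = "AAA", mid_year = 2005L, urbanicity = "urban"),
    valid_row(country = "AAA", mid_year = 2005L, urbanicity = "mixed"),
    valid_row(country = "AAA", mid_year = 2005L, urbanicity = "rural"))
  out <- urbanisation_offset(obs, meta)
  expect_equal(out$urban_offset, c(0.4, 0, -0.6))
})

test_that("offsets are bounded and vanish for mixed samples", {
  w <- tiny_world()
  obs <- validate_observations(tiny_obs(w),
                               years = c(2000L, 2011L))$observations
  out <- urbanisation_offset(obs, w$meta)
  expect_true(all(out$urban_offset >= -1 & out$urban_offset <= 1))
  expect_true(all(out$urban_offset[out$urbanicity == "mixed"] == 0))
})
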