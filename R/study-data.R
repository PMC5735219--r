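OBS_SCHEMA_VERSION <- 1L

OBS_COLUMNS <- c("study_id", "country", "mid_year", "sex", "age_lower",
                 "age_upper", "coverage", "urbanicity", "outcome", "value",
                 "standard_error", "sample_size")

SEX_LEVELS <- c("female", "male")
COVERAGE_LEVELS <- c("national", "subnational", "community")
URBANICITY_LEVELS <- c("mixed", "urban", "rural")

canonical_level <- function(x, levels, extra = character()) {
  x <- tolower(trimws(as.character(x)))
  map <- c(setNames(levels, levels), extra,
           f = "female", m = "male", girls = "female", boys = "male")
  unname(map[x])
}

#' Validate and normalise study-level observations
#'
#' Applies the structural checks every observation must pass before it can
#' enter the model: positive standard error, proportions in \[0, 1\] for
#' prevalence outcomes, valid age band, year inside the analysis window, and
#' recognised sex / coverage / urbanicity / outcome codes. Sex-combined rows
#' are rejected (there is no defensible weight for them at this level).
#' Missing standard errors are imputed as `sqrt(p(1-p)/n)` for prevalence
#' outcomes and `sd_pool/sqrt(n)` for means, and flagged in the issue report.
#'
#' @param data Tibble of raw observation rows (see [read_observations()] for
#'   the column contract).
#' @param years Analysis window as an inclusive year range, default 1975-2016.
#' @param sd_pool Pooled individual-level SD (kg/m^2) used to impute missing
#'   mean-BMI standard errors; default 3.5.
#' @return A list of class `bmi_obs_validation`:
#'   `observations` (accepted, canonicalised rows), `issues` (one row per
#'   rejected or imputed row, with a machine-readable `reason`), and
#'   `counts` (rows by disposition).
#' @export
validate_observations <- function(data, years = c(1975L, 2016L),
                                  sd_pool = 3.5) {
  data <- as_tibble(data)
  missing_cols <- setdiff(OBS_COLUMNS, names(data))
  if (length(missing_cols) > 0L) {
    stop_bad_arg(paste0("Missing observation columns: ",
                        paste(missing_cols, collapse = ", ")),
                 "bmitrends_schema_error")
  }
  unknown <- setdiff(names(data), OBS_COLUMNS)
  if (length(unknown) > 0L) {
    stop_bad_arg(paste0("Unknown observation columns: ",
                        paste(unknown, collapse = ", ")),
                 "bmitrends_schema_error")
  }
  n <- nrow(data)
  reason <- rep(NA_character_, n)
  flag <- function(bad, why) {
    reason[is.na(reason) & bad] <<- why
  }

  sex <- canonical_level(data$sex, SEX_LEVELS)
  flag(is.na(sex), "unknown_sex")
  coverage <- canonical_level(data$coverage, COVERAGE_LEVELS)
  flag(is.na(coverage), "unknown_coverage")
  urbanicity <- canonical_level(data$urbanicity, URBANICITY_LEVELS)
  flag(is.na(urbanicity), "unknown_urbanicity")

  outcome <- tolower(trimws(as.character(data$outcome)))
  ok_outcome <- outcome == "mean_bmi" | grepl("^prevalence:.+", outcome)
  flag(!ok_outcome, "unknown_outcome")
  is_prev <- grepl("^prevalence:", outcome)

  flag(!is.finite(data$mid_year) | data$mid_year < years[1] |
         data$mid_year > years[2], "year_out_of_window")
  flag(!is.finite(data$age_lower) | !is.finite(data$age_upper) |
         data$age_lower > data$age_upper | data$age_lower < 0,
       "bad_age_band")
  flag(!is.finite(data$sample_size) | data$sample_size < 1,
       "nonpositive_sample_size")
  flag(!is.finite(data$value), "missing_value")
  flag(is_prev & (data$value < 0 | data$value > 1), "value_out_of_range")

  se <- as.numeric(data$standard_error)
  imputable <- is.na(se) & is.na(reason)
  se[imputable & is_prev] <-
    sqrt(pmax(data$value * (1 - data$value), 0.25 * 0.05^2)[imputable &
                                                              is_prev] /
           data$sample_size[imputable & is_prev])
  se[imputable & !is_prev] <-
    sd_pool / sqrt(data$sample_size[imputable & !is_prev])
  flag(!is.na(se) & se <= 0, "nonpositive_se")
  flag(is.na(se) & !imputable & is.na(reason), "nonpositive_se")

  accepted <- is.na(reason)
  obs <- data[accepted, , drop = FALSE]
  obs$sex <- sex[accepted]
  obs$coverage <- coverage[accepted]
  obs$urbanicity <- urbanicity[accepted]
  obs$outcome <- outcome[accepted]
  obs$standard_error <- se[accepted]
  obs$mid_year <- as.integer(obs$mid_year)
  obs$age_lower <- as.integer(obs$age_lower)
  obs$age_upper <- as.integer(obs$age_upper)
  obs$sample_size <- as.integer(obs$sample_size)

  issues <- dplyr::bind_rows(
    tibble(row = which(!accepted),
           study_id = as.character(data$study_id[!accepted]),
           disposition = "rejected",
           reason = reason[!accepted]),
    tibble(row = which(imputable),
           study_id = as.character(data$study_id[imputable]),
           disposition = "accepted",
           reason = "imputed_se"))
  counts <- tibble(
    disposition = c("accepted", "rejected", "imputed_se"),
    rows = c(sum(accepted), sum(!accepted), sum(imputable)))

  structure(list(observations = as_tibble(obs), issues = issues,
                 counts = counts),
            class = "bmi_obs_validation")
}

#' @export
print.bmi_obs_validation <- function(x, ...) {
  cat("<bmi_obs_validation>\n")
  print(x$counts)
  invisible(x)
}

#' Read study-level observations from CSV
#'
#' One row per study x sex x age band x outcome, comma-separated with a
#' header. Columns: `study_id`, `country` (ISO3), `mid_year`, `sex`,
#' `age_lower`, `age_upper` (inclusive years; 1-year bands for ages 5-19),
#' `coverage` (national/subnational/community), `urbanicity`
#' (mixed/urban/rural), `outcome` (`mean_bmi` or `prevalence:<category>`),
#' `value`, `standard_error`, `sample_size`.
#'
#' @param path CSV file path.
#' @param schema_version Schema version of the file; only version 1 exists.
#' @inheritParams validate_observations
#' @return A `bmi_obs_validation` list, see [validate_observations()].
#' @export
read_observations <- function(path, schema_version = 1L,
                              years = c(1975L, 2016L), sd_pool = 3.5) {
  if (!identical(as.integer(schema_version), OBS_SCHEMA_VERSION)) {
    stop_bad_arg(sprintf("Unknown observation schema version %s.",
                         schema_version), "bmitrends_schema_error")
  }
  if (!file.exists(path)) {
    stop_bad_arg(sprintf("File not found: %s", path), "bmitrends_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(
    study_id = readr::col_character(),
    country = readr::col_character(),
    mid_year = readr::col_double(),
    sex = readr::col_character(),
    age_lower = readr::col_double(),
    age_upper = readr::col_double(),
    coverage = readr::col_character(),
    urbanicity = readr::col_character(),
    outcome = readr::col_character(),
    value = readr::col_double(),
    standard_error = readr::col_double(),
    sample_size = readr::col_double()))
  validate_observations(raw, years = years, sd_pool = sd_pool)
}

#' @rdname read_observations
#' @param observations Validated observation tibble.
#' @export
write_observations <- function(observations, path) {
  readr::write_csv(observations[, OBS_COLUMNS], path)
  invisible(path)
}

#' Assemble country metadata
#'
#' Joins a region map (country, region, superregion), an urbanisation series
#' (country, year, urban_proportion; linearly interpolated to integer years
#' when supplied at coarser intervals) and a population table
#' (country, year, sex, age, population) into one validated object.
#'
#' @param regions Tibble or CSV path with columns `country`, `region`,
#'   `superregion`; exactly one row per country.
#' @param urban Tibble or CSV path with columns `country`, `year`,
#'   `urban_proportion` in \[0, 1\].
#' @param population Tibble or CSV path with columns `country`, `year`,
#'   `sex`, `age`, `population` (person counts, non-negative).
#' @param years Analysis window; the interpolated urbanisation series must
#'   cover it for every country.
#' @return An object of class `bmi_country_meta` with tibbles `regions`,
#'   `urban` (interpolated to every window year) and `population`.
#' @export
country_meta <- function(regions, urban, population,
                         years = c(1975L, 2016L)) {
  read_if_path <- function(x, types) {
    if (is.character(x) && length(x) == 1L) {
      readr::read_csv(x, col_types = types)
    } else as_tibble(x)
  }
  regions <- read_if_path(regions, readr::cols(
    country = readr::col_character(), region = readr::col_character(),
    superregion = readr::col_character()))
  urban <- read_if_path(urban, readr::cols(
    country = readr::col_character(), year = readr::col_double(),
    urban_proportion = readr::col_double()))
  population <- read_if_path(population, readr::cols(
    country = readr::col_character(), year = readr::col_double(),
    sex = readr::col_character(), age = readr::col_double(),
    population = readr::col_double()))

  if (anyDuplicated(regions$country)) {
    dup <- regions$country[duplicated(regions$country)][1]
    stop_bad_arg(sprintf("Country '%s' appears more than once in the region map.",
                         dup), "bmitrends_schema_error")
  }
  if (any(urban$urban_proportion < 0 | urban$urban_proportion > 1)) {
    stop_bad_arg("urban_proportion must lie in [0, 1].",
                 "bmitrends_schema_error")
  }
  if (any(population$population < 0)) {
    stop_bad_arg("Populations must be non-negative.", "bmitrends_schema_error")
  }
  missing_urban <- setdiff(regions$country, unique(urban$country))
  if (length(missing_urban) > 0L) {
    stop_bad_arg(paste0("No urbanisation series for: ",
                        paste(missing_urban, collapse = ", ")),
                 "bmitrends_schema_error")
  }

  grid_years <- seq(years[1], years[2])
  urban <- urban |>
    dplyr::group_by(.data$country) |>
    dplyr::group_modify(function(d, key) {
      if (min(d$year) > years[1] || max(d$year) < years[2]) {
        stop_bad_arg(sprintf(
          "Urbanisation series for '%s' does not cover %d-%d.",
          key$country, years[1], years[2]), "bmitrends_schema_error")
      }
      out <- approx(d$year, d$urban_proportion, xout = grid_years)
      tibble(year = grid_years, urban_proportion = out$y)
    }) |>
    dplyr::ungroup()

  structure(list(regions = regions, urban = urban,
                 population = as_tibble(population),
                 years = as.integer(years)),
            class = "bmi_country_meta")
}

#' @rdname country_meta
#' @export
read_country_meta <- country_meta

#' @export
print.bmi_country_meta <- function(x, ...) {
  cat(sprintf("<bmi_country_meta: %d countries, %d regions, %d superregions, %d-%d>\n",
              nrow(x$regions), length(unique(x$regions$region)),
              length(unique(x$regions$superregion)), x$years[1], x$years[2]))
  invisible(x)
}

#' Study-level urbanisation offset
#'
#' The rural/urban fixed effects are weighted by the difference between
#' study-level and country-level urbanisation in the year the study was done:
#' study-level urbanisation is 1 for urban-only samples, 0 for rural-only
#' samples, and the country value for mixed samples, so the offset
#' `u_study - u_country(year)` lies in \[-1, 1\] and is exactly 0 for mixed
#' samples.
#'
#' @param observations Validated observation tibble.
#' @param meta A [country_meta()] object covering every observation.
#' @return `observations` with an added `urban_offset` column.
#' @export
urbanisation_offset <- function(observations, meta) {
  key <- paste(meta$urban$country, meta$urban$year)
  idx <- match(paste(observations$country, observations$mid_year), key)
  if (anyNA(idx)) {
    bad <- observations[is.na(idx), , drop = FALSE][1, ]
    stop_bad_arg(sprintf(
      "No urbanisation value for %s in %d.", bad$country, bad$mid_year),
      "bmitrends_lookup_error")
  }
  u_c <- meta$urban$urban_proportion[idx]
  u_s <- dplyr::case_when(
    observations$urbanicity == "urban" ~ 1,
    observations$urbanicity == "rural" ~ 0,
    TRUE ~ u_c)
  observations$urban_offset <- u_s - u_c
  observations
}
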