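#' Default pipeline configuration
#'
#' A nested list configuring the simulate -> validate -> fit -> report
#' pipeline; any subset can be overridden from a YAML file
#' ([read_pipeline_config()]) or an R list. The defaults are the desk-scale
#' world: 2 superregions x 4 regions x 12 countries, 1975-2016, ages 5-19,
#' one sex, mean BMI, with 5000 post-burn-in draws.
#'
#' @return Nested configuration list.
#' @export
pipeline_config <- function() {
  list(
    schema_version = 1L,
    world = list(n_superregions = 2L, n_regions = 4L, n_countries = 12L,
                 years = c(1975L, 2016L), ages = c(5L, 19L),
                 outcome = "mean_bmi", sex = "female"),
    design = list(p_study = 0.2, n_range = c(200L, 1500L)),
    model = list(iterations = 10000L, burn_in = 5000L, thin = 1L,
                 spline_knots = 5L),
    report = list(change_years = c(1975L, 2016L)),
    seed = 1L)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys override [pipeline_config()] defaults.
#' @return Nested configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- modifyList(pipeline_config(), user)
  if (!identical(as.integer(cfg$schema_version), 1L)) {
    stop_bad_arg(sprintf("Unknown pipeline schema version %s.",
                         cfg$schema_version), "bmitrends_schema_error")
  }
  required <- c("world", "design", "model", "report", "seed")
  missing <- setdiff(required, names(cfg))
  if (length(missing) > 0L) {
    stop_bad_arg(paste0("Config is missing: ", paste(missing, collapse = ", ")),
                 "bmitrends_config_error")
  }
  cfg
}

write_manifest <- function(dir, cfg, seed, files, stage,
                           extra = list()) {
  manifest <- c(list(
    stage = stage,
    config_hash = rlang::hash(cfg),
    seed = seed,
    software_version = as.character(utils::packageVersion("bmitrends")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = as.list(tools::md5sum(files))), extra)
  path <- file.path(dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Pipeline stage: simulate a fixture directory
#'
#' Generates a world and study database from the configuration and writes
#' the complete CSV input set plus a manifest with file digests.
#'
#' @param config Configuration list (see [pipeline_config()]) or YAML path.
#' @param out_dir Output directory.
#' @param seed Overrides `config$seed`.
#' @param force Overwrite an existing non-empty directory.
#' @return Invisibly, a list with the world, observations and file paths.
#' @export
pipeline_simulate <- function(config = pipeline_config(), out_dir,
                              seed = NULL, force = FALSE) {
  cfg <- if (is.character(config)) read_pipeline_config(config) else config
  seed <- as.integer(seed %||% cfg$seed)
  w <- cfg$world
  world <- generate_world(
    n_superregions = w$n_superregions, n_regions = w$n_regions,
    n_countries = w$n_countries, years = w$years[1]:w$years[2],
    ages = w$ages[1]:w$ages[2], outcome = w$outcome, sex = w$sex,
    seed = seed)
  design <- study_design(p_study = cfg$design$p_study,
                         n_range = cfg$design$n_range)
  obs <- simulate_studies(world, design, seed = child_seed(seed, 1))
  paths <- write_fixtures(world, obs, out_dir, force = force)
  write_manifest(out_dir, cfg, seed, paths, "simulate")
  invisible(list(world = world, observations = obs, paths = paths))
}

#' Pipeline stage: validate a fixture directory
#'
#' Reads and validates the observation and metadata files, writes the issue
#' report, and refuses to continue if any accepted observation cannot be
#' joined to the metadata.
#'
#' @param data_dir Directory produced by [pipeline_simulate()] (or
#'   hand-assembled in the same schema).
#' @param years Analysis window.
#' @return Invisibly, a list with `observations`, `issues` and `meta`.
#' @export
pipeline_validate <- function(data_dir, years = c(1975L, 2016L)) {
  val <- read_observations(file.path(data_dir, "observations.csv"),
                           years = years)
  meta <- country_meta(file.path(data_dir, "regions.csv"),
                       file.path(data_dir, "urban.csv"),
                       file.path(data_dir, "population.csv"),
                       years = years)
  orphan <- setdiff(val$observations$country, meta$regions$country)
  if (length(orphan) > 0L) {
    stop_bad_arg(paste0("Accepted observations reference countries absent ",
                        "from metadata: ", paste(orphan, collapse = ", ")),
                 "bmitrends_lookup_error")
  }
  readr::write_csv(val$issues, file.path(data_dir, "issues.csv"))
  invisible(list(observations = val$observations, issues = val$issues,
                 meta = meta))
}

#' Pipeline stage: fit one outcome
#'
#' Fits the hierarchical model for one outcome and sex, persists the draws
#' (RDS) with a JSON metadata sidecar (seed, config hash, diagnostics), and
#' returns the fit.
#'
#' @param data_dir Fixture directory.
#' @param out_dir Output directory for the draw store.
#' @param config Configuration list or YAML path.
#' @param outcome Outcome to fit; defaults to the config's.
#' @param seed Sampler seed; overrides `config$seed`.
#' @return The `bmi_fit`, invisibly.
#' @export
pipeline_fit <- function(data_dir, out_dir, config = pipeline_config(),
                         outcome = NULL, seed = NULL) {
  cfg <- if (is.character(config)) read_pipeline_config(config) else config
  seed <- as.integer(seed %||% cfg$seed)
  outcome <- outcome %||% cfg$world$outcome
  years <- cfg$world$years
  val <- pipeline_validate(data_dir, years = years)
  spec <- model_spec(outcome = outcome, years = years,
                     ages = cfg$world$ages[1]:cfg$world$ages[2],
                     spline_knots = cfg$model$spline_knots,
                     iterations = cfg$model$iterations,
                     burn_in = cfg$model$burn_in, thin = cfg$model$thin)
  ws <- build_model(val$observations, val$meta, spec)
  fit <- run_mcmc(ws, seed = child_seed(seed, 2))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  safe_outcome <- gsub("[^a-z_]", "_", outcome)
  store <- file.path(out_dir, paste0("draws_", safe_outcome, ".rds"))
  saveRDS(fit, store)
  jsonlite::write_json(
    list(outcome = outcome, seed = seed, config_hash = rlang::hash(cfg),
         n_draws = fit$n_draws,
         diagnostics = fit$diagnostics),
    file.path(out_dir, paste0("draws_", safe_outcome, ".json")),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(out_dir, cfg, seed, store, paste0("fit_", safe_outcome))
  invisible(fit)
}

#' Pipeline stage: report estimates from fitted draws
#'
#' Turns one or more fits into tidy result tables: country, region and world
#' estimates by year (age-standardised), changes per decade with credible
#' intervals and trend posterior probabilities, and, for prevalence
#' outcomes, rescaled categories, affected counts and the count-change
#' decomposition.
#'
#' @param fits A `bmi_fit` or named list of fits (one per outcome).
#' @param meta A [country_meta()] for populations and region membership.
#' @param std_pop Standard-population weights tibble.
#' @param out_dir Directory for the CSV tables.
#' @param change_years Two years for the change-per-decade and decomposition
#'   tables.
#' @return Invisibly, a named list of the result tibbles.
#' @export
pipeline_report <- function(fits, meta, std_pop = NULL, out_dir = NULL,
                            change_years = NULL) {
  if (inherits(fits, "bmi_fit")) {
    fits <- setNames(list(fits), fits$spec$outcome)
  }
  first <- fits[[1]]
  years <- first$workspace$years
  ages <- first$workspace$spec$ages
  sex <- first$workspace$sex
  change_years <- change_years %||% range(years)
  std_pop <- std_pop %||% standard_population(ages, sex)
  groups <- c(split(meta$regions$country, meta$regions$region),
              list(World = meta$regions$country))

  draws_by_outcome <- lapply(fits, predict)
  prev_outcomes <- names(draws_by_outcome)[
    grepl("^prevalence:", names(draws_by_outcome))]
  scaling <- NULL
  if (length(prev_outcomes) >= 2) {
    res <- rescale_categories(lapply(draws_by_outcome[prev_outcomes],
                                     unclass))
    for (nm in prev_outcomes) {
      a <- res$rescaled[[nm]]
      attributes(a) <- attributes(draws_by_outcome[[nm]])
      draws_by_outcome[[nm]] <- a
    }
    scaling <- res$scaling
  }

  estimates <- list(); changes <- list(); counts <- list()
  for (nm in names(draws_by_outcome)) {
    dr <- draws_by_outcome[[nm]]
    std_c <- age_standardise(unclass(dr), std_pop)
    dimnames(std_c) <- c(list(draw = NULL),
                         dimnames(unclass(dr))[c("country", "year")])
    agg <- aggregate_draws(unclass(dr), meta$population, groups = groups,
                           sex = sex)
    std_g <- age_standardise(agg, std_pop)
    est <- dplyr::bind_rows(
      dplyr::mutate(dplyr::rename(summarise_draws(std_c),
                                  entity = "country"), level = "country"),
      dplyr::mutate(dplyr::rename(summarise_draws(std_g),
                                  entity = "group"),
                    level = ifelse(.data$entity == "World", "world",
                                   "region")))
    est$metric <- nm; est$sex <- sex
    estimates[[nm]] <- est

    ch <- dplyr::bind_rows(
      dplyr::mutate(dplyr::rename(change_per_decade(
        std_c, change_years[1], change_years[2]), entity = "country"),
        level = "country"),
      dplyr::mutate(dplyr::rename(change_per_decade(
        std_g, change_years[1], change_years[2]), entity = "group"),
        level = ifelse(.data$entity == "World", "world", "region")))
    ch$metric <- nm; ch$sex <- sex
    changes[[nm]] <- ch

    if (grepl("^prevalence:", nm)) {
      cnt <- affected_count(unclass(dr), meta$population,
                            groups = groups, sex = sex)
      cnt_c <- affected_count(unclass(dr), meta$population, sex = sex)
      cc <- dplyr::bind_rows(
        dplyr::mutate(dplyr::rename(summarise_draws(cnt_c),
                                    entity = "country"), level = "country"),
        dplyr::mutate(dplyr::rename(summarise_draws(cnt),
                                    entity = "group"),
                      level = ifelse(.data$entity == "World", "world",
                                     "region")))
      cc$metric <- nm; cc$sex <- sex
      counts[[nm]] <- cc
    }
  }

  out <- list(estimates = dplyr::bind_rows(estimates),
              changes = dplyr::bind_rows(changes),
              counts = if (length(counts) > 0) dplyr::bind_rows(counts))

  # count-change decomposition per prevalence outcome, at posterior means
  if (length(prev_outcomes) > 0) {
    y0 <- as.character(change_years[1]); y1 <- as.character(change_years[2])
    pops <- meta$population[meta$population$sex %in% sex, , drop = FALSE]
    decomp <- lapply(prev_outcomes, function(nm) {
      dr <- unclass(draws_by_outcome[[nm]])
      ctys <- dimnames(dr)$country
      p_mean <- apply(dr, c(2, 3, 4), mean)
      grab <- function(yr) {
        n_age <- vapply(as.integer(dimnames(dr)$age), function(a) {
          sum(pops$population[pops$year == as.integer(yr) & pops$age == a])
        }, numeric(1))
        p_age <- vapply(seq_along(dimnames(dr)$age), function(ai) {
          pa <- vapply(ctys, function(cc) {
            sum(pops$population[pops$year == as.integer(yr) &
                                  pops$age == as.integer(dimnames(dr)$age[ai]) &
                                  pops$country == cc])
          }, numeric(1))
          weighted.mean(p_mean[match(ctys, dimnames(dr)$country),
                               match(yr, dimnames(dr)$year), ai], pa)
        }, numeric(1))
        list(p = p_age, n = n_age)
      }
      a0 <- grab(y0); a1 <- grab(y1)
      d <- decompose_count_change(a0$p, a1$p, a0$n, a1$n)
      d$metric <- nm
      d
    })
    out$decomposition <- dplyr::bind_rows(decomp)
  }
  if (!is.null(scaling)) {
    out$scaling_summary <- tibble(
      mean_scaling = mean(scaling),
      min_cell_mean = min(apply(scaling, seq_along(dim(scaling))[-1], mean)),
      max_cell_mean = max(apply(scaling, seq_along(dim(scaling))[-1], mean)))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    written <- character(0)
    for (nm in names(out)) {
      if (is.null(out[[nm]])) next
      p <- file.path(out_dir, paste0(nm, ".csv"))
      readr::write_csv(out[[nm]], p)
      written <- c(written, p)
    }
    write_manifest(out_dir, list(change_years = change_years),
                   NA_integer_, written, "report")
  }
  invisible(out)
}

#' Run the whole pipeline on one configuration
#'
#' simulate -> validate -> fit -> report with a single seed; every stage
#' writes a manifest so reruns can be checked digest-for-digest.
#'
#' @param config Configuration list or YAML path.
#' @param out_dir Working directory for all stages.
#' @param seed Overrides `config$seed`.
#' @param force Overwrite existing outputs.
#' @return Invisibly, a list with the fit and the report tables.
#' @export
pipeline_run <- function(config = pipeline_config(), out_dir,
                         seed = NULL, force = FALSE) {
  cfg <- if (is.character(config)) read_pipeline_config(config) else config
  seed <- as.integer(seed %||% cfg$seed)
  data_dir <- file.path(out_dir, "data")
  sim <- pipeline_simulate(cfg, data_dir, seed = seed, force = force)
  fit <- pipeline_fit(data_dir, file.path(out_dir, "fit"), cfg, seed = seed)
  rep <- pipeline_report(fit, sim$world$meta,
                         out_dir = file.path(out_dir, "results"),
                         change_years = cfg$report$change_years)
  invisible(list(world = sim$world, fit = fit, report = rep))
}
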