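#' Standard-population age weights
#'
#' Age-standardised estimates are weighted averages of age-specific estimates
#' with fixed standard-population weights, so comparisons over time and
#' between populations are free of age-structure differences. The weight
#' table is an input; `standard_population()` provides a documented synthetic
#' default (weights declining gently with age, as in young-age standard
#' populations), normalised to sum to 1 over the analysis age range.
#'
#' @param ages Integer ages the analysis uses.
#' @param sex Sex label carried through to outputs.
#' @return Tibble with columns `sex`, `age`, `weight` (summing to 1).
#' @export
standard_population <- function(ages, sex = "female") {
  w <- 1.1 - 0.02 * (ages - min(ages))
  tibble(sex = sex, age = as.integer(ages), weight = w / sum(w))
}

#' Read a standard-population weight table
#'
#' Two-column CSV (`age`, `weight`), optionally with a `sex` column. Weights
#' are validated to be non-negative and renormalised to sum to 1 over the
#' supplied ages.
#'
#' @param path CSV path.
#' @param ages If given, the table must cover exactly these ages.
#' @return Tibble with `age` and normalised `weight`.
#' @export
read_standard_population <- function(path, ages = NULL) {
  w <- readr::read_csv(path, col_types = readr::cols())
  if (!all(c("age", "weight") %in% names(w))) {
    stop_bad_arg("Standard population file needs columns age, weight.",
                 "bmitrends_schema_error")
  }
  if (any(w$weight < 0)) {
    stop_bad_arg("Standard-population weights must be non-negative.",
                 "bmitrends_schema_error")
  }
  if (!is.null(ages)) {
    if (!setequal(w$age, ages)) {
      stop_bad_arg("Standard population does not cover the analysis ages.",
                   "bmitrends_schema_error")
    }
    w <- w[match(ages, w$age), , drop = FALSE]
  }
  w$weight <- w$weight / sum(w$weight)
  as_tibble(w)
}

dim_index <- function(x, dim_name) {
  i <- match(dim_name, names(dimnames(x)))
  if (is.na(i)) {
    stop_bad_arg(sprintf("Draws array has no '%s' dimension.", dim_name),
                 "bmitrends_value_error")
  }
  i
}

#' Rescale separately-estimated category draws to sum to one
#'
#' The categories are modelled separately, so their estimated prevalences
#' need not sum to exactly 1 in a given draw and cell. Each category draw is
#' divided by the draw-wise sum over categories; the per-draw scaling factors
#' are returned so their distribution can be audited.
#'
#' @param category_draws Named list of draw arrays (one per category, all
#'   with identical dimensions), values in (0, 1).
#' @return List with `rescaled` (same shape, draw-wise sums exactly 1) and
#'   `scaling` (array of per-cell, per-draw factors `1 / sum`).
#' @export
rescale_categories <- function(category_draws) {
  if (!is.list(category_draws) || length(category_draws) < 2L ||
      is.null(names(category_draws)) || any(names(category_draws) == "")) {
    stop_bad_arg("Supply a named list with one draw array per category.",
                 "bmitrends_value_error")
  }
  d <- dim(category_draws[[1]]) %||% length(category_draws[[1]])
  for (nm in names(category_draws)) {
    if (!identical(dim(category_draws[[nm]]) %||%
                     length(category_draws[[nm]]), d)) {
      stop_bad_arg("All category draw arrays must share dimensions.",
                   "bmitrends_value_error")
    }
    if (any(category_draws[[nm]] <= 0) || any(category_draws[[nm]] >= 1)) {
      stop_bad_arg("Category draws must lie strictly in (0, 1).",
                   "bmitrends_domain_error")
    }
  }
  total <- Reduce(`+`, category_draws)
  rescaled <- lapply(category_draws, function(a) a / total)
  list(rescaled = rescaled, scaling = 1 / total)
}

#' Age-standardise draws with standard-population weights
#'
#' Collapses the `age` dimension by a weighted average, applied draw-wise
#' (standardisation commutes with posterior summarisation only for the mean,
#' so credible intervals must be formed after standardising each draw).
#'
#' @param draws Array with a named `age` dimension (e.g. from
#'   [predict.bmi_fit()]).
#' @param weights A tibble with `age` and `weight` columns (see
#'   [standard_population()]) or a named numeric vector by age.
#' @return Array with the `age` dimension removed.
#' @export
age_standardise <- function(draws, weights) {
  ai <- dim_index(draws, "age")
  ages <- dimnames(draws)[[ai]]
  if (is.data.frame(weights)) {
    weights <- setNames(weights$weight, weights$age)
  }
  if (!all(ages %in% names(weights))) {
    stop_bad_arg("Weights do not cover all ages present in the draws.",
                 "bmitrends_value_error")
  }
  w <- weights[ages]
  w <- w / sum(w)
  nd <- length(dim(draws))
  perm <- c(setdiff(seq_len(nd), ai), ai)
  xp <- aperm(draws, perm)
  d <- dim(xp)
  flat <- matrix(xp, ncol = d[nd])
  out <- flat %*% w
  new_dim <- d[-nd]
  new_dn <- dimnames(xp)[-nd]
  array(out, dim = new_dim, dimnames = new_dn)
}

population_weights <- function(populations, countries, years, ages,
                               sex = NULL) {
  if (!is.null(sex) && "sex" %in% names(populations)) {
    populations <- populations[populations$sex %in% sex, , drop = FALSE]
  }
  key <- paste(populations$country, populations$year, populations$age)
  grid <- expand.grid(country = countries, year = years, age = ages,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  idx <- match(paste(grid$country, grid$year, grid$age), key)
  if (anyNA(idx)) {
    bad <- grid[which(is.na(idx))[1], ]
    stop_bad_arg(sprintf("No population for %s, year %s, age %s.",
                         bad$country, bad$year, bad$age),
                 "bmitrends_lookup_error")
  }
  array(populations$population[idx],
        dim = c(length(countries), length(years), length(ages)),
        dimnames = list(country = countries, year = years, age = ages))
}

#' Population-weighted aggregation of country draws
#'
#' Estimates for groups of countries (regions, the world) are
#' population-weighted averages of the constituent country estimates by year
#' and age, applied draw-wise.
#'
#' @param draws Array `(draw, country, year, age)` or `(draw, country, year)`.
#' @param populations Population tibble (`country`, `year`, `age`,
#'   `population`, optionally `sex`). For draws without an age dimension the
#'   population is summed over ages first.
#' @param groups Named list mapping group name to a character vector of
#'   member countries, or a tibble with `country` and `group` columns.
#'   Default: a single group `"World"` containing every country present.
#' @param sex Optional sex filter applied to `populations`.
#' @return Array with the `country` dimension replaced by a `group` dimension.
#' @export
aggregate_draws <- function(draws, populations, groups = NULL, sex = NULL) {
  ci <- dim_index(draws, "country")
  countries <- dimnames(draws)[[ci]]
  years <- dimnames(draws)[[dim_index(draws, "year")]]
  has_age <- "age" %in% names(dimnames(draws))
  ages <- if (has_age) dimnames(draws)[[dim_index(draws, "age")]] else NULL
  if (is.null(groups)) groups <- list(World = countries)
  if (is.data.frame(groups)) {
    groups <- split(groups$country, groups$group)
  }
  all_ages <- if (has_age) as.numeric(ages) else
    sort(unique(populations$age))
  pop <- population_weights(populations, countries, as.numeric(years),
                            all_ages, sex = sex)
  if (!has_age) pop <- apply(pop, c(1, 2), sum)

  out_pieces <- lapply(names(groups), function(g) {
    members <- groups[[g]]
    miss <- setdiff(members, countries)
    if (length(miss) > 0L) {
      stop_bad_arg(sprintf("Group '%s' member(s) missing from draws: %s",
                           g, paste(miss, collapse = ", ")),
                   "bmitrends_lookup_error")
    }
    mi <- match(members, countries)
    if (has_age) {
      w <- pop[mi, , , drop = FALSE]
      wsum <- apply(w, c(2, 3), sum)
      sub <- draws[, mi, , , drop = FALSE]
      num <- colSums(aperm(sweep(sub, c(2, 3, 4), w, `*`), c(2, 1, 3, 4)))
      sweep(num, c(2, 3), wsum, `/`)
    } else {
      w <- pop[mi, , drop = FALSE]
      wsum <- colSums(w)
      sub <- draws[, mi, , drop = FALSE]
      num <- colSums(aperm(sweep(sub, c(2, 3), w, `*`), c(2, 1, 3)))
      sweep(num, 2, wsum, `/`)
    }
  })
  nd <- length(dim(out_pieces[[1]])) + 1L
  out <- array(unlist(out_pieces),
               dim = c(dim(out_pieces[[1]]), length(groups)))
  perm <- c(1L, nd, seq(2L, nd - 1L))
  out <- aperm(out, perm)
  dn <- c(list(draw = dimnames(draws)[[1]]), list(group = names(groups)),
          if (has_age) list(year = years, age = ages) else
            list(year = years))
  dimnames(out) <- dn
  out
}

#' Number of persons in a category
#'
#' Multiplies age-specific prevalence draws by the population by country,
#' year (and sex) and sums over ages; aggregation over countries is
#' summation.
#'
#' @param draws Prevalence draw array `(draw, country, year, age)`,
#'   values in \[0, 1\].
#' @param populations Population tibble as in [aggregate_draws()].
#' @param groups Optional grouping as in [aggregate_draws()]; when supplied,
#'   counts are summed within each group.
#' @param sex Optional sex filter for `populations`.
#' @return Count draw array `(draw, country, year)` (persons), or
#'   `(draw, group, year)` when `groups` is given.
#' @export
affected_count <- function(draws, populations, groups = NULL, sex = NULL) {
  if (any(draws < 0 | draws > 1)) {
    stop_bad_arg("Prevalence draws must lie in [0, 1].",
                 "bmitrends_domain_error")
  }
  countries <- dimnames(draws)[[dim_index(draws, "country")]]
  years <- dimnames(draws)[[dim_index(draws, "year")]]
  ages <- dimnames(draws)[[dim_index(draws, "age")]]
  pop <- population_weights(populations, countries, as.numeric(years),
                            as.numeric(ages), sex = sex)
  counts <- colSums(aperm(sweep(draws, c(2, 3, 4), pop, `*`),
                          c(4, 1, 2, 3)))
  dimnames(counts) <- list(draw = dimnames(draws)[[1]], country = countries,
                           year = years)
  if (is.null(groups)) return(counts)
  if (is.data.frame(groups)) groups <- split(groups$country, groups$group)
  pieces <- lapply(groups, function(members) {
    apply(counts[, match(members, countries), , drop = FALSE], c(1, 3), sum)
  })
  out <- array(unlist(pieces), dim = c(dim(pieces[[1]]), length(groups)))
  out <- aperm(out, c(1, 3, 2))
  dimnames(out) <- list(draw = dimnames(draws)[[1]], group = names(groups),
                        year = years)
  out
}

#' Summarise posterior draws
#'
#' Posterior mean and central 95% credible interval (2.5th to 97.5th
#' percentiles, linear-interpolation quantile rule) for every cell of a draw
#' array, collapsing the `draw` dimension.
#'
#' @param draws Numeric vector or array whose first dimension (or the
#'   dimension named `draw`) indexes draws.
#' @param probs Credible bounds, default `c(0.025, 0.975)`.
#' @return A tibble with one row per cell: the non-draw dimensions as
#'   columns plus `mean`, `lower`, `upper`.
#' @export
summarise_draws <- function(draws, probs = c(0.025, 0.975)) {
  if (is.null(dim(draws))) {
    draws <- array(draws, dim = c(length(draws), 1),
                   dimnames = list(draw = NULL, cell = "all"))
  }
  di <- match("draw", names(dimnames(draws)))
  if (is.na(di)) di <- 1L
  if (dim(draws)[di] < 100) {
    warn("Fewer than 100 draws; posterior summaries will be noisy.")
  }
  nd <- length(dim(draws))
  other <- setdiff(seq_len(nd), di)
  flat <- matrix(aperm(draws, c(di, other)), nrow = dim(draws)[di])
  qs <- apply(flat, 2, cri_quantiles, probs = probs)
  dn <- dimnames(draws)[other]
  for (i in seq_along(dn)) {
    if (is.null(dn[[i]])) dn[[i]] <- as.character(seq_len(dim(draws)[other[i]]))
  }
  names(dn) <- names(dimnames(draws))[other]
  grid <- expand.grid(dn, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- as_tibble(grid)
  out$mean <- colMeans(flat)
  out$lower <- qs[1, ]
  out$upper <- qs[2, ]
  out
}

#' Summarise a posterior change with its trend probability
#'
#' The reported direction is the sign of the posterior mean change; the
#' posterior probability (PP) that the estimated increase or decrease is a
#' truly increasing or decreasing trend is the fraction of draws with a
#' change in that direction.
#'
#' @param change_draws Vector or draw array of change draws.
#' @return As [summarise_draws()], plus `pp` and `direction` columns.
#' @export
summarise_change <- function(change_draws, probs = c(0.025, 0.975)) {
  out <- summarise_draws(change_draws, probs = probs)
  if (is.null(dim(change_draws))) {
    change_draws <- array(change_draws, dim = c(length(change_draws), 1),
                          dimnames = list(draw = NULL, cell = "all"))
  }
  di <- match("draw", names(dimnames(change_draws)))
  if (is.na(di)) di <- 1L
  nd <- length(dim(change_draws))
  flat <- matrix(aperm(change_draws, c(di, setdiff(seq_len(nd), di))),
                 nrow = dim(change_draws)[di])
  # exact zeros (flat trajectories) count half toward either direction
  frac_up <- colMeans(flat > 0) + colMeans(flat == 0) / 2
  out$direction <- ifelse(out$mean >= 0, "increase", "decrease")
  out$pp <- ifelse(out$direction == "increase", frac_up, 1 - frac_up)
  out
}

#' @rdname summarise_change
#' @param probs Credible bounds.
#' @export
trend_pp <- function(change_draws) {
  m <- mean(change_draws)
  half_zero <- mean(change_draws == 0) / 2
  if (m >= 0) mean(change_draws > 0) + half_zero else
    mean(change_draws < 0) + half_zero
}

#' Change per decade between two years
#'
#' Per draw, the endpoint difference scaled to a 10-year period:
#' `(value(y1) - value(y0)) * 10 / (y1 - y0)`. For a linear trajectory with
#' slope s per year this is exactly 10 s.
#'
#' @param draws Array with a named `year` dimension.
#' @param y0,y1 Start and end years (present in the draws; `y1 > y0`).
#' @return As [summarise_change()], in outcome units per decade.
#' @export
change_per_decade <- function(draws, y0, y1, probs = c(0.025, 0.975)) {
  if (y1 <= y0) stop_bad_arg("Need y1 > y0.", "bmitrends_value_error")
  yi <- dim_index(draws, "year")
  years <- dimnames(draws)[[yi]]
  i0 <- match(as.character(y0), years); i1 <- match(as.character(y1), years)
  if (is.na(i0) || is.na(i1)) {
    stop_bad_arg("Both years must be present in the draws.",
                 "bmitrends_value_error")
  }
  idx0 <- idx1 <- rep(list(quote(expr = )), length(dim(draws)))
  idx0[[yi]] <- i0; idx1[[yi]] <- i1
  d0 <- do.call(`[`, c(list(draws), idx0, list(drop = FALSE)))
  d1 <- do.call(`[`, c(list(draws), idx1, list(drop = FALSE)))
  ch <- (d1 - d0) * 10 / (y1 - y0)
  dn <- dimnames(draws)
  dn[[yi]] <- NULL
  ch <- array(ch, dim = dim(draws)[-yi], dimnames = dn)
  summarise_change(ch, probs = probs)
}

#' Decompose a change in affected counts
#'
#' Splits the change in the number of affected persons between two time
#' points into the part due to changing prevalence (at baseline population),
#' the part due to population growth and age-structure change (at baseline
#' prevalence), and their interaction:
#' \deqn{\Delta C = \sum_a N_{a,0}(p_{a,1}-p_{a,0})
#'   + \sum_a (N_{a,1}-N_{a,0})p_{a,0}
#'   + \sum_a (N_{a,1}-N_{a,0})(p_{a,1}-p_{a,0}),}
#' an exact identity. Shares are components relative to \eqn{\Delta C} and
#' may be negative when components oppose.
#'
#' @param p0,p1 Age-specific prevalence at the two time points: numeric
#'   vectors by age, or draws-by-age matrices.
#' @param n0,n1 Age-specific populations (vectors by age).
#' @return For vector input, a tibble with rows `prevalence`, `population`,
#'   `interaction`, `total` and columns `persons` and `share_pct` (share of
#'   the total change, in percent; `NA` when the total change is 0). For
#'   matrix input the same tibble built from posterior-mean components, plus
#'   a `draws` attribute holding per-draw components.
#' @export
decompose_count_change <- function(p0, p1, n0, n1) {
  if (is.matrix(p0) || is.matrix(p1)) {
    p0 <- rbind(p0); p1 <- rbind(p1)
    if (!all(dim(p0) == dim(p1)) || ncol(p0) != length(n0) ||
        length(n0) != length(n1)) {
      stop_bad_arg("Age grids of p0, p1, n0, n1 must match.",
                   "bmitrends_value_error")
    }
    comp <- cbind(
      prevalence = as.vector((p1 - p0) %*% n0),
      population = as.vector(p0 %*% (n1 - n0)),
      interaction = as.vector((p1 - p0) %*% (n1 - n0)))
    means <- unname(colMeans(comp))
    total <- sum(means)
    out <- tibble(
      component = c("prevalence", "population", "interaction", "total"),
      persons = c(means, total),
      share_pct = if (total == 0) rep(NA_real_, 4) else
        c(means, total) / total * 100)
    attr(out, "draws") <- comp
    return(out)
  }
  if (length(p0) != length(p1) || length(n0) != length(n1) ||
      length(p0) != length(n0)) {
    stop_bad_arg("Age grids of p0, p1, n0, n1 must match.",
                 "bmitrends_value_error")
  }
  prev <- sum(n0 * (p1 - p0))
  popn <- sum((n1 - n0) * p0)
  inter <- sum((n1 - n0) * (p1 - p0))
  total <- prev + popn + inter
  tibble(
    component = c("prevalence", "population", "interaction", "total"),
    persons = c(prev, popn, inter, total),
    share_pct = if (total == 0) rep(NA_real_, 4) else
      c(prev, popn, inter, total) / total * 100)
}
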