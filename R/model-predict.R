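#' Posterior outcome draws on the natural scale
#'
#' Evaluates the fitted mean structure for the requested country-year-age
#' cells at the national, population-mixed reference (coverage and
#' urbanicity fixed effects and study random effects set to zero), applies
#' the inverse link, and (for prevalence outcomes) clamps to
#' (1e-6, 1 - 1e-6). Years outside the fitted window are an error: the model
#' interpolates and smooths, it does not project.
#'
#' @param object A [run_mcmc()] fit.
#' @param countries,years,ages Cells to evaluate; defaults to the full
#'   fitted grid.
#' @param ... Unused.
#' @return A draw array of class `bmi_draws` with named dimensions
#'   `(draw, country, year, age)` and attributes `outcome`, `link`, `sex`.
#' @export
predict.bmi_fit <- function(object, countries = NULL, years = NULL,
                            ages = NULL, ...) {
  ws <- object$workspace
  countries <- countries %||% ws$countries
  years <- years %||% ws$years
  ages <- ages %||% ws$spec$ages
  if (any(!countries %in% ws$countries)) {
    stop_bad_arg("Unknown country requested.", "bmitrends_lookup_error")
  }
  if (any(years < ws$years[1] | years > ws$years[ws$T])) {
    stop_bad_arg(
      "Requested years fall outside the fitted window; projection beyond the window is unsupported.",
      "bmitrends_domain_error")
  }
  if (any(ages < min(ws$spec$ages) | ages > max(ws$spec$ages))) {
    stop_bad_arg("Requested ages fall outside the fitted age range.",
                 "bmitrends_domain_error")
  }
  D <- object$n_draws
  ci <- match(countries, ws$countries)
  ti <- match(years, ws$years)
  x <- ws$x_years[ti]
  g <- ws$col_group
  th <- object$draws$theta

  # country-level intercepts and slopes per draw
  alpha <- th[, g == "icpt", drop = FALSE][, 1] +
    th[, g == "a_sr", drop = FALSE][, ws$sr_of_ctry[ci], drop = FALSE] +
    th[, g == "a_reg", drop = FALSE][, ws$reg_of_ctry[ci], drop = FALSE] +
    th[, g == "a_ctry", drop = FALSE][, ci, drop = FALSE]
  beta <- th[, g == "slope", drop = FALSE][, 1] +
    th[, g == "b_sr", drop = FALSE][, ws$sr_of_ctry[ci], drop = FALSE] +
    th[, g == "b_reg", drop = FALSE][, ws$reg_of_ctry[ci], drop = FALSE] +
    th[, g == "b_ctry", drop = FALSE][, ci, drop = FALSE]

  nC <- length(ci); nT <- length(ti); nA <- length(ages)
  base <- array(0, dim = c(D, nC, nT))
  u <- object$draws$u
  for (jc in seq_len(nC)) {
    cc <- ci[jc]
    rw <- matrix(u$global[, 1, ti], D, nT) +
      matrix(u$superregion[, ws$sr_of_ctry[cc], ti], D, nT) +
      matrix(u$region[, ws$reg_of_ctry[cc], ti], D, nT) +
      matrix(u$country[, cc, ti], D, nT)
    base[, jc, ] <- alpha[, jc] + outer(beta[, jc], x) + rw
  }
  if (ws$spec$components$urban) {
    burb <- th[, g == "urb", drop = FALSE][, 1]
    for (jc in seq_len(nC)) {
      base[, jc, ] <- base[, jc, ] + outer(burb, ws$U[ci[jc], ti])
    }
  }

  eta <- array(NA_real_, dim = c(D, nC, nT, nA),
               dimnames = list(draw = NULL, country = countries,
                               year = years, age = ages))
  if (ws$k_spline > 0) {
    Bg <- t(spline_basis_at(ws, ages))   # k x nA
    G <- object$draws$gamma_g            # D x k
    for (jc in seq_len(nC)) {
      sp <- (G + object$draws$gamma_c[, , ci[jc]]) %*% Bg  # D x nA
      for (ja in seq_len(nA)) {
        eta[, jc, , ja] <- base[, jc, ] + sp[, ja]
      }
    }
  } else {
    for (ja in seq_len(nA)) eta[, , , ja] <- base
  }
  out <- if (ws$spec$link == "logit") {
    clamp(plogis(eta), 1e-6, 1 - 1e-6)
  } else eta
  dimnames(out) <- dimnames(eta)
  structure(out, class = c("bmi_draws", "array"),
            outcome = ws$spec$outcome, link = ws$spec$link, sex = ws$sex)
}

# evaluate the centred spline basis of a workspace at arbitrary ages
spline_basis_at <- function(ws, ages) {
  grid_ages <- ws$spec$ages
  idx <- match(ages, grid_ages)
  if (!anyNA(idx)) return(ws$B_grid[idx, , drop = FALSE])
  # off-grid ages: rebuild with the workspace's knots and centring
  stop_bad_arg("Requested ages must lie on the fitted age grid.",
               "bmitrends_domain_error")
}

#' @export
print.bmi_draws <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<bmi_draws: %s, %s>\n", attr(x, "outcome"),
              paste(paste0(names(dimnames(x)), "=", d), collapse = ", ")))
  invisible(x)
}

#' Tidy posterior draw arrays or fits
#'
#' For a `bmi_draws` array, returns the posterior summary as a long tibble
#' (one row per cell). For a `bmi_fit`, returns summaries of the model
#' parameters.
#'
#' @param x A `bmi_draws` array or `bmi_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy bmi_draws
#' @export
tidy.bmi_draws <- function(x, ...) {
  out <- summarise_draws(unclass(x))
  out$year <- as.integer(out$year)
  if ("age" %in% names(out)) out$age <- as.integer(out$age)
  out$outcome <- attr(x, "outcome")
  out$sex <- attr(x, "sex") %||% NA_character_
  out
}

#' @rdname tidy.bmi_draws
#' @method tidy bmi_fit
#' @export
tidy.bmi_fit <- function(x, ...) {
  ws <- x$workspace
  g <- ws$col_group
  label <- c(icpt = "intercept_global", slope = "slope_global",
             urb = "beta_urban", delta_sn = "delta_subnational",
             delta_cm = "delta_community", delta_u = "delta_urban",
             delta_r = "delta_rural")
  unit_names <- list(
    a_sr = ws$superregions, a_reg = ws$regions, a_ctry = ws$countries,
    b_sr = ws$superregions, b_reg = ws$regions, b_ctry = ws$countries)
  terms <- vapply(seq_along(g), function(j) {
    if (g[j] %in% names(label)) return(label[[g[j]]])
    un <- unit_names[[g[j]]]
    pos <- sum(g[seq_len(j)] == g[j])
    paste0(g[j], "[", un[pos], "]")
  }, character(1))
  th <- x$draws$theta
  par_tbl <- tibble(
    term = c(terms, colnames(x$draws$sds), colnames(x$draws$kappa)),
    estimate = c(colMeans(th), colMeans(x$draws$sds),
                 colMeans(x$draws$kappa)),
    lower = c(apply(th, 2, cri_quantiles)[1, ],
              apply(x$draws$sds, 2, cri_quantiles)[1, ],
              apply(x$draws$kappa, 2, cri_quantiles)[1, ]),
    upper = c(apply(th, 2, cri_quantiles)[2, ],
              apply(x$draws$sds, 2, cri_quantiles)[2, ],
              apply(x$draws$kappa, 2, cri_quantiles)[2, ]))
  par_tbl
}

#' One-line fit summary
#'
#' @param x A `bmi_fit`.
#' @param ... Unused.
#' @return One-row tibble with fit dimensions and convergence diagnostics.
#' @method glance bmi_fit
#' @export
glance.bmi_fit <- function(x, ...) {
  tibble(
    outcome = x$spec$outcome,
    n_obs = x$workspace$n,
    n_studies = x$workspace$n_study,
    n_countries = x$workspace$C,
    n_draws = x$n_draws,
    max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
    min_ess = min(x$diagnostics$ess, na.rm = TRUE),
    mean_lp = mean(x$draws$lp),
    runtime_s = x$runtime)
}
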