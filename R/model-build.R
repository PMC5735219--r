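#' Assemble the model workspace
#'
#' Joins validated observations to country metadata, moves prevalence
#' observations to the logit scale (delta-method standard errors,
#' `se_logit = se / (p (1 - p))` with p floored), builds the block design
#' matrices, the RW2 structure matrix and constraints, the centred cubic
#' B-spline age basis, and the index maps the sampler uses. Every country in
#' the metadata is part of the model, whether or not it has data: data-free
#' countries are estimated from the hierarchy alone.
#'
#' @param observations Validated observation tibble (from
#'   [validate_observations()] / [read_observations()]).
#' @param meta A [country_meta()] object covering every observation.
#' @param spec A [model_spec()].
#' @return A list of class `bmi_model_workspace`.
#' @export
build_model <- function(observations, meta, spec = model_spec()) {
  obs <- as_tibble(observations)
  obs <- obs[obs$outcome == spec$outcome, , drop = FALSE]
  if (nrow(obs) == 0L) {
    stop_bad_arg(sprintf("No observations for outcome '%s'.", spec$outcome),
                 "bmitrends_value_error")
  }
  sexes <- unique(obs$sex)
  if (length(sexes) > 1L) {
    stop_bad_arg("Analyses are run by sex: fit one sex per model.",
                 "bmitrends_value_error")
  }
  obs$age_mid <- (obs$age_lower + obs$age_upper) / 2
  keep <- obs$mid_year >= spec$years[1] & obs$mid_year <= spec$years[2] &
    obs$age_mid >= min(spec$ages) & obs$age_mid <= max(spec$ages)
  obs <- obs[keep, , drop = FALSE]
  if (nrow(obs) == 0L) {
    stop_bad_arg("No observations inside the analysis window/ages.",
                 "bmitrends_value_error")
  }
  unmatched <- setdiff(obs$country, meta$regions$country)
  if (length(unmatched) > 0L) {
    stop_bad_arg(paste0("Observations from countries missing in metadata: ",
                        paste(unmatched, collapse = ", ")),
                 "bmitrends_lookup_error")
  }
  obs <- urbanisation_offset(obs, meta)

  # link transform
  if (spec$link == "logit") {
    p <- clamp(obs$value, spec$p_floor, 1 - spec$p_floor)
    y <- qlogis(p)
    se <- obs$standard_error / (p * (1 - p))
  } else {
    y <- obs$value
    se <- obs$standard_error
  }

  countries <- meta$regions$country
  regions <- sort(unique(meta$regions$region))
  srs <- sort(unique(meta$regions$superregion))
  reg_of_ctry <- match(meta$regions$region, regions)
  sr_of_ctry <- match(meta$regions$superregion, srs)
  C <- length(countries); R <- length(regions); S <- length(srs)

  years <- spec$years[1]:spec$years[2]
  T <- length(years)
  t0 <- mean(years)
  x_years <- years - t0

  ct_i <- match(obs$country, countries)
  reg_i <- reg_of_ctry[ct_i]
  sr_i <- sr_of_ctry[ct_i]
  t_i <- match(obs$mid_year, years)
  x_i <- obs$mid_year - t0

  # urban covariate u_c(t) per country-year from metadata
  U <- matrix(NA_real_, C, T, dimnames = list(countries, years))
  idx <- cbind(match(meta$urban$country, countries),
               match(meta$urban$year, years))
  ok <- !is.na(idx[, 1]) & !is.na(idx[, 2])
  U[idx[ok, , drop = FALSE]] <- meta$urban$urban_proportion[ok]
  if (anyNA(U)) {
    stop_bad_arg("Urbanisation series does not cover the analysis window.",
                 "bmitrends_lookup_error")
  }

  # block-A design: hierarchical intercepts/slopes + fixed effects
  n <- nrow(obs)
  ind <- function(i, k) {
    m <- matrix(0, n, k)
    m[cbind(seq_len(n), i)] <- 1
    m
  }
  cols <- list(icpt = matrix(1, n, 1),
               a_sr = ind(sr_i, S), a_reg = ind(reg_i, R),
               a_ctry = ind(ct_i, C),
               slope = matrix(x_i, n, 1),
               b_sr = ind(sr_i, S) * x_i, b_reg = ind(reg_i, R) * x_i,
               b_ctry = ind(ct_i, C) * x_i)
  if (spec$components$urban) {
    cols$urb <- matrix(U[cbind(ct_i, t_i)], n, 1)
  }
  if (spec$components$coverage_fx) {
    cols$delta_sn <- matrix(as.numeric(obs$coverage == "subnational"), n, 1)
    cols$delta_cm <- matrix(as.numeric(obs$coverage == "community"), n, 1)
  }
  if (spec$components$urbanicity_fx) {
    cols$delta_u <- matrix(obs$urban_offset *
                             (obs$urbanicity == "urban"), n, 1)
    cols$delta_r <- matrix(obs$urban_offset *
                             (obs$urbanicity == "rural"), n, 1)
  }
  X <- do.call(cbind, cols)
  group <- rep(names(cols), vapply(cols, ncol, integer(1)))
  colnames(X) <- paste0(group, "_", unlist(lapply(cols, function(m)
    seq_len(ncol(m)))))

  # spline basis in age, centred over the estimation age grid
  B_obs <- NULL; B_grid <- NULL
  if (spec$components$spline && length(unique(spec$ages)) >= 4) {
    probs <- seq_len(spec$spline_knots) / (spec$spline_knots + 1)
    knots <- unique(quantile(obs$age_mid, probs = probs, type = 7))
    knots <- knots[knots > min(spec$ages) & knots < max(spec$ages)]
    bnd <- range(spec$ages)
    B_grid <- splines::bs(spec$ages, knots = knots, degree = 3,
                          Boundary.knots = bnd)
    centers <- colMeans(B_grid)
    B_grid <- sweep(unclass(B_grid), 2, centers)
    B_obs <- sweep(unclass(
      splines::bs(clamp(obs$age_mid, bnd[1], bnd[2]), knots = knots,
                  degree = 3, Boundary.knots = bnd)), 2, centers)
  }

  # study index and coverage class
  study_ids <- unique(obs$study_id)
  study_i <- match(obs$study_id, study_ids)
  study_class <- obs$coverage[match(study_ids, obs$study_id)]
  class_i <- match(obs$coverage, COVERAGE_LEVELS)

  # RW2 structure
  D2 <- diff(diag(T), differences = 2)
  K <- crossprod(D2)
  Cmat <- rbind(rep(1, T), seq_len(T) - (T + 1) / 2)

  # per-unit observation row lists for the RW2 blocks
  unit_rows <- list(
    global = list(seq_len(n)),
    superregion = split(seq_len(n), factor(sr_i, levels = seq_len(S))),
    region = split(seq_len(n), factor(reg_i, levels = seq_len(R))),
    country = split(seq_len(n), factor(ct_i, levels = seq_len(C))))

  structure(list(
    obs = obs, y = y, se = se, v = se^2, n = n,
    countries = countries, regions = regions, superregions = srs,
    reg_of_ctry = reg_of_ctry, sr_of_ctry = sr_of_ctry,
    C = C, R = R, S = S, T = T, years = years, t0 = t0, x_years = x_years,
    ct_i = ct_i, reg_i = reg_i, sr_i = sr_i, t_i = t_i, x_i = x_i,
    class_i = class_i, study_i = study_i, n_study = length(study_ids),
    study_ids = study_ids,
    study_class_i = match(study_class, COVERAGE_LEVELS),
    X = X, col_group = group, U = U,
    B_obs = B_obs, B_grid = B_grid,
    k_spline = if (is.null(B_grid)) 0L else ncol(B_grid),
    K = K, Cmat = Cmat, unit_rows = unit_rows,
    sex = sexes, spec = spec, meta = meta),
    class = "bmi_model_workspace")
}

#' @export
print.bmi_model_workspace <- function(x, ...) {
  cat(sprintf(
    "<bmi_model_workspace: %d obs, %d studies, %d countries (%d with data), %d-%d>\n",
    x$n, x$n_study, x$C, length(unique(x$ct_i)), x$years[1],
    x$years[x$T]))
  invisible(x)
}

#' Initial parameter state
#'
#' Weighted least squares on the linear hierarchy (block-A design plus the
#' age spline) under the prior ridge, zeros for the RW2 and study effects,
#' and variance components at half their prior scale (or their fixed
#' values).
#'
#' @param ws A [build_model()] workspace.
#' @return A parameter-state list.
#' @export
init_state <- function(ws) {
  spec <- ws$spec
  pr <- spec$priors
  fixed <- spec$fixed_sds
  pick <- function(name, default) {
    v <- fixed[[name]] %||% default
    if (is.null(names(v)) && length(v) == length(default)) {
      names(v) <- names(default)
    }
    v
  }
  sds <- list(
    alpha = pick("alpha", pr$sd_alpha_scale / 2),
    beta = pick("beta", pr$sd_beta_scale / 2),
    gamma = pick("gamma", pr$sd_gamma_scale / 2),
    phi = pick("phi", pr$phi_scale / 2),
    tau = pick("tau", pr$tau_scale / 2))
  kappa <- pick("kappa", c(global = 1e4, superregion = 1e4, region = 1e4,
                           country = 1e4))

  Xfull <- if (is.null(ws$B_obs)) ws$X else cbind(ws$X, ws$B_obs)
  W0 <- 1 / (ws$v + sds$tau[ws$class_i]^2)
  prior_prec <- c(prior_precision_A(ws, sds),
                  rep(1 / sds$gamma[["global"]]^2, ws$k_spline))
  Q <- crossprod(Xfull * sqrt(W0)) + diag(prior_prec, ncol(Xfull))
  est <- solve(Q, crossprod(Xfull, W0 * ws$y))
  theta <- as.numeric(est[seq_len(ncol(ws$X))])
  names(theta) <- colnames(ws$X)
  gamma_g <- if (ws$k_spline > 0)
    as.numeric(est[ncol(ws$X) + seq_len(ws$k_spline)]) else numeric(0)

  list(theta = theta,
       u = list(global = matrix(0, 1, ws$T),
                superregion = matrix(0, ws$S, ws$T),
                region = matrix(0, ws$R, ws$T),
                country = matrix(0, ws$C, ws$T)),
       gamma_g = gamma_g,
       gamma_c = matrix(0, ws$k_spline, ws$C),
       e = numeric(ws$n_study),
       sds = sds, kappa = kappa)
}

# prior precision for each block-A column under the current SDs
prior_precision_A <- function(ws, sds) {
  pr <- ws$spec$priors
  prec_by_group <- c(
    icpt = 1 / pr$fixef_sd^2, slope = 1 / pr$fixef_sd^2,
    urb = 1 / pr$fixef_sd^2, delta_sn = 1 / pr$fixef_sd^2,
    delta_cm = 1 / pr$fixef_sd^2, delta_u = 1 / pr$fixef_sd^2,
    delta_r = 1 / pr$fixef_sd^2,
    a_sr = 1 / sds$alpha[["superregion"]]^2,
    a_reg = 1 / sds$alpha[["region"]]^2,
    a_ctry = 1 / sds$alpha[["country"]]^2,
    b_sr = 1 / sds$beta[["superregion"]]^2,
    b_reg = 1 / sds$beta[["region"]]^2,
    b_ctry = 1 / sds$beta[["country"]]^2)
  unname(prec_by_group[ws$col_group])
}

#' Evaluate the mean structure at a parameter state
#'
#' The linear predictor (link scale) for every observation row in the
#' workspace, including study-type and urbanicity adjustments and study
#' random effects.
#'
#' @param ws A [build_model()] workspace.
#' @param state A parameter state (see [init_state()]).
#' @return Numeric vector of length `ws$n`.
#' @export
model_eta <- function(ws, state) {
  eta <- as.numeric(ws$X %*% state$theta)
  eta <- eta + state$u$global[1, ws$t_i] +
    state$u$superregion[cbind(ws$sr_i, ws$t_i)] +
    state$u$region[cbind(ws$reg_i, ws$t_i)] +
    state$u$country[cbind(ws$ct_i, ws$t_i)]
  if (ws$k_spline > 0) {
    eta <- eta + as.numeric(ws$B_obs %*% state$gamma_g) +
      rowSums(ws$B_obs * t(state$gamma_c)[ws$ct_i, , drop = FALSE])
  }
  if (ws$spec$components$study_re) {
    eta <- eta + state$e[ws$study_i]
  }
  eta
}

#' Log joint posterior density
#'
#' Gaussian likelihood on the link scale plus hierarchical Gaussian priors
#' on intercept/slope deviations and fixed effects, the constrained RW2
#' Gaussian Markov prior on each level's time deviations, spline-coefficient
#' shrinkage, study-random-effect priors, half-normal priors on SD
#' components and Gamma priors on RW2 precisions. Constraint or positivity
#' violations return `-Inf` rather than erroring.
#'
#' @inheritParams model_eta
#' @param terms If `TRUE`, return a list with the `likelihood` and `prior`
#'   contributions separately (their sum is the log posterior).
#' @return Scalar log density (finite for interior states), or a two-element
#'   list when `terms = TRUE`.
#' @export
log_posterior <- function(state, ws, terms = FALSE) {
  pr <- ws$spec$priors
  sds <- state$sds
  if (any(unlist(sds[c("alpha", "beta", "gamma", "phi")]) < 0) ||
      any(sds$tau < 0) || any(state$kappa <= 0)) {
    return(-Inf)
  }
  eta <- model_eta(ws, state)
  sd_obs <- sqrt(ws$v + sds$tau[ws$class_i]^2)
  loglik <- sum(dnorm(ws$y, eta, sd_obs, log = TRUE))
  lp <- loglik

  th <- state$theta
  g <- ws$col_group
  fix_groups <- c("icpt", "slope", "urb", "delta_sn", "delta_cm",
                  "delta_u", "delta_r")
  lp <- lp + sum(dnorm(th[g %in% fix_groups], 0, pr$fixef_sd, log = TRUE))
  lp <- lp + sum(dnorm(th[g == "a_sr"], 0, sds$alpha[["superregion"]],
                       log = TRUE)) +
    sum(dnorm(th[g == "a_reg"], 0, sds$alpha[["region"]], log = TRUE)) +
    sum(dnorm(th[g == "a_ctry"], 0, sds$alpha[["country"]], log = TRUE)) +
    sum(dnorm(th[g == "b_sr"], 0, sds$beta[["superregion"]], log = TRUE)) +
    sum(dnorm(th[g == "b_reg"], 0, sds$beta[["region"]], log = TRUE)) +
    sum(dnorm(th[g == "b_ctry"], 0, sds$beta[["country"]], log = TRUE))

  if (ws$spec$components$rw2) {
    rank <- ws$T - 2
    for (lev in names(state$u)) {
      uu <- state$u[[lev]]
      viol <- max(abs(uu %*% t(ws$Cmat)))
      if (viol > 1e-6) return(-Inf)
      quad <- sum(vapply(seq_len(nrow(uu)), function(j)
        sum(uu[j, ] * (ws$K %*% uu[j, ])), numeric(1)))
      lp <- lp + nrow(uu) * rank / 2 *
        (log(state$kappa[[lev]]) - log(2 * pi)) -
        state$kappa[[lev]] * quad / 2
      lp <- lp + dgamma(state$kappa[[lev]], pr$rw2_shape, pr$rw2_rate,
                        log = TRUE)
    }
  }
  if (ws$k_spline > 0) {
    lp <- lp + sum(dnorm(state$gamma_g, 0, sds$gamma[["global"]],
                         log = TRUE)) +
      sum(dnorm(state$gamma_c, 0, sds$gamma[["country"]], log = TRUE))
  }
  if (ws$spec$components$study_re) {
    lp <- lp + sum(dnorm(state$e, 0, sds$phi[ws$study_class_i], log = TRUE))
  }
  if (ws$spec$fit_variances) {
    lp <- lp + sum(dhalfnorm_log(sds$alpha, pr$sd_alpha_scale)) +
      sum(dhalfnorm_log(sds$beta, pr$sd_beta_scale)) +
      sum(dhalfnorm_log(sds$phi, pr$phi_scale)) +
      sum(dhalfnorm_log(sds$tau, pr$tau_scale))
    if (ws$k_spline > 0) {
      lp <- lp + sum(dhalfnorm_log(sds$gamma, pr$sd_gamma_scale))
    }
  }
  if (terms) list(likelihood = loglik, prior = lp - loglik) else lp
}
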