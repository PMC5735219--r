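#' Prior hyperparameters for the hierarchical model
#'
#' All standard deviations carry half-normal priors (weakly informative,
#' proper, sampler-friendly); global intercept/slope and fixed effects carry
#' Normal(0, `fixef_sd`^2) priors; RW2 precisions carry Gamma priors.
#' Scales are on the link scale of the outcome (kg/m^2 for mean BMI, logits
#' for prevalence). Study-effect and extra-variance scales increase from
#' national to community data, encouraging (without enforcing) larger
#' variability for less representative samples.
#'
#' @param fixef_sd Prior SD for global intercept/slope and fixed effects.
#' @param sd_alpha_scale,sd_beta_scale Half-normal scales for intercept and
#'   slope deviations at superregion/region/country level.
#' @param sd_gamma_scale Half-normal scales for global and country-level
#'   age-spline coefficients.
#' @param phi_scale Half-normal scales for study random-effect SDs by
#'   coverage class.
#' @param tau_scale Half-normal scales for the extra observation-level SD by
#'   coverage class.
#' @param rw2_shape,rw2_rate Gamma prior on each level's RW2 precision.
#' @return Named list of class `bmi_prior_spec`.
#' @export
prior_spec <- function(fixef_sd = 10,
                       sd_alpha_scale = c(superregion = 2, region = 1,
                                          country = 0.7),
                       sd_beta_scale = c(superregion = 0.05, region = 0.03,
                                         country = 0.02),
                       sd_gamma_scale = c(global = 2, country = 0.5),
                       phi_scale = c(national = 0.3, subnational = 0.6,
                                     community = 1.0),
                       tau_scale = c(national = 0.3, subnational = 0.6,
                                     community = 1.0),
                       rw2_shape = 1, rw2_rate = 1e-4) {
  structure(list(fixef_sd = fixef_sd, sd_alpha_scale = sd_alpha_scale,
                 sd_beta_scale = sd_beta_scale,
                 sd_gamma_scale = sd_gamma_scale, phi_scale = phi_scale,
                 tau_scale = tau_scale, rw2_shape = rw2_shape,
                 rw2_rate = rw2_rate),
            class = "bmi_prior_spec")
}

#' Specify a hierarchical trend model
#'
#' One fitted model owns exactly one outcome (mean BMI or a single prevalence
#' category; categories are analysed separately and only recombined at
#' reporting time) and one age range. The mean structure for observation i in
#' country c, year t, age a is
#' \deqn{\eta_i = A_c + B_c (t - t_0) + \sum_\ell u_\ell(t) + s_c(a)
#'   + \beta_{urb} u_c(t) + \delta_{sn} + \delta_{cm}
#'   + \delta_{u/r}\,w_i + e_{study(i)},}
#' where \eqn{A_c, B_c} decompose hierarchically over
#' global/superregion/region/country, \eqn{u_\ell} are level-specific
#' second-order random walks (sum-to-zero and zero-mean-slope constrained),
#' \eqn{s_c} is a cubic B-spline in age with hierarchically shrunk
#' coefficients, \eqn{w_i} the study-minus-country urbanisation difference,
#' and observations are Gaussian on the link scale with variance
#' `se_i^2 + tau_class^2`. Prevalence outcomes are moved to the logit scale
#' with delta-method standard errors.
#'
#' @param outcome `"mean_bmi"` or `"prevalence:<category>"`.
#' @param years Analysis window, inclusive year range (>= 2 years).
#' @param ages Integer age grid the model estimates for.
#' @param spline_knots Number of interior knots for the cubic age spline
#'   (placed at quantiles of observed ages).
#' @param components Feature switches: `rw2`, `spline`, `urban`,
#'   `coverage_fx`, `urbanicity_fx`, `study_re` (all `TRUE` by default).
#' @param priors A [prior_spec()].
#' @param iterations,burn_in,thin MCMC schedule; defaults give 5000
#'   post-burn-in draws.
#' @param fit_variances If `FALSE`, all variance components are held at
#'   their `fixed_sds` values (used for conjugate checks).
#' @param fixed_sds Named list overriding initial/fixed values of `alpha`,
#'   `beta`, `gamma`, `phi`, `tau` SD vectors and `kappa` precisions.
#' @param p_floor Floor applied to prevalence observations before the logit
#'   and delta-method transforms.
#' @return A list of class `bmi_model_spec`.
#' @export
model_spec <- function(outcome = "mean_bmi", years = c(1975L, 2016L),
                       ages = 5:19, spline_knots = 5,
                       components = list(), priors = prior_spec(),
                       iterations = 10000L, burn_in = 5000L, thin = 1L,
                       fit_variances = TRUE, fixed_sds = list(),
                       p_floor = 0.005) {
  if (diff(range(years)) < 1) {
    stop_bad_arg("The analysis window must span at least 2 years.",
                 "bmitrends_config_error")
  }
  if (iterations <= burn_in) {
    stop_bad_arg("iterations must exceed burn_in.", "bmitrends_config_error")
  }
  comp <- modifyList(list(rw2 = TRUE, spline = TRUE, urban = TRUE,
                          coverage_fx = TRUE, urbanicity_fx = TRUE,
                          study_re = TRUE), components)
  link <- if (identical(outcome, "mean_bmi")) "identity" else if
    (grepl("^prevalence:.+", outcome)) "logit" else
      stop_bad_arg(sprintf("Unknown outcome '%s'.", outcome),
                   "bmitrends_config_error")
  structure(list(outcome = outcome, link = link,
                 years = as.integer(range(years)), ages = as.integer(ages),
                 spline_knots = spline_knots, components = comp,
                 priors = priors, iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 fit_variances = fit_variances, fixed_sds = fixed_sds,
                 p_floor = p_floor),
            class = "bmi_model_spec")
}

#' @export
print.bmi_model_spec <- function(x, ...) {
  on <- names(Filter(isTRUE, x$components))
  cat(sprintf(
    "<bmi_model_spec: %s (%s link), %d-%d, ages %d-%d, components: %s>\n",
    x$outcome, x$link, x$years[1], x$years[2], min(x$ages), max(x$ages),
    paste(on, collapse = ", ")))
  invisible(x)
}
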