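#' Plot estimated trends with credible ribbons
#'
#' @param summary_tbl A summary tibble with `year`, `mean`, `lower`, `upper`
#'   columns and an entity column (e.g. from [tidy.bmi_draws()] after
#'   age-standardisation, or `pipeline_report()$estimates`).
#' @param entity Column to facet by (default `country` if present, else
#'   `entity`).
#' @return A ggplot object.
#' @export
plot_trend <- function(summary_tbl, entity = NULL) {
  entity <- entity %||%
    (if ("country" %in% names(summary_tbl)) "country" else "entity")
  ggplot2::ggplot(summary_tbl,
                  ggplot2::aes(x = .data$year, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(entity) +
    ggplot2::labs(x = "Year", y = "Estimate") +
    ggplot2::theme_minimal()
}

#' Plot the fitted age pattern of a model
#'
#' Posterior mean age effect (spline contribution) by country.
#'
#' @param fit A `bmi_fit` with the spline component enabled.
#' @return A ggplot object.
#' @export
plot_age_pattern <- function(fit) {
  ws <- fit$workspace
  if (ws$k_spline == 0) {
    stop_bad_arg("Fit has no age spline.", "bmitrends_value_error")
  }
  G <- colMeans(fit$draws$gamma_g)
  tbl <- purrr::map_dfr(seq_len(ws$C), function(c) {
    gc <- colMeans(fit$draws$gamma_c[, , c, drop = FALSE][, , 1,
                                                          drop = FALSE])
    tibble(country = ws$countries[c], age = ws$spec$ages,
           effect = as.numeric(ws$B_grid %*% (G + as.numeric(gc))))
  })
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$age, y = .data$effect,
                                    group = .data$country)) +
    ggplot2::geom_line(alpha = 0.5, colour = "grey30") +
    ggplot2::labs(x = "Age (years)", y = "Age effect (link scale)") +
    ggplot2::theme_minimal()
}

#' Autoplot a posterior draw array
#'
#' Age-standardised (equal weights unless supplied) trajectory ribbons per
#' country.
#'
#' @param object A `bmi_draws` array.
#' @param weights Optional standard-population weights.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bmi_draws
#' @export
autoplot.bmi_draws <- function(object, weights = NULL, ...) {
  ages <- dimnames(object)$age
  if (!is.null(ages)) {
    weights <- weights %||%
      setNames(rep(1 / length(ages), length(ages)), ages)
    object <- age_standardise(unclass(object), weights)
  }
  tbl <- summarise_draws(object)
  tbl$year <- as.integer(tbl$year)
  plot_trend(tbl)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
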