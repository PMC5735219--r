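#' Define a BMI category scheme
#'
#' A category scheme partitions the real line (on the z-score or BMI scale)
#' into ordered, contiguous categories: every finite value belongs to exactly
#' one category. Cutoffs are shared by adjacent categories, so a boundary
#' convention decides where a value exactly at a cutoff falls:
#'
#' * `closed = "median"`: a boundary value belongs to the category nearer the
#'   central (reference-median) category, so extreme categories are strict
#'   ("more than k SD"). This is the convention of the child/adolescent
#'   growth-reference scheme: z = -2 is mild underweight, z = +2 is
#'   overweight-not-obese, obesity requires z > 2.
#' * `closed = "lower"`: plain lower-closed intervals `[lower, upper)`, the
#'   convention of adult fixed-BMI cutoffs (BMI >= 30 is obesity).
#'
#' @param names Character vector of category names, ordered low to high.
#' @param breaks Strictly increasing interior cutoffs; one fewer than `names`.
#' @param scale `"zscore"` or `"bmi"`: the scale the breaks live on.
#' @param closed Boundary convention, see Details.
#' @param central For `closed = "median"`, the index of the central category;
#'   defaults to the category containing 0 (z scale).
#' @return An object of class `bmi_category_scheme`.
#' @seealso [scheme_who_child()], [scheme_adult_bmi()], [classify_value()]
#' @export
category_scheme <- function(names, breaks, scale = c("zscore", "bmi"),
                            closed = c("lower", "median"), central = NULL) {
  scale <- match.arg(scale)
  closed <- match.arg(closed)
  if (length(names) != length(breaks) + 1L) {
    stop_bad_arg("Need exactly one more category name than interior breaks.",
                 "bmitrends_config_error")
  }
  if (anyDuplicated(names)) {
    stop_bad_arg("Category names must be unique.", "bmitrends_config_error")
  }
  if (length(breaks) == 0L || any(!is.finite(breaks)) ||
      any(diff(breaks) <= 0)) {
    stop_bad_arg("`breaks` must be finite and strictly increasing.",
                 "bmitrends_config_error")
  }
  if (is.null(central)) {
    central <- findInterval(if (scale == "zscore") 0 else median(breaks),
                            breaks) + 1L
  }
  structure(
    list(names = as.character(names), breaks = as.numeric(breaks),
         scale = scale, closed = closed, central = as.integer(central)),
    class = "bmi_category_scheme")
}

#' @export
print.bmi_category_scheme <- function(x, ...) {
  lo <- c(-Inf, x$breaks); hi <- c(x$breaks, Inf)
  cat(sprintf("<bmi_category_scheme: %s scale, %s-closed>\n", x$scale,
              x$closed))
  for (i in seq_along(x$names)) {
    cat(sprintf("  %-28s [%g, %g)\n", x$names[i], lo[i], hi[i]))
  }
  invisible(x)
}

#' Shipped category schemes
#'
#' `scheme_who_child()` is the child/adolescent scheme on the z-score scale
#' with cutoffs at -2, -1, +1, +2 SD of the growth-reference median:
#' moderate-and-severe underweight (more than 2 SD below), mild underweight,
#' healthy weight, overweight-not-obese, and obesity (more than 2 SD above).
#' `scheme_adult_bmi()` is the conventional adult fixed-BMI scheme
#' (18.5 / 25 / 30 kg/m^2, lower-closed).
#'
#' @return A [category_scheme()] object.
#' @export
scheme_who_child <- function() {
  category_scheme(
    names = c("moderate_severe_underweight", "mild_underweight",
              "healthy_weight", "overweight", "obesity"),
    breaks = c(-2, -1, 1, 2),
    scale = "zscore", closed = "median", central = 3L)
}

#' @rdname scheme_who_child
#' @export
scheme_adult_bmi <- function() {
  category_scheme(
    names = c("underweight", "healthy_weight", "overweight", "obesity"),
    breaks = c(18.5, 25, 30),
    scale = "bmi", closed = "lower")
}

#' Classify values on a scheme's own scale
#'
#' @param values Finite numeric vector on the scheme's scale (z-scores for
#'   `scale = "zscore"`, kg/m^2 for `scale = "bmi"`).
#' @param scheme A [category_scheme()].
#' @return Factor of category names with levels in scheme order.
#' @export
classify_value <- function(values, scheme) {
  if (!inherits(scheme, "bmi_category_scheme")) {
    stop_bad_arg("`scheme` must be a bmi_category_scheme.",
                 "bmitrends_config_error")
  }
  if (any(!is.finite(values))) {
    stop_bad_arg("`values` must be finite.", "bmitrends_domain_error")
  }
  idx <- findInterval(values, scheme$breaks) + 1L
  if (scheme$closed == "median") {
    # boundary hits above the central category move toward the median
    hit <- match(values, scheme$breaks)
    move <- !is.na(hit) & idx > scheme$central
    idx[move] <- idx[move] - 1L
  }
  factor(scheme$names[idx], levels = scheme$names)
}

#' Classify individual BMI measurements
#'
#' Converts each BMI to a growth-reference z-score for its sex and age band
#' (for z-scale schemes) and assigns the category. Cutoffs are therefore
#' age-specific and sex-specific, applied in 1-year age bands.
#'
#' @param data Tibble with columns `bmi`, `sex`, and `age_years` (integer
#'   completed years) or `age_months`.
#' @param reference Growth-reference tibble (see [read_lms_reference()]).
#' @param scheme A [category_scheme()]; default child/adolescent scheme.
#' @return `data` with added `z` (for z-scale schemes) and `category` columns.
#' @export
classify_bmi <- function(data, reference, scheme = scheme_who_child()) {
  if (!all(c("bmi", "sex") %in% names(data))) {
    stop_bad_arg("`data` needs columns bmi and sex.", "bmitrends_schema_error")
  }
  if (scheme$scale == "bmi") {
    data$category <- classify_value(data$bmi, scheme)
    return(as_tibble(data))
  }
  rows <- lms_lookup(reference, data$sex,
                     age_years = data[["age_years"]],
                     age_months = data[["age_months"]])
  data$z <- lms_zscore(data$bmi, rows$L, rows$M, rows$S)
  data$category <- classify_value(data$z, scheme)
  as_tibble(data)
}

#' Category prevalences from an individual-level sample
#'
#' Classifies each individual against the growth reference and tallies
#' category proportions with binomial standard errors. The standard error is
#' floored at `sqrt(0.25/n) * 0.05` so degenerate observed proportions
#' (0 or 1) do not receive infinite weight downstream.
#'
#' @inheritParams classify_bmi
#' @return A tibble with one row per category (in scheme order): `category`,
#'   `prevalence`, `standard_error`, `n`. Prevalences sum to 1 exactly.
#' @export
sample_prevalence <- function(data, reference, scheme = scheme_who_child()) {
  if (nrow(data) == 0L) {
    stop_bad_arg("Need at least one individual.", "bmitrends_value_error")
  }
  classified <- classify_bmi(data, reference, scheme)
  n <- nrow(classified)
  counts <- table(classified$category)
  p <- as.numeric(counts) / n
  se <- pmax(sqrt(p * (1 - p) / n), sqrt(0.25 / n) * 0.05)
  tibble(category = scheme$names, prevalence = p, standard_error = se, n = n)
}
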