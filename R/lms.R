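#' LMS (Box-Cox) z-score for BMI against a growth reference
#'
#' Converts a BMI measurement into an SD score relative to a growth reference
#' parameterised by the Box-Cox power `L`, median `M` and coefficient of
#' variation `S` at the matching sex and age:
#' \deqn{z = \frac{(\mathrm{BMI}/M)^L - 1}{L S} \quad (L \neq 0), \qquad
#'       z = \frac{\log(\mathrm{BMI}/M)}{S} \quad (L = 0).}
#' The transform is strictly increasing in BMI, so classification by z-score
#' cutoffs is equivalent to classification by age/sex-specific BMI cutoffs.
#'
#' @param bmi Numeric vector of BMI values in kg/m^2; must be positive.
#' @param L,M,S Reference parameters, recycled against `bmi`. `M` and `S`
#'   must be positive.
#' @return Numeric vector of unitless SD scores.
#' @examples
#' lms_zscore(17.6, L = 1, M = 16, S = 0.1)  # 1
#' @seealso [lms_inverse()], [lms_lookup()]
#' @export
lms_zscore <- function(bmi, L, M, S) {
  if (any(!is.finite(bmi)) || any(bmi <= 0)) {
    stop_bad_arg("`bmi` must be finite and positive.", "bmitrends_domain_error")
  }
  if (any(M <= 0) || any(S <= 0)) {
    stop_bad_arg("Reference `M` and `S` must be positive.",
                 "bmitrends_domain_error")
  }
  n <- max(length(bmi), length(L), length(M), length(S))
  bmi <- rep_len(bmi, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  z <- numeric(n)
  log_case <- abs(L) < 1e-12
  z[log_case] <- log(bmi[log_case] / M[log_case]) / S[log_case]
  z[!log_case] <- ((bmi[!log_case] / M[!log_case])^L[!log_case] - 1) /
    (L[!log_case] * S[!log_case])
  z
}

#' Invert an LMS z-score back to the BMI scale
#'
#' Places an SD-score cutoff on the BMI scale for a given reference row:
#' \eqn{\mathrm{BMI} = M (1 + L S z)^{1/L}} for \eqn{L \neq 0} and
#' \eqn{M e^{S z}} at \eqn{L = 0}. For \eqn{L \neq 0} the transform is only
#' defined while \eqn{1 + L S z > 0}; z outside that range is a domain error.
#'
#' @inheritParams lms_zscore
#' @param z Numeric vector of SD scores.
#' @return BMI values in kg/m^2 satisfying
#'   `lms_zscore(lms_inverse(z, ...), ...) == z` to floating tolerance.
#' @export
lms_inverse <- function(z, L, M, S) {
  if (any(M <= 0) || any(S <= 0)) {
    stop_bad_arg("Reference `M` and `S` must be positive.",
                 "bmitrends_domain_error")
  }
  n <- max(length(z), length(L), length(M), length(S))
  z <- rep_len(z, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  out <- numeric(n)
  log_case <- abs(L) < 1e-12
  out[log_case] <- M[log_case] * exp(S[log_case] * z[log_case])
  base <- 1 + L[!log_case] * S[!log_case] * z[!log_case]
  if (any(base <= 0)) {
    stop_bad_arg(
      "z outside the invertible range for this reference row (1 + L*S*z <= 0).",
      "bmitrends_domain_error")
  }
  out[!log_case] <- M[!log_case] * base^(1 / L[!log_case])
  out
}

#' Look up growth-reference rows for given sexes and ages
#'
#' Observations carry integer age in years; they are matched to the reference
#' at the band midpoint in months (`year * 12 + 6`), a deterministic rule that
#' avoids interpolation ambiguity. Exact `age_months` can be supplied instead.
#'
#' @param reference A growth-reference tibble with columns
#'   `sex`, `age_months`, `L`, `M`, `S` (see [read_lms_reference()]).
#' @param sex Character vector, `"female"` or `"male"`.
#' @param age_years Integer ages in completed years; mapped to midpoint months.
#' @param age_months Integer ages in months; overrides `age_years` if given.
#' @return A tibble with one matched reference row per request, in order.
#' @export
lms_lookup <- function(reference, sex, age_years = NULL, age_months = NULL) {
  validate_lms_reference(reference)
  if (is.null(age_months)) {
    if (is.null(age_years)) {
      stop_bad_arg("Supply `age_years` or `age_months`.",
                   "bmitrends_value_error")
    }
    age_months <- as.integer(age_years) * 12L + 6L
  }
  n <- max(length(sex), length(age_months))
  req <- tibble(sex = rep_len(as.character(sex), n),
                age_months = rep_len(as.integer(age_months), n))
  key_ref <- paste(reference$sex, reference$age_months)
  idx <- match(paste(req$sex, req$age_months), key_ref)
  if (anyNA(idx)) {
    miss <- req[is.na(idx), , drop = FALSE][1, ]
    stop_bad_arg(
      sprintf("No reference row for sex '%s' at %d months.",
              miss$sex, miss$age_months),
      "bmitrends_lookup_error")
  }
  reference[idx, c("sex", "age_months", "L", "M", "S")]
}

validate_lms_reference <- function(reference) {
  needed <- c("sex", "age_months", "L", "M", "S")
  if (!all(needed %in% names(reference))) {
    stop_bad_arg(
      paste0("Growth reference must have columns: ",
             paste(needed, collapse = ", "), "."),
      "bmitrends_schema_error")
  }
  if (any(reference$M <= 0) || any(reference$S <= 0)) {
    stop_bad_arg("Growth reference requires M > 0 and S > 0.",
                 "bmitrends_schema_error")
  }
  if (!all(reference$sex %in% c("female", "male"))) {
    stop_bad_arg("Growth reference `sex` must be 'female' or 'male'.",
                 "bmitrends_schema_error")
  }
  by_sex <- split(reference$age_months, reference$sex)
  if (any(vapply(by_sex, function(a) any(diff(a) <= 0), logical(1)))) {
    stop_bad_arg("`age_months` must be strictly increasing within each sex.",
                 "bmitrends_schema_error")
  }
  invisible(reference)
}

#' Read / write a growth-reference table
#'
#' Delimited UTF-8 text with a header and columns
#' `sex, age_months, L, M, S` ("." decimal point). The package ships no
#' copyrighted reference table; [generate_lms_reference()] produces a
#' deterministic synthetic stand-in and any real table in this format can be
#' supplied instead.
#'
#' @param path File path.
#' @return `read_lms_reference()` returns a validated tibble.
#' @export
read_lms_reference <- function(path) {
  ref <- readr::read_csv(path, col_types = readr::cols(
    sex = readr::col_character(),
    age_months = readr::col_integer(),
    L = readr::col_double(),
    M = readr::col_double(),
    S = readr::col_double()))
  validate_lms_reference(ref)
  ref
}

#' @rdname read_lms_reference
#' @param reference A growth-reference tibble.
#' @export
write_lms_reference <- function(reference, path) {
  validate_lms_reference(reference)
  readr::write_csv(reference[, c("sex", "age_months", "L", "M", "S")], path)
  invisible(path)
}
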