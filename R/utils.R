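stop_bad_arg <- function(msg, class) {
  abort(msg, class = c(class, "bmitrends_error"))
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_bad_arg(sprintf("`%s` must be a single finite number.", name),
                 "bmitrends_value_error")
  }
  invisible(x)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# half-normal log density for a standard deviation parameter
dhalfnorm_log <- function(x, scale) {
  ifelse(x < 0, -Inf, log(2) + dnorm(x, 0, scale, log = TRUE))
}

#' Linear-interpolation posterior quantiles
#'
#' Central credible bounds from draws using the linear-interpolation quantile
#' rule (R type 7). Kept in one place so every summary in the package uses the
#' same convention.
#' @noRd
cri_quantiles <- function(x, probs = c(0.025, 0.975)) {
  unname(quantile(x, probs = probs, type = 7, names = FALSE))
}

# deterministic child seed: keeps derived seeds inside 32-bit integer range
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483646L) + 1L
}
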