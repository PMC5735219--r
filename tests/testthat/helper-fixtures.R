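# shared small fixtures, built in code at test time

tiny_world <- function(seed = 11, outcome = "mean_bmi", ...) {
  generate_world(n_superregions = 1, n_regions = 2, n_countries = 4,
                 years = 2000:2011, ages = c(8, 11, 14), outcome = outcome,
                 seed = seed, ...)
}

tiny_obs <- function(world, seed = 12, ...) {
  simulate_studies(world, study_design(p_study = 0.6, ...), seed = seed)
}

# one small fitted model reused across test files
tiny_fit_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      w <- tiny_world()
      obs <- tiny_obs(w)
      val <- validate_observations(obs, years = c(2000L, 2011L))
      spec <- model_spec(years = c(2000, 2011), ages = c(8, 11, 14),
                        spline_knots = 2, iterations = 300, burn_in = 100)
      ws <- build_model(val$observations, w$meta, spec)
      cache <<- list(world = w, obs = obs, ws = ws,
                     fit = run_mcmc(ws, seed = 13))
    }
    cache
  }
})

# a reference row used throughout the LMS tests
ref_row <- function(L = -1.6, M = 16, S = 0.11) {
  tibble::tibble(sex = "female", age_months = 126L, L = L, M = M, S = S)
}

random_draw_array <- function(dim, seed, lo = 0.01, hi = 0.4) {
  set.seed(seed)
  array(runif(prod(dim), lo, hi), dim = dim,
        dimnames = list(draw = NULL, country = paste0("C", seq_len(dim[2])),
                        year = 2000 + seq_len(dim[3]) - 1,
                        age = 4 + seq_len(dim[4])))
}
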