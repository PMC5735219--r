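test_that("category rescaling divides by the draw-wise sum", {
  cells <- list(a = 0.2, b = 0.2, c = 0.4, d = 0.1, e = 0.05)
  draws <- lapply(cells, function(v) array(v, dim = c(1, 1)))
  out <- rescale_categories(draws)
  expect_equal(as.numeric(out$scaling), 1 / 0.95)
  expect_equal(Reduce(`+`, out$rescaled)[1, 1], 1)
  expect_equal(out$rescaled$a[1, 1], 0.2 / 0.95)
})

test_that("rescaling is exact, idempotent and audited on random draws", {
  set.seed(91)
  dims <- c(50, 3, 4, 2)
  draws <- lapply(setNames(1:5, paste0("cat", 1:5)), function(i)
    random_draw_array(dims, seed = 90 + i, lo = 0.02, hi = 0.3))
  out <- rescale_categories(draws)
  sums <- Reduce(`+`, out$rescaled)
  expect_lt(max(abs(sums - 1)), 1e-12)
  twice <- rescale_categories(out$rescaled)
  for (nm in names(draws)) {
    expect_equal(twice$rescaled[[nm]], out$rescaled[[nm]], tolerance = 1e-12)
  }
  expect_lt(max(abs(twice$scaling - 1)), 1e-12)
  # already-normalised input is left unchanged
  ok <- lapply(out$rescaled, identity)
  again <- rescale_categories(ok)
  expect_equal(again$rescaled, ok, tolerance = 1e-12)
})

test_that("age-standardisation is a draw-wise weighted mean", {
  dr <- random_draw_array(c(20, 2, 3, 2), seed = 7)
  dr[] <- 0.1
  w <- tibble::tibble(age = as.integer(dimnames(dr)$age),
                      weight = c(0.3, 0.7))
  out <- age_standardise(dr, w)
  expect_equal(unname(dim(out)), c(20, 2, 3))
  expect_equal(max(abs(out - 0.1)), 0)
  # two ages, values 10 and 20, weights 1/4 and 3/4
  dr2 <- random_draw_array(c(5, 1, 1, 2), seed = 8)
  dr2[, , , 1] <- 10; dr2[, , , 2] <- 20
  out2 <- age_standardise(dr2, tibble::tibble(
    age = as.integer(dimnames(dr2)$age), weight = c(0.25, 0.75)))
  expect_equal(unique(as.numeric(out2)), 17.5)
  # equal weights give the arithmetic mean
  out3 <- age_standardise(dr2, tibble::tibble(
    age = as.integer(dimnames(dr2)$age), weight = c(0.5, 0.5)))
  expect_equal(unique(as.numeric(out3)), 15)
})

test_that("standardisation and aggregation commute with the posterior mean", {
  dr <- random_draw_array(c(40, 3, 2, 3), seed = 9)
  w <- tibble::tibble(age = as.integer(dimnames(dr)$age),
                      weight = c(0.2, 0.5, 0.3))
  std <- age_standardise(dr, w)
  mean_then_std <- age_standardise(
    array(colMeans(dr), dim = c(1, dim(dr)[-1]),
          dimnames = c(list(draw = NULL), dimnames(dr)[-1])), w)
  expect_equal(as.numeric(mean_then_std[1, , ]),
               as.numeric(colMeans(std)), tolerance = 1e-12)
})

test_that("population aggregation weights countries correctly", {
  dr <- random_draw_array(c(10, 2, 1, 1), seed = 10)
  dr[, 1, , ] <- 1; dr[, 2, , ] <- 3
  pops <- tibble::tibble(
    country = c("C1", "C2"), year = 2000L,
    age = as.integer(dimnames(dr)$age), sex = "female",
    population = c(1, 3))
  agg <- aggregate_draws(dr, pops)
  expect_equal(unique(as.numeric(agg)), 2.5)
  # permuting countries leaves the aggregate unchanged
  dr_perm <- dr[, 2:1, , , drop = FALSE]
  dimnames(dr_perm)$country <- c("C2", "C1")
  agg2 <- aggregate_draws(dr_perm, pops)
  expect_equal(as.numeric(agg2), as.numeric(agg))
  # a singleton group equals its member
  single <- aggregate_draws(dr, pops, groups = list(G = "C2"))
  expect_equal(as.numeric(single), as.numeric(dr[, 2, , ]))
  expect_error(aggregate_draws(dr, pops, groups = list(G = "C9")),
               class = "bmitrends_lookup_error")
})

test_that("affected counts multiply prevalence by population and sum ages", {
  dr <- random_draw_array(c(8, 1, 1, 1), seed = 11)
  dr[] <- 0.05
  pops <- tibble::tibble(country = "C1", year = 2000L,
                         age = as.integer(dimnames(dr)$age),
                         sex = "female", population = 1e6)
  cnt <- affected_count(dr, pops)
  expect_equal(unique(as.numeric(cnt)), 50000)
  dr0 <- dr; dr0[] <- 0
  expect_equal(max(abs(affected_count(dr0, pops))), 0)
})

test_that("rescaled category counts partition the total population", {
  dims <- c(30, 2, 2, 3)
  draws <- lapply(setNames(1:5, paste0("cat", 1:5)), function(i)
    random_draw_array(dims, seed = 60 + i, lo = 0.05, hi = 0.3))
  res <- rescale_categories(draws)$rescaled
  pops <- tidyr::expand_grid(country = c("C1", "C2"), year = 2000:2001,
                             age = 5:7)
  pops$sex <- "female"
  pops$population <- runif(nrow(pops), 1e4, 1e6)
  for (nm in names(res)) {
    dimnames(res[[nm]]) <- dimnames(draws[[nm]])
  }
  total <- Reduce(`+`, lapply(res, affected_count, populations = pops))
  pop_by_cy <- tapply(pops$population, list(pops$country, pops$year), sum)
  for (ci in 1:2) for (yi in 1:2) {
    expect_equal(unique(round(total[, ci, yi], 6)),
                 round(pop_by_cy[ci, yi], 6))
  }
})

test_that("posterior summaries use the stated quantile convention", {
  set.seed(2024)
  z <- rnorm(5000)
  s <- summarise_draws(z)
  expect_lt(abs(s$lower - (-1.96)), 0.1)
  expect_lt(abs(s$upper - 1.96), 0.1)
  expect_equal(s$lower, unname(quantile(z, 0.025, type = 7)))
  expect_warning(summarise_draws(rnorm(50)), "Fewer than 100")
})

test_that("trend probabilities follow the direction convention", {
  up <- summarise_change(abs(rnorm(200)) + 0.01)
  expect_equal(up$pp, 1)
  expect_equal(up$direction, "increase")
  z <- rnorm(100)
  sym <- summarise_change(c(z, -z))
  expect_equal(sym$pp, 0.5)
  down <- summarise_change(-abs(rnorm(200)) - 0.01)
  expect_equal(down$pp, 1)
  expect_equal(down$direction, "decrease")
  flat <- summarise_change(rep(0, 100))
  expect_equal(flat$pp, 0.5)
  expect_equal(trend_pp(rep(0, 10)), 0.5)
})

test_that("change per decade scales endpoint differences", {
  yrs <- 1975:2016
  dr <- array(0, dim = c(100, 1, length(yrs)),
              dimnames = list(draw = NULL, country = "C1", year = yrs))
  # linear trajectory with slope s per year
  s <- 0.041
  for (t in seq_along(yrs)) dr[, , t] <- s * (yrs[t] - 1975)
  ch <- change_per_decade(dr, 1975, 2016)
  expect_equal(ch$mean, 10 * s)
  # a 4.1-unit rise over 1975-2016 is 1.0 per decade
  dr2 <- dr; dr2[, , length(yrs)] <- dr2[, , 1] + 4.1
  ch2 <- change_per_decade(dr2, 1975, 2016)
  expect_equal(ch2$mean, 1.0)
  flat <- dr; flat[] <- 7
  ch3 <- change_per_decade(flat, 1975, 2016)
  expect_equal(ch3$mean, 0)
  expect_equal(ch3$pp, 0.5)
  expect_error(change_per_decade(dr, 2000, 2000),
               class = "bmitrends_value_error")
})

test_that("count-change decomposition reproduces the worked example", {
  d <- decompose_count_change(p0 = 0.01, p1 = 0.02, n0 = 100, n1 = 110)
  expect_equal(d$persons, c(1.0, 0.1, 0.1, 1.2))
  expect_equal(d$share_pct, c(1 / 1.2, 0.1 / 1.2, 0.1 / 1.2, 1) * 100,
               tolerance = 1e-12)
  # constant population: no population or interaction component
  d2 <- decompose_count_change(c(0.1, 0.2), c(0.15, 0.3),
                               c(50, 60), c(50, 60))
  expect_equal(d2$persons[2:3], c(0, 0))
  # constant prevalence: no prevalence or interaction component
  d3 <- decompose_count_change(c(0.1, 0.2), c(0.1, 0.2),
                               c(50, 60), c(70, 90))
  expect_equal(d3$persons[c(1, 3)], c(0, 0))
})

test_that("decomposition components always sum to the total change", {
  set.seed(101)
  for (i in 1:200) {
    k <- sample(1:12, 1)
    p0 <- runif(k); p1 <- runif(k)
    n0 <- runif(k, 10, 1e6); n1 <- runif(k, 10, 1e6)
    d <- decompose_count_change(p0, p1, n0, n1)
    total <- sum(n1 * p1) - sum(n0 * p0)
    expect_equal(d$persons[4], total, tolerance = 1e-9)
    expect_equal(sum(d$persons[1:3]), total, tolerance = 1e-9)
  }
  # zero total change flags shares as undefined
  d0 <- decompose_count_change(0.1, 0.1, 100, 100)
  expect_true(all(is.na(d0$share_pct)))
  expect_equal(d0$persons[4], 0)
})

test_that("matrix draws decompose row-wise with a draws attribute", {
  set.seed(17)
  p0 <- matrix(runif(20, 0.01, 0.2), 5, 4)
  p1 <- matrix(runif(20, 0.01, 0.2), 5, 4)
  n0 <- runif(4, 100, 1e4); n1 <- runif(4, 100, 1e4)
  d <- decompose_count_change(p0, p1, n0, n1)
  comp <- attr(d, "draws")
  expect_equal(nrow(comp), 5)
  expect_equal(sum(colMeans(comp)), d$persons[4], tolerance = 1e-9)
})

test_that("synthetic standard population is normalised and readable", {
  sp <- standard_population(5:19)
  expect_equal(sum(sp$weight), 1)
  expect_true(all(diff(sp$weight) < 0))
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(sp, path)
  back <- read_standard_population(path, ages = 5:19)
  expect_equal(back$weight, sp$weight, tolerance = 1e-12)
  expect_error(read_standard_population(path, ages = 5:25),
               class = "bmitrends_schema_error")
})
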