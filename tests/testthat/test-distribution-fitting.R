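test_that("frequency tables are the histogram of a month's caseloads", {
  counts <- matrix(c(0L, 0L, 1L, 3L, 3L), nrow = 1,
                   dimnames = list("2019-05", paste0("S", 1:5)))
  m <- toy_matrix(counts, "2019-05", paste0("S", 1:5))
  ft <- build_frequency_table(m, "2019-05")
  expect_equal(ft$x, c(0, 1, 3))
  expect_equal(ft$y, c(2, 1, 2))
  expect_equal(sum(ft$y), ncol(m))
  expect_error(build_frequency_table(m, "2019-06"), "2019-06")

  # all-zero month
  z <- matrix(0L, 1, 4, dimnames = list("2019-05", paste0("S", 1:4)))
  ftz <- build_frequency_table(toy_matrix(z, "2019-05", paste0("S", 1:4)), "2019-05")
  expect_equal(ftz$x, 0)
  expect_equal(ftz$y, 4)
})

test_that("frequency-table mass equals the provider count on generated data", {
  syn <- synthetic_config(n_providers = 40, n_units = 5,
                          months = month_seq("2019-01", "2019-04"), seed = 3)
  mat <- generate_caseloads(syn)
  for (m in rownames(mat)) {
    expect_equal(sum(build_frequency_table(mat, m)$y), ncol(mat))
  }
})

test_that("fit_curve recovers noise-free curves of either family", {
  x <- 1:10
  fe <- fit_curve(frequency_table(x, 10 * exp(-0.5 * x)), "exponential")
  expect_equal(fe$a, 10, tolerance = 1e-8)
  expect_equal(fe$b, 0.5, tolerance = 1e-8)
  expect_lt(fe$rss, 1e-12)

  fp <- fit_curve(frequency_table(x, 8 * x^(-2)), "power")
  expect_equal(fp$a, 8, tolerance = 1e-8)
  expect_equal(fp$b, 2, tolerance = 1e-8)
  expect_lt(fp$rss, 1e-12)
})

test_that("fit_curve enforces support and zero-handling rules", {
  expect_error(fit_curve(frequency_table(c(1, 2), c(5, 3)), "exponential"),
               "insufficient support")
  ft <- frequency_table(c(0, 1, 2, 3), c(9, 5, 3, 2))
  expect_error(fit_curve(ft, "power", include_zero = TRUE),
               "undefined at X = 0")
  # zero bin reported but excluded by default
  f <- fit_curve(ft, "exponential")
  expect_equal(f$zero_bin, 9)
  expect_equal(f$n_obs, 3)
  # AIC follows the declared Gaussian-profile convention
  expect_equal(f$aic, f$n_obs * log(f$rss / f$n_obs) + 2 * (f$n_params + 1))
})

test_that("fit_curve matches a dense grid-search oracle on noisy tables", {
  set.seed(11)
  for (family in c("exponential", "power")) {
    for (rep in 1:3) {
      x <- 1:sample(5:15, 1)
      a_true <- runif(1, 5, 40)
      b_true <- runif(1, 0.3, 1.5)
      mu <- if (family == "power") a_true * x^(-b_true) else a_true * exp(-b_true * x)
      y <- pmax(mu + rnorm(length(x), sd = 0.1 * mu), 0.1)
      fit <- fit_curve(frequency_table(x, y), family)
      oracle <- grid_oracle(x, y, family, a_range = c(1, 100),
                            b_range = c(0.05, 5))
      # the solver's optimum is never worse than the best grid point
      expect_lte(fit$rss, oracle$rss + 1e-9)
      expect_equal(fit$a, oracle$a, tolerance = 0.05)
      expect_equal(fit$b, oracle$b, tolerance = 0.05)
    }
  }
})

test_that("compare_families prefers the generating family and breaks ties", {
  x <- 1:12
  cmp_e <- compare_families(frequency_table(x, 30 * exp(-0.4 * x)))
  expect_equal(cmp_e$preferred, "exponential")
  expect_equal(min(cmp_e$delta_aic), 0)

  cmp_p <- compare_families(frequency_table(x, 30 * x^(-1.5)))
  expect_equal(cmp_p$preferred, "power")

  # constant data fits both families exactly (b = 0): delta (0, 0) and the
  # lexical tie-break picks "exponential"
  cmp_tie <- compare_families(frequency_table(1:5, rep(7, 5)))
  expect_equal(unname(cmp_tie$delta_aic), c(0, 0))
  expect_equal(cmp_tie$preferred, "exponential")
})

test_that("exponential decay beats the power law on overdispersed-count frequencies", {
  # expected frequencies of a gamma-Poisson (negative binomial) caseload
  # model: the regime the registry data resembles
  for (shape in c(0.5, 1, 2)) {
    x <- 1:40
    y <- 300 * stats::dnbinom(x, size = shape, mu = 4)
    keep <- y > 1e-8
    cmp <- compare_families(frequency_table(x[keep], y[keep]))
    expect_equal(cmp$preferred, "exponential")
  }
})

test_that("AIC ordering ignores entry permutation and month labels", {
  set.seed(5)
  x <- 1:9
  y <- 25 * exp(-0.6 * x) + abs(rnorm(9, sd = 0.3))
  perm <- sample(9)
  c1 <- compare_families(frequency_table(x, y, month = "2019-01"))
  c2 <- compare_families(frequency_table(x[perm], y[perm], month = "2020-12"))
  expect_equal(c1$preferred, c2$preferred)
  expect_equal(unname(c1$delta_aic), unname(c2$delta_aic), tolerance = 1e-8)
})

test_that("pool_monthly_fits combines monthly estimates sensibly", {
  x <- 1:10
  f <- fit_curve(frequency_table(x, 12 * exp(-0.5 * x)), "exponential")
  pooled_same <- pool_monthly_fits(list(f, f, f))
  expect_equal(pooled_same$fixed_a, f$a)
  expect_equal(pooled_same$fixed_b, f$b)
  expect_equal(pooled_same$between_month_sd_b, 0)

  # equal-weight symmetric case: exact fits fall back to equal weights
  fits <- lapply(c(0.4, 0.5, 0.6), function(b) {
    fit_curve(frequency_table(x, 12 * exp(-b * x)), "exponential")
  })
  pooled <- pool_monthly_fits(fits)
  expect_equal(pooled$fixed_b, 0.5, tolerance = 1e-6)

  fp <- fit_curve(frequency_table(x, 8 * x^(-2)), "power")
  expect_error(pool_monthly_fits(list(f, fp)), "mixed families")
})

test_that("pooled estimates lie within the monthly range", {
  set.seed(21)
  x <- 1:12
  for (rep in 1:200) {
    bs <- runif(3, 0.2, 1.2)
    as <- runif(3, 5, 50)
    fits <- mapply(function(a, b) {
      y <- a * exp(-b * x) * exp(rnorm(length(x), sd = 0.05))
      fit_curve(frequency_table(x, y), "exponential")
    }, as, bs, SIMPLIFY = FALSE)
    p <- pool_monthly_fits(fits)
    est_b <- vapply(fits, function(f) f$b, numeric(1))
    est_a <- vapply(fits, function(f) f$a, numeric(1))
    expect_gte(p$fixed_b, min(est_b) - 1e-12)
    expect_lte(p$fixed_b, max(est_b) + 1e-12)
    expect_gte(p$fixed_a, min(est_a) - 1e-12)
    expect_lte(p$fixed_a, max(est_a) + 1e-12)
  }
})

test_that("loglog_points maps X >= 1 bins and flags the zero bin", {
  pts <- loglog_points(frequency_table(c(1, 10), c(10, 1)))
  expect_equal(pts$log_x, c(0, log(10)))
  expect_equal(pts$log_y, c(log(10), 0))
  expect_false(attr(pts, "zero_bin_omitted"))

  pts0 <- loglog_points(frequency_table(c(0, 1), c(5, 5)))
  expect_equal(nrow(pts0), 1)
  expect_true(attr(pts0, "zero_bin_omitted"))

  # exact power law is collinear in log-log
  x <- 1:8
  ppts <- loglog_points(frequency_table(x, 40 * x^(-1.7)))
  res <- stats::residuals(stats::lm(log_y ~ log_x, data = ppts))
  expect_lt(max(abs(res)), 1e-9)
})
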