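test_that("explicit zero-variance rates reproduce counts exactly", {
  syn <- synthetic_config(n_providers = 3, n_units = 2,
                          months = month_seq("2019-01", "2019-02"),
                          rate_model = "explicit",
                          rate_params = list(rates = c(0, 0, 5), dispersion = "none"),
                          seed = 1)
  mat <- generate_caseloads(syn)
  expect_equal(unname(mat[1, ]), c(0L, 0L, 5L))
  expect_equal(unname(mat[2, ]), c(0L, 0L, 5L))
})

test_that("the same configuration always yields the same data", {
  syn <- synthetic_config(n_providers = 30, n_units = 5,
                          months = month_seq("2019-01", "2019-03"), seed = 77)
  m1 <- generate_caseloads(syn)
  m2 <- generate_caseloads(syn)
  expect_identical(m1[, ], m2[, ])
  e1 <- generate_registry_events(m1, syn)
  e2 <- generate_registry_events(m2, syn)
  expect_identical(e1$event_date, e2$event_date)
  expect_identical(e1$unit_id, e2$unit_id)

  m3 <- generate_caseloads(synthetic_config(n_providers = 30, n_units = 5,
                                            months = month_seq("2019-01", "2019-03"),
                                            seed = 78))
  expect_false(identical(m1[, ], m3[, ]))
})

test_that("gamma-Poisson caseloads hit the configured mean", {
  syn <- synthetic_config(n_providers = 300, n_units = 20,
                          months = month_seq("2019-01", "2019-12"),
                          rate_params = list(shape = 0.5, mean = 4), seed = 4)
  mat <- generate_caseloads(syn)
  xbar <- mean(mat)
  # CLT bound: var of a gamma-Poisson cell is mean + mean^2/shape, but the
  # dominant term is the between-provider rate variance (providers repeat
  # across months), so bound by the provider-level standard error
  rate_var <- 4^2 / 0.5
  se <- sqrt((rate_var + 4) / 300)
  expect_lt(abs(xbar - 4), 3 * se)
  # rates attribute carries the ground truth
  expect_length(attr(mat, "rates"), 300)
})

test_that("generated events round-trip through monthly aggregation", {
  for (seed in c(1, 12, 123)) {
    syn <- synthetic_config(n_providers = 25, n_units = 6,
                            months = month_seq("2020-11", "2021-02"), seed = seed)
    mat <- generate_caseloads(syn)
    ev <- generate_registry_events(mat, syn)
    expect_equal(nrow(ev), sum(mat))
    w <- study_window("2020-11-01", "2021-02-28")
    back <- monthly_caseloads(ev, colnames(mat), w, "provider")
    expect_identical(unclass(mat)[, ], unclass(back)[, ])
  }
})

test_that("unit affiliations respect multi_unit_prob and the cap", {
  syn0 <- synthetic_config(n_providers = 40, n_units = 10,
                           months = month_seq("2019-01", "2019-02"),
                           multi_unit_prob = 0, seed = 5)
  ev0 <- generate_registry_events(generate_caseloads(syn0), syn0)
  per <- tapply(ev0$unit_id, ev0$provider_id, function(u) length(unique(u)))
  expect_true(all(per == 1))

  syn1 <- synthetic_config(n_providers = 200, n_units = 50,
                           months = month_seq("2019-01", "2019-02"),
                           multi_unit_prob = 1, seed = 5)
  ev1 <- generate_registry_events(generate_caseloads(syn1), syn1)
  affil <- attr(ev1, "provider_units")
  expect_true(all(lengths(affil) >= 2))
  expect_true(all(lengths(affil) <= 7))
})

test_that("the Pareto-tail population is deterministic and ordered by alpha", {
  a <- log(5) / log(4)
  v1 <- make_pareto_tail_population(10000, a)
  v2 <- make_pareto_tail_population(10000, a)
  expect_identical(v1, v2)
  expect_error(make_pareto_tail_population(10000, 1), "exceed 1")

  # heavier tail (smaller alpha) concentrates more volume in the top 20%
  top_share <- function(v) {
    s <- sort(v, decreasing = TRUE)
    sum(s[1:(length(s) / 5)]) / sum(s)
  }
  expect_lt(top_share(make_pareto_tail_population(10000, 3)),
            top_share(make_pareto_tail_population(10000, a)))
})

test_that("finite-N Pareto-tail fractions match a direct-sum oracle", {
  # independent oracle: plain sort/cumsum, no interpolation machinery
  a <- log(5) / log(4)
  frac <- vapply(c(1e4, 1e5), function(N) {
    v <- make_pareto_tail_population(N, a)
    pareto_fraction(build_concentration_curve(v), 0.8)$fraction_q
  }, numeric(1))
  oracle <- vapply(c(1e4, 1e5), function(N) {
    s <- sort(make_pareto_tail_population(N, a), decreasing = TRUE)
    min(which(cumsum(s) >= 0.8 * sum(s))) / N
  }, numeric(1))
  expect_equal(frac, oracle, tolerance = 1e-3)
  # the fraction approaches the infinite-population 0.20 from above
  expect_lt(frac[2], frac[1])
  expect_gt(frac[2], 0.20)
})

test_that("zeta-model caseloads follow the generative power law where counts inform", {
  syn <- synthetic_config(n_providers = 10000, n_units = 10,
                          months = "2019-01",
                          rate_model = "zeta_power",
                          rate_params = list(s = 2.5), seed = 10)
  mat <- generate_caseloads(syn)
  ft <- build_frequency_table(mat, "2019-01")
  pts <- loglog_points(ft)
  # restrict to bins whose expected occupancy is >= 5; sparser tail bins
  # carry the usual log-log histogram noise
  x_max <- (10000 / (5 * 1.3415)) ^ (1 / 2.5)  # zeta(2.5) ~ 1.3415
  keep <- exp(pts$log_x) <= x_max
  fit <- stats::lm(log_y ~ log_x, data = pts[keep, ])
  expect_gt(summary(fit)$r.squared, 0.98)
  expect_equal(unname(stats::coef(fit)[2]), -2.5, tolerance = 0.15)
})

test_that("apply_shock thins only shock months by the band multipliers", {
  syn <- synthetic_config(n_providers = 100, n_units = 10,
                          months = month_seq("2019-01", "2019-04"), seed = 9)
  mat <- generate_caseloads(syn)
  asg <- assign_bands(colSums(mat))
  top <- max(asg$band)
  sm <- c("2019-03", "2019-04")

  # identity multiplier leaves everything unchanged
  all_one <- shock_spec(sm, stats::setNames(rep(1, top), 1:top))
  expect_identical(apply_shock(mat, asg, all_one, 1)[, ], mat[, ])

  # zero multiplier removes the top band's shock-month operations
  zero_top <- apply_shock(mat, asg, shock_spec(sm, stats::setNames(0, top)), 1)
  top_ids <- asg$entity_id[asg$band == top]
  expect_true(all(zero_top[sm, top_ids] == 0))
  # non-shock months untouched
  expect_identical(zero_top[c("2019-01", "2019-02"), ],
                   mat[c("2019-01", "2019-02"), ])

  # thinning is binomial: total within 3 SE of multiplier * total
  pre_total <- sum(mat[sm, top_ids])
  thinned <- apply_shock(mat, asg, shock_spec(sm, stats::setNames(0.3, top)), 2)
  post_total <- sum(thinned[sm, top_ids])
  se <- sqrt(pre_total * 0.3 * 0.7)
  expect_lt(abs(post_total - 0.3 * pre_total), 3 * se)
})

test_that("entities missing from the assignment default to band 1 with notice", {
  syn <- synthetic_config(n_providers = 10, n_units = 2,
                          months = month_seq("2019-01", "2019-02"), seed = 3)
  mat <- generate_caseloads(syn)
  asg <- assign_bands(colSums(mat))
  asg <- asg[asg$entity_id != colnames(mat)[1], ]
  class(asg) <- c("band_assignment", class(asg))
  shocked <- apply_shock(mat, asg, shock_spec("2019-02", c("1" = 0.5)), 4)
  expect_match(attr(shocked, "shock_notices"), "defaulted to band 1")
})
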