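days_all <- seq(0, 63, by = 3)

test_that("extinction transfers follow the back-fill definition", {
  exp <- pattern_experiment(list(
    gone_at_4 = seq(3, 9, by = 3),          # transfers 1-3, absent 4 on
    gap_bridged = c(seq(3, 12, by = 3), 21), # absent 5-6, seen at 7, gone 8 on
    day0_only = 0,                           # initial-adjustment loss
    survivor = days_all), days = days_all)
  rec <- extinction_times(exp)
  rec <- setNames(split(rec, rec$asv_id), sort(unique(rec$asv_id)))
  expect_equal(rec$gone_at_4$extinction_transfer, 3L)
  expect_equal(rec$gap_bridged$extinction_transfer, 7L)
  expect_true(rec$survivor$censored)
  expect_true(rec$.anchor$censored)
  expect_false("day0_only" %in% names(rec))
})

test_that("a missing baseline transfer is an error", {
  exp <- pattern_experiment(list(a = c(0, 6, 9)), days = c(0, 6, 9))
  expect_error(extinction_times(exp, baseline_transfer = 1),
               "baseline transfer 1 not sampled")
  rec <- extinction_times(exp, baseline_transfer = 2)
  expect_true(all(c("a", ".anchor") %in% rec$asv_id))
})

test_that("geometric pmf matches its closed form and normalizes", {
  expect_equal(geometric_pmf(0.5, 1), 0.5)
  expect_equal(geometric_pmf(0.5, 3), 0.125)
  expect_lt(abs(sum(geometric_pmf(0.3, 1:200)) - 1), 1e-12)
  expect_error(geometric_pmf(0.3, 0), "t must be")
  expect_error(geometric_pmf(1.2, 1), "p must be")
})

test_that("the geometric MLE is the inverse mean extinction time", {
  fit <- fit_geometric(c(2, 2, 2))
  expect_equal(fit$p_hat, 0.5)
  fit1 <- fit_geometric(c(1, 1, 1, 1))
  expect_equal(fit1$p_hat, 1)
  expect_equal(fit1$log_likelihood, 0)
  expect_error(fit_geometric(integer(0)), "no extinction times")
  expect_error(fit_geometric(c(2, NA)), "uncensored")

  # scale consistency: duplicating observations leaves p_hat unchanged
  t <- c(1, 2, 2, 5, 9)
  expect_equal(fit_geometric(rep(t, 2))$p_hat, fit_geometric(t)$p_hat)

  # Monte Carlo recovery within 3 delta-method standard errors
  t <- simulate_extinction_times(10000, 0.3, seed = 31)
  se <- 0.3^2 * sqrt((1 - 0.3) / 0.3^2 / 10000)
  expect_lt(abs(fit_geometric(t)$p_hat - 0.3), 3 * se)
})

test_that("tidy and glance summarize geometric fits", {
  fit <- fit_geometric(c(2, 4, 6))
  expect_equal(tidy(fit)$estimate, 0.25)
  expect_equal(glance(fit)$nobs, 3)
})

test_that("goodness of fit pools the tail and matches hand construction", {
  # constructed counts equal to n P(t) at p = 0.5: 10, 5, and 5 in the tail
  times <- c(rep(1L, 10), rep(2L, 5), rep(3L, 5))
  g <- geometric_gof(times, p = 0.5)
  expect_equal(g$chi2, 0)
  expect_equal(g$n_bins, 3)
  expect_equal(g$df, 1)
  expect_equal(g$p_value, 1)

  # all-ones data against a tiny p is overwhelmingly rejected
  g2 <- geometric_gof(rep(1L, 50), p = 0.01)
  expect_lt(g2$p_value, 1e-6)

  # calibration: simulated geometric data is rarely rejected
  rejected <- vapply(1:100, function(s) {
    t <- simulate_extinction_times(500, 0.3, seed = 1000 + s)
    geometric_gof(t, fit_geometric(t)$p_hat)$p_value <= 0.05
  }, logical(1))
  expect_gte(sum(!rejected), 90)
})

test_that("equal group means make the BIC comparison penalty-only", {
  groups <- list(g1 = c(1, 3), g2 = c(2, 2))
  cmpn <- compare_extinction_models(groups)
  expect_equal(cmpn$log_likelihood_common, cmpn$log_likelihood_individual)
  expect_equal(cmpn$preferred, "common")
  # B_k - B_1 = ln(n)(k - 1) with n = 2 groups
  expect_equal(cmpn$bic_individual - cmpn$bic_common, log(2) * (2 - 1))
  expect_equal(cmpn$relative_likelihood, exp(log(2) / 2))
})

test_that("nesting holds and records interface works", {
  sim <- generate_experiment(small_config(rng_seed = 23))
  rec <- extinction_times(sim$experiment)
  cmpn <- compare_extinction_models(rec)
  expect_gte(cmpn$log_likelihood_individual,
             cmpn$log_likelihood_common - 1e-9)
  expect_equal(sum(cmpn$per_group_fits$n_obs), cmpn$common_fit$n_obs)
  expect_error(compare_extinction_models(list(g1 = c(1, 2))), "2 groups")
  expect_error(compare_extinction_models(list(g1 = c(1), g2 = numeric(0))),
               "at least one extinction")
})

test_that("clearly different group rates favor the individual model", {
  wins <- vapply(1:20, function(s) {
    g <- list(a = simulate_extinction_times(200, 0.1, seed = 2000 + s),
              b = simulate_extinction_times(200, 0.8, seed = 3000 + s))
    compare_extinction_models(g)$preferred == "individual"
  }, logical(1))
  expect_true(all(wins))
})

test_that("the events BIC convention penalizes complexity more strongly", {
  groups <- list(g1 = c(1, 2, 3, 4, 2), g2 = c(2, 3, 1, 2, 2))
  a <- compare_extinction_models(groups, n_convention = "microcosms")
  b <- compare_extinction_models(groups, n_convention = "events")
  expect_equal(a$n_bic, 2)
  expect_equal(b$n_bic, 10)
  expect_gt(b$bic_individual - b$bic_common, a$bic_individual - a$bic_common)
})

test_that("expected relative richness decays from 1 to s", {
  expect_equal(expected_relative_richness(0, 0.3, 0.7), 1)
  expect_equal(expected_relative_richness(500, 0.3, 0.7), 0.3,
               tolerance = 1e-12)
  expect_equal(expected_relative_richness(1, 0.5, 0.5), 0.75)
  expect_error(expected_relative_richness(-1, 0.5, 0.5), "t must be")
})

test_that("the decay model is estimated from censoring and pooled times", {
  rec <- tibble::tibble(
    asv_id = sprintf("a%03d", 1:100), microcosm_id = "M01",
    treatment = "filtered",
    extinction_transfer = c(rep(NA_integer_, 50), rep(2L, 50)),
    censored = rep(c(TRUE, FALSE), each = 50))
  m <- estimate_decay_model(rec)
  expect_equal(m$survival_fraction, 0.5)
  expect_equal(m$extinction_rate, 0.5)
  all_cens <- rec[rec$censored, ]
  expect_error(estimate_decay_model(all_cens), "all records censored")
})

test_that("decay parameters are recovered from generator defaults", {
  sim <- generate_experiment(synthetic_config(rng_seed = 29))
  rec <- extinction_times(sim$experiment)
  m <- estimate_decay_model(rec)
  expect_lt(abs(m$survival_fraction - 0.5), 0.05)
  expect_lt(abs(m$extinction_rate - 0.3), 0.05)

  # mean backfilled relative richness tracks the expected decay curve
  rr <- relative_richness(sim$experiment)
  obs <- tapply(rr$rel_richness, rr$transfer - 1, mean)
  t <- as.integer(names(obs))
  expected <- expected_relative_richness(t, 0.5, 0.3)
  expect_lt(max(abs(obs - expected)), 0.08)
})
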