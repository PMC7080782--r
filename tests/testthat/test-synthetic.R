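test_that("generation is deterministic given the seed", {
  a <- generate_experiment(small_config(rng_seed = 5))
  b <- generate_experiment(small_config(rng_seed = 5))
  expect_equal(as.data.frame(a$experiment), as.data.frame(b$experiment))
  expect_equal(a$function_profiles, b$function_profiles)
  expect_equal(as.data.frame(a$ground_truth), as.data.frame(b$ground_truth))
  c <- generate_experiment(small_config(rng_seed = 6))
  expect_false(identical(a$experiment$count, c$experiment$count))
})

test_that("survival_fraction = 1 yields no extinctions after transfer 1", {
  sim <- generate_experiment(small_config(survival_fraction = 1,
                                          rng_seed = 2))
  rec <- extinction_times(sim$experiment)
  expect_true(all(rec$censored))
  expect_true(all(sim$ground_truth$fate == "survivor"))
})

test_that("infeasible configurations are refused", {
  expect_error(synthetic_config(pool_size = 10,
                                initial_richness_range = c(20, 30)),
               "config error")
  expect_error(synthetic_config(extinction_rate = 0), "config error")
  expect_error(synthetic_config(context_correlation = 0.9,
                                replicate_correlation = 0.5),
               "config error")
})

test_that("truncated geometric draws have the right support and mean", {
  expect_equal(simulate_extinction_times(50, p = 1, seed = 1),
               rep(1L, 50))
  capped <- simulate_extinction_times(2000, p = 0.3, cap = 5, seed = 2)
  expect_true(all(capped >= 1 & capped <= 5))
  t <- simulate_extinction_times(10000, p = 0.3, cap = Inf, seed = 3)
  se <- sqrt((1 - 0.3) / 0.3^2 / 10000)
  expect_lt(abs(mean(t) - 1 / 0.3), 3 * se)
})

test_that("ground-truth extinction transfers follow the configured geometric",
{
  sim <- generate_experiment(synthetic_config(rng_seed = 17))
  t <- sim$ground_truth$extinction_transfer
  t <- t[!is.na(t)]
  expect_true(all(t >= 1 & t <= 20))
  fit <- fit_geometric(t)
  gof <- geometric_gof(t, fit$p_hat)
  expect_gt(gof$p_value, 0.01)
  expect_lt(abs(fit$p_hat - 0.3), 0.05)
})

test_that("replicate latent series are identical at full innovation sharing",
{
  cfg <- small_config(replicate_correlation = 1, context_correlation = 0.2,
                      rng_seed = 4)
  membership <- tibble::tibble(asv_id = sprintf("a%02d", 1:10),
                               inoculum_id = "M01")
  fates <- tibble::tibble(asv_id = rep(membership$asv_id, 2),
                          inoculum_id = "M01",
                          treatment = rep(c("filtered", "unfiltered"),
                                          each = 10),
                          fate = "survivor",
                          extinction_transfer = NA_integer_)
  tr <- simulate_survivor_trajectories(cfg, membership, fates, seed = 9)
  expect_equal(tr[["M01|filtered"]], tr[["M01|unfiltered"]])
})

test_that("full reversion with zero noise pins the walk at its mean", {
  cfg <- small_config(walk_reversion = 1, walk_noise = 0, rng_seed = 4)
  membership <- tibble::tibble(asv_id = c("a1", "a2"), inoculum_id = "M01")
  fates <- tibble::tibble(asv_id = c("a1", "a2"), inoculum_id = "M01",
                          treatment = "filtered", fate = "survivor",
                          extinction_transfer = NA_integer_)
  tr <- simulate_survivor_trajectories(cfg, membership, fates, seed = 10)
  L <- tr[["M01|filtered"]]
  for (a in rownames(L)) {
    expect_equal(unname(L[a, -1]), rep(L[a, "1"], cfg$n_transfers))
  }
})

test_that("zero context correlation gives uncorrelated cross-inoculum innovations", {
  cfg <- synthetic_config(n_inocula = 2, pool_size = 200,
                          initial_richness_range = c(200L, 200L),
                          paired_treatments = FALSE, n_transfers = 21,
                          context_correlation = 0, replicate_correlation = 0,
                          walk_reversion = 0, walk_noise = 1, rng_seed = 8)
  asvs <- sprintf("a%03d", 1:200)
  membership <- tibble::tibble(asv_id = rep(asvs, 2),
                               inoculum_id = rep(c("M01", "M02"), each = 200))
  fates <- membership
  fates$treatment <- "filtered"
  fates$fate <- "survivor"
  fates$extinction_transfer <- NA_integer_
  tr <- simulate_survivor_trajectories(cfg, membership, fates, seed = 12)
  innov <- function(L) t(diff(t(L)))  # theta = 0: innovations are the steps
  i1 <- innov(tr[["M01|filtered"]]); i2 <- innov(tr[["M02|filtered"]])
  rs <- vapply(asvs, function(a) cor(i1[a, ], i2[a, ]), numeric(1))
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("read sampling is multinomial with detection at one read", {
  one <- matrix(c(0.3, 0.7), 1)
  expect_equal(sample_reads(one, depth = 0, seed = 1)[1, ], c(0L, 0L))
  single <- matrix(1, 1)
  expect_equal(sample_reads(single, depth = 500, seed = 1)[1, 1], 500L)
  expect_error(sample_reads(matrix(c(0.3, 0.3), 1), 10), "sum to 1")

  # detection probability of rel = 1e-5 at depth 5e4 ~ 1 - exp(-0.5)
  reps <- 2000
  rel <- matrix(rep(c(1e-5, 1 - 1e-5), each = reps), ncol = 2)
  counts <- sample_reads(rel, depth = 5e4, seed = 13)
  p_detect <- mean(counts[, 1] >= 1)
  expect_lt(abs(p_detect - (1 - exp(-0.5))), 0.04)
})

test_that("function profiles are exact ASV mixtures at zero noise", {
  cfg <- small_config(function_noise = 0, rng_seed = 3)
  df <- tibble::tibble(microcosm_id = "M01", treatment = "filtered",
                       day = c(0L, 3L), asv_id = "solo", count = 100)
  exp <- as_experiment(df)
  fd <- generate_function_data(cfg, exp, seed = 21)
  U <- matrix(runif(cfg$n_substrates), 1,
              dimnames = list("solo", sprintf("substrate_%02d",
                                              1:cfg$n_substrates)))
  fd2 <- generate_function_data(cfg, exp, truth = structure(
    tibble::tibble(), substrate_use = U, class = "synthetic_truth"),
    seed = 21)
  prof <- as.matrix(fd2$function_profiles[, -(1:2)])
  expect_equal(prof[1, ], U[1, ])
  expect_equal(prof[1, ], prof[2, ]) # identical composition, zero noise
  expect_equal(bray_curtis(prof[1, ], prof[2, ]), 0)
  expect_true(all(as.matrix(fd$function_profiles[, -(1:2)]) >= 0))
})

test_that("Day 0 carries transients and CO2 variance is inflated at Day 0", {
  sim <- generate_experiment(small_config(rng_seed = 7))
  exp <- sim$experiment
  day0 <- unique(exp$asv_id[exp$day == 0 & exp$microcosm_id == "M01" &
                              exp$treatment == "filtered"])
  later <- unique(exp$asv_id[exp$day > 0 & exp$microcosm_id == "M01" &
                               exp$treatment == "filtered"])
  expect_gt(length(setdiff(day0, later)), 0)
  v <- co2_variance_series(sim$co2)
  expect_gt(v$variance[v$day == 0], mean(v$variance[v$day > 0]))
})

test_that("synthetic artifacts round-trip through the on-disk formats", {
  dir <- withr::local_tempdir()
  sim <- generate_experiment(small_config(rng_seed = 19))
  write_synthetic_experiment(sim, dir)
  back <- read_abundance_long(file.path(dir, "abundance.tsv"),
                              n_transfers = 10)
  expect_equal(back$count, sim$experiment$count)
  fp <- read_function_profiles(file.path(dir, "function_profiles.csv"))
  expect_equal(nrow(fp), nrow(sim$function_profiles))
  expect_equal(read_co2_table(file.path(dir, "co2.csv"))$percent_co2,
               sim$co2$percent_co2)
})
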