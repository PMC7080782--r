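test_that("CLR rows are centered and follow the pseudo-read rule", {
  df <- tibble::tribble(
    ~microcosm_id, ~treatment, ~day, ~asv_id, ~count,
    "M01", "filtered", 0L, "a", 4,
    "M01", "filtered", 0L, "b", 4,
    "M01", "filtered", 3L, "a", 9,
    "M01", "filtered", 3L, "b", 3)
  clr <- clr_transform(as_experiment(df))
  d0 <- clr$clr[clr$day == 0]
  expect_equal(d0, c(0, 0)) # equal counts -> all zero
  expect_equal(sum(clr$clr[clr$day == 3]), 0, tolerance = 1e-9)
  # a zero count becomes ln(1) - mean of logs
  d3 <- clr[clr$day == 3, ]
  expect_equal(d3$clr[d3$asv_id == "a"], log(10) - mean(log(c(10, 4))))
})

test_that("CLR matches the brute-force oracle and its exact invariance", {
  set.seed(51)
  for (i in 1:10) {
    counts <- matrix(rpois(12, 20), 3, 4,
                     dimnames = list(NULL, paste0("a", 1:4)))
    df <- tibble::tibble(
      microcosm_id = "M01", treatment = "filtered",
      day = rep(c(0L, 3L, 6L), 4),
      asv_id = rep(paste0("a", 1:4), each = 3),
      count = as.vector(counts))
    df <- df[df$count > 0, ]
    clr <- clr_transform(as_experiment(df))
    # oracle: per timepoint, log(count + 1) centered over retained ASVs
    wide <- matrix(0, 3, 4, dimnames = list(NULL, paste0("a", 1:4)))
    wide[cbind(match(df$day, c(0, 3, 6)), match(df$asv_id, colnames(wide)))] <-
      df$count
    retained <- colSums(wide) > 0
    lg <- log(wide[, retained, drop = FALSE] + 1)
    oracle <- lg - rowMeans(lg)
    got <- matrix(clr$clr, 3, sum(retained),
                  dimnames = list(NULL, sort(colnames(wide)[retained])))
    expect_equal(got[, colnames(oracle)], oracle, tolerance = 1e-9,
                 ignore_attr = TRUE)
    # exact scale invariance of the pre-pseudo-read form
    pre <- log(wide[, retained, drop = FALSE] + 1e-12)
    pre_scaled <- log(3 * wide[, retained, drop = FALSE] + 3e-12)
    expect_equal(pre - rowMeans(pre), pre_scaled - rowMeans(pre_scaled),
                 tolerance = 1e-9)
  }
})

test_that("identical and mirrored trajectories give r = 1 and r = -1", {
  rising <- c(2, 4, 9, 20, 41)
  falling <- rev(rising)
  mk <- function(m) tibble::tibble(
    microcosm_id = m, treatment = "filtered",
    day = rep(seq(0, 12, by = 3), 2),
    asv_id = rep(c("up", "down"), each = 5),
    count = c(rising, falling))
  mirrored <- tibble::tibble(
    microcosm_id = "M03", treatment = "filtered",
    day = rep(seq(0, 12, by = 3), 2),
    asv_id = rep(c("up", "down"), each = 5),
    count = c(falling, rising)) # swapped: CLR is exactly negated
  exp <- as_experiment(dplyr::bind_rows(mk("M01"), mk("M02"), mirrored))
  tc <- trajectory_correlations(exp, seed = 1)
  same <- tc[tc$category != "random_pair" &
               tc$microcosm_a == "M01" & tc$microcosm_b == "M02", ]
  expect_equal(same$pearson_r, c(1, 1))
  neg <- tc[tc$category != "random_pair" & tc$microcosm_b == "M03" &
              tc$microcosm_a == "M01", ]
  expect_equal(neg$pearson_r, c(-1, -1))
})

test_that("replicate pairs are labelled by shared inoculum", {
  sim <- generate_experiment(small_config(rng_seed = 53))
  tc <- trajectory_correlations(sim$experiment, seed = 2)
  reps <- tc[tc$category == "same_inoculum", ]
  expect_true(all(reps$microcosm_a == reps$microcosm_b))
  expect_true(all(reps$treatment_a != reps$treatment_b))
  rnd <- tc[tc$category == "random_pair", ]
  expect_equal(nrow(rnd), sum(tc$category != "random_pair"))
  expect_true(all(rnd$asv_id != rnd$asv_id_b))
  # reproducible under the seed
  tc2 <- trajectory_correlations(sim$experiment, seed = 2)
  expect_equal(as.data.frame(tc), as.data.frame(tc2))
})

test_that("distribution summaries report mean and KDE mode", {
  s <- distribution_summary(rep(0.5, 10))
  expect_equal(s$mean, 0.5)
  expect_lt(abs(s$mode - 0.5), 0.01)
  expect_error(distribution_summary(c(0.1, 0.2)), "at least 5")

  set.seed(55)
  bimodal <- c(rnorm(500, -0.8, 0.05), rnorm(500, 0.8, 0.05))
  s <- distribution_summary(bimodal)
  expect_lt(abs(abs(s$mode) - 0.8), 0.1)
  expect_lt(abs(s$mean), 0.1)

  # the truncated-normal density is nearly flat at its peak, so the mode
  # estimate is noisy per replicate; its Monte Carlo average centers on 0
  modes <- vapply(1:20, function(i) {
    z <- rnorm(1e4); z <- z[abs(z) <= 1]
    distribution_summary(z)$mode
  }, numeric(1))
  expect_lt(abs(mean(modes)), 0.05)
})

test_that("cosine similarity is scale-invariant with zero-overlap zeroes", {
  x <- c(0.2, 0.5, 0.1)
  expect_equal(cosine_similarity(x, 2 * x), 1)
  expect_equal(cosine_similarity(c(1, 0, 2), c(0, 3, 0)), 0)
  expect_equal(cosine_similarity(c(1, 1), c(1, 0)), 1 / sqrt(2))
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
  set.seed(56)
  for (i in 1:20) {
    a <- runif(5); b <- runif(5)
    expect_gte(cosine_similarity(a, b), 0)
    expect_lte(cosine_similarity(a, b), 1 + 1e-12)
  }
})

test_that("duplicated communities sit at the coupling origin", {
  base <- tibble::tibble(
    microcosm_id = "M01", treatment = "filtered",
    day = rep(seq(0, 30, by = 3), each = 2),
    asv_id = rep(c("a", "b"), 11),
    count = rep(c(6, 4), 11))
  twin <- dplyr::mutate(base, microcosm_id = "M02")
  third <- dplyr::mutate(base, microcosm_id = "M03")
  cp <- composition_trajectory_coupling(
    as_experiment(dplyr::bind_rows(base, twin, third)),
    equilibration_day = 21)
  expect_equal(cp$points$mean_bray_curtis_final, rep(0, 3))
  expect_equal(cp$points$mean_cosine_distance, rep(0, 3))
})

test_that("synthetic coupling yields a positive no-intercept fit", {
  sim <- generate_experiment(synthetic_config(rng_seed = 57))
  cp <- composition_trajectory_coupling(sim$experiment)
  expect_gt(cp$beta, 0)
  expect_gt(cp$r_squared, 0.3)
  expect_true(all(cp$points$mean_bray_curtis_final >= 0 &
                    cp$points$mean_bray_curtis_final <= 1))
  expect_true(all(cp$points$mean_cosine_distance >= 0 &
                    cp$points$mean_cosine_distance <= 1 + 1e-9))
})

test_that("fates classify censoring as survival with occupancy counts", {
  days_all <- seq(0, 63, by = 3)
  exp1 <- pattern_experiment(list(doomed = seq(3, 15, by = 3),
                                  lives = days_all), days = days_all,
                             microcosm = "M01")
  exp2 <- pattern_experiment(list(lives = days_all), days = days_all,
                             microcosm = "M02")
  exp <- as_experiment(dplyr::bind_rows(tibble::as_tibble(exp1),
                                        tibble::as_tibble(exp2)))
  fates <- classify_fates(exp)
  expect_equal(fates$fate[fates$asv_id == "doomed"], "extinct")
  expect_equal(unique(fates$fate[fates$asv_id == "lives"]),
               "survivor")
  expect_equal(unique(fates$occupancy[fates$asv_id == "lives"]), 2L)
  expect_equal(fates$occupancy[fates$asv_id == "doomed"], 1L)
})

test_that("shared fate null follows f^(n-1)", {
  expect_equal(shared_fate_null(1), 1)
  expect_equal(shared_fate_null(2), 0.5)
  expect_equal(shared_fate_null(3), 0.25)
  expect_equal(shared_fate_null(4, f = 0.8), 0.8^3)
  expect_error(shared_fate_null(0), "n must be")
  n <- 1:10
  expect_true(all(diff(shared_fate_null(n, 0.7)) < 0))
})

test_that("i.i.d. coin fates match the shared-fate null", {
  set.seed(58)
  n_asv <- 2000
  fates <- tibble::tibble(
    asv_id = rep(sprintf("a%04d", 1:n_asv), each = 3),
    microcosm_id = rep(c("M01", "M02", "M03"), n_asv),
    treatment = "filtered",
    fate = sample(c("survivor", "extinct"), 3 * n_asv, replace = TRUE),
    occupancy = 3L)
  res <- shared_fate_test(fates)
  expect_equal(res$null_probability, 0.25)
  expect_lt(abs(res$observed_fraction - 0.25), 0.03)
  expect_gt(res$p_value, 0.001)

  all_same <- dplyr::mutate(fates, fate = "survivor")
  res2 <- shared_fate_test(all_same)
  expect_equal(res2$observed_fraction, 1)
  expect_lt(res2$p_value, 1e-100)
})

test_that("replicate fate agreement beats the null at occupancy 2", {
  sim <- generate_experiment(synthetic_config(rng_seed = 59))
  fates <- classify_fates(sim$experiment)
  res <- shared_fate_test(fates)
  at2 <- res[res$n == 2, ]
  expect_gt(at2$observed_fraction, at2$null_probability)
})
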