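#' Centered log-ratio transform of per-series counts
#'
#' Within each series, ASVs never observed in that series are dropped, one
#' pseudo-read is added to every retained (timepoint, ASV) count to handle
#' abundances below the detection threshold, and each timepoint's log counts
#' are centered by their mean: `clr = ln(count + 1) - mean(ln(count + 1))`
#' over the retained ASVs. Rows therefore sum to zero and the transform is
#' invariant to per-timepoint scaling of the (pre-pseudo-read) counts.
#'
#' @param exp a `transfer_experiment`.
#' @return tibble with `microcosm_id`, `inoculum_id`, `treatment`, `day`,
#'   `asv_id`, `clr`.
#' @export
clr_transform <- function(exp) {
  mats <- series_matrices(exp, value = "count")
  purrr::map_dfr(mats, function(s) {
    lg <- log(s$mat + 1)
    clr <- lg - rowMeans(lg)
    tibble(microcosm_id = s$microcosm_id, inoculum_id = s$inoculum_id,
           treatment = s$treatment,
           day = rep(s$days, times = ncol(clr)),
           asv_id = rep(colnames(clr), each = nrow(clr)),
           clr = as.vector(clr))
  })
}

# column variances and paired column-wise Pearson correlations
matrixStats_colVars <- function(m) {
  n <- nrow(m)
  (colSums(m^2) - colSums(m)^2 / n) / (n - 1)
}

colwise_cor <- function(x, y) {
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y, 2, colMeans(y))
  unname(colSums(xc * yc) / sqrt(colSums(xc^2) * colSums(yc^2)))
}

# per-series CLR matrices restricted to a day window
clr_matrices <- function(exp, window = NULL) {
  mats <- series_matrices(exp, value = "count")
  lapply(mats, function(s) {
    keep <- if (is.null(window)) rep(TRUE, length(s$days)) else
      s$days >= window[1] & s$days <= window[2]
    lg <- log(s$mat[keep, , drop = FALSE] + 1)
    s$mat <- lg - rowMeans(lg)
    s$days <- s$days[keep]
    s
  })
}

#' Cross-microcosm trajectory correlations of shared ASVs
#'
#' For every pair of series and every ASV present in both, the Pearson
#' correlation of the two CLR-transformed time series over the shared days
#' in `window`. Pairs of series founded from the same inoculum (replicate
#' filtered/unfiltered pairs) are labelled `same_inoculum`; pairs from
#' different inocula `different_inoculum`. A seeded `random_pair` null —
#' distinct ASVs in different series, count-matched to the same-ASV set —
#' calibrates the density. Series with CLR variance below `min_var` over the
#' window are skipped (Pearson undefined), not recorded as zero.
#'
#' @param exp a `transfer_experiment`.
#' @param window day range `c(from, to)` or `NULL` for all days.
#' @param min_var minimum CLR variance for a series to enter a correlation.
#' @param seed integer seed for the random-pair null.
#' @return tibble of class `trajectory_correlations` with `asv_id`,
#'   `asv_id_b` (differs from `asv_id` only for random pairs),
#'   `microcosm_a`, `treatment_a`, `microcosm_b`, `treatment_b`, `category`,
#'   `pearson_r`, `n_timepoints`.
#' @export
trajectory_correlations <- function(exp, window = NULL, min_var = 1e-10,
                                    seed = 1L) {
  cm <- clr_matrices(exp, window)
  if (any(vapply(cm, function(s) length(s$days), numeric(1)) == 0)) {
    abort("window contains no sampled days for at least one series")
  }
  ns <- length(cm)
  res <- list()
  for (i in seq_len(ns - 1)) {
    for (j in (i + 1):ns) {
      a <- cm[[i]]; b <- cm[[j]]
      if (a$microcosm_id == b$microcosm_id && a$treatment == b$treatment) next
      shared_days <- intersect(a$days, b$days)
      if (length(shared_days) < 3) next
      ia <- match(shared_days, a$days); ib <- match(shared_days, b$days)
      category <- if (a$inoculum_id == b$inoculum_id) "same_inoculum" else
        "different_inoculum"
      shared_asvs <- intersect(colnames(a$mat), colnames(b$mat))
      if (length(shared_asvs) == 0) next
      Xa <- a$mat[ia, shared_asvs, drop = FALSE]
      Xb <- b$mat[ib, shared_asvs, drop = FALSE]
      ok <- matrixStats_colVars(Xa) >= min_var &
        matrixStats_colVars(Xb) >= min_var
      if (!any(ok)) next
      res[[length(res) + 1]] <- tibble(
        asv_id = shared_asvs[ok], asv_id_b = shared_asvs[ok],
        microcosm_a = a$microcosm_id, treatment_a = a$treatment,
        microcosm_b = b$microcosm_id, treatment_b = b$treatment,
        category = category,
        pearson_r = colwise_cor(Xa[, ok, drop = FALSE],
                                Xb[, ok, drop = FALSE]),
        n_timepoints = length(shared_days))
    }
  }
  out <- bind_rows(res)
  n_target <- nrow(out)
  rnd <- with_seed(seed, {
    asv_a <- asv_b <- ma <- ta <- mb <- tb <- character(n_target)
    r <- numeric(n_target); nt <- integer(n_target)
    got <- 0L; attempts <- 0L
    while (got < n_target && attempts < 50L * (n_target + 1L)) {
      attempts <- attempts + 1L
      ij <- sample.int(ns, 2)
      a <- cm[[ij[1]]]; b <- cm[[ij[2]]]
      if (a$microcosm_id == b$microcosm_id && a$treatment == b$treatment) next
      shared_days <- intersect(a$days, b$days)
      if (length(shared_days) < 3) next
      aa <- sample(colnames(a$mat), 1)
      ab <- sample(colnames(b$mat), 1)
      if (aa == ab) next
      xa <- a$mat[match(shared_days, a$days), aa]
      xb <- b$mat[match(shared_days, b$days), ab]
      if (var(xa) < min_var || var(xb) < min_var) next
      got <- got + 1L
      asv_a[got] <- aa; asv_b[got] <- ab
      ma[got] <- a$microcosm_id; ta[got] <- a$treatment
      mb[got] <- b$microcosm_id; tb[got] <- b$treatment
      r[got] <- cor(xa, xb); nt[got] <- length(shared_days)
    }
    idx <- seq_len(got)
    tibble(asv_id = asv_a[idx], asv_id_b = asv_b[idx],
           microcosm_a = ma[idx], treatment_a = ta[idx],
           microcosm_b = mb[idx], treatment_b = tb[idx],
           category = "random_pair", pearson_r = r[idx],
           n_timepoints = nt[idx])
  })
  out <- bind_rows(out, rnd)
  class(out) <- c("trajectory_correlations", class(out))
  out
}

#' Mean and density mode of a correlation distribution
#'
#' The mode is the argmax of a Gaussian kernel density (Silverman's
#' bandwidth) evaluated on a 512-point grid over \[-1, 1\].
#'
#' @param rs numeric vector (at least 5 values).
#' @return tibble with `mean`, `mode`, `n`.
#' @export
distribution_summary <- function(rs) {
  if (length(rs) < 5) abort("need at least 5 values")
  d <- density(rs, bw = "nrd0", n = 512, from = -1, to = 1)
  tibble(mean = mean(rs), mode = d$x[which.max(d$y)], n = length(rs))
}

#' Cosine similarity between two trajectories
#'
#' `sum(x y) / (|x| |y|)`: scale-invariant, and timepoints where an ASV is
#' absent in one series contribute zero to the inner product, so no explicit
#' timepoint filtering is needed.
#'
#' @param x,y numeric vectors of equal length, each with at least one
#'   nonzero entry.
#' @return cosine similarity (in \[0, 1\] for non-negative input).
#' @export
cosine_similarity <- function(x, y) {
  if (length(x) != length(y)) abort("vectors must have equal length")
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) abort("zero vector has no direction")
  sum(x * y) / (nx * ny)
}

#' Couple compositional divergence to trajectory divergence
#'
#' For each pair of series: (i) the Bray-Curtis dissimilarity between their
#' final compositions (mean relative-abundance vectors over days past
#' `equilibration_day`, or the last day only when `final = "last_day"`), and
#' (ii) the mean cosine distance (1 - cosine similarity) between the
#' untransformed relative-abundance time series of ASVs shared by both
#' series and persisting past `equilibration_day` in each. A no-intercept
#' linear model of cosine distance on compositional dissimilarity summarizes
#' the coupling; its R-squared uses the uncentered total sum of squares.
#'
#' @param exp a `transfer_experiment`.
#' @param equilibration_day day after which communities are considered
#'   equilibrated (default 21).
#' @param final `"mean_post_equilibration"` (default) or `"last_day"`.
#' @return object of class `coupling_result`: `points` tibble
#'   (`microcosm_a`, `treatment_a`, `microcosm_b`, `treatment_b`,
#'   `mean_bray_curtis_final`, `mean_cosine_distance`, `n_shared_asvs`),
#'   `beta`, `r_squared`, `p_value`.
#' @export
composition_trajectory_coupling <- function(exp, equilibration_day = 21,
                                            final = c("mean_post_equilibration",
                                                      "last_day")) {
  final <- match.arg(final)
  mats <- series_matrices(exp, value = "rel_abundance")
  finals <- lapply(mats, function(s) {
    post <- if (final == "last_day") s$days == max(s$days) else
      s$days > equilibration_day
    if (!any(post)) return(NULL)
    list(comp = colMeans(s$mat[post, , drop = FALSE]),
         persisting = colnames(s$mat)[colSums(
           s$mat[post, , drop = FALSE] > 0) > 0])
  })
  ns <- length(mats)
  pts <- list()
  for (i in seq_len(ns - 1)) {
    for (j in (i + 1):ns) {
      a <- mats[[i]]; b <- mats[[j]]
      fa <- finals[[i]]; fb <- finals[[j]]
      if (is.null(fa) || is.null(fb)) next
      shared <- intersect(fa$persisting, fb$persisting)
      if (length(shared) == 0) next
      # final-composition dissimilarity on the union ASV axis
      asvs <- union(names(fa$comp), names(fb$comp))
      va <- setNames(numeric(length(asvs)), asvs); va[names(fa$comp)] <- fa$comp
      vb <- setNames(numeric(length(asvs)), asvs); vb[names(fb$comp)] <- fb$comp
      bc <- bray_curtis(va, vb)
      shared_days <- intersect(a$days, b$days)
      if (length(shared_days) < 2) next
      ia <- match(shared_days, a$days); ib <- match(shared_days, b$days)
      cosd <- vapply(shared, function(asv) {
        xa <- a$mat[ia, asv]; xb <- b$mat[ib, asv]
        if (all(xa == 0) || all(xb == 0)) return(NA_real_)
        1 - cosine_similarity(xa, xb)
      }, numeric(1))
      cosd <- cosd[!is.na(cosd)]
      if (length(cosd) == 0) next
      pts[[length(pts) + 1]] <- tibble(
        microcosm_a = a$microcosm_id, treatment_a = a$treatment,
        microcosm_b = b$microcosm_id, treatment_b = b$treatment,
        mean_bray_curtis_final = bc, mean_cosine_distance = mean(cosd),
        n_shared_asvs = length(cosd))
    }
  }
  points <- bind_rows(pts)
  if (nrow(points) < 3) abort("fewer than 3 qualifying series pairs")
  fit <- linear_fit(points$mean_bray_curtis_final,
                    points$mean_cosine_distance, with_intercept = FALSE)
  structure(list(points = points, beta = unname(fit$coefficients[1]),
                 r_squared = fit$r_squared, p_value = fit$p_value),
            class = "coupling_result")
}

#' @export
print.coupling_result <- function(x, ...) {
  cat(sprintf(
    "Composition-trajectory coupling: %d pairs, beta = %.3f, R^2 (no intercept) = %.3f, p = %.3g\n",
    nrow(x$points), x$beta, x$r_squared, x$p_value))
  invisible(x)
}

#' @export
glance.coupling_result <- function(x, ...) {
  tibble(beta = x$beta, r_squared = x$r_squared, p_value = x$p_value,
         n_pairs = nrow(x$points))
}

#' Classify the fate of each ASV in each series
#'
#' Survivor if the ASV is still present (censored) at the final transfer of
#' the series, extinct otherwise; occupancy is the number of series whose
#' baseline (transfer-1, back-filled) pool contains the ASV.
#'
#' @param exp a `transfer_experiment`.
#' @param baseline_transfer baseline for the at-risk pool (default 1).
#' @return tibble with `asv_id`, `microcosm_id`, `treatment`, `fate`
#'   (`"survivor"`/`"extinct"`), `occupancy`.
#' @export
classify_fates <- function(exp, baseline_transfer = 1) {
  rec <- extinction_times(exp, baseline_transfer = baseline_transfer)
  occ <- rec %>% count(.data$asv_id, name = "occupancy")
  rec %>%
    mutate(fate = ifelse(.data$censored, "survivor", "extinct")) %>%
    left_join(occ, by = "asv_id") %>%
    select("asv_id", "microcosm_id", "treatment", "fate", "occupancy")
}

#' Null probability of identical fate across n microcosms
#'
#' With a chance `f` of repeating the current fate in each additional
#' microcosm, the probability an ASV present in `n` microcosms has the same
#' fate in all of them is `f^(n - 1)`.
#'
#' @param n number of microcosms (integer >= 1; vectorized).
#' @param f per-microcosm same-fate probability (default 0.5, the random
#'   null).
#' @return numeric vector of probabilities.
#' @export
shared_fate_null <- function(n, f = 0.5) {
  if (any(n < 1)) abort("n must be >= 1")
  if (f < 0 || f > 1) abort("f must be in [0, 1]")
  f^(n - 1)
}

#' Test shared-fate enrichment against the random null
#'
#' For each occupancy level `n >= 2`, the fraction of ASVs with the same
#' fate in all `n` series is compared with the null `f^(n - 1)` by an exact
#' one-sided binomial test.
#'
#' @param fates tibble from [classify_fates()].
#' @param f null same-fate probability (default 0.5).
#' @return tibble with `n`, `n_asvs`, `n_all_same`, `observed_fraction`,
#'   `null_probability`, `p_value`.
#' @export
shared_fate_test <- function(fates, f = 0.5) {
  if (nrow(fates) == 0) abort("empty fate table")
  per_asv <- fates %>%
    group_by(.data$asv_id) %>%
    summarise(n = n(), all_same = n_distinct(.data$fate) == 1,
              .groups = "drop") %>%
    filter(.data$n >= 2)
  per_asv %>%
    group_by(.data$n) %>%
    summarise(n_asvs = n(), n_all_same = sum(.data$all_same),
              .groups = "drop") %>%
    mutate(observed_fraction = .data$n_all_same / .data$n_asvs,
           null_probability = shared_fate_null(.data$n, f),
           p_value = pbinom(.data$n_all_same - 1, .data$n_asvs,
                            .data$null_probability, lower.tail = FALSE))
}
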