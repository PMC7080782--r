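#' Water-subtract raw substrate-response profiles
#'
#' Subtracts each sample's water (background respiration) control from its
#' substrate responses and clips at zero; the number of clipped cells is
#' recorded as the `"n_clipped"` attribute.
#'
#' @param raw tibble with `microcosm_id`, `day`, a `water` column, and one
#'   column per substrate.
#' @param water_col name of the water-control column.
#' @return function-profile tibble (`microcosm_id`, `day`, substrates).
#' @export
process_function_profiles <- function(raw, water_col = "water") {
  if (!water_col %in% names(raw)) abort("missing water control column")
  subs <- setdiff(names(raw), c("microcosm_id", "day", water_col))
  out <- as_tibble(raw)
  n_clipped <- 0L
  for (s in subs) {
    v <- out[[s]] - out[[water_col]]
    n_clipped <- n_clipped + sum(v < 0)
    out[[s]] <- pmax(0, v)
  }
  out[[water_col]] <- NULL
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Variance of CO2 output across microcosms over time
#'
#' Sample variance (n - 1 denominator) of `percent_co2` across microcosms at
#' each day; days with fewer than two measurements are skipped with a
#' warning. A drop from high Day-0 variance to a low plateau indicates rapid
#' respiratory convergence.
#'
#' @param co2 tibble with `microcosm_id`, `day`, `percent_co2`.
#' @return tibble with `day`, `n_microcosms`, `variance`, ordered by day.
#' @export
co2_variance_series <- function(co2) {
  out <- co2 %>%
    group_by(.data$day) %>%
    summarise(n_microcosms = n(), variance = var(.data$percent_co2),
              .groups = "drop") %>%
    arrange(.data$day)
  skipped <- out$day[out$n_microcosms < 2]
  if (length(skipped) > 0) {
    warn(paste0("skipping day(s) with < 2 microcosms: ",
                paste(skipped, collapse = ", ")))
    out <- out %>% filter(.data$n_microcosms >= 2)
  }
  out
}

#' Paired composition and function dissimilarity matrices
#'
#' Matches abundance samples with function-profile samples by
#' `(microcosm, day)` — samples present in only one modality are dropped —
#' and returns the two Bray-Curtis matrices over the shared samples in the
#' same order, ready for [mantel_test()] or per-day ordination.
#'
#' @param exp a `transfer_experiment`.
#' @param function_profiles tibble with `microcosm_id`, `day` and substrate
#'   columns.
#' @param treatment abundance treatment matched to the profiles (default
#'   `"filtered"`).
#' @return list with `d_composition`, `d_function` (symmetric matrices,
#'   rownames `"<microcosm>|<day>"`) and `n_dropped`.
#' @export
composition_function_dissimilarities <- function(exp, function_profiles,
                                                 treatment = "filtered") {
  comp <- composition_matrix(exp, treatments = treatment)
  rownames(comp) <- sub("\\|[a-z]+\\|", "|", rownames(comp))
  fp_ids <- paste(function_profiles$microcosm_id, function_profiles$day,
                  sep = "|")
  shared <- intersect(rownames(comp), fp_ids)
  if (length(shared) < 4) abort("fewer than 4 samples with both modalities")
  fmat <- as.matrix(function_profiles[
    match(shared, fp_ids),
    setdiff(names(function_profiles), c("microcosm_id", "day"))])
  rownames(fmat) <- shared
  list(d_composition = dissimilarity_matrix(comp[shared, , drop = FALSE]),
       d_function = dissimilarity_matrix(fmat),
       n_dropped = (nrow(comp) - length(shared)) +
         (length(fp_ids) - length(shared)))
}

#' Mantel permutation test between two dissimilarity matrices
#'
#' The statistic is the Pearson (or Spearman) correlation of the
#' strictly-lower-triangle entries; significance comes from jointly
#' permuting one matrix's rows and columns with a seeded generator. The
#' one-tailed (positive association) p-value uses the add-one rule,
#' `p = (1 + #\{permuted r >= observed\}) / (n_perm + 1)`, so it can never
#' be zero.
#'
#' @param d1,d2 symmetric dissimilarity matrices over the same samples in
#'   the same order (checked via rownames when present).
#' @param n_perm number of permutations (default 9999, resolving p down to
#'   1e-4).
#' @param seed integer seed.
#' @param method correlation type, `"pearson"` (default) or `"spearman"`.
#' @return object of class `mantel_result`: `r`, `p_value`,
#'   `n_permutations`, `seed`, `n_samples`, `method`.
#' @export
mantel_test <- function(d1, d2, n_perm = 9999, seed = 1L,
                        method = c("pearson", "spearman")) {
  method <- match.arg(method)
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  if (!all(dim(m1) == dim(m2))) abort("matrices differ in size")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2))) {
    if (!identical(rownames(m1), rownames(m2))) {
      abort("matrices cover different sample sets or orders")
    }
  }
  n <- nrow(m1)
  if (n < 4) abort("need at least 4 samples")
  lt <- lower.tri(m1)
  v1 <- m1[lt]
  r_obs <- cor(v1, m2[lt], method = method)
  r_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      cor(v1, m2[p, p][lt], method = method)
    }, numeric(1))
  })
  p_value <- (1 + sum(r_perm >= r_obs)) / (n_perm + 1)
  structure(list(r = r_obs, p_value = p_value, n_permutations = n_perm,
                 seed = seed, n_samples = n, method = method),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test (%s): r = %.4f, p = %.4g (%d permutations, n = %d)\n",
              x$method, x$r, x$p_value, x$n_permutations, x$n_samples))
  invisible(x)
}

#' @export
glance.mantel_result <- function(x, ...) {
  tibble(r = x$r, p_value = x$p_value, n_permutations = x$n_permutations,
         n_samples = x$n_samples)
}

#' Procrustes superposition test between two ordinations
#'
#' Symmetric Procrustes rotation of two configurations (centered,
#' unit-scaled, optimal rotation from the cross-product SVD) with a
#' PROTEST-style row-permutation significance test, via `vegan::protest`.
#' The correlation is `sqrt(1 - m12^2)`, where `m12^2` is the symmetric
#' Procrustes sum of squares; configurations differing only by rotation,
#' reflection, translation and uniform scaling have correlation 1.
#'
#' @param a,b `ordination` objects (or coordinate matrices) over the same
#'   samples with the same dimensionality.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return object of class `procrustes_result`: `correlation`,
#'   `m12_squared`, `p_value`, `n_permutations`, `seed`, `n_samples`.
#' @export
procrustes_test <- function(a, b, n_perm = 999, seed = 1L) {
  xa <- if (inherits(a, "ordination")) a$coordinates else as.matrix(a)
  xb <- if (inherits(b, "ordination")) b$coordinates else as.matrix(b)
  if (!all(dim(xa) == dim(xb))) abort("configurations differ in dimension")
  if (nrow(xa) <= 2) {
    warn("2-point configurations are degenerate: correlation is always 1")
  }
  fit <- with_seed(seed, vegan::protest(xa, xb, permutations = n_perm))
  structure(list(correlation = fit$t0, m12_squared = fit$ss,
                 p_value = fit$signif, n_permutations = n_perm, seed = seed,
                 n_samples = nrow(xa)),
            class = "procrustes_result")
}

#' @export
print.procrustes_result <- function(x, ...) {
  cat(sprintf(
    "Procrustes test: correlation = %.4f (m12^2 = %.4f), p = %.4g (%d permutations)\n",
    x$correlation, x$m12_squared, x$p_value, x$n_permutations))
  invisible(x)
}

#' @export
glance.procrustes_result <- function(x, ...) {
  tibble(correlation = x$correlation, m12_squared = x$m12_squared,
         p_value = x$p_value, n_permutations = x$n_permutations)
}

#' Project per-strain enzyme activity onto community composition
#'
#' Cumulative community-level activity per sample:
#' `C(day) = sum_a activity(a) * rel_abundance(day, a)`. ASVs without a
#' measured activity contribute zero.
#'
#' @param exp a `transfer_experiment`.
#' @param activity tibble keyed by `asv_id` with one column per enzyme.
#' @param enzyme which activity column to project (default
#'   `"endochitinase"`).
#' @return tibble with `microcosm_id`, `treatment`, `day`,
#'   `cumulative_activity`.
#' @export
cumulative_activity <- function(exp, activity, enzyme = "endochitinase") {
  if (!enzyme %in% names(activity)) {
    abort(paste0("no '", enzyme, "' column in the activity table"))
  }
  act <- setNames(activity[[enzyme]], activity$asv_id)
  as_tibble(exp) %>%
    mutate(a = unname(act[.data$asv_id]),
           a = ifelse(is.na(.data$a), 0, .data$a)) %>%
    group_by(.data$microcosm_id, .data$treatment, .data$day) %>%
    summarise(cumulative_activity = sum(.data$a * .data$rel_abundance),
              .groups = "drop")
}

#' Ordinary least-squares fit with optional intercept
#'
#' With `with_intercept = FALSE`, the R-squared is computed against the
#' uncentered total sum of squares (the convention for intercept-free
#' models); the p-value comes from the F statistic.
#'
#' @param x,y numeric vectors (length >= 3).
#' @param with_intercept include an intercept (default `TRUE`).
#' @return list with `coefficients` (named numeric), `r_squared`,
#'   `p_value`, `n`.
#' @export
linear_fit <- function(x, y, with_intercept = TRUE) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need at least 3 points")
  if (with_intercept && var(x) == 0) {
    abort("x has zero variance: slope is unidentifiable")
  }
  fit <- if (with_intercept) lm(y ~ x) else lm(y ~ x + 0)
  s <- summary(fit)
  fstat <- s$fstatistic
  p_value <- if (is.null(fstat)) NA_real_ else
    unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  list(coefficients = coef(fit), r_squared = s$r.squared,
       p_value = p_value, n = length(x))
}
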