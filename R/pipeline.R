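#' Run the full serial-transfer analysis pipeline
#'
#' Orchestrates extinction-model fitting, richness decay, trajectory
#' context-dependence, shared-fate testing, and composition-function
#' statistics over one experiment, and returns every headline statistic in a
#' single machine-readable summary. Exactly one of `input` and `simulate`
#' must be given. All randomized stages (read sampling when simulating,
#' random-pair nulls, permutation tests) draw their seeds from `seed` via
#' [sub_seed()], so the run is deterministic.
#'
#' @param input named list with elements `experiment` (a
#'   `transfer_experiment`), `function_profiles`, `co2`, `activities`
#'   (tibbles as produced by the readers in this package), or a directory
#'   path containing `abundance.tsv`, `function_profiles.csv`, `co2.csv`,
#'   `activities.csv`.
#' @param simulate a [synthetic_config()], or `TRUE` for defaults (the
#'   generator is then seeded from `seed`).
#' @param baseline_transfer extinction-clock baseline (default 1 = Day 3).
#' @param equilibration_day day after which communities are treated as
#'   equilibrated (default 21).
#' @param extinction_treatment treatment whose series define the
#'   extinction/richness statistics (default `"filtered"`, the ten primary
#'   microcosms).
#' @param n_perm_mantel,n_perm_procrustes permutation counts.
#' @param seed integer top-level seed.
#' @param out_dir optional directory to write per-stage tables and the
#'   summary JSON into.
#' @return object of class `pipeline_report`: `summary` (named list of
#'   headline statistics) plus the per-stage result objects.
#' @export
run_pipeline <- function(input = NULL, simulate = NULL,
                         baseline_transfer = 1, equilibration_day = 21,
                         extinction_treatment = "filtered",
                         n_perm_mantel = 999, n_perm_procrustes = 999,
                         seed = 1L, out_dir = NULL) {
  if (is.null(input) == is.null(simulate)) {
    abort("exactly one of `input` and `simulate` must be given")
  }
  if (!is.null(simulate)) {
    cfg <- if (isTRUE(simulate)) synthetic_config(rng_seed = sub_seed(seed, 0))
           else simulate
    bundle <- generate_experiment(cfg)
  } else if (is.character(input)) {
    bundle <- list(
      experiment = read_abundance_long(file.path(input, "abundance.tsv")),
      function_profiles =
        read_function_profiles(file.path(input, "function_profiles.csv")),
      co2 = read_co2_table(file.path(input, "co2.csv")),
      activities = read_activity_table(file.path(input, "activities.csv")))
  } else {
    bundle <- input
  }
  exp <- bundle$experiment
  interval <- transfer_interval(exp)
  exp_main <- as_experiment(
    as_tibble(exp) %>% filter(.data$treatment == extinction_treatment),
    transfer_interval = interval, n_transfers = n_transfers(exp))

  # --- extinction stage ---------------------------------------------------
  records <- extinction_times(exp_main, baseline_transfer = baseline_transfer)
  comparison <- compare_extinction_models(records)
  decay <- estimate_decay_model(records)
  gof <- geometric_gof(records$extinction_transfer[!records$censored],
                       comparison$common_fit$p_hat)

  # --- richness stage -----------------------------------------------------
  rel_rich <- relative_richness(exp_main, baseline_transfer)
  last5 <- (n_transfers(exp) - 4):n_transfers(exp)
  equilibrium <- rel_rich %>%
    filter(.data$transfer %in% last5) %>%
    group_by(.data$microcosm_id) %>%
    summarise(m = mean(.data$rel_richness), .groups = "drop")
  eq_pct <- 100 * mean(equilibrium$m)
  reg <- richness_regression(exp_main, day_x = baseline_transfer * interval,
                             day_y = max(exp_main$day))

  # --- context stage ------------------------------------------------------
  correlations <- trajectory_correlations(exp, seed = sub_seed(seed, 3))
  corr_summary <- correlations %>%
    group_by(.data$category) %>%
    group_modify(~ distribution_summary(.x$pearson_r)) %>%
    ungroup()
  coupling <- composition_trajectory_coupling(
    exp, equilibration_day = equilibration_day)
  fates <- classify_fates(exp_main, baseline_transfer)
  fate_test <- shared_fate_test(fates)

  # --- function stage -----------------------------------------------------
  dd <- composition_function_dissimilarities(
    exp, bundle$function_profiles, treatment = extinction_treatment)
  d_comp <- dd$d_composition
  d_fun <- dd$d_function
  shared_ids <- rownames(d_comp)
  mantel <- mantel_test(d_comp, d_fun, n_perm = n_perm_mantel,
                        seed = sub_seed(seed, 1))
  final_day <- max(exp_main$day)
  final_ids <- shared_ids[endsWith(shared_ids, paste0("|", final_day))]
  procrustes <- NULL
  if (length(final_ids) >= 4) {
    ord_c <- ordinate(d_comp[final_ids, final_ids], k = 2)
    ord_f <- ordinate(d_fun[final_ids, final_ids], k = 2)
    procrustes <- procrustes_test(ord_c, ord_f, n_perm = n_perm_procrustes,
                                  seed = sub_seed(seed, 2))
  }
  co2_var <- co2_variance_series(bundle$co2)
  cum_act <- cumulative_activity(exp_main, bundle$activities)

  pick <- function(cat, col) {
    corr_summary[[col]][corr_summary$category == cat] %||% NA_real_
  }
  summary <- list(
    schema_version = "serialtransfer-report-1",
    seed = as.integer(seed),
    n_series = nrow(distinct(as_tibble(exp), .data$microcosm_id,
                             .data$treatment)),
    n_extinction_records = nrow(records),
    common_p_hat = comparison$common_fit$p_hat,
    gof_p_value = gof$p_value,
    bic_common = comparison$bic_common,
    bic_individual = comparison$bic_individual,
    relative_likelihood = comparison$relative_likelihood,
    preferred_model = comparison$preferred,
    survival_fraction = decay$survival_fraction,
    extinction_rate = decay$extinction_rate,
    equilibrium_relative_richness_pct = eq_pct,
    richness_regression_r_squared = reg$r_squared,
    richness_regression_p_value = reg$p_value,
    correlation_mean_same_inoculum = pick("same_inoculum", "mean"),
    correlation_mode_same_inoculum = pick("same_inoculum", "mode"),
    correlation_mean_different_inoculum = pick("different_inoculum", "mean"),
    correlation_mode_different_inoculum = pick("different_inoculum", "mode"),
    correlation_mean_random_pair = pick("random_pair", "mean"),
    correlation_mode_random_pair = pick("random_pair", "mode"),
    coupling_beta = coupling$beta,
    coupling_r_squared = coupling$r_squared,
    mantel_r = mantel$r,
    mantel_p_value = mantel$p_value,
    procrustes_correlation = if (is.null(procrustes)) NA_real_ else
      procrustes$correlation,
    procrustes_p_value = if (is.null(procrustes)) NA_real_ else
      procrustes$p_value,
    co2_variance_first = co2_var$variance[1],
    co2_variance_late_mean = mean(tail(co2_var$variance, 5)))
  report <- structure(
    list(summary = summary, records = records, comparison = comparison,
         decay = decay, gof = gof, relative_richness = rel_rich,
         richness_regression = reg, correlations = correlations,
         correlation_summary = corr_summary, coupling = coupling,
         fate_test = fate_test, mantel = mantel, procrustes = procrustes,
         co2_variance = co2_var, cumulative_activity = cum_act,
         experiment = exp),
    class = "pipeline_report")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_tsv(records, file.path(out_dir, "extinction_records.tsv"),
                     progress = FALSE)
    write_csv_with_schema(rel_rich, file.path(out_dir, "relative_richness.csv"),
                          "relative-richness")
    write_csv_with_schema(as_tibble(correlations),
                          file.path(out_dir, "trajectory_correlations.csv"),
                          "trajectory-correlations")
    write_csv_with_schema(coupling$points,
                          file.path(out_dir, "coupling_points.csv"),
                          "coupling-points")
    write_csv_with_schema(fate_test, file.path(out_dir, "fate_test.csv"),
                          "fate-test")
    write_csv_with_schema(co2_var, file.path(out_dir, "co2_variance.csv"),
                          "co2-variance")
    write_report(summary, file.path(out_dir, "summary.json"))
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  s <- x$summary
  cat("Serial-transfer pipeline report\n")
  cat(sprintf("  common extinction rate p_hat = %.4f (GOF p = %.3f)\n",
              s$common_p_hat, s$gof_p_value))
  cat(sprintf("  B_1 = %.1f, B_k = %.1f -> %s model (rel. likelihood %.3g)\n",
              s$bic_common, s$bic_individual, s$preferred_model,
              s$relative_likelihood))
  cat(sprintf("  survival fraction s = %.3f; equilibrium relative richness = %.1f%%\n",
              s$survival_fraction, s$equilibrium_relative_richness_pct))
  cat(sprintf("  richness regression R^2 = %.3f\n",
              s$richness_regression_r_squared))
  cat(sprintf("  correlation means: same inoc %.3f | diff inoc %.3f | random %.3f\n",
              s$correlation_mean_same_inoculum,
              s$correlation_mean_different_inoculum,
              s$correlation_mean_random_pair))
  cat(sprintf("  coupling R^2 (no intercept) = %.3f\n", s$coupling_r_squared))
  cat(sprintf("  Mantel r = %.4f (p = %.4g); Procrustes corr = %.4f (p = %.4g)\n",
              s$mantel_r, s$mantel_p_value, s$procrustes_correlation,
              s$procrustes_p_value))
  invisible(x)
}

report_keys <- c(
  "schema_version", "seed", "n_series", "n_extinction_records",
  "common_p_hat", "gof_p_value", "bic_common", "bic_individual",
  "relative_likelihood", "preferred_model", "survival_fraction",
  "extinction_rate", "equilibrium_relative_richness_pct",
  "richness_regression_r_squared", "richness_regression_p_value",
  "correlation_mean_same_inoculum", "correlation_mode_same_inoculum",
  "correlation_mean_different_inoculum", "correlation_mode_different_inoculum",
  "correlation_mean_random_pair", "correlation_mode_random_pair",
  "coupling_beta", "coupling_r_squared", "mantel_r", "mantel_p_value",
  "procrustes_correlation", "procrustes_p_value", "co2_variance_first",
  "co2_variance_late_mean")

#' Write and read the pipeline summary
#'
#' The summary is a flat, schema-versioned key-value document written as
#' JSON with a stable key order; writing validates that every expected key
#' is present.
#'
#' @param summary named list (the `summary` element of a
#'   [run_pipeline()] report).
#' @param path output path.
#' @return `path` (write) or the parsed summary list (read), invisibly for
#'   the writer.
#' @export
write_report <- function(summary, path) {
  missing_keys <- setdiff(report_keys, names(summary))
  if (length(missing_keys) > 0) {
    abort(paste0("summary is missing key(s): ",
                 paste(missing_keys, collapse = ", ")))
  }
  jsonlite::write_json(summary[report_keys], path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
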