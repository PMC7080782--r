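#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_density
#'   geom_abline geom_col facet_wrap labs theme_minimal autoplot
NULL

#' @export
ggplot2::autoplot

#' Relative richness decay curves with the fitted model
#'
#' One back-filled relative-richness curve per microcosm, overlaid with the
#' expected decay `s + (1 - s)(1 - p)^t` when a fitted
#' `richness_decay_model` is supplied.
#'
#' @param rel_rich tibble from [relative_richness()].
#' @param model optional [estimate_decay_model()] result.
#' @param baseline_transfer baseline used for the normalization.
#' @return a ggplot object.
#' @export
plot_richness_decay <- function(rel_rich, model = NULL,
                                baseline_transfer = 1) {
  p <- ggplot(rel_rich,
              aes(x = .data$transfer - baseline_transfer,
                  y = .data$rel_richness,
                  group = interaction(.data$microcosm_id, .data$treatment),
                  colour = .data$microcosm_id)) +
    geom_line(alpha = 0.6) +
    labs(x = "transfers past baseline", y = "relative richness",
         colour = "microcosm") +
    theme_minimal()
  if (!is.null(model)) {
    tmax <- max(rel_rich$transfer) - baseline_transfer
    curve <- tibble(t = 0:tmax,
                    y = expected_relative_richness(
                      0:tmax, model$survival_fraction,
                      model$extinction_rate))
    p <- p + geom_line(data = curve,
                       aes(x = .data$t, y = .data$y),
                       inherit.aes = FALSE, linewidth = 1)
  }
  p
}

#' Observed extinction-time distribution against the geometric fit
#'
#' @param records tibble from [extinction_times()].
#' @param fit a `geometric_fit` (e.g. the common fit).
#' @return a ggplot object.
#' @export
plot_extinction_fit <- function(records, fit) {
  obs <- records %>% filter(!.data$censored) %>%
    count(.data$extinction_transfer) %>%
    mutate(prob = .data$n / sum(.data$n))
  tmax <- max(obs$extinction_transfer)
  theo <- tibble(extinction_transfer = 1:tmax,
                 prob = geometric_pmf(fit$p_hat, 1:tmax))
  ggplot(obs, aes(x = .data$extinction_transfer, y = .data$prob)) +
    geom_col(alpha = 0.6) +
    geom_line(data = theo, colour = "black") +
    geom_point(data = theo, colour = "black") +
    labs(x = "extinction transfer t", y = "P(t)") +
    theme_minimal()
}

#' @describeIn trajectory_correlations density of correlation coefficients
#'   by pair category.
#' @param object a `trajectory_correlations` tibble.
#' @param ... ignored.
#' @export
autoplot.trajectory_correlations <- function(object, ...) {
  ggplot(object, aes(x = .data$pearson_r, colour = .data$category)) +
    geom_density() +
    labs(x = "Pearson r of CLR trajectories", y = "density") +
    theme_minimal()
}

#' @describeIn composition_trajectory_coupling coupling scatter with the
#'   no-intercept fit.
#' @param object a `coupling_result`.
#' @param ... ignored.
#' @export
autoplot.coupling_result <- function(object, ...) {
  ggplot(object$points,
         aes(x = .data$mean_bray_curtis_final,
             y = .data$mean_cosine_distance)) +
    geom_point(alpha = 0.7) +
    geom_abline(intercept = 0, slope = object$beta) +
    labs(x = "mean Bray-Curtis of final compositions",
         y = "mean cosine distance of shared-ASV trajectories") +
    theme_minimal()
}

#' @describeIn ordinate scatter of the first two ordination axes.
#' @param object an `ordination`.
#' @param ... ignored.
#' @export
autoplot.ordination <- function(object, ...) {
  df <- tibble(sample_id = object$sample_ids,
               axis1 = object$coordinates[, 1],
               axis2 = object$coordinates[, 2])
  ggplot(df, aes(x = .data$axis1, y = .data$axis2)) +
    geom_point() +
    labs(x = paste(object$method, "1"), y = paste(object$method, "2")) +
    theme_minimal()
}

#' CO2 variance across microcosms over time
#'
#' @param co2_var tibble from [co2_variance_series()].
#' @return a ggplot object.
#' @export
plot_co2_variance <- function(co2_var) {
  ggplot(co2_var, aes(x = .data$day, y = .data$variance)) +
    geom_line() + geom_point() +
    labs(x = "day", y = "variance in percent CO2") +
    theme_minimal()
}
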