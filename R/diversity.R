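#' Back-filled richness per timepoint
#'
#' Corrects for the sequencing detection limit: an ASV detected at any later
#' timepoint of a series is counted as present now, so each series' richness
#' curve is non-increasing. Naive (detected-only) richness is returned
#' alongside.
#'
#' @param exp a `transfer_experiment`.
#' @return tibble with `microcosm_id`, `inoculum_id`, `treatment`, `day`,
#'   `transfer`, `richness` (back-filled), `naive_richness`.
#' @export
backfilled_richness <- function(exp) {
  interval <- transfer_interval(exp)
  tbl <- as_tibble(exp) %>% filter(.data$count > 0)
  last_det <- tbl %>%
    group_by(.data$microcosm_id, .data$inoculum_id, .data$treatment,
             .data$asv_id) %>%
    summarise(last_day = max(.data$day), .groups = "drop")
  days <- tbl %>% distinct(.data$microcosm_id, .data$inoculum_id,
                           .data$treatment, .data$day)
  naive <- tbl %>%
    count(.data$microcosm_id, .data$treatment, .data$day,
          name = "naive_richness")
  days %>%
    left_join(last_det, by = c("microcosm_id", "inoculum_id", "treatment"),
              relationship = "many-to-many") %>%
    group_by(.data$microcosm_id, .data$inoculum_id, .data$treatment,
             .data$day) %>%
    summarise(richness = sum(.data$last_day >= .data$day), .groups = "drop") %>%
    left_join(naive, by = c("microcosm_id", "treatment", "day")) %>%
    mutate(transfer = .data$day %/% interval, .after = "day") %>%
    arrange(.data$microcosm_id, .data$treatment, .data$day)
}

#' Relative richness curves normalized at a baseline transfer
#'
#' Back-filled richness divided by its value at `baseline_transfer` for each
#' series, the normalization under which all series are expected to collapse
#' onto the common decay curve `s + (1 - s)(1 - p)^t`.
#'
#' @inheritParams backfilled_richness
#' @param baseline_transfer transfer used for normalization (default 1).
#' @return the [backfilled_richness()] tibble with an added `rel_richness`
#'   column, restricted to transfers at/after the baseline.
#' @export
relative_richness <- function(exp, baseline_transfer = 1) {
  r <- backfilled_richness(exp)
  base <- r %>% filter(.data$transfer == baseline_transfer) %>%
    select("microcosm_id", "treatment", base_richness = "richness")
  if (nrow(base) == 0) abort("baseline transfer not sampled")
  r %>% filter(.data$transfer >= baseline_transfer) %>%
    inner_join(base, by = c("microcosm_id", "treatment")) %>%
    mutate(rel_richness = .data$richness / .data$base_richness)
}

#' Effective number of species
#'
#' `exp(H)` with `H` the Shannon entropy of a relative-abundance vector;
#' zeros are excluded from the sum.
#'
#' @param rel_row numeric vector of fractions summing to 1 (within 1e-9).
#' @return scalar effective species number.
#' @export
effective_species <- function(rel_row) {
  if (any(rel_row < 0)) abort("negative relative abundances")
  if (abs(sum(rel_row) - 1) > 1e-9) abort("relative abundances must sum to 1")
  x <- rel_row[rel_row > 0]
  exp(-sum(x * log(x)))
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `1 - 2 sum(min(x, y)) / (sum(x) + sum(y))`: 0 for identical vectors, 1
#' for disjoint support.
#'
#' @param x,y non-negative numeric vectors of equal length.
#' @return dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) abort("vectors must have equal length")
  if (any(x < 0) || any(y < 0)) abort("abundances must be non-negative")
  denom <- sum(x) + sum(y)
  if (denom == 0) abort("both vectors are all-zero")
  1 - 2 * sum(pmin(x, y)) / denom
}

#' Pairwise dissimilarity matrix
#'
#' Rows of `samples` are abundance (or substrate-response) vectors on a
#' shared feature axis, absent features as zeros. Bray-Curtis and the other
#' metrics are computed with `vegan::vegdist`.
#'
#' @param samples numeric matrix, samples x features, with rownames as
#'   sample ids.
#' @param metric dissimilarity metric (any `vegan::vegdist` method;
#'   default `"bray"`).
#' @return symmetric matrix with zero diagonal and sample ids as dimnames.
#' @export
dissimilarity_matrix <- function(samples, metric = "bray") {
  samples <- as.matrix(samples)
  d <- vegan::vegdist(samples, method = metric)
  as.matrix(d)
}

#' Composition matrix of an experiment
#'
#' Wide samples-x-ASVs matrix (sample ids `"<microcosm>|<treatment>|<day>"`)
#' on the union ASV axis, for dissimilarity and ordination work.
#'
#' @param exp a `transfer_experiment`.
#' @param value `"rel_abundance"` (default) or `"count"`.
#' @param treatments optional treatment subset.
#' @param days optional day subset.
#' @return numeric matrix.
#' @export
composition_matrix <- function(exp, value = "rel_abundance",
                               treatments = NULL, days = NULL) {
  tbl <- as_tibble(exp)
  if (!is.null(treatments)) tbl <- tbl %>%
      filter(.data$treatment %in% treatments)
  if (!is.null(days)) tbl <- tbl %>% filter(.data$day %in% days)
  if (nrow(tbl) == 0) abort("no samples match the requested subset")
  tbl$sample_id <- paste(tbl$microcosm_id, tbl$treatment, tbl$day, sep = "|")
  ids <- sort(unique(tbl$sample_id))
  asvs <- sort(unique(tbl$asv_id))
  m <- matrix(0, length(ids), length(asvs), dimnames = list(ids, asvs))
  m[cbind(match(tbl$sample_id, ids), match(tbl$asv_id, asvs))] <- tbl[[value]]
  m
}

#' Bray-Curtis turnover between adjacent timepoints
#'
#' One dissimilarity per consecutive day pair within each series, the
#' equilibration diagnostic: turnover is high early and declines as
#' communities settle.
#'
#' @param exp a `transfer_experiment`.
#' @return tibble with `microcosm_id`, `treatment`, `day_from`, `day_to`,
#'   `dissimilarity`.
#' @export
adjacent_dissimilarity <- function(exp) {
  mats <- series_matrices(exp, value = "rel_abundance")
  purrr::map_dfr(mats, function(s) {
    nd <- length(s$days)
    if (nd < 2) {
      return(tibble(microcosm_id = character(), treatment = character(),
                    day_from = integer(), day_to = integer(),
                    dissimilarity = double()))
    }
    d <- vapply(seq_len(nd - 1), function(i) {
      bray_curtis(s$mat[i, ], s$mat[i + 1, ])
    }, numeric(1))
    tibble(microcosm_id = s$microcosm_id, treatment = s$treatment,
           day_from = s$days[-nd], day_to = s$days[-1], dissimilarity = d)
  })
}

#' Occupancy and mean abundance per ASV at a given day
#'
#' Occupancy counts the series in which an ASV is detected at `at_day`; mean
#' relative abundance is taken only over the series where it is present.
#'
#' @param exp a `transfer_experiment` (subset to one treatment first to count
#'   over the ten microcosms rather than all replicate series).
#' @param at_day day at which occupancy is assessed.
#' @return tibble with `asv_id`, `n_microcosms`, `mean_rel_abundance`.
#' @export
occupancy_summary <- function(exp, at_day) {
  tbl <- as_tibble(exp)
  if (!at_day %in% tbl$day) abort(paste0("day ", at_day, " not sampled"))
  tbl %>%
    filter(.data$day == at_day, .data$count > 0) %>%
    group_by(.data$asv_id) %>%
    summarise(n_microcosms = n_distinct(paste(.data$microcosm_id,
                                              .data$treatment)),
              mean_rel_abundance = mean(.data$rel_abundance),
              .groups = "drop")
}

#' Ordinate a dissimilarity matrix
#'
#' Classical scaling (PCoA; deterministic, exact on Euclidean-embeddable
#' input, negative eigenvalues dropped and reported) or non-metric
#' multidimensional scaling via `vegan::metaMDS` with seeded restarts and
#' Kruskal stress-1.
#'
#' @param d symmetric dissimilarity matrix (or `dist`).
#' @param k number of dimensions (default 2).
#' @param method `"pcoa"` (default) or `"nmds"`.
#' @param seed integer seed (NMDS restarts).
#' @param trymax NMDS random restarts.
#' @return object of class `ordination`: `sample_ids`, `coordinates`
#'   (samples x k), `method`, `stress` (`NA` for PCoA),
#'   `n_negative_eigenvalues` (PCoA only).
#' @export
ordinate <- function(d, k = 2, method = c("pcoa", "nmds"), seed = 1L,
                     trymax = 20) {
  method <- match.arg(method)
  m <- as.matrix(d)
  n <- nrow(m)
  if (k >= n) abort("k must be smaller than the number of samples")
  off <- m[lower.tri(m)]
  if (length(unique(round(off, 12))) == 1 && n > 2) {
    abort("degenerate dissimilarity matrix: all off-diagonal values equal")
  }
  ids <- rownames(m) %||% as.character(seq_len(n))
  if (method == "pcoa") {
    cs <- cmdscale(as.dist(m), k = k, eig = TRUE)
    coords <- cs$points
    if (ncol(coords) < k) {
      coords <- cbind(coords, matrix(0, n, k - ncol(coords)))
    }
    rownames(coords) <- ids
    res <- list(sample_ids = ids, coordinates = coords, method = "pcoa",
                stress = NA_real_, eigenvalues = cs$eig,
                n_negative_eigenvalues = sum(cs$eig < -1e-12))
  } else {
    fit <- with_seed(seed, suppressWarnings(
      vegan::metaMDS(as.dist(m), k = k, trace = 0, trymax = trymax)))
    coords <- fit$points
    rownames(coords) <- ids
    res <- list(sample_ids = ids, coordinates = coords, method = "nmds",
                stress = fit$stress, eigenvalues = NULL,
                n_negative_eigenvalues = NA_integer_)
  }
  class(res) <- "ordination"
  res
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("<ordination> %s, %d samples x %d dims%s\n",
              x$method, length(x$sample_ids), ncol(x$coordinates),
              if (!is.na(x$stress)) sprintf(", stress = %.4f", x$stress)
              else ""))
  invisible(x)
}

#' Regression of late richness on early richness across microcosms
#'
#' Ordinary least squares (with intercept) of back-filled richness at
#' `day_y` on richness at `day_x`, one point per series: the early-richness
#' predictability check.
#'
#' @param exp a `transfer_experiment`.
#' @param day_x,day_y predictor and response days.
#' @return list with `slope`, `intercept`, `r_squared`, `p_value`, `n`,
#'   and `data` (the per-series points).
#' @export
richness_regression <- function(exp, day_x = 3, day_y = 63) {
  r <- backfilled_richness(exp)
  pts <- r %>% filter(.data$day == day_x) %>%
    select("microcosm_id", "treatment", x = "richness") %>%
    inner_join(r %>% filter(.data$day == day_y) %>%
                 select("microcosm_id", "treatment", y = "richness"),
               by = c("microcosm_id", "treatment"))
  if (nrow(pts) < 3) abort("need at least 3 series with both days sampled")
  fit <- lm(y ~ x, data = pts)
  s <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = s$r.squared,
       p_value = unname(s$coefficients[2, 4]),
       n = nrow(pts), data = pts)
}
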