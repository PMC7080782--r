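# Hand-built fixtures shared across test files. Everything is constructed in
# code; no data files.

toy_long <- function() {
  tibble::tribble(
    ~microcosm_id, ~treatment, ~day, ~asv_id, ~count,
    "M01", "filtered", 0L, "asv_a", 6,
    "M01", "filtered", 0L, "asv_b", 4,
    "M01", "filtered", 3L, "asv_a", 8,
    "M01", "filtered", 3L, "asv_b", 2)
}

# Build a one-series experiment from detection patterns: `patterns` maps
# asv_id -> vector of days at which the ASV is detected (constant count).
# An always-present anchor ASV guarantees every day in `days` is a sample.
pattern_experiment <- function(patterns, days, microcosm = "M01",
                               treatment = "filtered", count = 10,
                               transfer_interval = 3) {
  rows <- purrr::imap_dfr(patterns, function(d, asv) {
    tibble::tibble(microcosm_id = microcosm, treatment = treatment,
                   day = as.integer(d), asv_id = asv, count = count)
  })
  anchor <- tibble::tibble(microcosm_id = microcosm, treatment = treatment,
                           day = as.integer(days), asv_id = ".anchor",
                           count = count)
  as_experiment(dplyr::bind_rows(rows, anchor),
                transfer_interval = transfer_interval,
                n_transfers = max(days) / transfer_interval)
}

# A small, fast synthetic configuration for unit tests.
small_config <- function(...) {
  synthetic_config(n_inocula = 4, pool_size = 80,
                   initial_richness_range = c(12L, 20L), n_transfers = 10,
                   read_depth = 5000, ...)
}
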