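#' Build a serial-transfer experiment table
#'
#' The canonical in-memory container is a long (tidy) tibble with one row per
#' observed `(microcosm, treatment, day, ASV)` count. Cells absent from the
#' table are zeros: an ASV not listed on a given day was not detected. Days
#' map to transfer indices as `transfer = day / transfer_interval`, so Day 0
#' is the pre-transfer inoculum and Day 3 is transfer 1 under the default
#' 3-day interval.
#'
#' @param df data frame with columns `microcosm_id`, `treatment` (one of
#'   `"filtered"`, `"unfiltered"`), `day` (non-negative integer), `asv_id`,
#'   `count` (non-negative integer); an optional `inoculum_id` column defaults
#'   to `microcosm_id` (replicate pairs of the two treatments share it).
#' @param transfer_interval days between transfers (default 3).
#' @param n_transfers number of transfers in the design; `NULL` (default)
#'   infers it as the latest sampled day divided by the interval.
#' @return a tibble of class `transfer_experiment` with the input columns plus
#'   `rel_abundance` (count divided by the sample's total; 0 for zero-read
#'   samples).
#' @export
as_experiment <- function(df, transfer_interval = 3, n_transfers = NULL) {
  req <- c("microcosm_id", "treatment", "day", "asv_id", "count")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("malformed abundance table: missing column(s) ",
                 paste(missing_cols, collapse = ", ")))
  }
  df <- as_tibble(df)
  if (!"inoculum_id" %in% names(df)) df$inoculum_id <- df$microcosm_id
  bad_treat <- setdiff(unique(df$treatment), c("filtered", "unfiltered"))
  if (length(bad_treat) > 0) {
    abort(paste0("unknown treatment value(s): ",
                 paste(bad_treat, collapse = ", ")))
  }
  if (any(df$count < 0)) {
    i <- which(df$count < 0)[1]
    abort(paste0("negative count in row ", i))
  }
  if (any(df$day < 0)) abort("days must be non-negative")
  dup <- duplicated(df[, c("microcosm_id", "treatment", "day", "asv_id")])
  if (any(dup)) {
    i <- which(dup)[1]
    abort(paste0(
      "duplicate (microcosm, treatment, day, asv) row at data row ", i, ": ",
      df$microcosm_id[i], "/", df$treatment[i], "/day ", df$day[i], "/",
      df$asv_id[i]))
  }
  out <- df %>%
    mutate(day = as.integer(.data$day), count = as.double(.data$count)) %>%
    group_by(.data$microcosm_id, .data$treatment, .data$day) %>%
    mutate(rel_abundance = if (sum(.data$count) > 0)
      .data$count / sum(.data$count) else 0) %>%
    ungroup() %>%
    arrange(.data$microcosm_id, .data$treatment, .data$day, .data$asv_id) %>%
    select("microcosm_id", "inoculum_id", "treatment", "day", "asv_id",
           "count", "rel_abundance")
  if (is.null(n_transfers)) {
    n_transfers <- if (nrow(out) == 0) 0L else
      as.integer(max(out$day) %/% transfer_interval)
  }
  new_experiment(out, transfer_interval, n_transfers)
}

new_experiment <- function(tbl, transfer_interval, n_transfers) {
  structure(tbl,
            class = c("transfer_experiment", class(tibble())),
            transfer_interval = as.integer(transfer_interval),
            n_transfers = as.integer(n_transfers))
}

#' @export
print.transfer_experiment <- function(x, ...) {
  cat(sprintf(
    "<transfer_experiment> %d series, %d ASVs, days %s-%s (interval %d d)\n",
    nrow(distinct(as_tibble(x), .data$microcosm_id, .data$treatment)),
    n_distinct(x$asv_id), min(x$day), max(x$day), transfer_interval(x)))
  NextMethod()
}

#' Transfer interval and design length of an experiment
#' @param exp a `transfer_experiment`.
#' @return integer scalar.
#' @export
transfer_interval <- function(exp) attr(exp, "transfer_interval") %||% 3L

#' @rdname transfer_interval
#' @export
n_transfers <- function(exp) {
  attr(exp, "n_transfers") %||%
    as.integer(max(exp$day) / transfer_interval(exp))
}

#' Read a long-format ASV abundance table
#'
#' Tab-delimited UTF-8 text with header columns `microcosm_id`, `treatment`,
#' `day`, `asv_id`, `count` (optionally `inoculum_id`); lines starting with
#' `#` are schema comments and skipped. Missing `(day, asv)` cells are zeros.
#'
#' @param path file path.
#' @inheritParams as_experiment
#' @return a `transfer_experiment` tibble.
#' @export
read_abundance_long <- function(path, transfer_interval = 3,
                                n_transfers = NULL) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  as_experiment(df, transfer_interval = transfer_interval,
                n_transfers = n_transfers)
}

schema_comment <- function(what) {
  paste0("# serialtransfer ", what, " v1")
}

#' Write an experiment as a long-format TSV
#'
#' Emits a `#` schema-version comment line followed by a tab-delimited table.
#' `read_abundance_long(write_abundance_long(exp, path))` reproduces the
#' counts exactly.
#'
#' @param exp a `transfer_experiment`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_abundance_long <- function(exp, path) {
  writeLines(schema_comment("abundance-long"), path)
  out <- as_tibble(exp) %>%
    select("microcosm_id", "inoculum_id", "treatment", "day", "asv_id",
           "count")
  readr::write_tsv(out, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Validate experiment invariants
#'
#' Checks the container's structural invariants and returns violations as
#' data rather than raising: relative abundances summing to one per non-empty
#' sample, non-negative counts, consistent replicate pairing, and zero-read
#' samples (flagged, not dropped).
#'
#' @param exp a `transfer_experiment`.
#' @return tibble with columns `microcosm_id`, `treatment`, `rule`, `detail`;
#'   zero rows when all invariants hold.
#' @export
validate_experiment <- function(exp) {
  v <- list()
  tbl <- as_tibble(exp)
  if (any(tbl$count < 0)) {
    bad <- tbl %>% filter(.data$count < 0) %>%
      distinct(.data$microcosm_id, .data$treatment) %>%
      mutate(rule = "non_negative_counts", detail = "negative count present")
    v <- c(v, list(bad))
  }
  sums <- tbl %>%
    group_by(.data$microcosm_id, .data$treatment, .data$day) %>%
    summarise(total = sum(.data$count), rel = sum(.data$rel_abundance),
              .groups = "drop")
  bad_rel <- sums %>% filter(.data$total > 0, abs(.data$rel - 1) > 1e-9)
  if (nrow(bad_rel) > 0) {
    v <- c(v, list(bad_rel %>%
      mutate(rule = "rel_abundance_sums_to_one",
             detail = sprintf("day %d sums to %.6f", .data$day, .data$rel)) %>%
      select("microcosm_id", "treatment", "rule", "detail")))
  }
  zero <- sums %>% filter(.data$total == 0)
  if (nrow(zero) > 0) {
    v <- c(v, list(zero %>%
      mutate(rule = "zero_read_sample",
             detail = sprintf("day %d has zero total reads", .data$day)) %>%
      select("microcosm_id", "treatment", "rule", "detail")))
  }
  inoc <- tbl %>% distinct(.data$microcosm_id, .data$treatment,
                           .data$inoculum_id) %>%
    count(.data$microcosm_id, .data$treatment) %>% filter(.data$n > 1)
  if (nrow(inoc) > 0) {
    v <- c(v, list(inoc %>%
      mutate(rule = "single_inoculum_per_series",
             detail = "series maps to multiple inoculum ids") %>%
      select("microcosm_id", "treatment", "rule", "detail")))
  }
  if (length(v) == 0) {
    tibble(microcosm_id = character(), treatment = character(),
           rule = character(), detail = character())
  } else {
    bind_rows(v)
  }
}

#' Split an experiment into per-series count matrices
#'
#' Internal working representation: one entry per `(microcosm, treatment)`
#' series holding a `days x ASVs` matrix.
#'
#' @param exp a `transfer_experiment`.
#' @param value `"count"` or `"rel_abundance"`.
#' @return named list; each element has `microcosm_id`, `treatment`,
#'   `inoculum_id`, `days` (sorted integer vector) and `mat`
#'   (days x ASVs matrix with dimnames).
#' @export
series_matrices <- function(exp, value = c("count", "rel_abundance")) {
  value <- match.arg(value)
  tbl <- as_tibble(exp)
  keys <- tbl %>% distinct(.data$microcosm_id, .data$treatment,
                           .data$inoculum_id) %>%
    arrange(.data$microcosm_id, .data$treatment)
  out <- purrr::pmap(keys, function(microcosm_id, treatment, inoculum_id) {
    sub <- tbl[tbl$microcosm_id == microcosm_id &
                 tbl$treatment == treatment, ]
    days <- sort(unique(sub$day))
    asvs <- sort(unique(sub$asv_id))
    mat <- matrix(0, length(days), length(asvs),
                  dimnames = list(as.character(days), asvs))
    mat[cbind(match(sub$day, days), match(sub$asv_id, asvs))] <- sub[[value]]
    list(microcosm_id = microcosm_id, treatment = treatment,
         inoculum_id = inoculum_id, days = days, mat = mat)
  })
  names(out) <- paste(keys$microcosm_id, keys$treatment, sep = "|")
  out
}

#' Read and write auxiliary measurement tables
#'
#' Function profiles are CSV with columns `microcosm_id`, `day` and one
#' column per substrate (31 for an EcoPlate); CO2 tables have columns
#' `microcosm_id`, `day`, `percent_co2`; activity tables have `asv_id` plus
#' one column per enzyme class (strain replicates pre-averaged). Writers
#' prepend a `#` schema comment; readers skip it.
#'
#' @param path file path.
#' @return a tibble.
#' @export
read_function_profiles <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if (!all(c("microcosm_id", "day") %in% names(df))) {
    abort("function profile table needs microcosm_id and day columns")
  }
  subs <- setdiff(names(df), c("microcosm_id", "day"))
  if (anyDuplicated(df[, c("microcosm_id", "day")])) {
    abort("duplicate (microcosm_id, day) rows in function profile table")
  }
  if (any(as.matrix(df[subs]) < 0, na.rm = TRUE)) {
    abort("negative substrate responses; run process_function_profiles first")
  }
  as_tibble(df)
}

#' @rdname read_function_profiles
#' @param tbl tibble to write.
#' @param what schema tag for the comment line.
#' @export
write_csv_with_schema <- function(tbl, path, what = "table") {
  writeLines(schema_comment(what), path)
  readr::write_csv(tbl, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' @rdname read_function_profiles
#' @export
read_co2_table <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if (!all(c("microcosm_id", "day", "percent_co2") %in% names(df))) {
    abort("CO2 table needs microcosm_id, day, percent_co2 columns")
  }
  if (any(df$percent_co2 < 0)) abort("percent_co2 must be non-negative")
  as_tibble(df)
}

#' @rdname read_function_profiles
#' @export
read_activity_table <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if (!"asv_id" %in% names(df)) abort("activity table needs asv_id column")
  if (anyDuplicated(df$asv_id)) {
    abort("one row per ASV required (average strain replicates first)")
  }
  num <- setdiff(names(df), "asv_id")
  if (any(as.matrix(df[num]) < 0, na.rm = TRUE)) {
    abort("activities must be non-negative")
  }
  as_tibble(df)
}
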