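#' Configuration for the synthetic serial-transfer generator
#'
#' Defaults emulate the study design the pipeline targets: ten inocula grown
#' as filtered/unfiltered replicate pairs, sampled at Day 0 and after each of
#' 21 transfers at 3-day intervals. Half of the ASVs present at transfer 1
#' are destined to go extinct, each at a constant per-transfer hazard
#' (geometric extinction times); survivors follow mean-reverting random walks
#' on latent log abundance whose innovations are shared across replicate
#' pairs (weight `replicate_correlation`) and, more weakly, across inocula
#' (weight `context_correlation`). Function profiles are linear mixtures of
#' sparse per-ASV substrate-use vectors, so compositionally similar samples
#' have similar functional fingerprints.
#'
#' @param n_inocula number of founding inocula (microcosms per treatment).
#' @param paired_treatments generate a filtered/unfiltered pair per inoculum.
#' @param n_transfers transfers after Day 0.
#' @param transfer_interval days between transfers.
#' @param pool_size size of the regional ASV pool.
#' @param initial_richness_range inclusive integer range of transfer-1
#'   richness per microcosm.
#' @param day0_transient_fraction transient ASVs at Day 0 (absent from
#'   transfer 1 onward), as a fraction of initial richness.
#' @param survival_fraction probability `s` that an ASV present at transfer 1
#'   persists indefinitely.
#' @param extinction_rate per-transfer extinction probability `p` for doomed
#'   ASVs, in (0, 1].
#' @param replicate_fate_agreement probability that the unfiltered replicate
#'   inherits its pair's survive/extinct fate rather than redrawing it.
#' @param context_correlation,replicate_correlation innovation-sharing
#'   weights across inocula and within replicate pairs; must satisfy
#'   `replicate_correlation >= context_correlation`.
#' @param walk_reversion,walk_noise mean-reversion strength and innovation
#'   standard deviation of the latent walk.
#' @param read_depth multinomial reads per sample.
#' @param n_substrates substrates per function profile (31 = EcoPlate).
#' @param substrate_sparsity probability a given substrate is used by a given
#'   ASV.
#' @param function_noise Gaussian noise s.d. added to substrate responses.
#' @param couple_occupancy_abundance give widely occurring ASVs higher mean
#'   latent abundance (occupancy-abundance coupling).
#' @param rng_seed integer seed; the whole experiment is generated from one
#'   stream seeded once.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_inocula = 10,
                             paired_treatments = TRUE,
                             n_transfers = 21,
                             transfer_interval = 3,
                             pool_size = 300,
                             initial_richness_range = c(20L, 80L),
                             day0_transient_fraction = 1.0,
                             survival_fraction = 0.5,
                             extinction_rate = 0.3,
                             replicate_fate_agreement = 0.9,
                             context_correlation = 0.3,
                             replicate_correlation = 0.95,
                             walk_reversion = 0.4,
                             walk_noise = 0.5,
                             read_depth = 50000,
                             n_substrates = 31,
                             substrate_sparsity = 0.3,
                             function_noise = 0.05,
                             couple_occupancy_abundance = TRUE,
                             rng_seed = 1L) {
  cfg <- list(n_inocula = n_inocula, paired_treatments = paired_treatments,
              n_transfers = n_transfers, transfer_interval = transfer_interval,
              pool_size = pool_size,
              initial_richness_range = as.integer(initial_richness_range),
              day0_transient_fraction = day0_transient_fraction,
              survival_fraction = survival_fraction,
              extinction_rate = extinction_rate,
              replicate_fate_agreement = replicate_fate_agreement,
              context_correlation = context_correlation,
              replicate_correlation = replicate_correlation,
              walk_reversion = walk_reversion, walk_noise = walk_noise,
              read_depth = read_depth, n_substrates = n_substrates,
              substrate_sparsity = substrate_sparsity,
              function_noise = function_noise,
              couple_occupancy_abundance = couple_occupancy_abundance,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  frac <- c("day0_transient_fraction", "survival_fraction",
            "replicate_fate_agreement", "context_correlation",
            "replicate_correlation", "substrate_sparsity")
  for (f in frac) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      abort(paste0("config error: ", f, " must be in [0, 1]"))
    }
  }
  if (cfg$extinction_rate <= 0 || cfg$extinction_rate > 1) {
    abort("config error: extinction_rate must be in (0, 1]")
  }
  if (cfg$replicate_correlation < cfg$context_correlation) {
    abort("config error: replicate_correlation must be >= context_correlation")
  }
  if (any(c(cfg$n_inocula, cfg$n_transfers, cfg$pool_size,
            cfg$n_substrates) < 1) || cfg$read_depth < 0) {
    abort("config error: sizes must be positive")
  }
  if (max(cfg$initial_richness_range) > cfg$pool_size) {
    abort("config error: initial richness exceeds pool_size")
  }
  if (cfg$walk_noise < 0 || cfg$function_noise < 0) {
    abort("config error: noise levels must be non-negative")
  }
  invisible(cfg)
}

#' Draw geometric extinction times with truncation
#'
#' i.i.d. draws from the geometric distribution on \{1, 2, ...\} with success
#' probability `p` (`P(t) = p (1 - p)^(t - 1)`); draws exceeding `cap` are
#' redrawn, so the result follows the geometric distribution truncated to
#' `[1, cap]`.
#'
#' @param n number of draws.
#' @param p per-transfer extinction probability in (0, 1].
#' @param cap largest allowed value (`Inf` for no truncation).
#' @param seed integer seed.
#' @return integer vector of length `n`.
#' @export
simulate_extinction_times <- function(n, p, cap = Inf, seed = 1L) {
  if (p <= 0 || p > 1) abort("p must be in (0, 1]")
  with_seed(seed, draw_truncated_geometric(n, p, cap))
}

# uses the current RNG stream
draw_truncated_geometric <- function(n, p, cap = Inf) {
  if (n == 0) return(integer(0))
  t <- rgeom(n, p) + 1L
  while (any(t > cap)) {
    i <- which(t > cap)
    t[i] <- rgeom(length(i), p) + 1L
  }
  as.integer(t)
}

#' Simulate latent survivor trajectories
#'
#' Mean-reverting walk on latent log abundance,
#' `l(t + 1) = l(t) + theta (mu - l(t)) + sigma e(t)`, for transfers
#' `t = 0 .. n_transfers`. The innovation for the series of inoculum `i`
#' under a given treatment decomposes as
#' `e = sqrt(rho_c) g + sqrt(rho_r - rho_c) h_i + sqrt(1 - rho_r) z`,
#' with `g` shared by every series carrying the ASV, `h_i` shared within the
#' replicate pair, and `z` private, so replicate pairs share innovations at
#' weight `rho_r = replicate_correlation` and series from different inocula
#' at weight `rho_c = context_correlation`. Initial values are shared within
#' a replicate pair (one inoculum aliquot). ASVs fated to go extinct follow a
#' deterministic log-linear ramp from their initial latent value down to a
#' detection-floor logit at their extinction transfer and are absent (`-Inf`)
#' afterwards.
#'
#' @param cfg a [synthetic_config()].
#' @param membership tibble with columns `asv_id`, `inoculum_id` listing each
#'   inoculum's transfer-1 pool.
#' @param fates tibble with columns `asv_id`, `inoculum_id`, `treatment`,
#'   `fate` (`"survivor"`/`"doomed"`) and `extinction_transfer` (`NA` for
#'   survivors).
#' @param seed integer seed.
#' @return named list (one element per `(inoculum, treatment)` series,
#'   `"<inoculum>|<treatment>"`) of latent matrices, ASVs x transfers
#'   `0..n_transfers`.
#' @export
simulate_survivor_trajectories <- function(cfg, membership, fates, seed = 1L) {
  with_seed(seed, {
    pool_ids <- sort(unique(membership$asv_id))
    mu <- setNames(rnorm(length(pool_ids), 0, 0.8), pool_ids)
    simulate_trajectories_stream(cfg, membership, fates, mu)
  })
}

# core walk simulation, consuming the caller's RNG stream
simulate_trajectories_stream <- function(cfg, membership, fates, mu,
                                         floor_logit = -4) {
  n_t <- cfg$n_transfers
  treatments <- if (cfg$paired_treatments) c("filtered", "unfiltered")
                else "filtered"
  inocula <- sort(unique(membership$inoculum_id))
  rc <- cfg$context_correlation
  rr <- cfg$replicate_correlation
  theta <- cfg$walk_reversion
  sigma <- cfg$walk_noise
  pool_ids <- sort(unique(membership$asv_id))
  # innovation components shared across all series carrying an ASV
  G <- matrix(rnorm(length(pool_ids) * n_t), length(pool_ids), n_t,
              dimnames = list(pool_ids, NULL))
  out <- list()
  for (ino in inocula) {
    m <- sort(membership$asv_id[membership$inoculum_id == ino])
    k <- length(m)
    l0 <- mu[m] + rnorm(k, 0, 0.7)      # shared by the replicate pair
    H <- matrix(rnorm(k * n_t), k, n_t) # shared within the pair
    for (tr in treatments) {
      Z <- matrix(rnorm(k * n_t), k, n_t)
      eps <- sqrt(rc) * G[m, , drop = FALSE] +
        sqrt(max(rr - rc, 0)) * H + sqrt(max(1 - rr, 0)) * Z
      L <- matrix(NA_real_, k, n_t + 1,
                  dimnames = list(m, as.character(0:n_t)))
      L[, 1] <- l0
      for (t in seq_len(n_t)) {
        L[, t + 1] <- L[, t] + theta * (mu[m] - L[, t]) + sigma * eps[, t]
      }
      f <- fates[fates$inoculum_id == ino & fates$treatment == tr, ]
      doomed <- f[f$fate == "doomed", ]
      for (j in seq_len(nrow(doomed))) {
        a <- doomed$asv_id[j]
        T_ext <- doomed$extinction_transfer[j]
        ramp_t <- seq_len(T_ext)          # present at transfers 1..T_ext
        start <- L[a, 2]
        frac <- if (T_ext > 1) (ramp_t - 1) / (T_ext - 1) else rep(1, 1)
        L[a, ramp_t + 1] <- start + frac * (floor_logit - start)
        if (T_ext < n_t) L[a, (T_ext + 2):(n_t + 1)] <- -Inf
      }
      out[[paste(ino, tr, sep = "|")]] <- L
    }
  }
  out
}

#' Multinomially sample sequencing reads from true compositions
#'
#' Each row of `true_rel` is a sample's true relative-abundance vector; reads
#' are a multinomial draw of size `depth`. Detection is `count >= 1`.
#'
#' @param true_rel matrix of fractions, rows summing to 1 (within 1e-9).
#' @param depth reads per sample.
#' @param seed integer seed.
#' @return integer matrix of the same shape and dimnames.
#' @export
sample_reads <- function(true_rel, depth, seed = 1L) {
  true_rel <- as.matrix(true_rel)
  rs <- rowSums(true_rel)
  if (any(abs(rs - 1) > 1e-9)) {
    abort("rows of true_rel must sum to 1")
  }
  with_seed(seed, sample_reads_stream(true_rel, depth))
}

sample_reads_stream <- function(true_rel, depth) {
  out <- t(apply(true_rel, 1, function(pr) {
    if (depth == 0) rep(0L, length(pr)) else
      as.integer(rmultinom(1, depth, pr))
  }))
  dimnames(out) <- dimnames(true_rel)
  out
}

#' Generate function profiles and CO2 series coupled to composition
#'
#' A sample's substrate profile is the abundance-weighted mixture of sparse,
#' non-negative per-ASV substrate-use vectors plus Gaussian noise (clipped at
#' zero), so samples with similar composition get similar functional
#' fingerprints. CO2 is a common level with small noise from transfer 1
#' onward and inflated variance at Day 0, mimicking rapid respiratory
#' convergence.
#'
#' @param cfg a [synthetic_config()].
#' @param abundance a `transfer_experiment` (profiles are generated for its
#'   filtered series, one per microcosm).
#' @param truth a `synthetic_truth` object carrying the per-ASV substrate
#'   vectors, or `NULL` to draw fresh ones.
#' @param seed integer seed.
#' @return list with `function_profiles` (tibble: `microcosm_id`, `day`, one
#'   column per substrate) and `co2` (tibble: `microcosm_id`, `day`,
#'   `percent_co2`).
#' @export
generate_function_data <- function(cfg, abundance, truth = NULL, seed = 1L) {
  with_seed(seed, {
    U <- if (!is.null(truth)) attr(truth, "substrate_use") else
      draw_substrate_use(cfg, sort(unique(abundance$asv_id)))
    generate_function_data_stream(cfg, abundance, U)
  })
}

draw_substrate_use <- function(cfg, asv_ids) {
  n <- length(asv_ids)
  U <- matrix(runif(n * cfg$n_substrates, 0.3, 1.2) *
                (runif(n * cfg$n_substrates) < cfg$substrate_sparsity),
              n, cfg$n_substrates,
              dimnames = list(asv_ids,
                              sprintf("substrate_%02d", 1:cfg$n_substrates)))
  U
}

generate_function_data_stream <- function(cfg, abundance, U) {
  tbl <- as_tibble(abundance) %>% filter(.data$treatment == "filtered")
  samples <- tbl %>% distinct(.data$microcosm_id, .data$day) %>%
    arrange(.data$microcosm_id, .data$day)
  prof <- matrix(0, nrow(samples), cfg$n_substrates,
                 dimnames = list(NULL, colnames(U)))
  for (i in seq_len(nrow(samples))) {
    sub <- tbl[tbl$microcosm_id == samples$microcosm_id[i] &
                 tbl$day == samples$day[i], ]
    mix <- drop(crossprod(U[sub$asv_id, , drop = FALSE], sub$rel_abundance))
    prof[i, ] <- pmax(0, mix + rnorm(cfg$n_substrates, 0, cfg$function_noise))
  }
  co2 <- samples %>%
    mutate(percent_co2 = pmax(0, 5 +
      rnorm(n(), 0, ifelse(.data$day == 0, 1.0, 0.1))))
  list(function_profiles = dplyr::bind_cols(samples, as_tibble(prof)),
       co2 = co2)
}

#' Generate a complete synthetic serial-transfer experiment
#'
#' Produces an abundance [as_experiment()] table, a function-profile table, a
#' CO2 table, a per-ASV enzyme-activity table, and the generator's hidden
#' ground truth (fates, extinction transfers, substrate-use vectors), all
#' from a single RNG stream seeded once with `cfg$rng_seed`.
#'
#' Each inoculum's transfer-1 pool is drawn from the regional pool with
#' heavy-tailed occupancy weights, so most ASVs occur in few microcosms while
#' a minority recur broadly. A fraction `survival_fraction` of each pool
#' persists indefinitely; the rest go extinct at truncated-geometric
#' transfers with rate `extinction_rate`, declining log-linearly to a
#' detection-floor abundance so extinction transfers remain observable at the
#' configured read depth. Day 0 additionally carries transient ASVs never
#' seen after transfer 1 (initial adjustment losses).
#'
#' @param cfg a [synthetic_config()].
#' @return list of class `synthetic_experiment` with elements `experiment`,
#'   `function_profiles`, `co2`, `activities`, `ground_truth`, `config`.
#' @export
generate_experiment <- function(cfg = synthetic_config()) {
  validate_synthetic_config(cfg)
  with_seed(cfg$rng_seed, {
    pool_ids <- sprintf("ASV%04d", seq_len(cfg$pool_size))
    w <- stats::rbeta(cfg$pool_size, 0.3, 1.5)
    mu <- if (cfg$couple_occupancy_abundance) {
      lw <- log(w + 1e-8)
      0.8 * (lw - mean(lw)) / sd(lw)
    } else rnorm(cfg$pool_size, 0, 0.8)
    names(mu) <- pool_ids
    inocula <- sprintf("M%02d", seq_len(cfg$n_inocula))
    rr_range <- cfg$initial_richness_range
    richness <- sample(seq(rr_range[1], rr_range[2]), cfg$n_inocula,
                       replace = TRUE)
    members <- lapply(seq_len(cfg$n_inocula), function(i) {
      sort(sample(pool_ids, richness[i], prob = w))
    })
    names(members) <- inocula
    membership <- purrr::map2_dfr(members, inocula, function(m, ino) {
      tibble(asv_id = m, inoculum_id = ino)
    })
    treatments <- if (cfg$paired_treatments) c("filtered", "unfiltered")
                  else "filtered"
    # fates: filtered drawn i.i.d.; unfiltered replicate agrees w.p. q
    fates <- purrr::map_dfr(inocula, function(ino) {
      m <- members[[ino]]
      surv_f <- runif(length(m)) < cfg$survival_fraction
      rows <- tibble(asv_id = m, inoculum_id = ino, treatment = "filtered",
                     survivor = surv_f)
      if (cfg$paired_treatments) {
        agree <- runif(length(m)) < cfg$replicate_fate_agreement
        surv_u <- ifelse(agree, surv_f, runif(length(m)) < cfg$survival_fraction)
        rows <- bind_rows(rows, tibble(asv_id = m, inoculum_id = ino,
                                       treatment = "unfiltered",
                                       survivor = surv_u))
      }
      rows
    })
    fates$fate <- ifelse(fates$survivor, "survivor", "doomed")
    fates$extinction_transfer <- NA_integer_
    n_doomed <- sum(!fates$survivor)
    # cap at n_transfers - 1 so extinction is observable within the design
    fates$extinction_transfer[!fates$survivor] <-
      draw_truncated_geometric(n_doomed, cfg$extinction_rate,
                               cap = cfg$n_transfers - 1L)
    latent <- simulate_trajectories_stream(cfg, membership, fates, mu)
    # Day-0 transients per inoculum (shared across the replicate pair)
    transients <- lapply(inocula, function(ino) {
      n_tr <- round(cfg$day0_transient_fraction * length(members[[ino]]))
      avail <- setdiff(pool_ids, members[[ino]])
      ids <- sort(sample(avail, min(n_tr, length(avail))))
      setNames(mu[ids] - 1.5 + rnorm(length(ids), 0, 0.7), ids)
    })
    names(transients) <- inocula
    # assemble true compositions and sample reads, one sample at a time
    days <- c(0L, seq_len(cfg$n_transfers) * cfg$transfer_interval)
    rows <- list()
    for (ino in inocula) {
      for (tr in treatments) {
        L <- latent[[paste(ino, tr, sep = "|")]]
        for (t_idx in 0:cfg$n_transfers) {
          l_t <- L[, t_idx + 1]
          if (t_idx == 0) {
            l_t <- c(l_t, transients[[ino]])
          }
          present <- is.finite(l_t)
          logits <- l_t[present]
          rel <- exp(logits - max(logits))
          rel <- rel / sum(rel)
          counts <- if (cfg$read_depth > 0)
            as.integer(rmultinom(1, cfg$read_depth, rel)) else
            rep(0L, length(rel))
          keep <- counts > 0
          if (!any(keep)) next
          rows[[length(rows) + 1]] <- tibble(
            microcosm_id = ino, inoculum_id = ino, treatment = tr,
            day = days[t_idx + 1], asv_id = names(logits)[keep],
            count = counts[keep])
        }
      }
    }
    exp_tbl <- as_experiment(bind_rows(rows),
                             transfer_interval = cfg$transfer_interval,
                             n_transfers = cfg$n_transfers)
    U <- draw_substrate_use(cfg, pool_ids)
    fun <- generate_function_data_stream(cfg, exp_tbl, U)
    act_active <- matrix(runif(cfg$pool_size * 3) < 0.25, cfg$pool_size, 3)
    act_val <- matrix(runif(cfg$pool_size * 3, 1, 10), cfg$pool_size, 3) *
      act_active
    activities <- tibble(asv_id = pool_ids,
                         endochitinase = act_val[, 1],
                         protease = act_val[, 2],
                         lipase = act_val[, 3])
    truth <- fates %>%
      mutate(microcosm_id = .data$inoculum_id) %>%
      select("asv_id", "microcosm_id", "inoculum_id", "treatment", "fate",
             "extinction_transfer")
    attr(truth, "substrate_use") <- U
    attr(truth, "occupancy_weight") <- setNames(w, pool_ids)
    attr(truth, "latent_mean") <- mu
    class(truth) <- c("synthetic_truth", class(truth))
    structure(list(experiment = exp_tbl,
                   function_profiles = fun$function_profiles,
                   co2 = fun$co2,
                   activities = activities,
                   ground_truth = truth,
                   config = cfg),
              class = "synthetic_experiment")
  })
}

#' Write the artifacts of a synthetic experiment to a directory
#'
#' Writes the abundance TSV plus function/CO2/activity CSVs and a
#' ground-truth TSV in the package's on-disk formats.
#'
#' @param sim a `synthetic_experiment` from [generate_experiment()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_experiment <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_abundance_long(sim$experiment, file.path(dir, "abundance.tsv"))
  write_csv_with_schema(sim$function_profiles,
                        file.path(dir, "function_profiles.csv"),
                        "function-profiles")
  write_csv_with_schema(sim$co2, file.path(dir, "co2.csv"), "co2")
  write_csv_with_schema(sim$activities, file.path(dir, "activities.csv"),
                        "activities")
  gt <- as_tibble(sim$ground_truth)
  writeLines(schema_comment("ground-truth"), file.path(dir, "ground_truth.tsv"))
  readr::write_tsv(gt, file.path(dir, "ground_truth.tsv"), append = TRUE,
                   col_names = TRUE, progress = FALSE)
  invisible(dir)
}
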