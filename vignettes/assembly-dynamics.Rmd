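---
title: "Assembly dynamics in serial-transfer microcosms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembly dynamics in serial-transfer microcosms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serialtransfer)
```

This vignette explains the models the package implements, the assumptions
behind them, the tunable parameters and their defaults, what the synthetic
generator does and does not emulate, and the numerical choices made where
the design was genuinely open.

## The experimental design the package assumes

A set of microcosm communities is founded from distinct environmental
inocula, optionally as replicate pairs (a "filtered" community holding only
the bacterial size fraction, and an "unfiltered" replicate retaining larger
organisms such as protozoa). Communities are serially diluted into fresh
medium at a fixed interval (default every 3 days) for a fixed number of
transfers (default 21, so Day 0 through Day 63). Each transfer yields an ASV
count table per community; some transfers additionally yield a 31-substrate
community-level substrate-use profile, a CO₂ measurement, and — for strains
isolated at the end — per-ASV enzyme activities. The time coordinate is the
transfer index `t = day / interval`; Day 0 is the pre-transfer inoculum.

All tabular inputs are long (tidy) delimited text; wide matrices exist only
in memory. Missing `(day, ASV)` cells are zeros, and zero-read samples are
flagged by `validate_experiment()` rather than silently dropped.

## The geometric extinction-time model

The null model for species loss assumes each ASV that will eventually go
extinct does so with a fixed per-transfer probability `p`, independent of
time and of the other ASVs:

`P(t) = p (1 - p)^(t-1), t = 1, 2, ...`

The MLE is the inverse mean extinction time, `p_hat = 1 / mean(t)`. Three
modelling commitments matter:

- **The clock starts at transfer 1, not Day 0.** Communities lose many taxa
  between Day 0 and Day 3 while adjusting to laboratory conditions; these
  initial-adjustment losses are excluded from the at-risk pool
  (`baseline_transfer = 1`), and richness is correspondingly normalized at
  transfer 1. ASVs seen only at Day 0 never enter the extinction records.
- **Detection-limit back-fill.** An ASV detected at any later transfer is
  counted present now. This bridges dropout gaps caused by finite read
  depth, makes richness curves non-increasing by construction, and defines
  the extinction transfer as `first (back-filled) absent transfer -
  baseline`.
- **Survivors are excluded, not censored into the likelihood.** The model
  is explicitly conditional on eventual extinction, so ASVs still present at
  the final transfer contribute no likelihood terms. The package deliberately
  avoids survival-analysis machinery (no Kaplan-Meier or interval
  censoring): the conditional geometric model is the object of study.

### Model comparison

`compare_extinction_models()` contrasts a single shared `p` with one `p` per
microcosm using `B_k = ln(n) k - L`, where `L` is the log-likelihood and `k`
the parameter count. Two conventions deserve comment, both implemented
deliberately:

- The penalty uses the **log-likelihood, not twice it**, and `n` defaults to
  the **number of microcosms**, matching the formulation this pipeline
  reproduces. The textbook alternative (`n` = number of extinction events)
  is available as `n_convention = "events"`; it penalizes the
  multi-parameter model more heavily and rarely changes the winner at this
  design's scale.
- The winner is the smaller BIC; `relative_likelihood()` reports
  `exp(|B_a - B_b| / 2)` as the evidence ratio.

Because the individual-rate model nests the common one, its pooled
log-likelihood can never be smaller; the comparison is decided purely by the
penalty against the likelihood gain. A Pearson chi-squared goodness-of-fit
test (`geometric_gof()`) pools the right tail so every expected bin count is
at least 5 and uses `bins - 2` degrees of freedom (one estimated
parameter) — standard Pearson practice, chosen because no binning rule is
canonical for this model.

### Richness decay

With survivor fraction `s` (estimated as the pooled fraction of censored
records) and common rate `p`, expected relative richness after `t` transfers
is `s + (1 - s)(1 - p)^t`. On default synthetic data this curve matches the
mean back-filled relative-richness trajectory within sampling noise, and its
asymptote `s` is the "equilibrium relative richness" reported by the
pipeline (average over the last five transfers, as a percentage of the
transfer-1 value).

## Context dependence of ASV trajectories

Per series, counts are CLR-transformed after dropping ASVs never observed in
that series and adding a one-read pseudocount to every retained cell:
`clr = ln(c + 1) - mean(ln(c + 1))` per timepoint. Rows sum to zero, and the
transform is scale-invariant in the counts before the pseudocount is
applied. Pearson correlations of the same ASV's CLR series across series
pairs are grouped as `same_inoculum` (replicate pairs), `different_inoculum`
and a seeded `random_pair` null (distinct ASVs in different series,
count-matched to the same-ASV set). Three numerical choices:

- The correlation window defaults to all sampled days; a `window` argument
  restricts it (early-phase dynamics, e.g. Days 0-21, are sometimes the
  target of interest).
- Series with CLR variance below `min_var` (default 1e-10) over the window
  are skipped, not recorded as `r = 0`: Pearson is undefined there and
  silent zeros would bias the density toward 0.
- The reported mode is the argmax of a Gaussian KDE (Silverman bandwidth) on
  a 512-point grid over [-1, 1]; a continuous-density mode has no canonical
  estimator, so this one is fixed and documented.

`composition_trajectory_coupling()` relates trajectory divergence to
compositional divergence: for each series pair, the mean cosine distance
between untransformed relative-abundance series of shared ASVs persisting
past the equilibration day (default Day 21) is regressed with no intercept
on the Bray-Curtis dissimilarity between final compositions. "Final
composition" defaults to the mean composition over post-equilibration
timepoints (more stable than a single day; `final = "last_day"` switches to
the last sample only). Cosine similarity is used on the raw relative
abundances precisely because timepoints where an ASV is absent in one series
contribute zero to the inner product, removing them automatically. The
R-squared of the intercept-free fit uses the uncentered total sum of
squares, the standard convention for through-origin models.

The shared-fate test classifies each `(ASV, series)` as survivor (censored
at the final transfer) or extinct, and compares, per occupancy level `n`,
the fraction of ASVs with identical fate in all `n` series against the null
`f^(n-1)` (default `f = 0.5`) by an exact one-sided binomial test.

## Composition-function coupling

Substrate profiles are water-control-subtracted and clipped at zero (the
clip count is recorded); Bray-Curtis dissimilarities over profiles and over
compositions, matched by `(microcosm, day)`, enter a Mantel test. The Mantel
statistic is the Pearson correlation of lower-triangle entries; significance
comes from jointly permuting one matrix's rows and columns, one-tailed for
positive association, with the add-one rule
`p = (1 + #(r_perm >= r_obs)) / (n_perm + 1)` so p can never be zero. The
default 9999 permutations resolve p down to 1e-4; Procrustes (PROTEST, via
vegan) defaults to 999. Whether Mantel should use Pearson or Spearman on
distances is not settled usage; Pearson is the default (vegan's too) and
`method = "spearman"` is exposed.

Ordination defaults to classical scaling (PCoA): it is deterministic,
exactly testable (it reproduces Euclidean-embeddable distances to 1e-9), and
sufficient input for Procrustes. NMDS (two dimensions, Kruskal stress-1,
seeded restarts via `vegan::metaMDS`) is available as `method = "nmds"` for
fidelity to common practice; downstream statistics accept either. Negative
PCoA eigenvalues are dropped without correction and their count reported —
the simplest defensible default for Bray-Curtis matrices.

`cumulative_activity()` projects per-strain enzyme activities onto
composition as `C(t) = sum_a activity(a) x rel_abundance(a, t)`; ASVs
without a measured activity contribute zero.

## What the synthetic generator emulates

`generate_experiment()` produces a complete experiment bundle from one RNG
stream seeded once, so whole objects (not just marginals) are reproducible.
Its defaults are the study conditions every recovery test runs under:

| parameter | default | meaning |
|---|---|---|
| `n_inocula`, `paired_treatments` | 10, TRUE | ten inocula, filtered/unfiltered pairs |
| `n_transfers`, `transfer_interval` | 21, 3 d | Day 0 plus 21 transfers to Day 63 |
| `pool_size` | 300 | regional ASV pool |
| `initial_richness_range` | 20-80 | transfer-1 richness per microcosm |
| `day0_transient_fraction` | 1.0 | Day-0-only transients per initial ASV |
| `survival_fraction` | 0.5 | P(an initial ASV persists indefinitely) |
| `extinction_rate` | 0.3 | per-transfer hazard for doomed ASVs |
| `replicate_fate_agreement` | 0.9 | replicate inherits its pair's fate |
| `replicate_correlation`, `context_correlation` | 0.95, 0.3 | innovation sharing within pairs / across inocula |
| `walk_reversion`, `walk_noise` | 0.4, 0.5 | latent-walk dynamics |
| `read_depth` | 50000 | multinomial reads per sample |
| `n_substrates`, `substrate_sparsity`, `function_noise` | 31, 0.3, 0.05 | EcoPlate emulation |

Mechanics and the reasoning behind them:

- **Occupancy.** Each inoculum's pool is a weighted sample (Beta(0.3, 1.5)
  occupancy weights), so most ASVs occur in one or two microcosms while a
  minority recur broadly; by default widely occurring ASVs also get higher
  mean latent abundance (`couple_occupancy_abundance`), reproducing the
  occupancy-abundance pattern.
- **Fates and extinction times.** Fates are i.i.d. coin flips at
  `survival_fraction` per (ASV, inoculum); the unfiltered replicate inherits
  its pair's fate with probability 0.9, else redraws. Doomed entries draw
  truncated-geometric extinction transfers (redraw above the cap). The cap
  is `n_transfers - 1` so every doomed ASV is observably absent at the final
  transfer — a draw equal to the final transfer would be indistinguishable
  from a survivor, blurring the ground truth the recovery tests need. At
  `p = 0.3` the truncation redraws well under 0.1% of draws, so the pooled
  MLE still recovers `p` to within sampling error.
- **Survivor trajectories.** The study's data show strongly correlated
  replicate dynamics but give no quantitative trajectory model, so survivors
  follow a deliberately simple mean-reverting walk on latent log abundance
  whose innovations decompose into a global, an inoculum-level and a private
  component; the weights give replicate pairs innovation correlation
  `replicate_correlation` and cross-inoculum series `context_correlation`
  (the configuration validates `rho_rep >= rho_context`). This walk is a
  stand-in chosen to make the correlation structure tunable, not a
  mechanistic model (no consumer-resource dynamics, no predation, no
  within-experiment evolution).
- **Extinction trajectories.** Doomed ASVs decay log-linearly from their
  transfer-1 latent value to a detection-floor logit (-4, about 2x10^-4
  relative abundance at default richness — an expected ~10 reads at depth
  50000) at their extinction transfer, then are absent. Extinction is
  therefore both realistic-looking (declining, not cliff-edged) and exactly
  recoverable at the default read depth.
- **Closure and reads.** Present ASVs' latent values pass through a softmax
  to strictly positive compositions; reads are one multinomial draw per
  sample. Detection is one read, which is how sub-detection abundances and
  back-fill get exercised.
- **Function data.** Each ASV uses each substrate with probability 0.3
  (magnitudes uniform on 0.3-1.2); a sample's profile is the
  abundance-weighted mixture plus Gaussian noise (sd 0.05), clipped at zero,
  for the filtered series. CO₂ is a common level (5%) with sd 1.0 at Day 0
  and 0.1 afterwards, mimicking fast respiratory convergence.

**What passing tests on this generator do and do not show.** They show the
estimators are correct and well-calibrated under the stated model: the MLE
recovers the hidden rate, BIC selection is consistent, the Mantel test holds
its type-I error, category orderings reflect the planted correlation
structure. They do not show that real communities obey a geometric law, that
real trajectory noise is Gaussian or mean-reverting, or that real
composition-function coupling is linear — those are scientific claims about
data, not properties of the software. The generator also omits taxonomic
structure, chimeras/contamination, variable read depth, and compositional
overdispersion beyond multinomial.

## Determinism and problem sizes

Every randomized stage takes an explicit seed; `run_pipeline()` expands one
top-level seed into stage seeds by the documented rule in `sub_seed()`
(`(seed * 1009 + index) mod (2^31 - 1)`), so whole runs are byte-identical
under a fixed seed. The test suite and the acceptance script run the
generator at the default design (10 inocula x 2 treatments x 22 timepoints,
depth 50000) for multi-seed pattern checks, 10 seeds at a time; calibration
checks use 100-500 replicates at reduced sizes (e.g. 20-sample Mantel
datasets with 999 permutations, 10x50 extinction draws for BIC
consistency) — sizes chosen so each check is statistically informative while
the whole suite stays desk-scale.

## Known limitations

- Phylogenetic diversity (UniFrac, Faith's PD) is out of scope: it needs a
  tree. Any precomputed dissimilarity matrix can be supplied to
  `ordinate()`, `mantel_test()` and `procrustes_test()` instead.
- The extinction model is conditional on eventual extinction; it does not
  model the survive/extinct decision itself beyond the fraction `s`, nor
  interval-censored losses between sampled transfers.
- `composition_trajectory_coupling()` treats "final composition" and the
  equilibration day as configuration, because "final" admits several
  readings; results at the defaults should be checked against
  `final = "last_day"` for sensitivity.
- The raw-data path expects counts already denoised to ASVs; no sequence
  processing, taxonomy assignment, or BIOM/FASTQ parsing is included.
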