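# serialtransfer

Tools for analyzing community assembly in serially transferred microbial
microcosms from 16S amplicon time series. The package targets experiments of
the classic design: replicate communities founded from distinct natural
inocula (for example pitcher-plant fluid), diluted into fresh medium at a
fixed interval for tens of transfers, and profiled at every transfer by
amplicon sequencing (ASV counts), community-level substrate use (31-substrate
EcoPlate fingerprints), CO₂ output, and per-strain enzyme activities.

The scientific questions the package addresses:

- **Is species loss a memoryless process with a universal rate?** For ASVs
  destined to go extinct, the extinction-time null model is geometric: the
  probability of dropping out at transfer *t* is *P(t) = p(1 − p)^(t−1)* with
  a single per-transfer rate *p*, whose maximum-likelihood estimate is the
  inverse mean extinction time, *p̂ = 1/t̄*. A Bayesian Information Criterion
  comparison, *B_k = ln(n)·k − 𝓛*, decides between one common *p* across
  microcosms (*k* = 1) and one *p* per microcosm (*k* = number of
  microcosms); the evidence ratio is the relative likelihood *exp(ΔB/2)*.
- **How fast does richness decay, and to where?** Back-filled richness
  (counting an ASV as present whenever it is detected later, to correct for
  the sequencing detection limit) is expected to decay as
  *s + (1 − s)(1 − p)^t* relative to its transfer-1 value, where *s* is the
  fraction of ASVs that persist indefinitely.
- **How context-dependent are individual ASV trajectories?** CLR-transformed
  (centered log-ratio, with a one-read pseudocount) time series of the same
  ASV are correlated across microcosm pairs and compared between replicate
  pairs sharing an inoculum, pairs from different inocula, and a
  count-matched random-ASV null; a shared-fate test compares the fraction of
  ASVs with identical survive/extinct outcomes in *n* microcosms to the null
  *f^(n−1)*; and mean cosine distance between trajectories of shared ASVs is
  regressed (no intercept) on the Bray–Curtis dissimilarity of final
  compositions.
- **Does composition predict function?** Mantel and Procrustes (PROTEST)
  permutation tests relate Bray–Curtis dissimilarities (and ordinations) of
  composition and substrate-use profiles; CO₂ variance across microcosms
  tracks respiratory convergence; per-strain enzyme activities are projected
  onto composition as Σₐ activity(a) × frequency(a, t).

Because conclusions of this kind need recovery tests, the package ships a
seeded synthetic-experiment generator (`generate_experiment()`) that emulates
the full design — paired filtered/unfiltered microcosms, geometric
extinctions with known ground truth, context-correlated survivor walks,
multinomial read sampling, and composition-coupled function profiles — so
every stage of the pipeline can be checked against known truth at desk scale.

## Worked example

```r
library(serialtransfer)

cfg <- synthetic_config(rng_seed = 42)   # 10 inocula x 2 treatments, 21 transfers
sim <- generate_experiment(cfg)
sim$experiment
#> <transfer_experiment> 20 series, 285 ASVs, days 0-63 (interval 3 d)
#> # A tibble: 13,478 x 7
#>    microcosm_id inoculum_id treatment   day asv_id  count rel_abundance
#>  1 M01          M01         filtered      0 ASV0004   130       0.0026
#>  ...

rec <- extinction_times(sim$experiment)            # back-filled, baseline = transfer 1
compare_extinction_models(subset(rec, treatment == "filtered"))
#> Extinction-rate model comparison (10 groups):
#>   common p_hat = 0.3306   B_1 = 459.19
#>   individual (k = 10)   B_k = 476.18
#>   preferred: common (relative likelihood 4.89e+03)

estimate_decay_model(subset(rec, treatment == "filtered"))
#> Richness decay: s = 0.500 (survivors), p = 0.331 per transfer (238 extinct, 238 censored)

report <- run_pipeline(input = sim, seed = 42)
report
#> Serial-transfer pipeline report
#>   common extinction rate p_hat = 0.3306 (GOF p = 0.537)
#>   B_1 = 459.2, B_k = 476.2 -> common model (rel. likelihood 4.89e+03)
#>   survival fraction s = 0.500; equilibrium relative richness = 50.2%
#>   richness regression R^2 = 0.697
#>   correlation means: same inoc 0.855 | diff inoc 0.153 | random 0.114
#>   coupling R^2 (no intercept) = 0.880
#>   Mantel r = 0.5223 (p = 0.001); Procrustes corr = 0.5274 (p = 0.164)
```

Reading the output: the generator hid a common extinction rate of 0.3 and a
survival fraction of 0.5; the fitted common rate is p̂ = 0.33, the BIC
comparison prefers the single-rate model, recovered *s* = 0.50, and relative
richness equilibrates at ~50% of its transfer-1 value. Replicate pairs
sharing an inoculum correlate far more strongly (mean r = 0.86) than the same
ASV across different inocula (0.15), which in turn edges out random ASV pairs
(0.11) — trajectory dynamics are dominated by community context, not species
identity. The Mantel test confirms that compositionally similar samples have
similar substrate-use fingerprints.

Per-stage functions (`backfilled_richness()`, `clr_transform()`,
`trajectory_correlations()`, `mantel_test()`, `procrustes_test()`,
`shared_fate_test()`, ...) expose every intermediate as a tibble;
`tidy()`/`glance()` methods summarize fitted objects, and
`autoplot()`/`plot_*()` helpers draw the standard diagnostic figures. Real
data enter through `read_abundance_long()` (long TSV: microcosm, treatment,
day, ASV, count) plus CSV readers for function, CO₂, and activity tables; see
the methods vignette (`vignettes/assembly-dynamics.Rmd`) for the model
details and numerical choices.

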