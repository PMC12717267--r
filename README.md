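# airedna

Analysis of multi-decadal biodiversity time series reconstructed from
airborne environmental DNA (eDNA).

High-volume aerosol samplers (e.g. radionuclide monitoring stations) pump
more than 100,000 m³ of air per week through filters that are archived for
decades. Shotgun sequencing of those filters, followed by taxonomic read
classification, yields a genus-by-week read-count table spanning the whole
tree of life. `airedna` implements the statistical chain that turns such a
table into biodiversity inferences, for ecologists and molecular-monitoring
groups working with archival air (or comparable eDNA) time series:

* **Taxon filtering** — a gradient-boosted classifier separates genuine
  detections from classifier false positives using 31 documented statistics
  on abundance level, detection frequency, per-read classification quality
  (distinct-minimizer ratios, confidence) and database/genome footprint,
  trained on occurrence-curated labels (≥ 4 records within 40 km → positive;
  none within 5000 km and no unsequenced-family conflict → negative), with a
  stratified holdout and an inclusive 0.75 probability threshold.
* **Compositional geometry** — prevalence filtering (zero in ≥ 2/3 of weeks),
  geometric Bayesian-multiplicative zero replacement, CLR/ILR/pivot log-ratio
  transforms with stored invertible bases, and the variation matrix
  T_ij = var(ln x_i/x_j).
* **Detrending** — per-coordinate Gaussian GLMs of weekly mean read length
  (identity/log/inverse links, AIC selection) and partial-RDA conditioning on
  filter manufacturer and human-read fraction.
* **Temporal assemblages** — Ward clustering of the variation matrix,
  cluster-level abundance shares, seasonal fingerprints.
* **Diversity partition** — Hill/Rényi α (evenness), β = exp of the Rényi
  divergence from a pooled reference (temporal distinctiveness) and
  γ = α·β (exponential cross-entropy; weekly contribution to total
  biodiversity), with exact per-genus γ contributions at q = 1 and
  era contrasts via Wilcoxon signed-rank tests with Hodges–Lehmann
  intervals and Benjamini–Hochberg adjustment.
* **Structural state-space models** — local-linear-trend and
  integrated-random-walk models with trigonometric seasonality and
  spike-and-slab regression, Gibbs-sampled (C++ FFBS core), compared by
  leave-future-out ELPD; residual and convergence diagnostics.
* **Survey cross-validation** — survey routes as observers of a shared
  latent trend with route-specific AR(1) errors (Kalman MLE), correlated
  with eDNA annual indices by OLS on z-scores.
* **Catchment and receptor models** — back-trajectory endpoint binning into
  8 directions × 11 distance classes (2–860 km), moving-block bootstrap
  standard errors, Monte-Carlo half-mass radii, and simplified quantitative
  transport bias analysis (SQTBA) source fields with wind roses.
* **Synthetic data** — a seed-deterministic generator that plants cluster
  structure, a surge genus (40% → 80% community share), read-length and
  batch biases, spurious genera, biased trajectories and trend-coupled
  surveys, so every method is tested by ground-truth recovery.

## Worked example

Simulate a 120-genus, 200-week community with 20 spiked false positives,
filter it, and push it through clustering, diversity partition and a trend
model:

```r
library(airedna)

cfg    <- synthetic_config(n_genera = 120, n_weeks = 200, n_clusters = 5,
                           n_spurious_genera = 20, seed = 1)
truth  <- make_community(cfg)
counts <- sample_reads(truth, cfg)
spiked <- spike_false_positives(counts, truth, cfg)
spiked$counts
#> count_matrix: 140 genera x 200 weeks, 2.02e+07 total reads

features <- build_features(spiked$counts, spiked$summaries)
model    <- train_filter(features, spiked$labels, seed = 1)
model
#> filter_model: threshold 0.75; holdout (n=19) precision 1.000, recall 1.000

calls <- classify_genera(model, features)
kept  <- spiked$counts
kept$counts <- kept$counts[calls$genus[calls$call], ]
comp  <- impute_zeros(prevalence_filter(kept))
comp
#> composition_matrix: 120 genera x 200 weeks (7 cells imputed)
```

All 20 spurious genera are rejected at the 0.75 threshold and the 120
planted genera are retained. The variation-matrix clustering then recovers
the planted 5-cluster structure almost exactly:

```r
sol    <- cluster_genera(variation_matrix(comp), k = 5)
common <- intersect(names(sol$cluster), truth$genus)
adjusted_rand_index(sol$cluster[common],
                    truth$cluster[match(common, truth$genus)])
#> [1] 0.979
```

(The one "misplaced" genus is the planted surge genus, whose trajectory is
deliberately unlike its nominal cluster.) Diversity partition and the
era contrast identify the surge genus as the driver of γ-diversity change —
its contribution rises (Δγ = +0.110) while other genera decline:

```r
prof <- partition_diversity(comp)
prof
#> diversity_profile: 200 weeks, q = {1, 2, 3}; mean gamma at q=1: 17.45

ctr <- gamma_contributions(comp)
res <- contrast_periods(ctr, c(1974, 1975), c(1976, 1977))
head(res[order(res$p_adj), c("genus", "delta", "ci_lo", "ci_hi", "p_adj")], 3)
#>    genus    delta    ci_lo    ci_hi    p_adj
#> 1   g001  0.11020  0.09886  0.12055 1.43e-09
#> 10  g010 -0.01782 -0.02645 -0.01184 1.43e-09
#> 18  g018 -0.00656 -0.00836 -0.00322 1.43e-09
```

A structural trend model of the weekly log-γ series decomposes it into
seasonality and a latent trend, with residual/convergence diagnostics:

```r
g1  <- log(prof$profile$gamma[prof$profile$q == 1])
fit <- fit_ssm(g1, ssm_spec("llt",
                            regressors = seasonal_regressors(seq_along(g1)),
                            iterations = 800, burn_in = 200), seed = 1)
fit
#> ssm_fit (llt): 200 weeks (200 observed); mean slope -0.0029 [-0.0064, 0.0008]
ssm_diagnostics(fit)
#> ssm_diagnostics: F = 1.72 (p = 0.030); 5/42 significant ACF lags; KS d = 0.155; min ESS = 10; max |Geweke z| = 0.72
```

The slope interval covers zero: after accounting for seasonality, this
simulated 200-week window shows no directional γ trend (the planted surge
peaks and partially reverts within the window). `run_pipeline()` chains all
stages (simulate → filter → transform → detrend → cluster → diversity →
trends → catchment) into flat TSV/JSON outputs with a hashed manifest, and
`inst/cli/airedna.R` exposes the same stages as shell subcommands.

## Acceptance script

`scripts/acceptance.R` re-runs the full synthetic pipeline from scratch
against the installed package — community simulation, false-positive
spiking, gradient-boosted filtering, compositional transforms, detrending,
clustering, diversity partition, a state-space trend fit and the
catchment/receptor summaries — printing key recovered quantities and
writing the acceptance JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## The vignette

`vignettes/airedna-methods.Rmd` documents the models and their assumptions,
every tunable parameter with its default and rationale, what the synthetic
generator does and does not emulate, the numerical guard rails, and known
limitations.
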