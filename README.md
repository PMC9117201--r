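# paleodive

Sampling-corrected diversity dynamics from fossil occurrence data.

Regional diversity curves read directly from a fossil occurrence table are
distorted along two axes: the spatial footprint of sampling drifts and
stretches between time bins, and the fraction of once-living taxa that made
it into the record varies with preservation rate. `paleodive` is an R
toolkit for palaeobiologists that addresses both:

* **Spatial standardisation** — sliding spatial windows per time bin,
  hexagonal binning of occurrences, longitude–latitude clipping, and greedy
  minimum-spanning-tree (MST) trimming of low-data tip cells to a target
  tree length, with one-tailed Pearson/Spearman diversity-versus-extent
  diagnostics under Benjamini–Hochberg correction.
* **Hierarchical Bayesian diversity estimation** — sampled richness per
  bin is modelled as `x_t ~ Bin(D_t, p_t)`, with the sampling probability
  `p_t = 1 − exp(−q_t δ_t)` derived from time-variable Poisson preservation
  rates `q_t` (optionally averaged over gamma-distributed across-lineage
  rate multipliers `g ~ Γ(α, α)`), a Brownian prior on `log D`, and an
  MCMC sampler that resamples `(q, α)` from a preservation posterior so
  that preservation uncertainty propagates into the diversity intervals.
* **Validation machinery** — a birth–death simulator with a piecewise
  preservation process (scenario presets incl. preservation gaps and strong
  rate heterogeneity), baseline estimators (raw, range-through,
  coverage-based rarefaction, squares extrapolator), MAPE/R² scoring
  against simulated truth, and paired one-tailed comparisons.
* **Turnover** — abundance-corrected Forbes* dissimilarity
  (`F* = a(n+√n) / [a(n+√n) + 3bc/2]`) between adjacent bins, with
  coverage-standardised subsampling and a pooled-abundance null.

## A worked example

Simulate a clade, sample its fossil record, and recover true diversity:

```r
library(paleodive)

preset  <- scenario_preset("A")                      # constant-rate birth-death
lineages <- simulate_bd(root_age = 25, schedule = preset$schedule, seed = 11)
regime   <- draw_preservation_regime()               # six log-uniform rates
record   <- simulate_fossils(lineages, regime)

bins  <- time_bins_uniform(25, 0, 1)                 # 1-Myr bins
truth <- true_diversity(lineages, bins)

# preservation rates from counts and spans on the regime's intervals
sampled <- lineages[lineages$lineage %in% record$occurrences$taxon, ]
counts  <- occurrence_count_matrix(record$occurrences, regime$segments)
spans   <- span_matrix(sampled, regime$segments)[rownames(counts), ]
post <- estimate_preservation(counts, spans, iters = 10000, seed = 2)

x   <- bin_richness(assign_point_ages(record$occurrences, bins),
                    bins)$richness
fit <- run_mcmcdive(x, bins, post, preservation_bins = regime$segments,
                    iters = 50000, seed = 3)
validation_metrics(truth$d_true, summarise_trajectory(fit)$median)
#> # A tibble: 1 × 4
#>    mape    r2 r2_pearson n_bins
#>   <dbl> <dbl>      <dbl>  <int>
#> 1 0.128 0.962      0.980     25
```

The posterior-median trajectory tracks the true curve to within ~13% mean
absolute error (relative to mean true diversity), with a coefficient of
determination of 0.96 — while the raw sampled richness for the same dataset
is off by ~50%. `tidy(fit)` returns the per-bin medians and HPD intervals,
`autoplot(fit)` draws the trajectory.

The same estimator runs on real occurrence tables via `read_occurrences()`,
`filter_occurrences()` (10-Myr age-uncertainty cutoff),
`randomise_ages()` (locality-shared age quantiles), `assign_bins()`
(midpoint or major-overlap rules), and the spatial workflow
(`make_window_series()`, `clip_to_windows()`, `hex_bin()`,
`standardise_lonlat()`, `standardise_mst()`,
`extent_diversity_diagnostics()`). A PyRate-compatible log interface
(`read_preservation_log()`) lets a full occurrence-level preservation
posterior stand in for the built-in estimator.

## Package layout

| Area | Functions |
| --- | --- |
| Occurrence I/O & binning | `read_occurrences`, `write_occurrences`, `filter_occurrences`, `assign_bins`, `randomise_ages`, `bin_richness`, `time_bins` |
| Spatial standardisation | `make_window_series`, `clip_to_windows`, `hex_bin`, `mst_length`, `standardise_mst`, `standardise_lonlat`, `spatial_metrics`, `extent_diversity_diagnostics` |
| Simulation | `bd_schedule`, `simulate_bd`, `draw_preservation_regime`, `simulate_fossils`, `true_diversity`, `scenario_preset` |
| Preservation | `estimate_preservation`, `compare_preservation_models`, `sampling_probability`, `occurrence_count_matrix`, `span_matrix`, `read_preservation_log`, `write_preservation_log` |
| Diversity MCMC | `dive_log_likelihood`, `dive_log_prior`, `run_mcmcdive`, `summarise_trajectory`, `tidy`, `glance`, `autoplot` |
| Baselines & scoring | `raw_and_rangethrough`, `sqs_estimate`, `squares_estimate`, `validation_metrics`, `compare_methods` |
| Turnover | `forbes_star`, `rac_forbes`, `turnover_series` |
| Study orchestration | `run_validation_study`, `make_fixtures` |

See the vignette `vignettes/diversity-estimation-methods.Rmd` for the model
details, numerical choices, and known limitations.
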