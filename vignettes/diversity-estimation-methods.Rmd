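---
title: "Estimating sampling-corrected diversity dynamics from fossil occurrences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating sampling-corrected diversity dynamics from fossil occurrences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Apparent diversity read directly off a fossil occurrence table confounds
two signals: true changes in standing richness, and changes in how much of
the world (and of its rock record) was sampled. `paleodive` implements a
workflow that attacks both axes of bias:

1. **Spatial standardisation** — sliding spatial windows, hexagonal
   occurrence binning, longitude–latitude clipping and minimum-spanning-tree
   (MST) trimming enforce a geographically consistent sampling footprint
   across time bins, with correlation diagnostics to verify that residual
   extent variation no longer tracks diversity.
2. **Temporal sampling correction** — a hierarchical Bayesian model
   estimates the true per-bin richness from the sampled richness and
   preservation rates, propagating preservation uncertainty.

A birth–death + preservation simulator provides ground truth for
validation, baseline estimators (raw, range-through, coverage-based
rarefaction, squares) provide comparators, and an abundance-corrected
Forbes* statistic measures taxonomic turnover between adjacent bins.

# The hierarchical diversity model

Within each time bin $t$ the number of sampled taxa $x_t$ is modelled as a
binomial draw from the unknown true richness $D_t$:

$$x_t \sim \mathrm{Bin}(D_t,\, p_t)$$

where $p_t$ is the probability that a taxon alive in bin $t$ is sampled at
least once. Under a time-variable Poisson preservation process with rate
$q_t$ (expected occurrences per lineage per Myr) and bin duration
$\delta_t$,

$$p_t = 1 - e^{-q_t\,\delta_t}.$$

When preservation rates vary across lineages, per-lineage multipliers
$g \sim \Gamma(\alpha, \alpha)$ (mean 1) are integrated over a deterministic
grid of $R = 1000$ midpoint quantiles:

$$p_t = \frac{1}{R}\sum_{i=1}^{R} \left(1 - e^{-q_t g_i \delta_t}\right),$$

which is always smaller than the homogeneous probability at the same mean
rate, because the gamma distribution is right-skewed and the rate-to-
probability map is concave. We use quantile discretisation rather than
random draws so that $p_t$ is a deterministic function of $(q_t, \alpha)$;
the difference from Monte-Carlo averaging is bounded by the Monte-Carlo
error itself (checked in the test suite).

Temporal autocorrelation of diversity is encoded by a Brownian prior on the
log trajectory,

$$\log D_t \sim \mathcal{N}\!\left(\log D_{t-1},\ \sqrt{\sigma^2\,\delta_t}\right),$$

with a vague prior on the first bin and an $\mathrm{Exp}(1)$ hyperprior on
the Brownian variance $\sigma^2$. The posterior
$P(D, \sigma^2 \mid x, q, \alpha)$ is sampled by Metropolis–Hastings:
multiplicative sliding-window proposals on a random 30% of the $D$
coordinates per iteration (floored at $x_t$, which is a hard bound of the
model), a multiplicative proposal on $\sigma^2$, and — every 10 iterations —
a fresh $(q, \alpha)$ draw from the preservation posterior so that
preservation uncertainty widens the diversity intervals rather than being
ignored. Proposal windows self-tune towards roughly 25% acceptance during
burn-in only, so the post-burn-in chain is a fixed-kernel sampler.

Numerical choices: $D_t$ is treated as continuous (the binomial coefficient
is generalised via log-gamma), which avoids integer reversible-jump
proposals and changes nothing material at the scales involved; the vague
first-bin prior contributes zero to the log-prior and is proper in effect
because the likelihood bounds $D_0$ below by $x_0$ and stochastically above;
burn-in defaults to 20% with thinning to at most 2000 retained samples;
$p_t = 0$ with $x_t > 0$ is treated as an impossible datum ($-\infty$).

# Preservation-rate estimation

The preservation module estimates $q_t$ (and $\alpha$) from per-taxon,
per-interval occurrence counts $c_{i,t}$ and residence spans
$\Delta_{i,t}$:

$$c_{i,t} \sim \mathrm{Poisson}(q_t\, g_i\, \Delta_{i,t}), \qquad
  g_i \sim \Gamma(\alpha, \alpha).$$

The multipliers are marginalised analytically (a negative-binomial form in
the per-lineage totals), and the likelihood is conditioned on each included
lineage having been sampled at least once — only sampled lineages are
observable, and ignoring that truncation inflates $q$. Priors follow a
regularising hierarchy: $q_t \sim \Gamma(2, \beta)$ with the rate
hyperparameter $\beta$ given an $\mathrm{Exp}(1)$ hyperprior
(Gibbs-updated), and a vague exponential prior on $\alpha$.

This module is deliberately a *simplified stand-in* for a full
occurrence-level Bayesian preservation analysis: it conditions on known
spans (true spans from simulation; range-through spans for empirical data)
instead of jointly inferring origination and extinction times. The
posterior log reader/writer is compatible with PyRate-style mcmc logs
(`q_0 ... q_T` plus `alpha` columns), so a posterior produced by the full
machinery can be substituted anywhere a preservation posterior is accepted.

# The simulator

`simulate_bd()` runs a forward continuous-time birth–death process from one
lineage at the root age (default 25 Ma), with piecewise-constant rate
schedules, and rejection-samples until the *total* species count falls in
100–500 — the count before preservation sampling, since sampling can only
reduce observed richness. `draw_preservation_regime()` draws six rates
log-uniformly on $[0.25, 2.5]$ (so most rates are small) with shifts fixed
at 23, 15, 8, 5.3 and 2.6 Ma; optional gap intervals force complete
preservation failure. `simulate_fossils()` samples occurrences exactly per
constant-rate segment (Poisson count + uniform times), with optional
$\Gamma(0.5, 0.5)$ per-lineage multipliers — at mean rate 1 the implied 95%
interval of lineage rates runs from below 0.001 to about 5, i.e. strong
heterogeneity.

Scenario presets A–F wire these together: A constant rates
($\lambda = 0.3$, $\mu = 0.1$ per lineage per Myr), B adds two complete
preservation gaps (15–8 and 5.3–2.6 Ma), C shifts the diversification
regime at 12 Ma, D adds gamma heterogeneity to A, E inserts a brief
mass-extinction pulse ($\mu = 2.5$ for 0.5 Myr), and F combines C with
heterogeneity. The birth–death settings are package defaults chosen so that
clades of 100–500 species arise with workable acceptance rates over a
25-Myr span; they are configuration, not estimates.

What the simulator does *not* emulate: spatially structured sampling (all
validation runs are aspatial), taxonomic error, and age uncertainty of
individual occurrences (the occurrence module's locality-shared age
randomisation covers that workflow for empirical data). Passing validation
therefore demonstrates correct sampling correction under the stated
preservation model, not robustness to every empirical pathology.

# Validation design

For each simulated dataset the study pipeline estimates preservation on the
regime's six intervals (using true lineage spans), runs the diversity MCMC
in 1-Myr bins, and scores the posterior-median trajectory against true
standing diversity with two statistics: **MAPE**, the mean absolute
true-vs-estimated difference across bins divided by mean true diversity,
and **R²**, the coefficient of determination proper,
$1 - SS_{res}/SS_{tot}$, of the estimate against the truth. This definition
punishes systematic scale bias and can go negative for degenerate
estimators (a constant line through varying truth), both of which are
informative properties for a validation statistic. Because probabilistic
diversity estimators are known to underestimate absolute diversity under
strong across-lineage rate heterogeneity, the squared Pearson correlation —
a symmetric trend-agreement measure insensitive to scale offsets — is also
returned as `r2_pearson`. Baselines are scored identically; bins with zero true
diversity are excluded pairwise.

Scaled-down study sizes: the packaged validation (tests and the acceptance
script) runs 20 datasets per scenario with 50,000 diversity-MCMC iterations
and 10,000 preservation-MCMC iterations — enough for stable means of the
per-dataset statistics while keeping a full two-scenario study under ten
minutes on one core.

Because the preservation stand-in conditions on true spans, its rate
estimates avoid part of the bias a full joint analysis incurs, and the
resulting errors sit at or below the reported accuracy levels — the
validation checks are therefore bounded above by the published error
levels rather than centred on them.

# Spatial standardisation choices

* **Hexagonal grid**: a regular pointy-top lattice in a cylindrical
  equal-area projection, default centre spacing 250 km. Any fixed
  hexagonal tessellation serves here — the grid is a density-binning
  device, not an analysis unit.
* **Projection for window drift**: cylindrical equal-area centred on the
  base polygon; translation in the projected plane conserves area exactly,
  and a drift that would carry the window past a pole is a fatal error.
* **MST metric**: great-circle (haversine) edge lengths on a 6371-km
  sphere over occupied cell centres; the tree is rebuilt from scratch after
  every removal (safe and unambiguous; incremental updates would risk
  stale topologies).
* **Trimming loop**: among unmasked degree-1 (tip) cells, remove the one
  with the smallest tally; ties resolve to the removal that moves the tree
  length closest to the target, then lexicographically by cell id. All
  visited states are recorded and the state closest to the target is
  returned, so overshoot self-corrects.
* **Longitude–latitude windows**: candidate left edges are the sorted
  unique occurrence coordinates (sufficient for the maximisation);
  membership is boundary-inclusive; ties resolve to the westernmost then
  southernmost window; antimeridian-crossing windows are not supported.
  In serial standardisation the longitude–latitude step always runs first
  and its extent-defining cells are masked from MST trimming.
* **Diagnostics**: one-tailed (positive association) Pearson and Spearman
  tests of diversity against each extent metric, Benjamini–Hochberg
  adjusted across the whole family; constant or short series are excluded
  from the family rather than imputed.

# Turnover

Forbes* similarity, $F^* = a(n + \sqrt{n}) / \left[a(n + \sqrt{n}) +
\tfrac{3}{2}bc\right]$ with $n = a + b + c$, is computed on
coverage-standardised subsamples (individuals drawn without replacement
until the parent-sample coverage share of the drawn species reaches the
quorum, default 0.5). The relative-abundance correction draws null
assemblage pairs from the pooled relative-abundance distribution at the
original sample sizes, standardises them identically, and chance-corrects
the observed dissimilarity as $(\mathrm{obs} - \mathrm{null}) / (1 -
\mathrm{null})$, clamped to $[0, 1]$. This form was chosen over a purely
subtractive correction because it preserves both anchor points — identical
assemblages score near 0 *and* fully disjoint assemblages score near 1 —
and is monotone in the true replacement fraction; all three properties are
asserted in the test suite. Assemblages too small to standardise fall back
to the uncorrected value with a flag.

# Known limitations

* The preservation module is not a substitute for joint origination/
  extinction/preservation inference; with empirical data its range-through
  spans are truncated versions of the true spans, biasing $q$ upwards.
  Use the log-file interface to bring in a full posterior instead.
* Scenario presets C–F use package-default birth–death settings; they
  exercise the machinery but are not calibrated to any published
  supplementary configuration.
* Antimeridian-crossing study regions and pole-adjacent windows are
  unsupported.
* Coverage-based rarefaction inherits the usual instability of
  coverage estimates in bins dominated by singletons; such bins are
  reported `NA` and excluded pairwise from validation scoring.
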