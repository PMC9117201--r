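# Orchestration of the simulation-based validation study:
# simulate -> estimate preservation -> diversity MCMC -> baselines -> metrics.

#' Run the simulation validation study
#'
#' For each requested scenario (see [scenario_preset()]) and dataset:
#' simulates a birth-death clade (accepted at 100-500 total species),
#' samples fossils under a randomly drawn time-variable preservation regime,
#' estimates preservation rates (homogeneous or gamma-heterogeneous model
#' matching the scenario) on the regime's intervals using true lineage
#' spans, runs the diversity MCMC in 1-Myr bins, computes the baseline
#' trajectories (raw, range-through, coverage-based rarefaction, squares),
#' and scores every method against the true diversity.
#'
#' Bins older than the clade origin or with zero true diversity are excluded
#' from scoring. Everything is deterministic given `seed`.
#'
#' @param scenarios Character vector of scenario letters.
#' @param n_datasets Datasets per scenario.
#' @param seed Integer master seed; per-dataset seeds are derived from it.
#' @param bin_width Analysis bin width, Myr (default 1).
#' @param dive_iters Diversity MCMC iterations per dataset.
#' @param pres_iters Preservation MCMC iterations per dataset.
#' @param quorum Coverage quorum for the rarefaction baseline.
#' @return List with `metrics` (long tibble: scenario, dataset, method,
#'   mape, r2, r2_pearson) and `comparisons` (per-scenario paired one-tailed
#'   t-tests of the diversity MCMC against each baseline).
#' @export
run_validation_study <- function(scenarios = "A", n_datasets = 20,
                                 seed = 1, bin_width = 1,
                                 dive_iters = 50000, pres_iters = 10000,
                                 quorum = 0.5) {
  metrics <- list()
  for (sc in scenarios) {
    for (ds in seq_len(n_datasets)) {
      ds_seed <- as.integer((as.numeric(seed) * 10000 +
                               match(sc, LETTERS) * 1000 + ds) %% 2147483647)
      m <- run_one_dataset(sc, ds_seed, bin_width, dive_iters, pres_iters,
                           quorum)
      m$scenario <- sc
      m$dataset <- ds
      metrics[[length(metrics) + 1]] <- m
    }
  }
  metrics <- dplyr::bind_rows(metrics)
  comparisons <- metrics |>
    dplyr::group_by(.data$scenario) |>
    dplyr::group_modify(~ compare_methods(.x)) |>
    dplyr::ungroup()
  list(metrics = metrics, comparisons = comparisons)
}

# Simulate, estimate and score one dataset; returns one row per method.
run_one_dataset <- function(scenario, seed, bin_width = 1,
                            dive_iters = 50000, pres_iters = 10000,
                            quorum = 0.5) {
  preset <- scenario_preset(scenario)
  lineages <- simulate_bd(root_age = preset$root_age,
                          schedule = preset$schedule, seed = seed)
  regime <- draw_preservation_regime(
    heterogeneity = preset$heterogeneity, alpha = preset$alpha,
    gaps = preset$gaps, root_age = preset$root_age)
  record <- simulate_fossils(lineages, regime)
  bins <- time_bins_uniform(preset$root_age, 0, bin_width)
  truth <- true_diversity(lineages, bins)

  # preservation estimation on the regime's intervals, true spans
  intervals <- regime$segments
  sampled <- lineages[lineages$lineage %in%
                        unique(record$occurrences$taxon), , drop = FALSE]
  counts <- occurrence_count_matrix(record$occurrences, intervals)
  spans <- span_matrix(sampled, intervals)
  spans <- spans[rownames(counts), , drop = FALSE]
  # zero-rate gap intervals carry no information about q (rate fixed at 0);
  # exclude them from estimation and reinsert q = 0 afterwards
  est_cols <- which(!gap_interval(intervals))
  model <- if (preset$heterogeneity == "gamma") "gamma" else "homogeneous"
  post <- suppressWarnings(estimate_preservation(
    counts[, est_cols, drop = FALSE], spans[, est_cols, drop = FALSE],
    model = model, iters = pres_iters, seed = seed + 1))
  post <- reinsert_gap_rates(post, est_cols, nrow(intervals))

  x <- bin_richness(assign_point_ages(record$occurrences, bins), bins)$richness
  fit <- run_mcmcdive(x, bins, post, preservation_bins = intervals,
                      iters = dive_iters, seed = seed + 2)
  est <- summarise_trajectory(fit)$median

  base <- raw_and_rangethrough(record$occurrences, bins)
  ab_by_bin <- split(record$occurrences,
                     bin_index_of_age(record$occurrences$age, bins))
  sqs <- rep(NA_real_, nrow(bins))
  sqr <- rep(NA_real_, nrow(bins))
  for (b in names(ab_by_bin)) {
    ab <- as.numeric(table(ab_by_bin[[b]]$taxon))
    bi <- as.integer(b)
    sqs[bi] <- tryCatch(suppressWarnings(sqs_estimate(ab, quorum)),
                        error = function(e) NA_real_)
    sqr[bi] <- suppressWarnings(squares_estimate(ab))
  }

  score_bins <- truth$d_true > 0
  score <- function(est_vec, method) {
    dplyr::bind_cols(method = method,
                     validation_metrics(truth$d_true[score_bins],
                                        est_vec[score_bins]))
  }
  dplyr::bind_rows(
    score(est, "mcmcdive"),
    score(base$raw, "raw"),
    score(base$range_through, "range_through"),
    score(sqs, "sqs"),
    score(sqr, "squares")
  )
}

# TRUE for intervals created by a preservation gap (rate exactly zero).
gap_interval <- function(intervals) intervals$q == 0

# Re-expand a preservation posterior estimated on a subset of intervals to
# the full interval set, with rate 0 in the gap intervals.
reinsert_gap_rates <- function(post, est_cols, n_total) {
  if (length(est_cols) == n_total) return(post)
  s <- post$samples
  qcols <- grep("^q_", names(s), value = TRUE)
  full <- matrix(0, nrow(s), n_total)
  full[, est_cols] <- as.matrix(s[, qcols])
  colnames(full) <- paste0("q_", seq_len(n_total))
  out <- tibble::as_tibble(full)
  out$alpha <- s$alpha
  post$samples <- out
  post
}

#' Assign point-aged occurrences to time bins
#'
#' Attaches a `bin` index to occurrences that already carry point ages
#' (e.g. simulated records or age-randomised tables); ages outside the
#' binning are dropped. Bins are half-open `(top, base]`.
#'
#' @param occurrences Tibble with an `age` column (Ma).
#' @param bins A [time_bins()] tibble.
#' @return The occurrences with an integer `bin` column.
#' @export
assign_point_ages <- function(occurrences, bins) {
  occurrences$bin <- bin_index_of_age(occurrences$age, bins)
  occurrences[!is.na(occurrences$bin), , drop = FALSE]
}

#' Generate small deterministic example datasets
#'
#' Writes a toy occurrence table, a preservation regime description and a
#' lineage truth table to `dir`, regenerated identically for a given seed.
#' Useful as quick-start inputs and for tests.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Named character vector of the files written, invisibly.
#' @export
make_fixtures <- function(dir = tempdir(), seed = 42) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  preset <- scenario_preset("A")
  lineages <- simulate_bd(root_age = preset$root_age,
                          schedule = preset$schedule,
                          accept_range = c(20, 120), seed = seed)
  regime <- draw_preservation_regime(heterogeneity = "none",
                                     root_age = preset$root_age)
  record <- simulate_fossils(lineages, regime)
  occ <- record$occurrences
  set.seed(seed + 1)
  locs <- sprintf("loc%02d", sample.int(25, nrow(occ), replace = TRUE))
  occ_tbl <- tibble::tibble(
    taxon = occ$taxon, fad = occ$age + 0.5, lad = pmax(occ$age - 0.5, 0),
    lon = round(runif(nrow(occ), -30, 30), 3),
    lat = round(runif(nrow(occ), -20, 40), 3),
    locality = locs, abundance = 1)
  files <- c(
    occurrences = file.path(dir, "toy_occurrences.csv"),
    lineages = file.path(dir, "toy_lineages.csv"),
    regime = file.path(dir, "toy_regime.csv"))
  write_occurrences(occ_tbl, files["occurrences"])
  readr::write_csv(lineages, files["lineages"], progress = FALSE)
  readr::write_csv(regime$segments, files["regime"], progress = FALSE)
  invisible(files)
}
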