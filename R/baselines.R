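# Comparator diversity estimators and validation metrics.

#' Raw and range-through diversity trajectories
#'
#' Raw diversity is the number of distinct sampled taxa per bin.
#' Range-through diversity counts each taxon in every bin intersected by the
#' interval between its first and last sampled occurrence, so a taxon
#' sampled in bins 1 and 3 is also counted in bin 2.
#'
#' @param occurrences Tibble with `taxon` and `age` (point ages, Ma).
#' @param bins A [time_bins()] tibble.
#' @return Tibble: `bin`, `base`, `top`, `raw`, `range_through`.
#' @export
raw_and_rangethrough <- function(occurrences, bins) {
  idx <- bin_index_of_age(occurrences$age, bins)
  ok <- !is.na(idx)
  raw <- vapply(bins$bin, function(b) {
    length(unique(occurrences$taxon[ok & idx == b]))
  }, numeric(1))
  spans <- occurrences |>
    dplyr::group_by(.data$taxon) |>
    dplyr::summarise(first = max(.data$age), last = min(.data$age),
                     .groups = "drop")
  rt <- vapply(seq_len(nrow(bins)), function(b) {
    sum(spans$first > bins$top[b] & spans$last <= bins$base[b])
  }, numeric(1))
  tibble::tibble(bin = bins$bin, base = bins$base, top = bins$top,
                 raw = raw, range_through = rt)
}

# Expected coverage of a size-m subsample (Chao & Jost 2012).
expected_coverage <- function(ab, m) {
  n <- sum(ab)
  if (m >= n) return(sample_coverage(ab))
  1 - sum((ab / n) * exp(lchoose(n - ab, m) - lchoose(n - 1, m)))
}

# Estimated coverage of the full sample (Good-Turing with Chao correction).
sample_coverage <- function(ab) {
  n <- sum(ab)
  f1 <- sum(ab == 1); f2 <- sum(ab == 2)
  if (n <= 1) return(0)
  if (f1 == 0) return(1)
  A <- if ((n - 1) * f1 + 2 * f2 > 0) (n - 1) * f1 / ((n - 1) * f1 + 2 * f2) else 1
  1 - (f1 / n) * A
}

# Expected richness of a size-m subsample (classic hypergeometric rarefaction).
rarefied_richness <- function(ab, m) {
  n <- sum(ab)
  if (m >= n) return(length(ab))
  sum(1 - exp(lchoose(n - ab, m) - lchoose(n, m)))
}

#' Coverage-based rarefaction (shareholder quorum) richness estimate
#'
#' Expected species richness standardised to a target sample coverage
#' (quorum) rather than a fixed sample size. For quorums at or below the
#' observed coverage, richness is interpolated at the smallest subsample
#' size whose expected coverage reaches the quorum; above it, richness is
#' extrapolated along the coverage curve towards the Chao1 asymptote.
#'
#' @param ab Abundance vector (per-taxon counts within one bin, all >= 1).
#' @param quorum Target coverage in (0, 1).
#' @return Estimated richness; `NA` with a warning when the estimate is
#'   undefined (e.g. an all-singleton sample, whose estimated coverage is 0).
#' @export
sqs_estimate <- function(ab, quorum = 0.5) {
  stopifnot(quorum > 0, quorum < 1, length(ab) >= 1, all(ab >= 1))
  n <- sum(ab)
  if (length(ab) == 1) return(1)
  Chat <- sample_coverage(ab)
  f1 <- sum(ab == 1); f2 <- sum(ab == 2)
  if (Chat <= 0) {
    warning("all-singleton abundance vector: coverage 0, estimate unreliable",
            call. = FALSE)
    return(NA_real_)
  }
  if (quorum <= Chat) {
    for (m in seq_len(n)) {
      if (expected_coverage(ab, m) >= quorum) return(rarefied_richness(ab, m))
    }
    return(length(ab))
  }
  # extrapolation beyond the observed coverage
  S_obs <- length(ab)
  f0 <- if (f2 > 0) (n - 1) / n * f1^2 / (2 * f2) else
    (n - 1) / n * f1 * (f1 - 1) / 2
  if (f0 <= 0 || f1 == 0) return(S_obs)
  r <- (n - 1) * f1 / ((n - 1) * f1 + 2 * f2)
  mstar <- log(n / f1 * (1 - quorum)) / log(r) - 1
  if (!is.finite(mstar) || mstar < 0) return(S_obs)
  S_obs + f0 * (1 - (1 - f1 / (n * f0 + f1))^mstar)
}

#' Squares extrapolated richness
#'
#' `S = S_obs + s1^2 * sum(n_i^2) / (N^2 - s1 * S_obs)` with `s1` the
#' singleton count and `N` the total abundance. Undefined (reported `NA`
#' with a warning) when every taxon is a singleton.
#'
#' @param ab Abundance vector (counts >= 1).
#' @return Extrapolated richness, or `NA` when undefined.
#' @export
squares_estimate <- function(ab) {
  stopifnot(length(ab) >= 1, all(ab >= 1))
  S <- length(ab)
  N <- sum(ab)
  s1 <- sum(ab == 1)
  den <- N^2 - s1 * S
  if (den <= 0) {
    warning("squares estimate undefined (all singletons)", call. = FALSE)
    return(NA_real_)
  }
  S + s1^2 * sum(ab^2) / den
}

#' Error metrics of an estimated diversity trajectory
#'
#' MAPE is the mean absolute difference between true and estimated diversity
#' across bins, divided by the mean true diversity through time. `r2` is the
#' coefficient of determination of the estimate against the truth,
#' `1 - SS_res / SS_tot` (negative values possible and preserved: a constant
#' estimate of varying truth scores at or below zero). The squared Pearson
#' correlation is also returned as `r2_pearson` — a symmetric trend-agreement
#' measure insensitive to systematic scale offsets, undefined (`NA`) for
#' constant series. Bins where the estimate is missing are excluded
#' pairwise.
#'
#' @param d_true,d_est Numeric vectors of equal length (>= 2 bins).
#' @return Tibble with columns `mape`, `r2`, `r2_pearson`, `n_bins`.
#' @export
validation_metrics <- function(d_true, d_est) {
  stopifnot(length(d_true) == length(d_est), length(d_true) >= 2)
  ok <- is.finite(d_true) & is.finite(d_est)
  d_true <- d_true[ok]; d_est <- d_est[ok]
  if (mean(d_true) == 0) stop("zero mean true diversity", call. = FALSE)
  mape <- mean(abs(d_est - d_true)) / mean(d_true)
  r2_pearson <- if (stats::sd(d_est) > 0 && stats::sd(d_true) > 0) {
    cor(d_est, d_true)^2
  } else {
    NA_real_
  }
  r2 <- 1 - sum((d_est - d_true)^2) / sum((d_true - mean(d_true))^2)
  tibble::tibble(mape = mape, r2 = r2, r2_pearson = r2_pearson,
                 n_bins = sum(ok))
}

#' Paired one-tailed comparison of per-dataset errors against a reference
#'
#' For each non-reference method, a paired one-tailed t-test of whether the
#' reference method's per-dataset error is smaller than the comparator's.
#'
#' @param errors Long tibble with columns `dataset`, `method` and `mape`.
#' @param reference Name of the reference method (default `"mcmcdive"`).
#' @return Tibble: `method`, `mean_diff` (comparator - reference), `t`,
#'   `df`, `p_value`. Zero-variance differences are flagged with `p_value`
#'   0 or 1 by sign and a warning.
#' @export
compare_methods <- function(errors, reference = "mcmcdive") {
  stopifnot(reference %in% errors$method)
  wide <- tidyr::pivot_wider(errors[, c("dataset", "method", "mape")],
                             names_from = "method", values_from = "mape")
  ref <- wide[[reference]]
  others <- setdiff(unique(errors$method), reference)
  purrr::map_dfr(others, function(m) {
    cmp <- wide[[m]]
    ok <- is.finite(ref) & is.finite(cmp)
    d <- cmp[ok] - ref[ok]
    if (length(d) < 2) stop("need >= 2 paired datasets", call. = FALSE)
    if (stats::sd(d) == 0) {
      warning("zero variance of paired differences for ", m, call. = FALSE)
      p <- if (mean(d) > 0) 0 else if (mean(d) < 0) 1 else 0.5
      return(tibble::tibble(method = m, mean_diff = mean(d), t = NA_real_,
                            df = length(d) - 1, p_value = p))
    }
    tt <- t.test(ref[ok], cmp[ok], paired = TRUE, alternative = "less")
    tibble::tibble(method = m, mean_diff = mean(d),
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p_value = tt$p.value)
  })
}
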