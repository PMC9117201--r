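# Hierarchical Bayesian estimation of true diversity trajectories from
# binned sampled richness and preservation-derived sampling probabilities.
#
# Model: x_t ~ Binomial(D_t, p_t) with D_t the unknown true diversity
# (treated as continuous, >= x_t, with the binomial coefficient generalised
# through log-gamma), a Brownian-motion prior on log(D) with per-Myr
# variance sigma^2 (vague prior on the first bin), and an Exp(1) hyperprior
# on sigma^2. Preservation uncertainty enters by resampling (q, alpha) from
# a preservation posterior during the MCMC and recomputing p.

#' Binomial sampling log-likelihood of sampled richness
#'
#' `sum_t log Binomial(x_t | D_t, p_t)` with real-valued `D_t` (the binomial
#' coefficient is generalised via log-gamma). `p_t = 0` contributes 0 when
#' `x_t = 0` and `-Inf` otherwise (an impossible datum).
#'
#' @param x Per-bin sampled richness (non-negative, `x <= D`).
#' @param D Per-bin true diversity (real, `D >= x`).
#' @param p Per-bin sampling probabilities in `[0, 1]`.
#' @return Log-likelihood (scalar).
#' @export
dive_log_likelihood <- function(x, D, p) {
  stopifnot(length(x) == length(D), length(x) == length(p))
  if (any(D < x)) return(-Inf)
  ll <- 0
  zero <- p <= 0
  if (any(zero & x > 0)) return(-Inf)
  one <- p >= 1
  if (any(one & D > x)) return(-Inf)
  use <- !zero & !one
  if (any(use)) {
    ll <- sum(lgamma(D[use] + 1) - lgamma(x[use] + 1) -
                lgamma(D[use] - x[use] + 1) +
                x[use] * log(p[use]) + (D[use] - x[use]) * log1p(-p[use]))
  }
  ll
}

#' Brownian-trajectory log-prior on diversity
#'
#' Brownian process on the log-transformed trajectory:
#' `log D_t ~ Normal(log D_{t-1}, sqrt(sigma2 * delta_t))` for every bin
#' after the first; the first bin carries a vague (improper uniform)
#' prior contributing 0. The Exp(1) hyperprior on `sigma2` is included.
#'
#' @param D Per-bin diversity trajectory (positive).
#' @param sigma2 Brownian variance per Myr (> 0).
#' @param delta Per-bin durations, Myr (recycled if scalar).
#' @return Log-prior density (scalar).
#' @export
dive_log_prior <- function(D, sigma2, delta = 1) {
  if (any(D <= 0)) stop("non-positive diversity", call. = FALSE)
  if (sigma2 <= 0) return(-Inf)
  T_ <- length(D)
  delta <- rep_len(delta, T_)
  steps <- if (T_ > 1) {
    sum(dnorm(log(D[-1]), log(D[-T_]), sqrt(sigma2 * delta[-1]), log = TRUE))
  } else {
    0
  }
  steps + dexp(sigma2, 1, log = TRUE)
}

# Duration-weighted projection of segment rates onto analysis bins.
# Returns a weight matrix W (bins x segments) with rows summing to 1 where
# the binning is covered; q_bins = W %*% q_segments.
rate_projection_matrix <- function(segments, bins) {
  W <- matrix(0, nrow(bins), nrow(segments))
  for (s in seq_len(nrow(segments))) {
    W[, s] <- pmax(0, pmin(bins$base, segments$base[s]) -
                     pmax(bins$top, segments$top[s]))
  }
  sweep(W, 1, pmax(rowSums(W), 1e-12), "/")
}

#' Run the hierarchical diversity MCMC
#'
#' Metropolis-Hastings sampler for the posterior of the true diversity
#' trajectory `D` and Brownian variance `sigma2` given per-bin sampled
#' richness and a preservation posterior. Each iteration proposes
#' multiplicative sliding-window updates on a random subset of the `D`
#' coordinates (floored at the sampled richness) and on `sigma2`; every
#' `resample_every` iterations a fresh `(q, alpha)` draw is taken uniformly
#' from the preservation posterior and the sampling probabilities are
#' recomputed, propagating preservation uncertainty into the diversity
#' estimates.
#'
#' @param x Per-bin sampled richness (integer vector, one per analysis bin).
#' @param bins A [time_bins()] tibble for the analysis bins.
#' @param preservation A `preservation_posterior` whose rate columns refer
#'   to `preservation_bins`.
#' @param preservation_bins Tibble (`base`, `top`) giving the intervals the
#'   preservation rates apply to; defaults to the analysis bins.
#' @param iters Total MCMC iterations (default 50000).
#' @param seed Integer seed.
#' @param prop_frac Fraction of `D` coordinates proposed per iteration.
#' @param window Half-width of the multiplicative log-uniform proposal.
#' @param resample_every Iterations between preservation-posterior redraws.
#' @param burnin Fraction discarded.
#' @param max_samples Cap on retained samples (thinning adjusts).
#' @return Object of class `dive_fit`: `D` (samples x bins matrix),
#'   `sigma2`, `x`, `bins`, `acceptance`, `seed`.
#' @export
run_mcmcdive <- function(x, bins, preservation, preservation_bins = NULL,
                         iters = 50000, seed = NULL, prop_frac = 0.3,
                         window = 0.3, resample_every = 10, burnin = 0.2,
                         max_samples = 2000) {
  stopifnot(inherits(preservation, "preservation_posterior"),
            length(x) == nrow(bins), all(x >= 0))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(preservation_bins)) preservation_bins <- bins
  qmat <- as.matrix(preservation$samples[, grep("^q_",
                                                names(preservation$samples))])
  stopifnot(ncol(qmat) == nrow(preservation_bins), nrow(qmat) >= 1)
  alphas <- preservation$samples$alpha
  W <- rate_projection_matrix(preservation_bins, bins)
  delta <- bins$duration
  T_ <- length(x)

  # precompute per-posterior-sample bin sampling probabilities
  pmat <- t(vapply(seq_len(nrow(qmat)), function(j) {
    sampling_probability(as.numeric(W %*% qmat[j, ]), delta, alphas[j])
  }, numeric(T_)))
  draw_p <- function() pmat[sample.int(nrow(pmat), 1), ]

  p <- draw_p()
  if (all(x == 0) && all(p == 0)) {
    warning("all bins empty with zero sampling probability: output is ",
            "prior-dominated", call. = FALSE)
  }
  D <- pmax(pmax(x, 1) / pmax(p, 0.05), x)
  sigma2 <- 0.1
  ll <- dive_log_likelihood(x, D, p)
  lp <- dive_log_prior(D, sigma2, delta)
  n_prop <- max(1L, round(prop_frac * T_))
  keep_from <- floor(iters * burnin) + 1
  win_d <- window
  win_s <- window
  block_acc_d <- 0; block_acc_s <- 0; block_n <- 0
  thin <- max(1L, floor((iters - keep_from + 1) / max_samples))
  n_keep <- length(seq(keep_from, iters, by = thin))
  Dout <- matrix(NA_real_, n_keep, T_)
  s2out <- numeric(n_keep)
  k <- 0L
  acc_d <- 0; acc_s <- 0
  for (it in seq_len(iters)) {
    if (it %% resample_every == 0) {
      p <- draw_p()
      ll <- dive_log_likelihood(x, D, p)
    }
    idx <- sample.int(T_, n_prop)
    Dp <- D
    mult <- exp(runif(n_prop, -win_d, win_d))
    Dp[idx] <- D[idx] * mult
    if (all(Dp[idx] >= x[idx])) {
      llp <- dive_log_likelihood(x, Dp, p)
      lpp <- dive_log_prior(Dp, sigma2, delta)
      ratio <- llp + lpp - ll - lp + sum(log(mult))
      if (is.nan(ratio)) ratio <- if (llp + lpp > -Inf) Inf else -Inf
      if (log(runif(1)) < ratio) {
        D <- Dp; ll <- llp; lp <- lpp
        acc_d <- acc_d + 1; block_acc_d <- block_acc_d + 1
      }
    }
    m <- exp(runif(1, -win_s, win_s))
    s2p <- sigma2 * m
    lpp <- dive_log_prior(D, s2p, delta)
    if (log(runif(1)) < lpp - lp + log(m)) {
      sigma2 <- s2p; lp <- lpp
      acc_s <- acc_s + 1; block_acc_s <- block_acc_s + 1
    }
    # adapt proposal windows towards ~25% acceptance during burn-in only
    block_n <- block_n + 1
    if (it < keep_from && block_n == 100) {
      if (block_acc_d / block_n < 0.15) win_d <- max(win_d * 0.7, 0.005)
      if (block_acc_d / block_n > 0.40) win_d <- min(win_d * 1.3, 2)
      if (block_acc_s / block_n < 0.15) win_s <- max(win_s * 0.7, 0.005)
      if (block_acc_s / block_n > 0.40) win_s <- min(win_s * 1.3, 2)
      block_acc_d <- 0; block_acc_s <- 0; block_n <- 0
    }
    if (it >= keep_from && (it - keep_from) %% thin == 0) {
      k <- k + 1L
      Dout[k, ] <- D
      s2out[k] <- sigma2
    }
  }
  structure(list(D = Dout[seq_len(k), , drop = FALSE],
                 sigma2 = s2out[seq_len(k)],
                 x = x, bins = bins,
                 acceptance = c(D = acc_d / iters, sigma2 = acc_s / iters),
                 seed = seed),
            class = "dive_fit")
}

#' Summarise a diversity posterior trajectory
#'
#' Per-bin posterior median and highest-posterior-density intervals at the
#' requested levels, optionally rescaled so the series maximum (of the
#' medians) equals 1.
#'
#' @param fit A `dive_fit`.
#' @param levels HPD levels, e.g. `c(0.5, 0.75, 0.95)`.
#' @param rescale Rescale medians and intervals by the maximum median.
#' @return Tibble: `bin`, `base`, `top`, `x`, `median`, and `hpdXX_lo` /
#'   `hpdXX_hi` per level.
#' @export
summarise_trajectory <- function(fit, levels = c(0.5, 0.75, 0.95),
                                 rescale = FALSE) {
  stopifnot(inherits(fit, "dive_fit"))
  if (nrow(fit$D) < 100) {
    stop("too few retained posterior samples (need >= 100)", call. = FALSE)
  }
  out <- tibble::tibble(bin = fit$bins$bin, base = fit$bins$base,
                        top = fit$bins$top, x = fit$x,
                        median = apply(fit$D, 2, median))
  for (lv in levels) {
    h <- apply(fit$D, 2, hpd_interval, level = lv)
    out[[sprintf("hpd%d_lo", round(lv * 100))]] <- h[1, ]
    out[[sprintf("hpd%d_hi", round(lv * 100))]] <- h[2, ]
  }
  if (rescale) {
    mx <- max(out$median)
    num <- setdiff(names(out), c("bin", "base", "top", "x"))
    out[num] <- lapply(out[num], function(v) v / mx)
  }
  out
}

# Shortest interval containing `level` of the sorted samples.
hpd_interval <- function(v, level = 0.95) {
  v <- sort(v)
  n <- length(v)
  m <- max(1L, ceiling(level * n))
  if (m >= n) return(c(v[1], v[n]))
  starts <- seq_len(n - m + 1)
  widths <- v[starts + m - 1] - v[starts]
  i <- which.min(widths)
  c(v[i], v[i + m - 1])
}

#' @export
print.dive_fit <- function(x, ...) {
  cat("Diversity MCMC fit:", nrow(x$D), "retained samples over",
      ncol(x$D), "bins\n")
  cat("acceptance: D", round(x$acceptance["D"], 3),
      "| sigma2", round(x$acceptance["sigma2"], 3), "\n")
  invisible(x)
}

#' @rdname summarise_trajectory
#' @param x A `dive_fit` (for `tidy`).
#' @param ... Passed to `summarise_trajectory()`.
#' @export
tidy.dive_fit <- function(x, ...) summarise_trajectory(x, ...)

#' @export
glance.dive_fit <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x$D), n_bins = ncol(x$D),
                 sigma2_median = median(x$sigma2),
                 accept_D = unname(x$acceptance["D"]),
                 accept_sigma2 = unname(x$acceptance["sigma2"]))
}

#' Plot a posterior diversity trajectory
#'
#' Median trajectory with shaded HPD ribbons and the sampled richness
#' overlaid as points. Time runs from old (left) to young (right).
#'
#' @param object A `dive_fit`.
#' @param levels HPD levels for the ribbons.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dive_fit <- function(object, levels = c(0.5, 0.95), ...) {
  s <- summarise_trajectory(object, levels = levels)
  mid <- (s$base + s$top) / 2
  gg <- ggplot2::ggplot(s, ggplot2::aes(x = mid))
  for (lv in sort(levels, decreasing = TRUE)) {
    gg <- gg + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data[[sprintf("hpd%d_lo", round(lv * 100))]],
                   ymax = .data[[sprintf("hpd%d_hi", round(lv * 100))]]),
      fill = "seagreen", alpha = 0.25)
  }
  gg +
    ggplot2::geom_line(ggplot2::aes(y = .data$median), colour = "seagreen4") +
    ggplot2::geom_point(ggplot2::aes(y = .data$x), size = 0.8) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Age (Ma)", y = "Diversity",
                  title = "Posterior diversity trajectory")
}
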