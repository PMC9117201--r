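# single-sample preservation posterior with constant rate q on given bins
constant_preservation <- function(q, n_bins, alpha = Inf, n_samples = 1) {
  s <- tibble::as_tibble(matrix(q, n_samples, n_bins,
                                dimnames = list(NULL, paste0("q_", 1:n_bins))))
  s$alpha <- alpha
  structure(list(samples = s, model = "homogeneous",
                 acceptance = c(q = NA, alpha = NA),
                 log_posterior = numeric(0)),
            class = "preservation_posterior")
}

test_that("binomial log-likelihood matches exact pmf values", {
  expect_equal(dive_log_likelihood(5, 10, 0.5), log(252 / 1024),
               tolerance = 1e-9)
  expect_equal(dive_log_likelihood(c(3, 7), c(9, 12), c(0.4, 0.6)),
               sum(stats::dbinom(c(3, 7), c(9, 12), c(0.4, 0.6), log = TRUE)),
               tolerance = 1e-9)
  expect_equal(dive_log_likelihood(4, 4, 1), 0)
  expect_equal(dive_log_likelihood(0, 5, 0), 0)
  expect_identical(dive_log_likelihood(2, 5, 0), -Inf)
  # real-valued diversity interpolates smoothly between integers
  expect_gt(dive_log_likelihood(5, 10.5, 0.5), -Inf)
})

test_that("Brownian log-prior matches closed forms", {
  # flat step at sigma2 = 1, delta = 1: density 1/sqrt(2*pi) per step
  lp2 <- dive_log_prior(c(10, 10), 1, 1)
  expect_equal(lp2 - dexp(1, 1, log = TRUE), -0.5 * log(2 * pi),
               tolerance = 1e-9)
  # doubling sigma2 on a flat trajectory costs half log 2 per step
  lp4 <- dive_log_prior(c(10, 10), 2, 1)
  expect_equal((lp2 - dexp(1, 1, log = TRUE)) -
                 (lp4 - dexp(2, 1, log = TRUE)),
               0.5 * log(2), tolerance = 1e-9)
  # degenerate limit: unequal steps at vanishing variance
  expect_lt(dive_log_prior(c(10, 20), 1e-12, 1), -1e6)
  expect_error(dive_log_prior(c(-1, 2), 1, 1), "non-positive")
})

test_that("fully sampled limit pins diversity at the observed counts", {
  bins <- time_bins_uniform(10, 0, 1)
  x <- c(12, 15, 14, 18, 20, 19, 17, 13, 11, 10)
  post <- constant_preservation(50, 10)  # p = 1 - exp(-50) ~ 1
  fit <- run_mcmcdive(x, bins, post, iters = 5000, seed = 1)
  s <- summarise_trajectory(fit)
  expect_true(all(abs(s$median - x) / x < 0.02))
  # hard constraint: no retained sample below x
  expect_true(all(sweep(fit$D, 2, x, ">=")))
})

test_that("known-probability recovery keeps truth inside the credible interval", {
  bins <- time_bins_uniform(20, 0, 1)
  post <- constant_preservation(-log(0.5), 20)  # p = 0.5 exactly
  hits <- 0; reps <- 30
  for (r in seq_len(reps)) {
    set.seed(100 + r)
    x <- rbinom(20, 100, 0.5)
    fit <- run_mcmcdive(x, bins, post, iters = 8000, seed = r)
    s <- summarise_trajectory(fit, levels = 0.95)
    covered <- mean(s$hpd95_lo <= 100 & s$hpd95_hi >= 100)
    hits <- hits + (covered >= 0.9)
  }
  expect_gte(hits / reps, 0.9)
})

test_that("widening the preservation posterior cannot narrow the intervals", {
  bins <- time_bins_uniform(15, 0, 1)
  set.seed(42)
  x <- rbinom(15, 120, 0.45)
  narrow <- constant_preservation(-log(0.55), 15)
  qwide <- matrix(rep(exp(seq(log(0.3), log(1.4), length.out = 50)),
                      each = 15), 50, 15, byrow = TRUE)
  colnames(qwide) <- paste0("q_", 1:15)
  wide <- narrow
  wide$samples <- tibble::as_tibble(qwide)
  wide$samples$alpha <- Inf
  f1 <- run_mcmcdive(x, bins, narrow, iters = 20000, seed = 7)
  f2 <- run_mcmcdive(x, bins, wide, iters = 20000, seed = 7)
  w1 <- summarise_trajectory(f1, 0.95)
  w2 <- summarise_trajectory(f2, 0.95)
  expect_gt(mean(w2$hpd95_hi - w2$hpd95_lo), mean(w1$hpd95_hi - w1$hpd95_lo))
})

test_that("zero-preservation bins interpolate finitely through the prior", {
  bins <- time_bins_uniform(10, 0, 1)
  q <- rep(1, 10); q[4:6] <- 0   # preservation gap
  s <- tibble::as_tibble(matrix(q, 1, 10,
                                dimnames = list(NULL, paste0("q_", 1:10))))
  s$alpha <- Inf
  post <- structure(list(samples = s, model = "homogeneous",
                         acceptance = c(q = NA, alpha = NA),
                         log_posterior = numeric(0)),
                    class = "preservation_posterior")
  x <- c(40, 42, 38, 0, 0, 0, 39, 41, 40, 38)
  fit <- run_mcmcdive(x, bins, post, iters = 15000, seed = 3)
  sm <- summarise_trajectory(fit)
  expect_true(all(is.finite(sm$median)))
  # gap bins interpolate between the flanks rather than dropping to zero
  expect_true(all(sm$median[4:6] > 10))
})

test_that("trajectory summaries honour HPD semantics and rescaling", {
  bins <- time_bins_uniform(2, 0, 1)
  fit <- structure(list(D = cbind(1:100, rep(7, 100)),
                        sigma2 = rep(1, 100), x = c(1, 7), bins = bins,
                        acceptance = c(D = 1, sigma2 = 1), seed = 1),
                   class = "dive_fit")
  s <- summarise_trajectory(fit, levels = 0.95)
  # 95% HPD over 1..100 covers 95 consecutive values
  expect_equal(s$hpd95_hi[1] - s$hpd95_lo[1], 94)
  # constant samples give zero-width intervals
  expect_equal(s$hpd95_lo[2], 7)
  expect_equal(s$hpd95_hi[2], 7)
  r <- summarise_trajectory(fit, levels = 0.95, rescale = TRUE)
  expect_equal(max(r$median), 1)
  few <- fit; few$D <- few$D[1:50, ]
  expect_error(summarise_trajectory(few), "too few")
})

test_that("tidy, glance and autoplot methods work on fits", {
  bins <- time_bins_uniform(5, 0, 1)
  post <- constant_preservation(1, 5)
  fit <- run_mcmcdive(c(5, 6, 7, 6, 5), bins, post, iters = 2000, seed = 2)
  td <- tidy(fit)
  expect_true(all(c("bin", "median", "hpd95_lo") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_bins, 5)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("preservation resampling uses the posterior spread deterministically", {
  bins <- time_bins_uniform(8, 0, 1)
  post <- constant_preservation(0.8, 8, n_samples = 40)
  post$samples[, 1:8] <- post$samples[, 1:8] *
    matrix(exp(seq(-0.5, 0.5, length.out = 40)), 40, 8)
  x <- c(10, 12, 9, 14, 11, 13, 10, 12)
  f1 <- run_mcmcdive(x, bins, post, iters = 4000, seed = 9)
  f2 <- run_mcmcdive(x, bins, post, iters = 4000, seed = 9)
  expect_identical(f1$D, f2$D)
})
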