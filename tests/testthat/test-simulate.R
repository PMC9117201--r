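test_that("pure-birth simulations never go extinct and seeds reproduce", {
  sched <- bd_schedule(lambda = 0.25, mu = 0)
  lin <- simulate_bd(root_age = 20, schedule = sched,
                     accept_range = c(20, 300), seed = 2)
  expect_true(all(lin$extinction == 0))
  lin2 <- simulate_bd(root_age = 20, schedule = sched,
                      accept_range = c(20, 300), seed = 2)
  expect_identical(lin, lin2)
  expect_true(all(lin$origin > lin$extinction))
})

test_that("lineage-level simulator agrees with a population-level oracle", {
  # same birth-death law implemented two independent ways; compare the mean
  # total and extant species counts under the same acceptance window
  lambda <- 0.2; mu <- 0.1; root <- 25; rng <- c(30, 400); reps <- 120
  set.seed(14)
  ours <- replicate(reps, {
    lin <- simulate_bd(root, bd_schedule(lambda, mu), accept_range = rng)
    c(total = nrow(lin), extant = sum(lin$extinction == 0))
  })
  oracle <- matrix(NA_real_, 2, reps)
  r <- 0
  while (r < reps) {
    cnt <- oracle_bd_counts(root, lambda, mu)
    if (cnt["total"] >= rng[1] && cnt["total"] <= rng[2]) {
      r <- r + 1
      oracle[, r] <- cnt
    }
  }
  # means agree within Monte-Carlo error (~3 SE)
  for (i in 1:2) {
    se <- sqrt(stats::var(ours[i, ]) / reps + stats::var(oracle[i, ]) / reps)
    expect_lt(abs(mean(ours[i, ]) - mean(oracle[i, ])), 3.5 * se)
  }
})

test_that("acceptance failure is fatal with diagnostics", {
  expect_error(
    simulate_bd(5, bd_schedule(0.01, 0), accept_range = c(400, 500),
                seed = 1, max_attempts = 5),
    "attempts")
})

test_that("preservation regimes draw six log-uniform rates with fixed shifts", {
  reg <- draw_preservation_regime(seed = 3)
  expect_equal(nrow(reg$segments), 6)
  expect_true(all(reg$segments$q >= 0.25 & reg$segments$q <= 2.5))
  expect_equal(reg$segments$base, c(25, 23, 15, 8, 5.3, 2.6))
  expect_equal(draw_preservation_regime(seed = 1,
                                        heterogeneity = "gamma")$alpha, 0.5)
  expect_identical(reg$alpha, Inf)
})

test_that("gap intervals force the rate to exactly zero", {
  reg <- draw_preservation_regime(seed = 4,
                                  gaps = list(c(15, 8), c(5.3, 2.6)))
  seg <- reg$segments
  in_gap <- function(b, t) (b <= 15 && t >= 8) || (b <= 5.3 && t >= 2.6)
  for (i in seq_len(nrow(seg))) {
    expect_equal(seg$q[i] == 0, in_gap(seg$base[i], seg$top[i]))
  }
  # segments still partition the span
  expect_equal(seg$base[1], 25)
  expect_equal(seg$top[nrow(seg)], 0)
  expect_true(all(abs(seg$top[-nrow(seg)] - seg$base[-1]) < 1e-12))
})

test_that("log preservation rates are uniform on [log 0.25, log 2.5]", {
  set.seed(6)
  rates <- unlist(replicate(1700, draw_preservation_regime()$segments$q))
  ks <- stats::ks.test(log(rates), "punif", log(0.25), log(2.5))
  expect_gt(ks$p.value, 0.01)
})

test_that("fossil sampling is an exact Poisson process within segments", {
  lin <- tibble::tibble(lineage = "t1", origin = 10, extinction = 0)
  reg <- draw_preservation_regime(seed = 1)
  reg$segments <- tibble::tibble(base = 10, top = 0, q = 1)
  set.seed(10)
  counts <- replicate(3000, nrow(simulate_fossils(lin, reg)$occurrences))
  expect_equal(mean(counts), 10, tolerance = 0.03)  # Poisson(10) mean
  expect_equal(stats::var(counts), 10, tolerance = 0.1)
})

test_that("all-zero regimes yield no occurrences and gaps stay empty", {
  lin <- tibble::tibble(lineage = c("t1", "t2"), origin = c(20, 15),
                        extinction = c(0, 2))
  reg <- draw_preservation_regime(seed = 2)
  reg$segments$q <- 0
  rec <- simulate_fossils(lin, reg, seed = 1)
  expect_equal(nrow(rec$occurrences), 0)
  reg2 <- draw_preservation_regime(seed = 2, gaps = list(c(15, 8)))
  reg2$segments$q[reg2$segments$q > 0] <- 5
  rec2 <- simulate_fossils(lin, reg2, seed = 1)
  expect_false(any(rec2$occurrences$age < 15 & rec2$occurrences$age > 8))
  # occurrence times always inside the lineage span
  sp <- merge(rec2$occurrences, lin, by.x = "taxon", by.y = "lineage")
  expect_true(all(sp$age <= sp$origin & sp$age >= sp$extinction))
})

test_that("gamma heterogeneity spreads per-lineage rates over orders of magnitude", {
  # gamma(0.5, 0.5) multipliers at mean rate 1: the 95% interval of
  # per-lineage rates extends below 0.001 and above 5
  expect_lt(qgamma(0.025, 0.5, 0.5), 0.001)
  expect_gte(qgamma(0.975, 0.5, 0.5), 5)
  lin <- tibble::tibble(lineage = sprintf("t%04d", 1:3000),
                        origin = 10, extinction = 0)
  reg <- draw_preservation_regime(seed = 1, heterogeneity = "gamma")
  rec <- simulate_fossils(lin, reg, seed = 2)
  # empirical quantiles at n = 3000 carry Monte-Carlo error around the
  # analytic values (0.00098 and 5.02)
  q95 <- quantile(rec$multipliers$g, c(0.025, 0.975))
  expect_lt(q95[1], 0.002)
  expect_gt(q95[2], 4.5)
})

test_that("true diversity counts bin-span intersections with half-open bins", {
  bins <- time_bins(base = c(10, 8, 6), top = c(8, 6, 4))
  one <- tibble::tibble(lineage = "a", origin = 12, extinction = 0)
  expect_equal(true_diversity(one, bins)$d_true, c(1, 1, 1))
  # dies exactly at the 8 Ma boundary: older bin only
  edge <- tibble::tibble(lineage = "b", origin = 12, extinction = 8)
  expect_equal(true_diversity(edge, bins)$d_true, c(1, 0, 0))
  # random lineages vs brute-force interval overlap
  set.seed(3)
  lin <- tibble::tibble(lineage = sprintf("t%02d", 1:40),
                        origin = runif(40, 0.5, 12))
  lin$extinction <- pmax(0, lin$origin - rexp(40, 0.3))
  got <- true_diversity(lin, bins)$d_true
  want <- vapply(seq_len(3), function(b) {
    sum(vapply(seq_len(40), function(i) {
      lin$origin[i] > bins$top[b] && lin$extinction[i] < bins$base[b]
    }, logical(1)))
  }, numeric(1))
  expect_equal(got, want)
})

test_that("observed richness never exceeds truth and converges to it as q grows", {
  preset <- scenario_preset("A")
  lin <- simulate_bd(25, preset$schedule, accept_range = c(50, 300), seed = 9)
  reg <- draw_preservation_regime(seed = 9)
  rec <- simulate_fossils(lin, reg, seed = 9)
  expect_lte(length(unique(rec$occurrences$taxon)), nrow(lin))
  reg$segments$q <- 500
  rec2 <- simulate_fossils(lin, reg, seed = 9)
  expect_equal(length(unique(rec2$occurrences$taxon)), nrow(lin))
})

test_that("scenario presets wire gaps and heterogeneity as documented", {
  expect_equal(scenario_preset("B")$gaps, list(c(15, 8), c(5.3, 2.6)))
  expect_equal(scenario_preset("D")$heterogeneity, "gamma")
  expect_equal(scenario_preset("F")$heterogeneity, "gamma")
  expect_equal(scenario_preset("A")$heterogeneity, "none")
  expect_gt(length(scenario_preset("E")$schedule$shifts), 0)
})
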