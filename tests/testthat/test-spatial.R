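square_poly <- function(lon0 = 0, lat0 = 0, half = 10) {
  cbind(lon = c(lon0 - half, lon0 + half, lon0 + half, lon0 - half),
        lat = c(lat0 - half, lat0 - half, lat0 + half, lat0 + half))
}

test_that("window series: zero drift repeats the base polygon", {
  ws <- make_window_series(square_poly(), n_bins = 4)
  for (b in 2:4) expect_equal(ws$polygon[[b]], ws$polygon[[1]])
})

test_that("window series: constant eastward drift is unidirectional and area-preserving", {
  ws <- make_window_series(square_poly(), n_bins = 5,
                           drift_per_bin = c(300, 0))
  centro <- vapply(ws$polygon, function(p) mean(p[, 1]), numeric(1))
  expect_true(all(diff(centro) > 0))
  areas <- attr(ws, "area")
  expect_true(all(abs(areas / areas[1] - 1) < 0.01))
})

test_that("window series: drifting across a pole is fatal", {
  expect_error(
    make_window_series(square_poly(lat0 = 70), n_bins = 10,
                       drift_per_bin = c(0, 2000)),
    "pole")
})

test_that("clipping matches a brute-force rectangle containment oracle", {
  set.seed(81)
  occ <- tibble::tibble(taxon = "t", lon = runif(200, -30, 30),
                        lat = runif(200, -30, 30), bin = 1L)
  ws <- make_window_series(square_poly(half = 15), n_bins = 1)
  kept <- clip_to_windows(occ, ws)
  inside <- abs(occ$lon) <= 15 & abs(occ$lat) <= 15
  expect_equal(sort(kept$lon), sort(occ$lon[inside]))
  # boundary point (vertex) is retained
  vert <- tibble::tibble(taxon = "v", lon = -15, lat = -15, bin = 1L)
  expect_equal(nrow(clip_to_windows(vert, ws)), 1)
  # all inside -> unchanged
  inner <- occ[inside, , drop = FALSE]
  expect_equal(nrow(clip_to_windows(inner, ws)), nrow(inner))
})

test_that("hexagonal binning is deterministic with conserved tallies", {
  occ <- tibble::tibble(lon = c(0, 0, 0.1, 20, -40),
                        lat = c(0, 0, 0.05, 10, -5))
  hx <- hex_bin(occ, spacing_km = 250)
  expect_equal(hx$occurrences$cell[1], hx$occurrences$cell[2])
  expect_equal(sum(hx$cells$tally), nrow(occ))
  hx2 <- hex_bin(occ, spacing_km = 250)
  expect_identical(hx$occurrences$cell, hx2$occurrences$cell)
})

test_that("points beyond two cell diameters land in distinct cells", {
  set.seed(4)
  pts <- tibble::tibble(lon = runif(40, -60, 60), lat = runif(40, -50, 50))
  hx <- hex_bin(pts, spacing_km = 250)
  cell_of <- hx$occurrences$cell
  for (i in 1:39) {
    d <- oracle_haversine(pts$lon[i], pts$lat[i],
                          pts$lon[(i + 1):40], pts$lat[(i + 1):40])
    same <- cell_of[(i + 1):40] == cell_of[i]
    expect_true(all(d[same] < 1000))  # 2 diameters = 4 x 250 km (projected)
  }
})

test_that("MST length matches exhaustive spanning-tree enumeration", {
  expect_equal(mst_length(tibble::tibble(lon = 5, lat = 5)), 0)
  tri <- tibble::tibble(lon = c(0, 3, 10), lat = c(0, 4, 0))
  expect_equal(mst_length(tri), oracle_mst_length(tri$lon, tri$lat),
               tolerance = 1e-9)
  set.seed(21)
  pts <- tibble::tibble(lon = runif(8, -40, 40), lat = runif(8, -30, 30))
  expect_equal(mst_length(pts), oracle_mst_length(pts$lon, pts$lat),
               tolerance = 1e-9)
})

# hand-built chain assignment: 5 collinear cells; the second cell from the
# southern end holds almost no data
chain_assignment <- function() {
  occ <- tibble::tibble(
    lon = 0,
    lat = rep(0:4, times = c(5, 1, 9, 9, 7)))
  hex_bin(occ, spacing_km = 50)
}

test_that("MST trimming removes the low-tally cell once it becomes a tip and matches exhaustive search", {
  hx <- chain_assignment()
  expect_equal(nrow(hx$cells), 5)
  full_len <- mst_length(hx$cells)
  target <- full_len / 2  # two segments of the four
  out <- standardise_mst(hx, target)
  # low-tally cell was removed after one end tip
  expect_true(length(out$removed) >= 2)
  expect_false(all(hx$cells$cell[hx$cells$tally == 1] %in% out$cells$cell))
  # visited lengths are monotone non-increasing along the greedy path
  expect_true(all(diff(out$path$mst_km) <= 1e-9))
  # best achievable |length - target| over all tip-removal sequences
  best <- oracle_best_trim(as.data.frame(hx$cells), target)
  expect_equal(abs(out$mst_km - target), best, tolerance = 1e-6)
})

test_that("MST trimming returns the initial state when already at or below target", {
  hx <- chain_assignment()
  full_len <- mst_length(hx$cells)
  out <- standardise_mst(hx, full_len + 100)
  expect_equal(nrow(out$cells), 5)
  expect_equal(out$mst_km, full_len)
})

test_that("masked cells are never removed and their branches stay counted", {
  hx <- chain_assignment()
  tip_cell <- hx$cells$cell[which.max(hx$cells$lat)]
  # mask the top tip; trim aggressively
  out <- suppressWarnings(standardise_mst(hx, 0, masked_cells = tip_cell))
  expect_true(tip_cell %in% out$cells$cell)
  # with every cell masked nothing can be removed
  out2 <- suppressWarnings(
    standardise_mst(hx, 0, masked_cells = hx$cells$cell))
  expect_equal(nrow(out2$cells), 5)
})

test_that("longitude-latitude standardisation maximises retained data", {
  occ <- tibble::tibble(taxon = letters[1:4], lon = c(0, 10, 20, 50),
                        lat = c(0, 1, 2, 3), bin = 1L)
  out <- standardise_lonlat(occ, target_lon = 25, target_lat = 90)
  expect_setequal(out$lon, c(0, 10, 20))
  # realised ranges never exceed the targets
  expect_lte(diff(range(out$lon)), 25)
  expect_lte(diff(range(out$lat)), 90)
  # extent already within targets -> unchanged, extremal rows marked
  out2 <- standardise_lonlat(occ, target_lon = 60, target_lat = 90)
  expect_equal(nrow(out2), 4)
  expect_true(out2$extent_marker[out2$lon == 0])
  expect_true(out2$extent_marker[out2$lon == 50])
})

test_that("tied windows resolve to the westernmost candidate", {
  occ <- tibble::tibble(taxon = letters[1:4], lon = c(0, 1, 10, 11),
                        lat = 0, bin = 1L)
  out <- standardise_lonlat(occ, target_lon = 2, target_lat = 10)
  expect_setequal(out$lon, c(0, 1))
})

test_that("diagnostics report one-tailed correlations with BH adjustment", {
  div <- tibble::tibble(quorum = 0.5, bin = 1:8, diversity = 2 * (1:8))
  metrics <- tibble::tibble(bin = 1:8, mst_km = as.numeric(1:8))
  res <- extent_diversity_diagnostics(div, metrics)
  pear <- res[res$method == "pearson", ]
  expect_equal(pear$estimate, 1, tolerance = 1e-12)
  expect_lt(pear$p_value, 1e-6)
  # anti-correlated: one-tailed (greater) p above 0.5
  div2 <- dplyr::mutate(div, diversity = rev(diversity))
  res2 <- extent_diversity_diagnostics(div2, metrics)
  expect_true(all(res2$p_value > 0.5))
  # constant series excluded from the family
  div3 <- dplyr::mutate(div, diversity = 3)
  res3 <- extent_diversity_diagnostics(div3, metrics)
  expect_true(all(is.na(res3$p_value)))
})

test_that("BH adjustment matches the step-up oracle", {
  # three synthetic series engineered to give increasing raw p-values,
  # then checked against the definitional BH procedure
  p_raw <- c(0.01, 0.02, 0.04)
  expect_equal(oracle_bh(p_raw), c(0.03, 0.03, 0.04))
  expect_equal(p.adjust(p_raw, "BH"), oracle_bh(p_raw))
  set.seed(9)
  p_rand <- runif(7)
  expect_equal(p.adjust(p_rand, "BH"), oracle_bh(p_rand))
})

test_that("spatial metrics are non-negative and zero for singleton bins", {
  occ <- tibble::tibble(taxon = "a", lon = 5, lat = 5, bin = 1L)
  bins <- time_bins(base = c(2, 1), top = c(1, 0))
  m <- spatial_metrics(occ, bins)
  expect_equal(m$mst_km, c(0, 0))
  expect_equal(m$n_cells, c(1L, 0L))
})
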