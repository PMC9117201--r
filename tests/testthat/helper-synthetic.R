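# Synthetic record whose spatial extent varies ~3-fold across bins while
# per-cell diversity stays constant: each grid point carries its own taxa
# with a fixed abundance profile, so regional diversity scales with the
# number of occupied cells unless the extent is standardised away.
extent_synthetic <- function(n_bins = 10, seed = 5) {
  set.seed(seed)
  rows <- list()
  for (b in seq_len(n_bins)) {
    half <- 3 + 1.0 * (b - 1)          # square half-width, degrees
    xs <- seq(-half, half, by = 1.8)
    grid <- expand.grid(lon = xs, lat = xs)
    grid$lon <- grid$lon + runif(nrow(grid), -0.15, 0.15)
    grid$lat <- grid$lat + runif(nrow(grid), -0.15, 0.15)
    for (i in seq_len(nrow(grid))) {
      # 8 point-specific taxa; abundances resampled per point so that
      # regional diversity varies continuously
      ab <- as.integer(rmultinom(1, 20, c(8, 4, 2, 2, 1, 1, 1, 1)))
      keep <- ab > 0
      rows[[length(rows) + 1]] <- tibble::tibble(
        taxon = sprintf("b%d_p%d_t%d", b, i, which(keep)),
        lon = grid$lon[i], lat = grid$lat[i], bin = as.integer(b),
        abundance = ab[keep])
    }
  }
  dplyr::bind_rows(rows)
}

bin_sqs <- function(occ, n_bins, quorum = 0.6) {
  vapply(seq_len(n_bins), function(b) {
    d <- occ[occ$bin == b, , drop = FALSE]
    if (nrow(d) == 0) return(NA_real_)
    ab <- tapply(d$abundance, d$taxon, sum)
    suppressWarnings(sqs_estimate(as.numeric(ab), quorum))
  }, numeric(1))
}
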