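#' Build a sliding spatial window series
#'
#' Constructs one window polygon per time bin from a base polygon, applying a
#' constant (unidirectional) drift per bin. The drift is applied cumulatively
#' in a cylindrical equal-area projection centred on the base polygon, so the
#' sampling area of the window is conserved through the series; vertices are
#' re-projected to decimal degrees after each step.
#'
#' @param base_polygon Two-column matrix or data frame of polygon vertices
#'   (`lon`, `lat`, decimal degrees), in order, not self-intersecting.
#' @param n_bins Number of time bins (polygons) in the series.
#' @param drift_per_bin Numeric length-2 vector: displacement per bin in
#'   projected km, `c(dx, dy)` (east, north). Default no drift.
#' @return A tibble with columns `bin` and `polygon` (list-column of
#'   two-column `lon`/`lat` matrices). The projection parameters and per-bin
#'   projected areas are attached as attributes `"projection"` and `"area"`.
#' @export
make_window_series <- function(base_polygon, n_bins, drift_per_bin = c(0, 0)) {
  poly <- as.matrix(as.data.frame(base_polygon))
  stopifnot(ncol(poly) == 2, nrow(poly) >= 3, n_bins >= 1,
            length(drift_per_bin) == 2)
  lon0 <- mean(range(poly[, 1]))
  lat_ts <- mean(range(poly[, 2]))
  pr <- cea_project(poly[, 1], poly[, 2], lon0, lat_ts)
  polys <- vector("list", n_bins)
  areas <- numeric(n_bins)
  for (b in seq_len(n_bins)) {
    x <- pr$x + (b - 1) * drift_per_bin[1]
    y <- pr$y + (b - 1) * drift_per_bin[2]
    areas[b] <- polygon_area(x, y)
    ll <- cea_unproject(x, y, lon0, lat_ts)
    polys[[b]] <- cbind(lon = ll$lon, lat = ll$lat)
  }
  out <- tibble::tibble(bin = seq_len(n_bins), polygon = polys)
  attr(out, "projection") <- c(lon0 = lon0, lat_ts = lat_ts)
  attr(out, "area") <- areas
  out
}

#' Clip binned occurrences to their bin's spatial window
#'
#' Retains only occurrences whose coordinates fall inside (boundary
#' inclusive) the window polygon of their assigned time bin.
#'
#' @param binned Occurrence tibble with a `bin` column.
#' @param windows A [make_window_series()] tibble aligned to the binning.
#' @return The retained occurrences.
#' @export
clip_to_windows <- function(binned, windows) {
  binned <- tibble::as_tibble(binned)
  keep <- logical(nrow(binned))
  for (b in windows$bin) {
    rows <- which(binned$bin == b)
    if (length(rows) == 0) next
    poly <- windows$polygon[[match(b, windows$bin)]]
    keep[rows] <- point_in_polygon(binned$lon[rows], binned$lat[rows],
                                   poly[, 1], poly[, 2])
  }
  binned[keep, , drop = FALSE]
}
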