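#' Standardise the longitude-latitude extent of binned occurrences
#'
#' Per time bin, selects a longitude interval of width at most `target_lon`
#' degrees retaining the greatest number of occurrences (candidate left edges
#' are the sorted unique occurrence longitudes; membership is inclusive), and
#' then, among the retained occurrences, a latitude interval of width at most
#' `target_lat` retaining the most data. Ties are broken towards the
#' westernmost (then southernmost) window. Occurrences outside the chosen
#' window are dropped. The occurrences that define the realised extent
#' (minimum/maximum retained longitude and latitude) are flagged in an
#' `extent_marker` column so the cells holding them can be masked from MST
#' trimming.
#'
#' Antimeridian-crossing windows are not supported.
#'
#' @param binned Occurrence tibble with a `bin` column.
#' @param target_lon,target_lat Maximum window widths in degrees (> 0).
#' @return The retained occurrences with a logical `extent_marker` column.
#' @export
standardise_lonlat <- function(binned, target_lon, target_lat) {
  stopifnot(target_lon > 0, target_lat > 0)
  binned <- tibble::as_tibble(binned)
  binned$.row <- seq_len(nrow(binned))
  pieces <- lapply(split(binned, binned$bin), function(d) {
    keep_lon <- best_window(d$lon, target_lon)
    d <- d[keep_lon, , drop = FALSE]
    keep_lat <- best_window(d$lat, target_lat)
    d <- d[keep_lat, , drop = FALSE]
    d$extent_marker <- d$lon == min(d$lon) | d$lon == max(d$lon) |
      d$lat == min(d$lat) | d$lat == max(d$lat)
    d
  })
  out <- dplyr::bind_rows(pieces)
  out <- out[order(out$.row), , drop = FALSE]
  out$.row <- NULL
  out
}

# Logical mask of values within the best [L, L + width] window; candidate
# left edges are the sorted unique values; ties go to the smallest edge.
best_window <- function(v, width) {
  if (length(v) == 0) return(logical(0))
  edges <- sort(unique(v))
  counts <- vapply(edges, function(L) sum(v >= L & v <= L + width),
                   numeric(1))
  L <- edges[which.max(counts)]  # which.max takes the first (smallest) edge
  v >= L & v <= L + width
}

#' Per-bin spatial extent metrics
#'
#' Computes, for each time bin, the MST length over occupied hexagonal grid
#' cells and the longitude and latitude ranges of the occurrences.
#'
#' @param binned Occurrence tibble with a `bin` column.
#' @param bins A [time_bins()] tibble.
#' @param spacing_km Hexagonal grid spacing passed to [hex_bin()].
#' @return Tibble with columns `bin`, `n_cells`, `mst_km`, `lon_range`,
#'   `lat_range` (empty bins reported with zero extent).
#' @export
spatial_metrics <- function(binned, bins, spacing_km = 250) {
  rows <- lapply(bins$bin, function(b) {
    d <- binned[binned$bin == b, , drop = FALSE]
    if (nrow(d) == 0) {
      return(tibble::tibble(bin = b, n_cells = 0L, mst_km = 0,
                            lon_range = 0, lat_range = 0))
    }
    hx <- hex_bin(d, spacing_km)
    tibble::tibble(bin = b, n_cells = nrow(hx$cells),
                   mst_km = mst_length(hx$cells),
                   lon_range = diff(range(d$lon)),
                   lat_range = diff(range(d$lat)))
  })
  dplyr::bind_rows(rows)
}
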