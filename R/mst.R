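# Minimum-spanning-tree extent metric and greedy MST standardisation.

# MST edge list (two-column index matrix) over points; empty for n < 2.
# Built with vegan::spantree on the haversine distance matrix.
mst_edges <- function(lon, lat) {
  n <- length(lon)
  if (n < 2) return(matrix(integer(0), 0, 2))
  d <- haversine_matrix(lon, lat)
  tr <- vegan::spantree(stats::as.dist(d))
  cbind(2:n, tr$kid)
}

#' Total minimum-spanning-tree length over cell centres
#'
#' Great-circle (haversine, radius 6371 km) length of the minimum spanning
#' tree connecting a set of grid-cell centres; the primary spatial-extent
#' metric. Zero when one or no centre is supplied.
#'
#' @param cells Tibble or data frame with `lon` and `lat` columns (decimal
#'   degrees), one row per occupied cell.
#' @return Total MST length in km.
#' @export
mst_length <- function(cells) {
  cells <- as.data.frame(cells)
  e <- mst_edges(cells$lon, cells$lat)
  if (nrow(e) == 0) return(0)
  sum(haversine_km(cells$lon[e[, 1]], cells$lat[e[, 1]],
                   cells$lon[e[, 2]], cells$lat[e[, 2]]))
}

#' Trim a hexagonally binned dataset to a target MST length
#'
#' Greedy spatial subsampling: among the current tips (degree-1 cells) of the
#' minimum spanning tree over occupied cell centres, the unmasked tip with
#' the smallest occurrence tally is removed; the tree is then rebuilt over
#' the remaining cells (masked cells always included, their branch lengths
#' always counted). The loop stops once the tree length falls to or below the
#' target (or no removable tip remains), and the visited state whose length
#' is closest to the target is returned.
#'
#' Ties between equal-tally tips are broken by whichever removal moves the
#' tree length closest to the target, then lexicographically by cell id.
#'
#' @param assignment A [hex_bin()] `hex_assignment`.
#' @param target_km Target MST length, km (>= 0).
#' @param masked_cells Character vector of cell ids that must never be
#'   removed (e.g. cells defining the longitude-latitude extent).
#' @return A `hex_assignment` restricted to the retained cells, with extra
#'   elements `mst_km` (realised length), `target_km`, `removed` (cell ids
#'   removed, in order) and `path` (tibble of visited states: `n_cells`,
#'   `mst_km`).
#' @export
standardise_mst <- function(assignment, target_km, masked_cells = character()) {
  stopifnot(inherits(assignment, "hex_assignment"), target_km >= 0)
  cells <- assignment$cells
  removed_order <- character(0)
  states <- list()
  repeat {
    len <- mst_length(cells)
    states[[length(states) + 1]] <- list(ids = cells$cell, len = len)
    if (len <= target_km) break
    e <- mst_edges(cells$lon, cells$lat)
    deg <- tabulate(c(e[, 1], e[, 2]), nbins = nrow(cells))
    tips <- which(deg == 1 & !(cells$cell %in% masked_cells))
    if (length(tips) == 0) {
      warning("removable tips exhausted before reaching the target length; ",
              "returning the closest state seen", call. = FALSE)
      break
    }
    cand <- tips[cells$tally[tips] == min(cells$tally[tips])]
    if (length(cand) > 1) {
      newlens <- vapply(cand, function(i) {
        mst_length(cells[-i, , drop = FALSE])
      }, numeric(1))
      gap <- abs(newlens - target_km)
      cand <- cand[gap == min(gap)]
      if (length(cand) > 1) cand <- cand[order(cells$cell[cand])][1]
    }
    removed_order <- c(removed_order, cells$cell[cand])
    cells <- cells[-cand, , drop = FALSE]
  }
  gaps <- vapply(states, function(s) abs(s$len - target_km), numeric(1))
  best <- states[[which.min(gaps)]]
  keep <- assignment$cells$cell %in% best$ids
  out <- assignment
  out$cells <- assignment$cells[keep, , drop = FALSE]
  out$occurrences <- assignment$occurrences[
    assignment$occurrences$cell %in% best$ids, , drop = FALSE]
  out$mst_km <- best$len
  out$target_km <- target_km
  out$removed <- setdiff(assignment$cells$cell, best$ids)
  out$path <- tibble::tibble(
    n_cells = vapply(states, function(s) length(s$ids), integer(1)),
    mst_km = vapply(states, function(s) s$len, numeric(1)))
  out
}
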