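#' Bin occurrences on a fixed-resolution hexagonal grid
#'
#' Coordinates are projected with a cylindrical equal-area projection and
#' assigned to the nearest centre of a regular (pointy-top) hexagonal lattice
#' with the requested centre spacing. The assignment is deterministic; cell
#' identifiers are axial lattice coordinates (`"q:r"`) and cell centres are
#' reported back in decimal degrees.
#'
#' @param occs Tibble with `lon` and `lat` columns.
#' @param spacing_km Distance between adjacent cell centres in projected km;
#'   default 250 (mean cell spacing of roughly 250 km).
#' @return A list of class `hex_assignment` with elements `occurrences` (the
#'   input with an added `cell` column), `cells` (tibble: `cell`, `lon`,
#'   `lat`, `tally`), and `spacing_km`.
#' @export
hex_bin <- function(occs, spacing_km = 250) {
  stopifnot(spacing_km > 0)
  occs <- tibble::as_tibble(occs)
  p <- cea_project(occs$lon, occs$lat)
  size <- spacing_km / sqrt(3)  # hex circumradius for centre spacing d
  # axial coordinates (pointy-top)
  qf <- (sqrt(3) / 3 * p$x - 1 / 3 * p$y) / size
  rf <- (2 / 3 * p$y) / size
  ax <- hex_round(qf, rf)
  occs$cell <- paste0(ax$q, ":", ax$r)
  cells <- occs |>
    dplyr::count(.data$cell, name = "tally") |>
    dplyr::arrange(.data$cell)
  qr <- do.call(rbind, strsplit(cells$cell, ":", fixed = TRUE))
  q <- as.numeric(qr[, 1]); r <- as.numeric(qr[, 2])
  cx <- size * sqrt(3) * (q + r / 2)
  cy <- size * 3 / 2 * r
  ll <- cea_unproject(cx, cy)
  cells$lon <- ll$lon
  cells$lat <- ll$lat
  structure(list(occurrences = occs,
                 cells = cells[, c("cell", "lon", "lat", "tally")],
                 spacing_km = spacing_km),
            class = "hex_assignment")
}

# Round fractional axial hex coordinates to the nearest cell (cube rounding).
hex_round <- function(qf, rf) {
  sf <- -qf - rf
  q <- round(qf); r <- round(rf); s <- round(sf)
  dq <- abs(q - qf); dr <- abs(r - rf); ds <- abs(s - sf)
  fix_q <- dq > dr & dq > ds
  fix_r <- !fix_q & dr > ds
  q[fix_q] <- -r[fix_q] - s[fix_q]
  r[fix_r] <- -q[fix_r] - s[fix_r]
  list(q = as.integer(q), r = as.integer(r))
}

#' @export
print.hex_assignment <- function(x, ...) {
  cat("Hexagonal grid assignment:", nrow(x$cells), "occupied cells,",
      nrow(x$occurrences), "occurrences, spacing", x$spacing_km, "km\n")
  invisible(x)
}
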