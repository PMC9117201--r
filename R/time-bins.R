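#' Define an ordered series of geological time bins
#'
#' Bins are ordered oldest first and must be contiguous: the top (youngest
#' edge) of each bin equals the base (oldest edge) of the next. Ages are in
#' millions of years before present (Ma), so `base > top` within each bin.
#' Bins are treated as half-open intervals `(top, base]` throughout the
#' package: a point age falling exactly on a shared boundary belongs to the
#' *younger* bin.
#'
#' @param base Numeric vector of bin bases (older edges), Ma, oldest first.
#' @param top Numeric vector of bin tops (younger edges), Ma.
#' @return A tibble with columns `bin` (1-based index, oldest first), `base`,
#'   `top` and `duration` (Myr).
#' @examples
#' time_bins(base = c(252, 247), top = c(247, 242))
#' @export
time_bins <- function(base, top) {
  stopifnot(length(base) == length(top), length(base) >= 1)
  if (any(base <= top)) stop("each bin must have base > top", call. = FALSE)
  if (length(base) > 1 && any(abs(base[-1] - top[-length(top)]) > 1e-9)) {
    stop("bins must be contiguous (top of each bin = base of the next)",
         call. = FALSE)
  }
  tibble::tibble(
    bin = seq_along(base),
    base = as.numeric(base),
    top = as.numeric(top),
    duration = as.numeric(base - top)
  )
}

#' Uniform-width time bins spanning an interval
#'
#' @param oldest,youngest Interval limits in Ma (`oldest > youngest`).
#' @param width Bin width in Myr.
#' @return A [time_bins()] tibble.
#' @export
time_bins_uniform <- function(oldest, youngest = 0, width = 1) {
  stopifnot(oldest > youngest, width > 0)
  edges <- seq(oldest, youngest, by = -width)
  if (tail(edges, 1) > youngest) edges <- c(edges, youngest)
  time_bins(base = edges[-length(edges)], top = edges[-1])
}

# Index of the bin containing each point age under the (top, base] convention;
# NA when outside the binning.
bin_index_of_age <- function(age, bins) {
  idx <- rep(NA_integer_, length(age))
  for (b in seq_len(nrow(bins))) {
    hit <- age > bins$top[b] & age <= bins$base[b]
    idx[hit & is.na(idx)] <- bins$bin[b]
  }
  # ages exactly at the youngest edge of the whole series (e.g. 0 Ma)
  at_floor <- is.na(idx) & abs(age - min(bins$top)) < 1e-12
  idx[at_floor] <- bins$bin[which.min(bins$top)]
  idx
}

# Overlap length of the interval [lo, hi] with each bin; returns a matrix
# (length(lo) x nrow(bins)).
bin_overlap_matrix <- function(lo, hi, bins) {
  n <- length(lo)
  out <- matrix(0, n, nrow(bins))
  for (b in seq_len(nrow(bins))) {
    out[, b] <- pmax(0, pmin(hi, bins$base[b]) - pmax(lo, bins$top[b]))
  }
  out
}
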