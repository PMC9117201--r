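#' Read a fossil occurrence table from delimited text
#'
#' Reads a comma- or tab-delimited file (auto-detected from the header line)
#' with one row per occurrence. Required fields: taxon name, oldest possible
#' age (FAD, Ma), youngest possible age (LAD, Ma), longitude and latitude in
#' decimal degrees, and a locality (collection/section) identifier. An
#' abundance column is optional; missing abundance defaults to 1.
#'
#' Rows violating the row invariants (`fad >= lad >= 0`, coordinates within
#' range, non-negative abundance) are dropped with a summarised warning;
#' missing required columns are an error.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector mapping canonical names
#'   (`taxon`, `fad`, `lad`, `lon`, `lat`, `locality`, `abundance`) to the
#'   column names used in the file. Defaults to the canonical names.
#' @return A tibble with columns `taxon`, `fad`, `lad`, `lon`, `lat`,
#'   `locality`, `abundance`. Rejected rows are reported via the
#'   `"rejected"` attribute (a tibble of row numbers and reasons).
#' @export
read_occurrences <- function(path, column_map = NULL) {
  defaults <- c(taxon = "taxon", fad = "fad", lad = "lad", lon = "lon",
                lat = "lat", locality = "locality", abundance = "abundance")
  if (!is.null(column_map)) defaults[names(column_map)] <- column_map
  header <- readLines(path, n = 1)
  delim <- if (grepl("\t", header)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  required <- defaults[c("taxon", "fad", "lad", "lon", "lat", "locality")]
  missing <- setdiff(unname(required), names(raw))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tbl <- tibble::tibble(
    taxon = as.character(raw[[defaults[["taxon"]]]]),
    fad = suppressWarnings(as.numeric(raw[[defaults[["fad"]]]])),
    lad = suppressWarnings(as.numeric(raw[[defaults[["lad"]]]])),
    lon = suppressWarnings(as.numeric(raw[[defaults[["lon"]]]])),
    lat = suppressWarnings(as.numeric(raw[[defaults[["lat"]]]])),
    locality = as.character(raw[[defaults[["locality"]]]])
  )
  tbl$abundance <- if (defaults[["abundance"]] %in% names(raw)) {
    suppressWarnings(as.numeric(raw[[defaults[["abundance"]]]]))
  } else {
    1
  }
  validate_occurrences(tbl)
}

#' Validate an occurrence table against its row invariants
#'
#' @param tbl A data frame with occurrence columns (see [read_occurrences()]).
#' @return The validated tibble; invalid rows dropped, recorded in the
#'   `"rejected"` attribute and summarised in a warning.
#' @export
validate_occurrences <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  if (!"abundance" %in% names(tbl)) tbl$abundance <- 1
  reason <- rep(NA_character_, nrow(tbl))
  bad <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    reason[cond & is.na(reason)] <<- why
  }
  bad(!is.finite(tbl$fad) | !is.finite(tbl$lad), "unparseable age")
  bad(!is.finite(tbl$lon) | !is.finite(tbl$lat), "unparseable coordinate")
  bad(tbl$fad < tbl$lad, "fad < lad")
  bad(tbl$lad < 0, "negative age")
  bad(tbl$lon < -180 | tbl$lon > 180 | tbl$lat < -90 | tbl$lat > 90,
      "coordinate out of range")
  bad(!is.finite(tbl$abundance) | tbl$abundance < 0, "invalid abundance")
  rejected <- tibble::tibble(row = which(!is.na(reason)),
                             reason = reason[!is.na(reason)])
  if (nrow(rejected) > 0) {
    warning(nrow(rejected), " occurrence row(s) rejected: ",
            paste(unique(rejected$reason), collapse = "; "), call. = FALSE)
  }
  out <- tbl[is.na(reason), , drop = FALSE]
  attr(out, "rejected") <- rejected
  out
}

#' Write an occurrence table as delimited text
#'
#' Emits the same dialect [read_occurrences()] reads (comma-delimited with
#' header), so tables round-trip.
#'
#' @param tbl Occurrence tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(tbl, path) {
  readr::write_csv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Drop occurrences with large age uncertainty
#'
#' Removes rows whose age interval `fad - lad` exceeds `max_uncertainty`
#' (the comparison is inclusive: an interval exactly equal to the cutoff is
#' retained). Row order is preserved.
#'
#' @param tbl Occurrence tibble.
#' @param max_uncertainty Cutoff in Myr (> 0); default 10.
#' @return Filtered tibble.
#' @export
filter_occurrences <- function(tbl, max_uncertainty = 10) {
  stopifnot(max_uncertainty > 0)
  dplyr::filter(tibble::as_tibble(tbl),
                (.data$fad - .data$lad) <= max_uncertainty)
}

#' Assign occurrences to time bins
#'
#' Two assignment rules are supported. `"midpoint"` places each occurrence in
#' the unique bin containing its age-interval midpoint `(fad + lad) / 2`;
#' a midpoint exactly on a shared bin boundary goes to the younger bin.
#' `"overlap"` (major overlap) places an occurrence in the bin with which at
#' least 50% of its `[lad, fad]` interval intersects; when no bin reaches
#' 50%, the occurrence is unassignable. Unassignable occurrences are dropped
#' and counted.
#'
#' @param tbl Occurrence tibble.
#' @param bins A [time_bins()] tibble.
#' @param rule `"midpoint"` or `"overlap"`.
#' @return The occurrence tibble with an added integer `bin` column, restricted
#'   to assigned rows. The number of dropped rows is stored in the
#'   `"dropped"` attribute.
#' @export
assign_bins <- function(tbl, bins, rule = c("midpoint", "overlap")) {
  rule <- match.arg(rule)
  if (is.null(bins) || nrow(bins) == 0) stop("empty binning", call. = FALSE)
  tbl <- tibble::as_tibble(tbl)
  if (nrow(tbl) == 0) {
    out <- tbl
    out$bin <- integer(0)
    attr(out, "dropped") <- 0L
    return(out)
  }
  if (rule == "midpoint") {
    idx <- bin_index_of_age((tbl$fad + tbl$lad) / 2, bins)
  } else {
    ov <- bin_overlap_matrix(tbl$lad, tbl$fad, bins)
    dur <- pmax(tbl$fad - tbl$lad, 0)
    idx <- integer(nrow(tbl))
    for (i in seq_len(nrow(tbl))) {
      if (dur[i] == 0) {
        idx[i] <- bin_index_of_age(tbl$fad[i], bins)
      } else {
        frac <- ov[i, ] / dur[i]
        b <- which(frac >= 0.5)
        # ties cannot arise above 50% except exactly at 50/50; take younger
        idx[i] <- if (length(b) == 0) NA_integer_ else max(b)
      }
    }
  }
  out <- tbl[!is.na(idx), , drop = FALSE]
  out$bin <- idx[!is.na(idx)]
  dropped <- sum(is.na(idx))
  if (dropped > 0) {
    message(dropped, " occurrence(s) not assignable to any bin; dropped")
  }
  attr(out, "dropped") <- dropped
  out
}

#' Per-bin sampled richness
#'
#' Counts distinct taxa per time bin (the sampled diversity `x_t`). Bins with
#' no occurrences are reported with zero richness.
#'
#' @param binned Occurrence tibble with a `bin` column (see [assign_bins()]).
#' @param bins A [time_bins()] tibble.
#' @return Tibble with columns `bin`, `base`, `top`, `duration`,
#'   `n_occurrences`, `richness`.
#' @export
bin_richness <- function(binned, bins) {
  counts <- binned |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n_occurrences = dplyr::n(),
                     richness = dplyr::n_distinct(.data$taxon),
                     .groups = "drop")
  bins |>
    dplyr::left_join(counts, by = "bin") |>
    tidyr::replace_na(list(n_occurrences = 0L, richness = 0L))
}

#' Randomise occurrence point ages with locality-age dependence
#'
#' Draws one uniform quantile per locality and assigns every occurrence at
#' that locality the point age `lad + u * (fad - lad)`. Occurrences from one
#' locality represent a geographically localised, temporally discrete fauna,
#' so they share the randomised age quantile; when age intervals differ
#' within a locality, the shared quantile preserves their relative ranking.
#'
#' @param tbl Occurrence tibble.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return The tibble with an added numeric `age` column (point ages, Ma).
#' @export
randomise_ages <- function(tbl, seed = NULL) {
  tbl <- tibble::as_tibble(tbl)
  if (!is.null(seed)) set.seed(seed)
  locs <- unique(tbl$locality)
  u <- stats::setNames(runif(length(locs)), locs)
  tbl$age <- tbl$lad + unname(u[tbl$locality]) * (tbl$fad - tbl$lad)
  tbl
}
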