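#' Diversity-versus-extent correlation diagnostics
#'
#' Tests whether standardised diversity still tracks spatial sampling extent.
#' For every combination of diversity series (one per coverage quorum) and
#' extent metric, one-tailed (positive association) Pearson and Spearman
#' correlation tests are run, and p-values are adjusted across the whole
#' family with the Benjamini-Hochberg step-up procedure. A well-standardised
#' dataset should show no significant positive correlations.
#'
#' Pairs with fewer than 4 finite observations, or a constant series, yield
#' an undefined coefficient: reported as `NA` and excluded from the
#' adjustment family.
#'
#' @param diversity Tibble in long format with columns `quorum`, `bin` and
#'   `diversity`.
#' @param metrics Tibble with column `bin` plus one column per extent metric
#'   (e.g. the output of [spatial_metrics()]).
#' @return Tibble with columns `quorum`, `metric`, `method`, `estimate`,
#'   `p_value`, `p_adjusted`.
#' @export
extent_diversity_diagnostics <- function(diversity, metrics) {
  metric_cols <- setdiff(names(metrics), c("bin", "n_cells"))
  grid <- tidyr::expand_grid(quorum = unique(diversity$quorum),
                             metric = metric_cols,
                             method = c("pearson", "spearman"))
  res <- purrr::pmap_dfr(grid, function(quorum, metric, method) {
    d <- diversity[diversity$quorum == quorum, c("bin", "diversity")]
    m <- metrics[, c("bin", metric)]
    names(m)[2] <- "extent"
    dd <- dplyr::inner_join(d, m, by = "bin")
    dd <- dd[is.finite(dd$diversity) & is.finite(dd$extent), , drop = FALSE]
    if (nrow(dd) < 4 || stats::sd(dd$diversity) == 0 ||
        stats::sd(dd$extent) == 0) {
      return(tibble::tibble(quorum = quorum, metric = metric, method = method,
                            estimate = NA_real_, p_value = NA_real_))
    }
    ct <- suppressWarnings(
      cor.test(dd$diversity, dd$extent, method = method,
               alternative = "greater", exact = FALSE))
    tibble::tibble(quorum = quorum, metric = metric, method = method,
                   estimate = unname(ct$estimate), p_value = ct$p.value)
  })
  res$p_adjusted <- NA_real_
  ok <- !is.na(res$p_value)
  res$p_adjusted[ok] <- p.adjust(res$p_value[ok], method = "BH")
  res
}
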