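# broom-style tidiers for the package's result objects.

#' @describeIn differential_expression Tidy the per-gene DE table.
#' @param x A `bifate_de` object.
#' @param ... Unused.
#' @export
tidy.bifate_de <- function(x, ...) {
  as_tibble(x) %>%
    rename(estimate = "log2_fold_change", p.value = "p_value",
           adj.p.value = "p_adjusted")
}

#' @describeIn differential_expression One-row summary of the contrast.
#' @export
glance.bifate_de <- function(x, ...) {
  tibble(
    contrast = x$contrast[1],
    n_genes = nrow(x),
    n_significant = sum(x$significant),
    alpha = attr(x, "alpha"),
    min_fc = attr(x, "min_fc")
  )
}

#' @describeIn contingency_chi_square Tidy one-row test summary.
#' @param x A `bifate_contingency` object.
#' @param ... Unused.
#' @export
tidy.bifate_contingency <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_value,
         parameter = x$df, yates = x$yates_corrected,
         method = if (x$yates_corrected) {
           "Pearson chi-square (Yates corrected)"
         } else {
           "Pearson chi-square"
         })
}

#' @describeIn normalize_median_of_ratios Per-sample size factors.
#' @param x A `bifate_norm` object.
#' @param ... Unused.
#' @export
tidy.bifate_norm <- function(x, ...) x$size_factors

#' @describeIn normalize_median_of_ratios One-row normalization summary.
#' @export
glance.bifate_norm <- function(x, ...) {
  tibble(n_samples = nrow(x$size_factors),
         n_reference_genes = x$n_reference_genes)
}

#' @describeIn compartment_similarity Distances of attachment to each
#'   neighbour.
#' @param x A `bifate_similarity` object.
#' @param ... Unused.
#' @export
tidy.bifate_similarity <- function(x, ...) x$distances

#' @describeIn compartment_similarity One-row summary with the `closer_to`
#'   call.
#' @export
glance.bifate_similarity <- function(x, ...) {
  d <- setNames(x$distances$distance, x$distances$cell_type)
  tibble(closer_to = x$closer_to,
         distance_tenocyte = d[["tenocyte"]],
         distance_chondrocyte = d[["chondrocyte"]])
}

#' @describeIn set_enrichment Tidy one-row enrichment summary.
#' @param x A `bifate_enrichment` object.
#' @param ... Unused.
#' @export
tidy.bifate_enrichment <- function(x, ...) {
  tibble(
    foreground_fraction = x$foreground_fraction,
    background_fraction = x$background_fraction,
    statistic = x$statistic, p.value = x$p_value,
    yates = x$yates_corrected
  )
}

#' @describeIn set_enrichment One-row summary with set sizes.
#' @export
glance.bifate_enrichment <- function(x, ...) {
  tibble(n_foreground = x$n_foreground, n_universe = x$n_universe,
         p.value = x$p_value)
}

#' @describeIn summarize_sharing Per-location sharing table.
#' @param x A `bifate_sharing` object.
#' @param ... Unused.
#' @export
tidy.bifate_sharing <- function(x, ...) x$location_table

#' @describeIn summarize_sharing One-row summary with the contingency
#'   p-value and attachment decomposition.
#' @export
glance.bifate_sharing <- function(x, ...) {
  dec <- setNames(x$attachment_decomposition$n, x$attachment_decomposition$group)
  tibble(
    n_peaks = x$n_peaks,
    contingency_statistic = if (is.null(x$contingency)) NA_real_ else x$contingency$statistic,
    contingency_p = if (is.null(x$contingency)) NA_real_ else x$contingency$p_value,
    attachment_accessible = dec[["attachment_accessible"]],
    shared_with_one = dec[["shared_with_one"]],
    attachment_only = dec[["attachment_only"]]
  )
}

#' @describeIn filter_peaks Filter report as a one-row tibble.
#' @param x A `bifate_filtered` object.
#' @param ... Unused.
#' @export
glance.bifate_filtered <- function(x, ...) {
  as_tibble(attr(x, "filter_report"))
}
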