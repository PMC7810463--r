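#' Median-of-ratios size-factor normalization
#'
#' The standard size-factor estimator for sequencing count matrices: a
#' pseudo-reference sample is built as the per-gene geometric mean across
#' samples (using only genes with strictly positive counts in every sample),
#' and each sample's size factor is the median over those genes of the ratio
#' count / geometric mean. Normalized counts are raw counts divided by the
#' sample's factor. Used identically for expression (genes x samples) and
#' chromatin-accessibility (peaks x samples) matrices.
#'
#' @param counts Tibble whose first column is a feature id (`gene_id` or
#'   `peak_id`) followed by one numeric column per sample, or a numeric
#'   matrix with feature rownames.
#' @return A list of class `bifate_norm` with `normalized` (tibble, same
#'   shape as `counts`), `size_factors` (tibble: `sample`, `size_factor`)
#'   and `n_reference_genes` (number of all-positive features used).
#' @export
#' @examples
#' counts <- tibble::tibble(gene_id = c("g1", "g2"), s1 = c(10, 20), s2 = c(20, 40))
#' normalize_median_of_ratios(counts)$size_factors
normalize_median_of_ratios <- function(counts) {
  if (is.matrix(counts)) counts <- matrix_to_tibble(counts, "feature_id")
  id_col <- names(counts)[1]
  m <- counts_to_matrix(counts, id_col)
  if (ncol(m) < 2) stop_bifate("normalization needs at least 2 samples")
  all_pos <- rowSums(m > 0) == ncol(m)
  if (!any(all_pos)) {
    stop_bifate(paste0(
      "no feature has positive counts in every sample; ",
      "median-of-ratios reference is undefined (pseudo-reference fallback is off)"
    ))
  }
  log_gm <- rowMeans(log(m[all_pos, , drop = FALSE]))
  sf <- apply(m[all_pos, , drop = FALSE], 2, function(col) {
    median(exp(log(col) - log_gm))
  })
  structure(
    list(
      normalized = matrix_to_tibble(sweep(m, 2, sf, "/"), id_col),
      size_factors = tibble(sample = colnames(m), size_factor = unname(sf)),
      n_reference_genes = sum(all_pos)
    ),
    class = "bifate_norm"
  )
}
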