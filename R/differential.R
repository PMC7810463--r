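#' Per-gene differential expression between two compartments
#'
#' Applies the selection rule used throughout the package: a gene is called
#' differential when its Benjamini-Hochberg adjusted p-value is at most
#' `alpha` AND its absolute fold change is at least `min_fc`. The per-gene
#' statistic is a Welch (unequal-variance) two-sample t test on
#' `log2(normalized + 1)`; the test is pluggable via `test_fun` so an
#' NB-based engine can be swapped in without touching the thresholds. Fold
#' change is computed on normalized group means with a pseudocount of 1.
#' Genes with zero variance in both groups get p = 1 by convention. Output
#' rows are ordered by gene id so ties are deterministic.
#'
#' @param counts Raw counts tibble (first column `gene_id`).
#' @param samples Sample metadata tibble with `sample` and `compartment`.
#' @param group_a,group_b Character vectors of compartment names for the two
#'   sides of the contrast (e.g. both tenocyte compartments vs both
#'   chondrocyte compartments). `group_a` is the numerator of the fold
#'   change.
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param min_fc Fold-change cutoff on the natural scale (default 2, i.e.
#'   |log2FC| >= 1).
#' @param normalized Optional pre-normalized tibble (as in
#'   [normalize_median_of_ratios()]`$normalized`); when supplied, `counts`
#'   may be the same object and no normalization is re-run.
#' @param test_fun Function `(x, y) -> p-value` applied per gene to the two
#'   groups' `log2(normalized + 1)` values; defaults to the internal Welch
#'   test.
#' @return A tibble of class `bifate_de` with columns `gene_id`,
#'   `log2_fold_change`, `p_value`, `p_adjusted`, `significant` and
#'   `contrast`, plus attributes `alpha` and `min_fc`.
#' @export
differential_expression <- function(counts, samples, group_a, group_b,
                                    alpha = 0.05, min_fc = 2,
                                    normalized = NULL, test_fun = NULL) {
  assert_columns(samples, c("sample", "compartment"), "samples")
  a_samples <- samples$sample[samples$compartment %in% group_a]
  b_samples <- samples$sample[samples$compartment %in% group_b]
  if (length(a_samples) < 2 || length(b_samples) < 2) {
    stop_bifate("both contrast groups need at least 2 replicates (got %d vs %d)",
                length(a_samples), length(b_samples))
  }
  if (is.null(normalized)) normalized <- normalize_median_of_ratios(counts)$normalized
  m <- counts_to_matrix(normalized)
  missing <- setdiff(c(a_samples, b_samples), colnames(m))
  if (length(missing) > 0) {
    stop_bifate("samples absent from count matrix: %s", paste(missing, collapse = ", "))
  }
  la <- log2(m[, a_samples, drop = FALSE] + 1)
  lb <- log2(m[, b_samples, drop = FALSE] + 1)
  p <- if (is.null(test_fun)) {
    welch_p(la, lb)
  } else {
    vapply(seq_len(nrow(la)), function(i) test_fun(la[i, ], lb[i, ]), numeric(1))
  }
  lfc <- log2(rowMeans(m[, a_samples, drop = FALSE]) + 1) -
    log2(rowMeans(m[, b_samples, drop = FALSE]) + 1)
  out <- tibble(
    gene_id = rownames(m),
    log2_fold_change = unname(lfc),
    p_value = unname(p)
  ) %>%
    arrange(.data$gene_id) %>%
    mutate(
      p_adjusted = p.adjust(.data$p_value, method = "BH"),
      significant = .data$p_adjusted <= alpha &
        abs(.data$log2_fold_change) >= log2(min_fc),
      contrast = paste(paste(group_a, collapse = "+"), "vs",
                       paste(group_b, collapse = "+"))
    )
  structure(out, class = c("bifate_de", class(out)),
            alpha = alpha, min_fc = min_fc)
}

# Vectorised Welch two-sample t test over matrix rows; zero pooled variance
# gives p = 1 (no evidence under the convention for flat genes).
welch_p <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  se2 <- va / na + vb / nb
  p <- rep(1, length(ma))
  ok <- se2 > 0
  tt <- (ma[ok] - mb[ok]) / sqrt(se2[ok])
  df <- se2[ok]^2 / ((va[ok] / na)^2 / (na - 1) + (vb[ok] / nb)^2 / (nb - 1))
  p[ok] <- 2 * pt(abs(tt), df, lower.tail = FALSE)
  p
}
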