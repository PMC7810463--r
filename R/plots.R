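# ggplot2 autoplot methods for the package's result objects.

#' Volcano plot of a differential-expression result
#'
#' @param object A `bifate_de` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bifate_de <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_fold_change,
                                   y = -log10(.data$p_adjusted),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p",
                  colour = "significant", title = df$contrast[1]) +
    ggplot2::theme_minimal()
}

#' PCA plot of samples with compartment colouring
#'
#' @param object A `bifate_similarity` object.
#' @param ... Unused.
#' @return A ggplot of PC1 vs PC2.
#' @export
autoplot.bifate_similarity <- function(object, ...) {
  ve <- attr(object$pca, "variance_explained")
  ggplot2::ggplot(object$pca, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                           colour = .data$compartment)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(
      x = sprintf("PC1 (%.0f%%)", 100 * ve[1]),
      y = sprintf("PC2 (%.0f%%)", 100 * ve[2])
    ) +
    ggplot2::theme_minimal()
}

#' Bar plot of sharing-class (Venn cell) counts
#'
#' @param object A `bifate_sharing` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bifate_sharing <- function(object, ...) {
  df <- object$venn_counts %>%
    mutate(class = factor(.data$class, levels = SHARING_CLASSES))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "accessibility sharing class", y = "peaks") +
    ggplot2::theme_minimal()
}

#' Fraction bars for a motif enrichment result
#'
#' @param object A `bifate_enrichment` object.
#' @param ... Unused.
#' @return A ggplot comparing foreground and background site fractions.
#' @export
autoplot.bifate_enrichment <- function(object, ...) {
  df <- tibble(
    set = factor(c("foreground", "background"), c("foreground", "background")),
    fraction = c(object$foreground_fraction, object$background_fraction)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$set, y = .data$fraction)) +
    ggplot2::geom_col(width = 0.6, fill = c("firebrick", "grey60")) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "genes with a motif site (fraction)",
                  subtitle = sprintf("chi-square p = %.3g", object$p_value)) +
    ggplot2::theme_minimal()
}

#' Score profile of ranked candidate enhancers
#'
#' @param object A `bifate_candidates` object.
#' @param n_top Number of top candidates to show (default 30).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bifate_candidates <- function(object, n_top = 30, ...) {
  df <- head(as_tibble(object), n_top)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$score,
                                   colour = .data$congruence_type)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "rank", y = "evidence score", colour = "congruence") +
    ggplot2::theme_minimal()
}
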