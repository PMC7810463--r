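mean_compartment_expression <- function(normalized, samples, compartment) {
  m <- counts_to_matrix(normalized)
  sel <- samples$sample[samples$compartment %in% compartment]
  rowMeans(m[, sel, drop = FALSE])
}

#' Classify genes into the mixed-transcriptome set
#'
#' The mixed set is the heart of the bi-fated definition: genes that are
#' differentially expressed between tenocytes and chondrocytes AND are also
#' expressed by attachment cells. A gene is `tenogenic_mixed` when the
#' tenocyte-vs-chondrocyte contrast calls it significant with tenocyte-high
#' fold change and its mean normalized expression in the attachment
#' compartment is at least `attachment_expr_threshold`; `chondrogenic_mixed`
#' mirrors this. All other genes are `unclassified` at this stage.
#'
#' @param de A `bifate_de` result for the tenocyte-vs-chondrocyte contrast
#'   (tenocyte compartments as `group_a`).
#' @param normalized Normalized counts tibble (first column `gene_id`).
#' @param samples Sample metadata (`sample`, `compartment`).
#' @param attachment_expr_threshold Mean normalized count above which a gene
#'   counts as "expressed by attachment cells" (default 10).
#' @return Tibble `gene_id`, `label`.
#' @export
classify_mixed_genes <- function(de, normalized, samples,
                                 attachment_expr_threshold = 10) {
  if (attachment_expr_threshold < 0) stop_bifate("threshold must be >= 0")
  att <- mean_compartment_expression(normalized, samples, "attachment")
  de %>%
    as_tibble() %>%
    mutate(
      attachment_mean = unname(att[.data$gene_id]),
      label = case_when(
        .data$significant & .data$log2_fold_change > 0 &
          .data$attachment_mean >= attachment_expr_threshold ~ "tenogenic_mixed",
        .data$significant & .data$log2_fold_change < 0 &
          .data$attachment_mean >= attachment_expr_threshold ~ "chondrogenic_mixed",
        TRUE ~ "unclassified"
      )
    ) %>%
    select("gene_id", "label")
}

#' Detect genes uniquely up- or downregulated in attachment cells
#'
#' A gene is `attachment_up` when it is called significant with positive
#' fold change in BOTH the attachment-vs-tenocyte and the
#' attachment-vs-chondrocyte contrasts; `attachment_down` mirrors this with
#' negative fold changes. A gene shifted against only one neighbour is
#' excluded.
#'
#' @param counts Raw counts tibble (first column `gene_id`).
#' @param samples Sample metadata (`sample`, `compartment`).
#' @param alpha,min_fc Selection thresholds, as in
#'   [differential_expression()].
#' @param normalized Optional pre-normalized matrix to avoid re-running
#'   normalization.
#' @return Tibble `gene_id`, `label` with labels in
#'   {`attachment_up`, `attachment_down`, `unclassified`}.
#' @export
detect_attachment_unique <- function(counts, samples, alpha = 0.05, min_fc = 2,
                                     normalized = NULL) {
  if (is.null(normalized)) normalized <- normalize_median_of_ratios(counts)$normalized
  teno <- c("remote_tenocyte", "adjacent_tenocyte")
  chon <- c("remote_chondrocyte", "adjacent_chondrocyte")
  de_t <- differential_expression(counts, samples, "attachment", teno,
                                  alpha, min_fc, normalized = normalized)
  de_c <- differential_expression(counts, samples, "attachment", chon,
                                  alpha, min_fc, normalized = normalized)
  tibble(gene_id = de_t$gene_id) %>%
    mutate(
      up = de_t$significant & de_t$log2_fold_change > 0 &
        de_c$significant & de_c$log2_fold_change > 0,
      down = de_t$significant & de_t$log2_fold_change < 0 &
        de_c$significant & de_c$log2_fold_change < 0,
      label = case_when(
        .data$up ~ "attachment_up",
        .data$down ~ "attachment_down",
        TRUE ~ "unclassified"
      )
    ) %>%
    select("gene_id", "label")
}

#' Full gene-class partition
#'
#' Combines [classify_mixed_genes()] and [detect_attachment_unique()] into a
#' single mutually exclusive label per gene. Attachment-unique labels take
#' precedence over mixed labels (a gene shifted in attachment against both
#' neighbours describes the attachment program, not a borrowed one); genes
#' matching neither rule are `unclassified`, so the labels always partition
#' the gene universe.
#'
#' @param counts Raw counts tibble (first column `gene_id`).
#' @param samples Sample metadata (`sample`, `compartment`).
#' @param alpha,min_fc Selection thresholds.
#' @param attachment_expr_threshold See [classify_mixed_genes()].
#' @return A tibble of class `bifate_gene_classes` (`gene_id`, `label`) with
#'   attribute `de` (the tenocyte-vs-chondrocyte `bifate_de` table).
#' @export
classify_genes <- function(counts, samples, alpha = 0.05, min_fc = 2,
                           attachment_expr_threshold = 10) {
  norm <- normalize_median_of_ratios(counts)$normalized
  teno <- c("remote_tenocyte", "adjacent_tenocyte")
  chon <- c("remote_chondrocyte", "adjacent_chondrocyte")
  de_tc <- differential_expression(counts, samples, teno, chon,
                                   alpha, min_fc, normalized = norm)
  mixed <- classify_mixed_genes(de_tc, norm, samples, attachment_expr_threshold)
  unique_att <- detect_attachment_unique(counts, samples, alpha, min_fc,
                                         normalized = norm)
  # Precedence: a gene differential between tenocytes and chondrocytes
  # belongs to the tenocyte/chondrocyte axis (mixed or unclassified); only
  # genes flat on that axis can be attachment-unique. This keeps the labels
  # mutually exclusive and mirrors the cluster semantics of the design.
  tc_de <- tibble(gene_id = de_tc$gene_id, tc_significant = de_tc$significant)
  out <- mixed %>%
    rename(mixed_label = "label") %>%
    left_join(rename(unique_att, unique_label = "label"), by = "gene_id") %>%
    left_join(tc_de, by = "gene_id") %>%
    mutate(label = case_when(
      !.data$tc_significant & .data$unique_label != "unclassified" ~ .data$unique_label,
      TRUE ~ .data$mixed_label
    )) %>%
    select("gene_id", "label")
  structure(out, class = c("bifate_gene_classes", class(out)), de = de_tc)
}

#' Position the attachment profile between tenocytes and chondrocytes
#'
#' Computes, over a gene set (typically the tenocyte-vs-chondrocyte DE
#' genes), the correlation distance (1 - Pearson r of mean `log2(norm+1)`
#' profiles) between the attachment compartment and each neighbour, plus a
#' PCA of all samples on the full log-normalized matrix.
#'
#' @param counts Raw counts tibble (first column `gene_id`).
#' @param samples Sample metadata (`sample`, `compartment`).
#' @param gene_set Character vector of gene ids (>= 3) over which distances
#'   are computed.
#' @return A list of class `bifate_similarity`: `distances` (tibble
#'   `cell_type`, `distance`), `closer_to` (`"tenocyte"` or
#'   `"chondrocyte"`), and `pca` (tibble `sample`, `compartment`, `PC1`,
#'   `PC2`, ... plus a `variance_explained` attribute).
#' @export
compartment_similarity <- function(counts, samples, gene_set) {
  if (length(gene_set) < 3) stop_bifate("gene_set needs at least 3 genes")
  norm <- normalize_median_of_ratios(counts)$normalized
  m <- log2(counts_to_matrix(norm) + 1)
  missing <- setdiff(gene_set, rownames(m))
  if (length(missing) > 0) stop_bifate("gene_set contains unknown genes")
  profile <- function(compartments) {
    sel <- samples$sample[samples$compartment %in% compartments]
    rowMeans(m[gene_set, sel, drop = FALSE])
  }
  att <- profile("attachment")
  teno <- profile(c("remote_tenocyte", "adjacent_tenocyte"))
  chon <- profile(c("remote_chondrocyte", "adjacent_chondrocyte"))
  d <- c(tenocyte = 1 - cor(att, teno), chondrocyte = 1 - cor(att, chon))
  keep <- apply(m, 1, sd) > 0
  pc <- prcomp(t(m[keep, , drop = FALSE]), center = TRUE, scale. = FALSE)
  pca <- as_tibble(pc$x[, seq_len(min(5, ncol(pc$x))), drop = FALSE]) %>%
    mutate(sample = rownames(pc$x)) %>%
    left_join(samples[c("sample", "compartment")], by = "sample") %>%
    select("sample", "compartment", dplyr::starts_with("PC"))
  attr(pca, "variance_explained") <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(
      distances = tibble(cell_type = names(d), distance = unname(d)),
      closer_to = names(d)[which.min(d)],
      pca = pca
    ),
    class = "bifate_similarity"
  )
}
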