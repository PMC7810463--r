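# A tiny deterministic five-compartment matrix with known structure:
# g_ten:  tenocyte-high, attachment-expressed  -> tenogenic_mixed
# g_sil:  tenocyte-high, attachment-silent     -> unclassified
# g_flat: uniform everywhere                   -> unclassified
# g_up:   attachment-only upregulation         -> attachment_up
# g_half: up vs tenocytes only                 -> excluded from unique sets
toy_study <- function() {
  samples <- tidyr::expand_grid(
    compartment = c("remote_tenocyte", "adjacent_tenocyte", "attachment",
                    "adjacent_chondrocyte", "remote_chondrocyte"),
    replicate = 1:3
  ) |>
    dplyr::mutate(sample = sprintf("%s_rep%d", compartment, replicate))
  means <- list(
    g_ten = c(400, 400, 200, 100, 100),
    g_sil = c(400, 400, 2, 100, 100),
    g_flat = c(100, 100, 100, 100, 100),
    g_up = c(100, 100, 420, 100, 100),
    g_half = c(50, 50, 210, 210, 210)
  )
  filler <- lapply(1:40, function(i) rep(80 + i, 5))
  names(filler) <- sprintf("g_fill%02d", 1:40)
  means <- c(means, filler)
  set.seed(99)
  counts <- tibble::tibble(gene_id = names(means))
  jitter <- c(0.95, 1, 1.05)
  for (j in seq_len(nrow(samples))) {
    comp_idx <- match(samples$compartment[j],
                      c("remote_tenocyte", "adjacent_tenocyte", "attachment",
                        "adjacent_chondrocyte", "remote_chondrocyte"))
    counts[[samples$sample[j]]] <- vapply(means, function(mu) {
      round(mu[comp_idx] * jitter[samples$replicate[j]])
    }, numeric(1))
  }
  list(counts = counts, samples = samples)
}

test_that("mixed classification needs both differential status and attachment expression", {
  toy <- toy_study()
  norm <- normalize_median_of_ratios(toy$counts)$normalized
  de <- differential_expression(toy$counts, toy$samples,
                                c("remote_tenocyte", "adjacent_tenocyte"),
                                c("remote_chondrocyte", "adjacent_chondrocyte"),
                                normalized = norm)
  lab <- classify_mixed_genes(de, norm, toy$samples, attachment_expr_threshold = 10)
  get <- function(g) lab$label[lab$gene_id == g]
  expect_equal(get("g_ten"), "tenogenic_mixed")
  expect_equal(get("g_sil"), "unclassified")   # T-high but absent in attachment
  expect_equal(get("g_flat"), "unclassified")  # expressed everywhere, not DE
  expect_error(classify_mixed_genes(de, norm, toy$samples, -1), "threshold")
})

test_that("attachment-unique detection requires both contrasts to move together", {
  toy <- toy_study()
  lab <- detect_attachment_unique(toy$counts, toy$samples)
  get <- function(g) lab$label[lab$gene_id == g]
  expect_equal(get("g_up"), "attachment_up")
  expect_equal(get("g_flat"), "unclassified")
  expect_equal(get("g_half"), "unclassified")  # up vs tenocytes, flat vs chondrocytes
})

test_that("every gene receives exactly one label and planted labels recover", {
  sim <- small_sim()
  lab <- classify_genes(sim$expression$counts, sim$expression$samples)
  expect_setequal(lab$gene_id, sim$genes$gene_id)
  expect_equal(anyDuplicated(lab$gene_id), 0)
  expect_true(all(lab$label %in% c("tenogenic_mixed", "chondrogenic_mixed",
                                   "attachment_up", "attachment_down",
                                   "unclassified")))
  cmp <- dplyr::inner_join(tibble::as_tibble(lab), sim$gene_labels,
                           by = "gene_id", suffix = c("_rec", "_true"))
  acc <- mean(cmp$label_rec == expected_label(cmp$label_true))
  expect_gte(acc, 0.9)
})

test_that("similarity distances and PCA behave on constructed profiles", {
  toy <- toy_study()
  # attachment column copied from tenocyte -> distance 0, closer_to tenocyte
  counts <- toy$counts
  for (r in 1:3) {
    counts[[sprintf("attachment_rep%d", r)]] <-
      counts[[sprintf("remote_tenocyte_rep%d", r)]]
  }
  simres <- compartment_similarity(counts, toy$samples, counts$gene_id[1:10])
  expect_equal(simres$closer_to, "tenocyte")
  d <- simres$distances$distance[simres$distances$cell_type == "tenocyte"]
  expect_lt(d, 1e-6)
  expect_error(compartment_similarity(counts, toy$samples, c("g_ten", "g_up")),
               "at least 3")
  expect_s3_class(autoplot(simres), "ggplot")
  expect_equal(glance(simres)$closer_to, "tenocyte")
})

test_that("an attachment profile at the log midpoint lands between the centroids on PC1", {
  set.seed(13)
  n_genes <- 60
  samples <- tidyr::expand_grid(
    compartment = c("remote_tenocyte", "adjacent_tenocyte", "attachment",
                    "adjacent_chondrocyte", "remote_chondrocyte"),
    replicate = 1:3
  ) |>
    dplyr::mutate(sample = sprintf("%s_rep%d", compartment, replicate))
  lt <- rnorm(n_genes, 8, 2)   # log2 tenocyte profile
  lc <- rnorm(n_genes, 8, 2)   # log2 chondrocyte profile
  lmid <- (lt + lc) / 2
  counts <- tibble::tibble(gene_id = sprintf("g%03d", seq_len(n_genes)))
  for (j in seq_len(nrow(samples))) {
    prof <- switch(sub("_rep\\d", "", samples$sample[j]) |> sub("(remote|adjacent)_", "", x = _),
                   tenocyte = lt, chondrocyte = lc, attachment = lmid)
    counts[[samples$sample[j]]] <- round(2^(prof + rnorm(n_genes, 0, 0.01)))
  }
  simres <- compartment_similarity(counts, samples, counts$gene_id)
  pc <- simres$pca
  centroid <- function(comps) mean(pc$PC1[pc$compartment %in% comps])
  att <- centroid("attachment")
  ten <- centroid(c("remote_tenocyte", "adjacent_tenocyte"))
  cho <- centroid(c("remote_chondrocyte", "adjacent_chondrocyte"))
  expect_true(att > min(ten, cho) && att < max(ten, cho))
})
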