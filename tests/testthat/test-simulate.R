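test_that("simulation is deterministic for a fixed seed", {
  cfg <- sim_config(seed = 3, n_genes = 60, background_peak_count = 20)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$genes, b$genes)
  expect_identical(a$expression$counts, b$expression$counts)
  expect_identical(a$atac$counts, b$atac$counts)
  expect_identical(a$motifs$sequences, b$motifs$sequences)
  dir_a <- withr::local_tempdir()
  dir_b <- withr::local_tempdir()
  write_simulation(a, dir_a)
  write_simulation(b, dir_b)
  for (f in list.files(dir_a)) {
    expect_identical(
      unname(tools::md5sum(file.path(dir_a, f))),
      unname(tools::md5sum(file.path(dir_b, f))),
      label = sprintf("md5 of %s", f)
    )
  }
})

test_that("genome generation handles empty, counts and bad configs", {
  empty <- simulate_genome(sim_config(n_genes = 0))
  expect_equal(nrow(empty$genes), 0)

  g <- simulate_genome(sim_config(seed = 2, n_genes = 1000, n_chroms = 2))
  expect_equal(sum(table(g$genes$chrom)), 1000)
  expect_true(all(g$genes$tss >= 0 & g$genes$tss < sim_config()$chrom_length))
  expect_equal(anyDuplicated(g$genes$gene_id), 0)
  expect_true(all(g$genes$strand %in% c("+", "-")))

  expect_error(sim_config(n_genes = -5), "n_genes")
  expect_error(sim_config(chrom_length = 0), "chrom_length")
  expect_error(sim_config(nb_dispersion = -1), "dispersion")
  expect_error(sim_config(motif_consensus = "ACGX"), "IUPAC")
  expect_error(sim_config(peak_width_range = c(1e5, 2e5), chrom_length = 5e4),
               "exceed")
})

test_that("planted class counts match configured fractions", {
  cfg <- sim_config(seed = 5, n_genes = 1000)
  labels <- assign_gene_labels(simulate_genome(cfg)$genes, cfg)
  tab <- table(labels$label)
  for (cls in names(cfg$class_fractions)) {
    expect_equal(unname(tab[[cls]]), round(cfg$class_fractions[[cls]] * 1000))
  }
})

test_that("empirical fold changes converge to the planted effect", {
  # law-of-large-numbers check: tiny dispersion, many replicates
  cfg <- sim_config(seed = 9, n_genes = 200, n_replicates_expr = 10,
                    nb_dispersion = 1e-4, baseline_mean = 5000)
  labels <- assign_gene_labels(simulate_genome(cfg)$genes, cfg)
  expr <- simulate_expression(cfg, labels)
  norm <- normalize_median_of_ratios(expr$counts)$normalized
  m <- log2(as.matrix(norm[-1]) + 1)
  rownames(m) <- norm$gene_id
  teno <- expr$samples$sample[expr$samples$compartment %in%
                               c("remote_tenocyte", "adjacent_tenocyte")]
  chon <- expr$samples$sample[expr$samples$compartment %in%
                               c("remote_chondrocyte", "adjacent_chondrocyte")]
  lfc <- rowMeans(m[, teno]) - rowMeans(m[, chon])
  teno_genes <- labels$gene_id[labels$label == "tenogenic_mixed"]
  chon_genes <- labels$gene_id[labels$label == "chondrogenic_mixed"]
  expect_lt(abs(mean(lfc[teno_genes]) - cfg$planted_log2fc), 0.2)
  expect_lt(abs(mean(lfc[chon_genes]) + cfg$planted_log2fc), 0.2)
  expect_error(simulate_expression(cfg, tibble::tibble(gene_id = "g1", label = "bogus")),
               "unknown gene label")
})

test_that("planted peaks carry their sharing class in expectation", {
  sim <- small_sim()
  atac <- sim$atac
  counts <- as.matrix(atac$counts[-1])
  rownames(counts) <- atac$counts$peak_id
  tm <- atac$tissue_map
  mean_by_tissue <- sapply(unique(tm$tissue), function(t) {
    rowMeans(counts[, tm$sample[tm$tissue == t], drop = FALSE])
  })
  sharing <- sim$truth$peak_sharing
  prom <- grepl("^prom_", sharing$peak_id)
  # all-shared promoter peaks: every tissue mean comfortably above 30
  expect_true(all(mean_by_tissue[prom, ] >= 30))
  ac <- sharing$peak_id[sharing$class == "AC"]
  expect_true(mean(mean_by_tissue[ac, "tenocyte"] < 30) > 0.95)
  # conservation of emitted peaks: promoters + distal + background
  n_distal <- sum(sim$gene_labels$label %in%
                    c("tenogenic_mixed", "chondrogenic_mixed",
                      "tenogenic_nonmixed", "chondrogenic_nonmixed",
                      "attachment_up"))
  expect_equal(nrow(atac$peaks), nrow(sim$genes) + n_distal + 80)
})

test_that("motif planting round-trips through the scanner and respects the ratio", {
  sim <- small_sim()
  motif <- motif_consensus(sim$config$motif_consensus)
  planted <- sim$motifs$planted_sites
  seqs <- sim$motifs$sequences
  hit <- purrr::map2_lgl(planted$peak_id, planted$offset, function(id, off) {
    s <- seqs$sequence[seqs$peak_id == id]
    h <- scan_motif(s, motif)
    off %in% h$offset
  })
  expect_true(all(hit))

  # ratio 1: foreground and background planting fractions agree (pooled
  # over four generator seeds to keep the binomial noise well below 3 SD)
  per_seed <- sapply(21:24, function(sd) {
    cfg <- sim_config(seed = sd, n_genes = 400, motif_enrichment_ratio = 1,
                      motif_site_prob = 0.5, background_peak_count = 300)
    sim1 <- simulate_study(cfg)
    info <- dplyr::left_join(sim1$atac$truth$peak_gene_link,
                             sim1$atac$truth$peak_sharing, by = "peak_id")
    fg <- !is.na(info$gene_id) & !grepl("^prom_", info$peak_id) &
      grepl("A", info$class)
    planted1 <- info$peak_id %in% sim1$motifs$planted_sites$peak_id
    c(p_fg = mean(planted1[fg]), p_bg = mean(planted1[!fg]),
      n_fg = sum(fg), n_bg = sum(!fg))
  })
  diff <- mean(per_seed["p_fg", ] - per_seed["p_bg", ])
  se <- sqrt(0.5 * 0.5 * (1 / sum(per_seed["n_fg", ]) + 1 / sum(per_seed["n_bg", ])))
  expect_lt(abs(diff), 3 * se)
})
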