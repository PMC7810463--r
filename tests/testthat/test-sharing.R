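test_that("venn partition maps flags to classes and conserves totals", {
  flags <- tibble::tibble(
    peak_id = c("p1", "p2", "p3"),
    tenocyte = c(TRUE, FALSE, TRUE),
    attachment = c(TRUE, TRUE, FALSE),
    chondrocyte = c(TRUE, FALSE, FALSE)
  )
  v <- venn_partition(flags)
  expect_equal(v$classes$class, c("TAC", "A", "T"))
  expect_equal(sum(v$counts$n), 3)

  set.seed(2)
  n <- 100
  rnd <- tibble::tibble(
    peak_id = sprintf("p%03d", 1:n),
    tenocyte = runif(n) < 0.5, attachment = runif(n) < 0.5,
    chondrocyte = runif(n) < 0.5
  )
  rnd <- rnd[rowSums(as.matrix(rnd[-1])) > 0, ]
  expect_equal(sum(venn_partition(rnd)$counts$n), nrow(rnd))

  bad <- tibble::tibble(peak_id = "p", tenocyte = FALSE,
                        attachment = FALSE, chondrocyte = FALSE)
  expect_error(venn_partition(bad), "all-false")
})

test_that("gene linking picks the two nearest TSSs with documented tie-breaks", {
  genes <- tibble::tibble(
    gene_id = c("gA", "gB", "gC"),
    chrom = "chr1",
    tss = c(10000L, 30000L, 2000000L),
    strand = c("+", "-", "+")
  )
  peak_at <- function(mid) tibble::tibble(peak_id = "p", chrom = "chr1",
                                          start = mid - 50L, end = mid + 50L)
  at_tss <- link_genes(peak_at(10000L), genes)
  expect_equal(at_tss$gene_id[1], "gA")
  expect_equal(at_tss$distance[1], 0)
  expect_equal(nrow(at_tss), 2)

  # equidistant between gA and gB: lexicographic gene id breaks the tie
  tie <- link_genes(peak_at(20000L), genes)
  expect_equal(tie$gene_id, c("gA", "gB"))

  # strand-aware sign: 1 kb right of gB (- strand) is upstream -> negative
  gb <- link_genes(peak_at(31000L), genes)
  expect_equal(gb$distance[gb$gene_id == "gB"], -1000)

  far <- link_genes(
    tibble::tibble(peak_id = "p", chrom = "chr1", start = 4e6, end = 4e6 + 100),
    genes[1:2, ], max_distance = 1e6
  )
  expect_equal(nrow(far), 0)
  expect_equal(nrow(link_genes(peak_at(10000L), genes[0, ])), 0)
})

test_that("promoter calls follow the strand-aware window", {
  genes <- tibble::tibble(gene_id = c("plus", "minus"), chrom = "chr1",
                          tss = c(10000L, 10000L), strand = c("+", "-"))
  check <- function(start, end, gene, expected) {
    peaks <- tibble::tibble(peak_id = "p", chrom = "chr1",
                            start = start, end = end)
    links <- tibble::tibble(peak_id = "p", gene_id = gene,
                            distance = 0L, rank = 1L)
    loc <- annotate_location(peaks, links, genes)
    expect_equal(loc$location, expected,
                 label = sprintf("[%d,%d) vs %s", start, end, gene))
  }
  check(8500L, 9500L, "plus", "promoter")    # within 2 kb upstream
  check(10501L, 11000L, "plus", "distal")    # just past +500 downstream
  check(10100L, 10600L, "minus", "promoter") # upstream on the - strand
  check(8500L, 9400L, "minus", "distal")     # 600 bp downstream of - TSS
})

test_that("promoter/distal calls are invariant under coordinate reflection", {
  set.seed(6)
  L <- 100000L
  genes <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:20), chrom = "chr1",
    tss = sort(sample.int(L - 1L, 20)),
    strand = sample(c("+", "-"), 20, replace = TRUE)
  )
  peaks <- tibble::tibble(
    peak_id = sprintf("p%02d", 1:40), chrom = "chr1",
    start = sample.int(L - 700L, 40)
  ) |> dplyr::mutate(end = start + 500L)
  links <- link_genes(peaks, genes)
  loc <- annotate_location(peaks, links, genes)

  flip <- c(`+` = "-", `-` = "+")
  genes_r <- genes |> dplyr::mutate(tss = L - 1L - tss, strand = unname(flip[strand]))
  peaks_r <- peaks |> dplyr::mutate(start2 = L - end, end = L - start, start = start2,
                                    start2 = NULL)
  links_r <- link_genes(peaks_r, genes_r)
  loc_r <- annotate_location(peaks_r, links_r, genes_r)
  merged <- dplyr::inner_join(loc, loc_r, by = "peak_id")
  expect_equal(merged$location.x, merged$location.y)
})

test_that("sharing summary reproduces printed-count arithmetic and identities", {
  build_annotated <- function(n_prom_tac, n_prom_diff, n_dist_ta, n_dist_ac,
                              n_dist_a, n_dist_tac = 0) {
    n <- n_prom_tac + n_prom_diff + n_dist_ta + n_dist_ac + n_dist_a + n_dist_tac
    tibble::tibble(
      peak_id = sprintf("p%05d", seq_len(n)),
      chrom = "chr1", start = seq_len(n) * 1000L,
      end = seq_len(n) * 1000L + 500L,
      class = c(rep("TAC", n_prom_tac), rep("TA", n_prom_diff),
                rep("TA", n_dist_ta), rep("AC", n_dist_ac),
                rep("A", n_dist_a), rep("TAC", n_dist_tac)),
      location = c(rep("promoter", n_prom_tac + n_prom_diff),
                   rep("distal", n_dist_ta + n_dist_ac + n_dist_a + n_dist_tac)),
      gene1 = "g1", distance1 = 100L, gene2 = NA_character_,
      distance2 = NA_integer_
    )
  }
  ann <- build_annotated(708, 111, 400, 272, 248, 74)
  s <- summarize_sharing(ann)
  prom_shared <- s$location_table |>
    dplyr::filter(location == "promoter", sharing == "common")
  expect_equal(prom_shared$percent, 86)
  dec <- setNames(s$attachment_decomposition$n, s$attachment_decomposition$group)
  expect_equal(unname(dec["attachment_accessible"]),
               unname(dec["shared_with_one"] + dec["attachment_only"]))
  expect_equal(unname(dec["shared_with_one"]), 672)
  expect_equal(unname(dec["attachment_accessible"]), 920)

  all_tac <- build_annotated(10, 0, 0, 0, 0, 5)
  s2 <- summarize_sharing(all_tac)
  diff_rows <- s2$location_table |> dplyr::filter(sharing == "differential")
  expect_true(all(diff_rows$percent == 0))
  expect_s3_class(autoplot(s), "ggplot")
  expect_equal(glance(s)$attachment_only, 248)
})

test_that("annotation keeps every retained peak in exactly one venn cell", {
  sim <- small_sim()
  cons <- consensus_peaks(
    sim$atac$replicate_beds, sim$atac$counts, sim$atac$peaks,
    sim$atac$tissue_map, sim$chrom_sizes, sim$evidence$blacklist
  )
  ann <- annotate_peaks(cons, sim$genes)
  expect_equal(nrow(ann), nrow(cons$peaks))
  expect_false(any(is.na(ann$class)))
  expect_equal(sum(attr(ann, "venn_counts")$n), nrow(ann))
  expect_true(all(ann$location %in% c("promoter", "distal")))
})
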