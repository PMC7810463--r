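test_that("evidence overlap uses half-open any-overlap semantics with OR across tracks", {
  peaks <- tibble::tibble(peak_id = "p1", chrom = "chr1", start = 1000L, end = 1500L)
  flags <- function(tracks) overlap_evidence(peaks, tracks)
  exact <- tibble::tibble(name = "t", role = "enhancer_mark", chrom = "chr1",
                          start = 1000L, end = 1500L)
  expect_true(flags(exact)$enhancer_mark)
  adjacent <- tibble::tibble(name = "t", role = "enhancer_mark", chrom = "chr1",
                             start = 1500L, end = 1600L)
  expect_false(flags(adjacent)$enhancer_mark)  # book-ended, no shared base
  two <- tibble::tibble(name = c("far", "near"), role = "enhancer_mark",
                        chrom = "chr1", start = c(9000L, 1400L),
                        end = c(9100L, 1600L))
  expect_true(flags(two)$enhancer_mark)
  expect_false(flags(two)$conservation)
  bad <- tibble::tibble(name = "t", role = "weird", chrom = "chr1",
                        start = 1L, end = 2L)
  expect_error(flags(bad), "unknown evidence role")
})

test_that("congruence pairs the sharing class with the gene program", {
  expect_true(congruence("AC", "chondrogenic_mixed")$congruent)
  expect_true(congruence("TA", "tenogenic_mixed")$congruent)
  expect_false(congruence("TA", "chondrogenic_mixed")$congruent)
  expect_false(congruence("TAC", "tenogenic_mixed")$congruent)  # not differential
  att <- congruence("A", "attachment_up")
  expect_false(att$congruent)
  expect_equal(att$congruence_type, "attachment_only")
  expect_true(is.na(congruence("AC", "unclassified")$congruence_type))
})

make_candidate_fixture <- function() {
  annotated <- tibble::tibble(
    peak_id = c("mgp_like", "plain", "promoter_peak", "wrong_class"),
    chrom = "chr1",
    start = c(10000L, 20000L, 30000L, 40000L),
    end = c(10500L, 20500L, 30500L, 40500L),
    class = c("AC", "AC", "AC", "TA"),
    location = c("distal", "distal", "promoter", "distal"),
    gene1 = c("gMgp", "gOther", "gProm", "gMgp"),
    distance1 = c(-8000L, 9000L, -1000L, 12000L),
    gene2 = NA_character_, distance2 = NA_integer_
  )
  evidence <- tibble::tibble(
    peak_id = annotated$peak_id,
    enhancer_mark = c(TRUE, FALSE, TRUE, TRUE),
    promoter_mark = FALSE,
    repressive_mark = FALSE,
    conservation = c(TRUE, FALSE, TRUE, TRUE),
    interaction = FALSE
  )
  labels <- tibble::tibble(
    gene_id = c("gMgp", "gOther", "gProm"),
    label = c("chondrogenic_mixed", "chondrogenic_mixed", "chondrogenic_mixed")
  )
  list(annotated = annotated, evidence = evidence, labels = labels)
}

test_that("scoring gates and ranks a constructed chondrogenic fixture", {
  fx <- make_candidate_fixture()
  ranked <- score_and_rank(fx$annotated, fx$evidence, fx$labels)
  # the evidence-rich congruent chondrocyte+attachment peak leads
  expect_equal(ranked$peak_id[1], "mgp_like")
  expect_equal(ranked$rank[1], 1)
  # promoter-located peak excluded no matter its evidence
  expect_false("promoter_peak" %in% ranked$peak_id)
  # class TA with a chondrogenic gene is incongruent
  expect_false("wrong_class" %in% ranked$peak_id)

  # removing the enhancer mark strictly decreases the score
  ev2 <- fx$evidence
  ev2$enhancer_mark[ev2$peak_id == "mgp_like"] <- FALSE
  ranked2 <- score_and_rank(fx$annotated, ev2, fx$labels)
  expect_lt(ranked2$score[ranked2$peak_id == "mgp_like"],
            ranked$score[ranked$peak_id == "mgp_like"])
})

test_that("adding positive evidence never drops a peak below its twin", {
  set.seed(4)
  for (i in 1:20) {
    base_flags <- runif(4) < 0.5
    annotated <- tibble::tibble(
      peak_id = c("twin_plus", "twin_base"),
      chrom = "chr1", start = c(1000L, 5000L), end = c(1500L, 5500L),
      class = "TA", location = "distal",
      gene1 = "g1", distance1 = 7000L, gene2 = NA_character_,
      distance2 = NA_integer_
    )
    extra <- sample(c("enhancer_mark", "conservation", "interaction"), 1)
    evidence <- tibble::tibble(
      peak_id = annotated$peak_id,
      enhancer_mark = rep(base_flags[1], 2),
      promoter_mark = rep(base_flags[2], 2),
      repressive_mark = FALSE,
      conservation = rep(base_flags[3], 2),
      interaction = rep(base_flags[4], 2)
    )
    evidence[[extra]] <- c(TRUE, FALSE)  # the twin gains genuinely new evidence
    labels <- tibble::tibble(gene_id = "g1", label = "tenogenic_mixed")
    ranked <- score_and_rank(annotated, evidence, labels)
    expect_lte(ranked$rank[ranked$peak_id == "twin_plus"],
               ranked$rank[ranked$peak_id == "twin_base"])
  }
})

test_that("emitted candidates never violate the hard gates (random fixtures)", {
  sim <- small_sim()
  cons <- consensus_peaks(
    sim$atac$replicate_beds, sim$atac$counts, sim$atac$peaks,
    sim$atac$tissue_map, sim$chrom_sizes, sim$evidence$blacklist
  )
  ann <- annotate_peaks(cons, sim$genes)
  ev <- overlap_evidence(ann, sim$evidence$tracks)
  labels <- classify_genes(sim$expression$counts, sim$expression$samples)
  cand <- score_and_rank(ann, ev, labels)
  expect_true(all(cand$location == "distal"))
  expect_true(all(cand$congruence_type %in% c("mixed", "attachment_only")))
  mixed <- cand[cand$congruence_type == "mixed", ]
  expect_true(all(mixed$gene_label %in% c("tenogenic_mixed", "chondrogenic_mixed")))
  expect_true(all(diff(cand$score) <= 0))  # sorted by score, descending
  expect_true(!is.unsorted(cand$rank))
  expect_s3_class(autoplot(cand), "ggplot")
})
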