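SHARING_CLASSES <- c("T", "A", "C", "TA", "TC", "AC", "TAC")

#' Partition peaks by their cross-tissue accessibility pattern
#'
#' Maps each peak's three per-tissue accessibility flags to one of the seven
#' non-empty subsets of {tenocyte (T), attachment (A), chondrocyte (C)} -
#' the cells of the three-way Venn diagram.
#'
#' @param flags Tibble with `peak_id` and logical columns `tenocyte`,
#'   `attachment`, `chondrocyte`.
#' @return A list with `classes` (tibble `peak_id`, `class`) and `counts`
#'   (tibble `class`, `n` over all seven classes, zeros included).
#' @export
venn_partition <- function(flags) {
  assert_columns(flags, c("peak_id", names(TISSUES)), "flags")
  fm <- as.matrix(flags[names(TISSUES)])
  if (any(rowSums(fm) == 0)) {
    stop_bifate("peak with all-false flags reached venn_partition; filter first")
  }
  cls <- apply(fm, 1, function(f) paste(TISSUES[f], collapse = ""))
  classes <- tibble(peak_id = flags$peak_id, class = unname(cls))
  counts <- tibble(class = SHARING_CLASSES) %>%
    left_join(dplyr::count(classes, .data$class), by = "class") %>%
    mutate(n = dplyr::coalesce(.data$n, 0L))
  list(classes = classes, counts = counts)
}

#' Link peaks to their two nearest genes
#'
#' For each peak, the nearest and second-nearest gene by absolute distance
#' between the peak midpoint and the TSS, capped at `max_distance`.
#' The signed distance is strand-aware: positive when the peak midpoint lies
#' downstream of the TSS in the gene's direction of transcription, negative
#' upstream. Equidistant genes are ordered lexicographically by gene id.
#'
#' @param peaks Interval tibble with `peak_id`, `chrom`, `start`, `end`.
#' @param genes Gene tibble with `gene_id`, `chrom`, `tss`, `strand`.
#' @param max_distance Maximum linking distance in bp (default 1e6).
#' @return Tibble `peak_id`, `gene_id`, `distance` (signed), `rank` (1 or
#'   2); peaks with no gene in range are absent.
#' @export
link_genes <- function(peaks, genes, max_distance = 1e6) {
  assert_columns(peaks, c("peak_id", "chrom", "start", "end"), "peaks")
  empty <- tibble(peak_id = character(), gene_id = character(),
                  distance = integer(), rank = integer())
  if (nrow(genes) == 0 || nrow(peaks) == 0) return(empty)
  assert_columns(genes, c("gene_id", "chrom", "tss", "strand"), "genes")
  mids <- peaks %>% mutate(mid = (.data$start + .data$end) %/% 2L)
  win <- GenomicRanges::GRanges(
    mids$chrom,
    IRanges::IRanges(start = pmax(1L, mids$mid + 1L - as.integer(max_distance)),
                     end = mids$mid + 1L + as.integer(max_distance))
  )
  tss_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(start = genes$tss + 1L, width = 1L)
  )
  ov <- GenomicRanges::findOverlaps(win, tss_gr)
  if (length(ov) == 0) return(empty)
  pairs <- tibble(
    peak_id = mids$peak_id[S4Vectors::queryHits(ov)],
    mid = mids$mid[S4Vectors::queryHits(ov)],
    gene_id = genes$gene_id[S4Vectors::subjectHits(ov)],
    tss = genes$tss[S4Vectors::subjectHits(ov)],
    strand = genes$strand[S4Vectors::subjectHits(ov)]
  ) %>%
    mutate(
      abs_distance = abs(.data$mid - .data$tss),
      distance = if_else(.data$strand == "+",
                         .data$mid - .data$tss, .data$tss - .data$mid)
    ) %>%
    filter(.data$abs_distance <= max_distance) %>%
    arrange(.data$peak_id, .data$abs_distance, .data$gene_id) %>%
    group_by(.data$peak_id) %>%
    mutate(rank = row_number()) %>%
    filter(.data$rank <= 2) %>%
    ungroup()
  select(pairs, "peak_id", "gene_id", "distance", "rank")
}

# Strand-aware promoter window of one gene as a half-open interval:
# `upstream` bp before to `downstream` bp after the TSS in transcription
# coordinates (positions TSS-2000 .. TSS+500 inclusive by default).
promoter_window <- function(tss, strand, upstream = 2000L, downstream = 500L) {
  start <- ifelse(strand == "+", tss - upstream, tss - downstream)
  end <- ifelse(strand == "+", tss + downstream + 1L, tss + upstream + 1L)
  list(start = start, end = end)
}

#' Classify linked peaks as promoter or distal
#'
#' A peak is a promoter peak when it overlaps (by >= 1 bp) the strand-aware
#' window from `upstream` bp before to `downstream` bp after the TSS of any
#' of its linked genes; otherwise it is distal. Unlinked peaks are distal.
#'
#' @param peaks Interval tibble with `peak_id`, `chrom`, `start`, `end`.
#' @param links Output of [link_genes()].
#' @param genes Gene tibble (`gene_id`, `chrom`, `tss`, `strand`).
#' @param upstream,downstream Window extent in bp (defaults 2000 and 500).
#' @return Tibble `peak_id`, `location` (`"promoter"` or `"distal"`).
#' @export
annotate_location <- function(peaks, links, genes,
                              upstream = 2000L, downstream = 500L) {
  joined <- links %>%
    left_join(genes, by = "gene_id") %>%
    left_join(peaks[c("peak_id", "start", "end")], by = "peak_id")
  win <- promoter_window(joined$tss, joined$strand, upstream, downstream)
  joined$in_promoter <- joined$start < win$end & joined$end > win$start
  prom <- joined %>%
    group_by(.data$peak_id) %>%
    summarise(promoter = any(.data$in_promoter), .groups = "drop")
  peaks %>%
    left_join(prom, by = "peak_id") %>%
    mutate(location = if_else(dplyr::coalesce(.data$promoter, FALSE),
                              "promoter", "distal")) %>%
    select("peak_id", "location")
}

#' Annotate a consensus peak set with sharing class, location and genes
#'
#' Convenience wrapper running [venn_partition()], [link_genes()] and
#' [annotate_location()] and assembling the flat per-peak annotation table
#' used by the downstream prioritizer and reports.
#'
#' @param consensus A `bifate_consensus` object (or a list with `peaks` and
#'   `flags`).
#' @param genes Gene tibble.
#' @param max_distance Maximum gene-linking distance (default 1e6).
#' @param upstream,downstream Promoter window (defaults 2000/500).
#' @return A tibble of class `bifate_annotated`: `peak_id`, `chrom`,
#'   `start`, `end`, `class`, `location`, `gene1`, `distance1`, `gene2`,
#'   `distance2`, with the Venn `counts` tibble as an attribute.
#' @export
annotate_peaks <- function(consensus, genes, max_distance = 1e6,
                           upstream = 2000L, downstream = 500L) {
  peaks <- as_tibble(consensus$peaks)
  venn <- venn_partition(consensus$flags)
  links <- link_genes(peaks, genes, max_distance)
  location <- annotate_location(peaks, links, genes, upstream, downstream)
  wide <- links %>%
    tidyr::pivot_wider(id_cols = "peak_id", names_from = "rank",
                       values_from = c("gene_id", "distance"))
  nm <- c(gene_id_1 = "gene1", gene_id_2 = "gene2",
          distance_1 = "distance1", distance_2 = "distance2")
  present <- intersect(names(nm), names(wide))
  names(wide)[match(present, names(wide))] <- nm[present]
  for (col in setdiff(unname(nm), names(wide))) {
    wide[[col]] <- if (grepl("^gene", col)) NA_character_ else NA_integer_
  }
  out <- peaks %>%
    left_join(venn$classes, by = "peak_id") %>%
    left_join(location, by = "peak_id") %>%
    left_join(wide, by = "peak_id") %>%
    select("peak_id", "chrom", "start", "end", "class", "location",
           "gene1", "distance1", "gene2", "distance2")
  structure(out, class = c("bifate_annotated", class(out)),
            venn_counts = venn$counts)
}

#' Summarize accessibility sharing by genomic location
#'
#' Produces the headline sharing report: for promoter and distal peaks
#' separately, how many are common to all three cell types (class `TAC`)
#' versus differential (any other class); the chi-square contingency of
#' location x sharing; and, among differential distal peaks, the
#' attachment-accessible decomposition (shared with exactly one other cell
#' type, classes `TA`/`AC`, versus attachment-only, class `A`). Percentages
#' are rounded half-up to integers; raw fractions are reported alongside.
#'
#' @param annotated A `bifate_annotated` tibble.
#' @param gene_set Optional character vector; when given, only peaks whose
#'   linked gene1/gene2 is in the set are summarized (e.g. peaks near
#'   differentially expressed genes).
#' @param yates Use the Yates correction in the contingency test? Default
#'   `FALSE`.
#' @return A list of class `bifate_sharing`: `location_table`,
#'   `contingency`, `attachment_decomposition`, `venn_counts`, `n_peaks`.
#' @export
summarize_sharing <- function(annotated, gene_set = NULL, yates = FALSE) {
  peaks <- as_tibble(annotated)
  if (!is.null(gene_set)) {
    peaks <- peaks %>%
      filter(.data$gene1 %in% gene_set | .data$gene2 %in% gene_set)
  }
  peaks <- peaks %>%
    mutate(sharing = if_else(.data$class == "TAC", "common", "differential"))
  location_table <- peaks %>%
    dplyr::count(.data$location, .data$sharing) %>%
    tidyr::complete(location = c("promoter", "distal"),
                    sharing = c("common", "differential"),
                    fill = list(n = 0L)) %>%
    group_by(.data$location) %>%
    mutate(
      total = sum(.data$n),
      fraction = if_else(.data$total > 0, .data$n / .data$total, NA_real_),
      percent = round_half_up(100 * .data$fraction)
    ) %>%
    ungroup()

  tab <- matrix(
    c(
      sum(location_table$n[location_table$location == "promoter" &
                             location_table$sharing == "common"]),
      sum(location_table$n[location_table$location == "distal" &
                             location_table$sharing == "common"]),
      sum(location_table$n[location_table$location == "promoter" &
                             location_table$sharing == "differential"]),
      sum(location_table$n[location_table$location == "distal" &
                             location_table$sharing == "differential"])
    ),
    nrow = 2, dimnames = list(c("promoter", "distal"), c("common", "differential"))
  )
  contingency <- tryCatch(contingency_chi_square(tab, yates = yates),
                          bifate_error = function(e) NULL)

  distal_diff <- peaks %>%
    filter(.data$location == "distal", .data$sharing == "differential")
  shared_one <- sum(distal_diff$class %in% c("TA", "AC"))
  att_only <- sum(distal_diff$class == "A")
  decomposition <- tibble(
    group = c("attachment_accessible", "shared_with_one", "attachment_only"),
    n = c(shared_one + att_only, shared_one, att_only)
  )

  venn_counts <- tibble(class = SHARING_CLASSES) %>%
    left_join(dplyr::count(peaks, .data$class), by = "class") %>%
    mutate(n = dplyr::coalesce(.data$n, 0L))

  structure(
    list(
      location_table = location_table,
      contingency = contingency,
      attachment_decomposition = decomposition,
      venn_counts = venn_counts,
      n_peaks = nrow(peaks)
    ),
    class = "bifate_sharing"
  )
}
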