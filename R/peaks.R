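#' Per-tissue accessibility by replicate voting
#'
#' A peak is called accessible in a tissue when a normalized read count of at
#' least `threshold` is observed in at least `min_fraction` of that tissue's
#' replicates (both bounds inclusive, read literally from the rule).
#'
#' @param normalized Normalized peak counts tibble (first column `peak_id`).
#' @param tissue_map Tibble with `sample`, `tissue` covering every count
#'   column.
#' @param threshold Normalized-count threshold (default 30).
#' @param min_fraction Minimum fraction of passing replicates (default 0.5).
#' @return Tibble with `peak_id` and one logical column per tissue.
#' @export
#' @examples
#' counts <- tibble::tibble(peak_id = "p1", t_rep1 = 35, t_rep2 = 10)
#' map <- tibble::tibble(sample = c("t_rep1", "t_rep2"), tissue = "tenocyte")
#' vote_accessibility(counts, map)
vote_accessibility <- function(normalized, tissue_map, threshold = 30,
                               min_fraction = 0.5) {
  assert_columns(tissue_map, c("sample", "tissue"), "tissue_map")
  m <- counts_to_matrix(normalized)
  unmapped <- setdiff(colnames(m), tissue_map$sample)
  if (length(unmapped) > 0) {
    stop_bifate("samples missing from tissue_map: %s", paste(unmapped, collapse = ", "))
  }
  tissues <- unique(tissue_map$tissue)
  flags <- purrr::map(tissues, function(t) {
    reps <- intersect(tissue_map$sample[tissue_map$tissue == t], colnames(m))
    if (length(reps) == 0) stop_bifate("tissue '%s' has no replicates in the matrix", t)
    rowMeans(m[, reps, drop = FALSE] >= threshold) >= min_fraction
  })
  names(flags) <- tissues
  dplyr::bind_cols(tibble(peak_id = rownames(m)), as_tibble(flags))
}

#' Filter a consensus peak set
#'
#' Applies the three retention rules in order and reports how many peaks each
#' removes: (1) voting - peaks accessible in no tissue are dropped; (2)
#' blacklist - peaks overlapping any blacklist interval by >= 1 bp are
#' dropped; (3) average signal - peaks whose mean normalized count is below
#' `avg_threshold` in every tissue are dropped.
#'
#' @param peaks Interval tibble with `peak_id`, `chrom`, `start`, `end`.
#' @param flags Per-tissue logical flags from [vote_accessibility()].
#' @param normalized Normalized counts tibble (first column `peak_id`).
#' @param tissue_map Tibble with `sample`, `tissue`.
#' @param blacklist Interval tibble (may have 0 rows).
#' @param avg_threshold Per-tissue mean normalized count needed in at least
#'   one tissue (default 30).
#' @return The retained `peaks` rows (class `bifate_filtered`), with a
#'   `filter_report` attribute listing counts removed per rule in
#'   application order.
#' @export
filter_peaks <- function(peaks, flags, normalized, tissue_map, blacklist,
                         avg_threshold = 30) {
  assert_columns(peaks, c("peak_id", "chrom", "start", "end"), "peaks")
  n0 <- nrow(peaks)
  tissue_cols <- setdiff(names(flags), "peak_id")
  voted <- flags$peak_id[rowSums(as.matrix(flags[tissue_cols])) > 0]
  kept <- peaks %>% filter(.data$peak_id %in% voted)
  n_voting <- n0 - nrow(kept)

  n_black <- 0L
  if (!is.null(blacklist) && nrow(blacklist) > 0 && nrow(kept) > 0) {
    hits <- GenomicRanges::countOverlaps(
      intervals_to_granges(kept),
      intervals_to_granges(blacklist),
      minoverlap = 1L
    )
    n_black <- sum(hits > 0)
    kept <- kept[hits == 0, , drop = FALSE]
  }

  m <- counts_to_matrix(normalized)
  tissue_means <- sapply(unique(tissue_map$tissue), function(t) {
    reps <- intersect(tissue_map$sample[tissue_map$tissue == t], colnames(m))
    rowMeans(m[, reps, drop = FALSE])
  })
  pass_avg <- rownames(m)[apply(tissue_means >= avg_threshold, 1, any)]
  n_before <- nrow(kept)
  kept <- kept %>% filter(.data$peak_id %in% pass_avg)
  n_avg <- n_before - nrow(kept)

  structure(
    kept,
    class = c("bifate_filtered", class(kept)),
    filter_report = list(
      input = n0,
      removed_voting = n_voting,
      removed_blacklist = as.integer(n_black),
      removed_average = n_avg,
      retained = nrow(kept)
    )
  )
}

#' Build a filtered consensus peak set from replicate peak files
#'
#' The full merge-extend-normalize-vote-filter pipeline: replicate peak
#' intervals from all samples are combined and merged (book-ended intervals
#' fuse), merged peaks are extended to a minimum length of `min_length` bp,
#' counts for each consensus peak are aggregated from the input peak count
#' matrix (rows whose midpoint falls inside the consensus peak), the matrix
#' is normalized by median-of-ratios, per-tissue accessibility is voted, and
#' the voting/blacklist/average filters are applied.
#'
#' @param replicate_beds List of interval tibbles (one per replicate; a
#'   `name` column, when present, identifies the source peak).
#' @param counts Peak count matrix tibble (first column `peak_id`, one
#'   column per sample) quantified on the input peaks named in the BEDs.
#' @param peak_locations Interval tibble (`peak_id`, `chrom`, `start`,
#'   `end`) giving the coordinates of the count-matrix rows.
#' @param tissue_map Tibble `sample`, `tissue`.
#' @param chrom_sizes Tibble `chrom`, `size`.
#' @param blacklist Interval tibble (0 rows allowed).
#' @param min_length Minimum consensus peak length (default 500).
#' @param threshold,min_fraction Voting parameters (defaults 30 and 0.5).
#' @param avg_threshold Average-signal filter threshold (default 30).
#' @return A list of class `bifate_consensus`: `peaks` (retained consensus
#'   intervals with `peak_id`), `flags`, `normalized`, `size_factors`,
#'   `filter_report` and `provenance` (consensus peak -> contributing input
#'   peak ids).
#' @export
consensus_peaks <- function(replicate_beds, counts, peak_locations, tissue_map,
                            chrom_sizes, blacklist = NULL, min_length = 500L,
                            threshold = 30, min_fraction = 0.5,
                            avg_threshold = 30) {
  combined <- bind_rows(replicate_beds)
  merged <- merge_intervals(combined) %>%
    extend_to_min_length(chrom_sizes, min_length) %>%
    mutate(peak_id = sprintf("peak_%06d", row_number()))

  # Aggregate the input count matrix onto consensus peaks by midpoint hit.
  assert_columns(peak_locations, c("peak_id", "chrom", "start", "end"))
  mids <- peak_locations %>%
    mutate(mid = (.data$start + .data$end) %/% 2L,
           start = .data$mid, end = .data$mid + 1L)
  ov <- GenomicRanges::findOverlaps(intervals_to_granges(mids),
                                    intervals_to_granges(merged))
  prov <- tibble(
    input_peak = peak_locations$peak_id[S4Vectors::queryHits(ov)],
    peak_id = merged$peak_id[S4Vectors::subjectHits(ov)]
  )
  m_in <- counts_to_matrix(counts)
  grouped <- rowsum(m_in[prov$input_peak, , drop = FALSE], group = prov$peak_id)
  consensus_counts <- matrix_to_tibble(grouped, "peak_id")

  norm <- normalize_median_of_ratios(consensus_counts)
  flags <- vote_accessibility(norm$normalized, tissue_map, threshold, min_fraction)
  retained <- filter_peaks(merged[merged$peak_id %in% rownames(grouped), ],
                           flags, norm$normalized, tissue_map,
                           blacklist, avg_threshold)
  structure(
    list(
      peaks = as_tibble(retained),
      flags = flags %>% filter(.data$peak_id %in% retained$peak_id),
      normalized = norm$normalized,
      size_factors = norm$size_factors,
      filter_report = attr(retained, "filter_report"),
      provenance = prov
    ),
    class = "bifate_consensus"
  )
}
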