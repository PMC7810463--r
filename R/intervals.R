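#' Merge genomic intervals
#'
#' Maximal union of a 0-based half-open interval set: intervals on the same
#' chromosome that overlap or are book-ended (gap 0) fuse into one; the
#' result is sorted and disjoint.
#'
#' @param intervals Tibble with `chrom`, `start`, `end`.
#' @return Sorted, disjoint interval tibble.
#' @export
#' @examples
#' merge_intervals(tibble::tibble(chrom = "chr1", start = c(10, 15), end = c(20, 30)))
merge_intervals <- function(intervals) {
  assert_intervals(intervals)
  if (nrow(intervals) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  gr <- GenomicRanges::reduce(intervals_to_granges(intervals), min.gapwidth = 1L)
  granges_to_intervals(gr) %>% arrange(.data$chrom, .data$start)
}

#' Extend intervals to a minimum length
#'
#' Intervals shorter than `min_length` are extended symmetrically to exactly
#' `min_length`, an odd remainder going to the right; when the extension
#' runs off a chromosome edge the deficit is pushed to the other side, then
#' clipped at `[0, chrom_size)`. Intervals already at least `min_length`
#' long are returned unchanged.
#'
#' @param intervals Tibble with `chrom`, `start`, `end` (extra columns are
#'   kept).
#' @param chrom_sizes Tibble with `chrom`, `size`.
#' @param min_length Minimum interval length in bp (default 500).
#' @return Interval tibble, same rows and order.
#' @export
extend_to_min_length <- function(intervals, chrom_sizes, min_length = 500L) {
  assert_intervals(intervals)
  assert_columns(chrom_sizes, c("chrom", "size"), "chrom_sizes")
  if (nrow(intervals) == 0) return(intervals)
  size <- setNames(chrom_sizes$size, chrom_sizes$chrom)
  if (any(!intervals$chrom %in% names(size))) {
    stop_bifate("interval chromosome absent from chrom_sizes")
  }
  cs <- unname(size[intervals$chrom])
  if (any(min_length > cs)) stop_bifate("min_length exceeds a chromosome size")
  len <- intervals$end - intervals$start
  ext <- pmax(0L, as.integer(min_length) - len)
  start <- intervals$start - ext %/% 2L
  end <- intervals$end + (ext - ext %/% 2L)
  # push the deficit across when one edge clips; chrom_size >= min_length
  # guarantees at most one side ever clips
  over_left <- pmax(0L, -start)
  start <- start + over_left
  end <- end + over_left
  over_right <- pmax(0L, end - cs)
  end <- end - over_right
  start <- pmax(0L, start - over_right)
  out <- intervals
  out$start <- as.integer(start)
  out$end <- as.integer(end)
  out
}
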