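# File-format boundary: BED via rtracklayer, FASTA via Biostrings, TSV via
# readr. Internally everything is a 0-based half-open tibble.

#' Read a BED file into an interval tibble
#'
#' @param path Path to a BED3+ file.
#' @return Tibble with `chrom`, `start`, `end` (0-based half-open) and,
#'   when present, `name`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop_bifate("BED file not found: %s", path)
  gr <- rtracklayer::import(path, format = "BED")
  out <- granges_to_intervals(gr)
  nm <- gr$name
  if (!is.null(nm) && !all(is.na(nm))) out$name <- nm
  out
}

#' Write an interval tibble to a BED file
#'
#' @param intervals Tibble with `chrom`, `start`, `end` and optional `name`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  if (nrow(intervals) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  assert_intervals(intervals)
  gr <- intervals_to_granges(intervals)
  if ("name" %in% names(intervals)) gr$name <- intervals$name
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read peak sequences from FASTA
#'
#' @param path FASTA path.
#' @return Tibble with `peak_id` and `sequence`.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  tibble(peak_id = names(seqs), sequence = unname(as.character(seqs)))
}

#' Write peak sequences to FASTA
#'
#' @param sequences Tibble with `peak_id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::DNAStringSet(sequences$sequence)
  names(set) <- sequences$peak_id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

read_tsv_strict <- function(path, what) {
  if (!file.exists(path)) stop_bifate("%s file not found: %s", what, path)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
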