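#' Reverse complement of a DNA string
#' @param x Character scalar over A/C/G/T/N (IUPAC codes allowed).
#' @return Character scalar.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Define a motif by IUPAC consensus
#'
#' @param consensus IUPAC consensus string (e.g. `"CCACACCC"` for a
#'   KLF-type CACCC box).
#' @param id Motif identifier.
#' @return A `bifate_motif` object.
#' @export
motif_consensus <- function(consensus, id = consensus) {
  validate_iupac(consensus)
  structure(list(id = id, type = "consensus", consensus = toupper(consensus),
                 length = nchar(consensus)),
            class = "bifate_motif")
}

#' Define a motif by position-weight matrix
#'
#' Scores are log-odds against a configurable background; a position scores
#' `log2(p_base / background_base)` and a window is a hit when its summed
#' score reaches `score_threshold` times the maximum achievable score.
#'
#' @param matrix 4 x L numeric matrix of base probabilities, rows named
#'   `A`, `C`, `G`, `T`; columns must each sum to 1 (tolerance 1e-9).
#' @param score_threshold Fraction of the maximum log-odds score in (0, 1]
#'   (default 0.85).
#' @param id Motif identifier.
#' @param background Length-4 background base probabilities (default
#'   uniform 0.25).
#' @return A `bifate_motif` object.
#' @export
motif_pwm <- function(matrix, score_threshold = 0.85, id = "pwm",
                      background = rep(0.25, 4)) {
  m <- as.matrix(matrix)
  if (nrow(m) != 4) stop_bifate("PWM must have 4 rows (A, C, G, T)")
  if (is.null(rownames(m))) rownames(m) <- c("A", "C", "G", "T")
  m <- m[c("A", "C", "G", "T"), , drop = FALSE]
  if (any(abs(colSums(m) - 1) > 1e-9)) stop_bifate("PWM columns must sum to 1")
  if (score_threshold <= 0 || score_threshold > 1) {
    stop_bifate("score_threshold must be in (0, 1]")
  }
  structure(list(id = id, type = "pwm", pwm = m, length = ncol(m),
                 score_threshold = score_threshold, background = background),
            class = "bifate_motif")
}

BASES <- c("A", "C", "G", "T")

seq_to_chars <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(chars, c(BASES, "N"))
  if (length(bad) > 0) {
    stop_bifate("invalid base(s) in sequence: %s", paste(unique(bad), collapse = ", "))
  }
  chars
}

# Positions (0-based offsets) where the consensus matches, one strand.
# An N in the sequence never matches any motif letter.
scan_consensus_one <- function(chars, consensus) {
  letters <- strsplit(consensus, "")[[1]]
  L <- length(letters)
  n <- length(chars)
  if (n < L) return(integer())
  n_win <- n - L + 1L
  ok <- rep(TRUE, n_win)
  for (j in seq_len(L)) {
    ok <- ok & chars[seq_len(n_win) + j - 1L] %in% IUPAC[[letters[j]]]
  }
  which(ok) - 1L
}

scan_pwm_one <- function(chars, pwm, background) {
  lo <- log2(sweep(pwm, 1, background, "/"))
  L <- ncol(pwm)
  n <- length(chars)
  if (n < L) return(list(offset = integer(), score = numeric()))
  idx <- match(chars, BASES)  # N -> NA -> -Inf contribution
  n_win <- n - L + 1L
  score <- rep(0, n_win)
  for (j in seq_len(L)) {
    contrib <- unname(lo[, j][idx[seq_len(n_win) + j - 1L]])
    contrib[is.na(contrib)] <- -Inf
    score <- score + contrib
  }
  list(offset = seq_len(n_win) - 1L, score = score)
}

#' Scan a sequence for motif hits on both strands
#'
#' Consensus mode reports every window (on either strand) where all IUPAC
#' letter classes match; an `N` in the sequence never matches. PWM mode
#' reports windows whose log-odds score (against the motif's background)
#' reaches `score_threshold` x the maximum achievable score. Minus-strand
#' hits are found by scanning the forward sequence with the
#' reverse-complemented motif, so the reported offset is always the 0-based
#' position of the window on the forward strand.
#'
#' @param sequence DNA string over A/C/G/T/N.
#' @param motif A `bifate_motif` from [motif_consensus()] or [motif_pwm()].
#' @return Tibble `offset` (0-based), `strand` (`"+"`/`"-"`), `score`
#'   (NA in consensus mode), sorted by offset then strand. Empty when the
#'   sequence is shorter than the motif.
#' @export
#' @examples
#' scan_motif("TTACGTT", motif_consensus("ACGT"))
scan_motif <- function(sequence, motif) {
  stopifnot(inherits(motif, "bifate_motif"))
  chars <- seq_to_chars(sequence)
  if (motif$type == "consensus") {
    fwd <- scan_consensus_one(chars, motif$consensus)
    rev <- scan_consensus_one(chars, revcomp(motif$consensus))
    out <- bind_rows(
      tibble(offset = fwd, strand = "+", score = NA_real_),
      tibble(offset = rev, strand = "-", score = NA_real_)
    )
  } else {
    max_score <- sum(apply(log2(sweep(motif$pwm, 1, motif$background, "/")), 2, max))
    cutoff <- motif$score_threshold * max_score
    rc_pwm <- motif$pwm[c("T", "G", "C", "A"), rev(seq_len(motif$length)), drop = FALSE]
    rownames(rc_pwm) <- BASES
    fwd <- scan_pwm_one(chars, motif$pwm, motif$background)
    rev <- scan_pwm_one(chars, rc_pwm, motif$background)
    out <- bind_rows(
      tibble(offset = fwd$offset, strand = "+", score = fwd$score),
      tibble(offset = rev$offset, strand = "-", score = rev$score)
    ) %>% filter(.data$score >= cutoff)
  }
  arrange(out, .data$offset, .data$strand)
}

#' Scan many peak sequences for one or more motifs
#'
#' @param sequences Tibble with `peak_id`, `sequence`.
#' @param motifs A `bifate_motif` or list of them.
#' @return Tibble `peak_id`, `motif_id`, `offset`, `strand`, `score` (one
#'   row per hit).
#' @export
scan_peaks <- function(sequences, motifs) {
  if (inherits(motifs, "bifate_motif")) motifs <- list(motifs)
  purrr::map_dfr(motifs, function(mo) {
    purrr::map2_dfr(sequences$peak_id, sequences$sequence, function(id, s) {
      hits <- scan_motif(s, mo)
      if (nrow(hits) == 0) return(NULL)
      mutate(hits, peak_id = id, motif_id = mo$id)
    })
  }) %>%
    { if (nrow(.) == 0) tibble(peak_id = character(), motif_id = character(),
                               offset = integer(), strand = character(),
                               score = numeric()) else . } %>%
    select(any_of(c("peak_id", "motif_id", "offset", "strand", "score")))
}

#' Per-gene motif-site table over linked peaks
#'
#' A gene carries a site when at least one of its linked, retained peaks
#' contains at least one motif hit. The detail table mirrors a per-peak
#' report: peak, gene, signed distance to TSS, promoter/distal annotation
#' and one flag column per motif.
#'
#' @param genes Character vector: the gene universe.
#' @param links Peak-gene links (`peak_id`, `gene_id`, `distance`) for
#'   retained peaks only (see [link_genes()]).
#' @param hits Hit table from [scan_peaks()] (`peak_id`, `motif_id`).
#' @param locations Optional tibble `peak_id`, `location` for the detail
#'   annotation column.
#' @return List with `gene_table` (tibble `gene_id`, `has_site`) and
#'   `detail` (per linked peak-gene pair).
#' @export
gene_site_table <- function(genes, links, hits, locations = NULL) {
  hit_peaks <- unique(hits$peak_id)
  gene_table <- tibble(gene_id = genes) %>%
    left_join(
      links %>%
        group_by(.data$gene_id) %>%
        summarise(has_site = any(.data$peak_id %in% hit_peaks), .groups = "drop"),
      by = "gene_id"
    ) %>%
    mutate(has_site = dplyr::coalesce(.data$has_site, FALSE))
  detail <- links %>%
    filter(.data$gene_id %in% genes)
  if (!is.null(locations)) detail <- left_join(detail, locations, by = "peak_id")
  if (nrow(hits) > 0) {
    flag_wide <- hits %>%
      distinct(.data$peak_id, .data$motif_id) %>%
      mutate(flag = TRUE) %>%
      tidyr::pivot_wider(names_from = "motif_id", values_from = "flag",
                         names_prefix = "site_", values_fill = FALSE)
    detail <- left_join(detail, flag_wide, by = "peak_id") %>%
      mutate(across(dplyr::starts_with("site_"), ~ dplyr::coalesce(.x, FALSE)))
  }
  list(gene_table = gene_table, detail = detail)
}

#' Motif-site enrichment of a gene set against a universe
#'
#' Tests whether the fraction of foreground genes whose linked regulatory
#' peaks carry a motif site exceeds that of the rest of the universe, by
#' chi-square on the 2x2 table (foreground/rest x site/no-site).
#'
#' @param foreground Character vector of gene ids; must be a strict,
#'   non-empty subset of `universe`.
#' @param universe Character vector: all genes considered.
#' @param gene_table `gene_table` from [gene_site_table()] covering the
#'   universe.
#' @param yates Use the Yates correction? Default `FALSE`.
#' @return A list of class `bifate_enrichment`: `foreground_fraction`,
#'   `background_fraction` (rest of universe), `table`, `statistic`,
#'   `p_value`, `yates_corrected`, `n_foreground`, `n_universe`.
#' @export
set_enrichment <- function(foreground, universe, gene_table, yates = FALSE) {
  foreground <- unique(foreground)
  universe <- unique(universe)
  if (length(foreground) == 0 || length(universe) == 0) {
    stop_bifate("foreground and universe must be non-empty")
  }
  if (length(setdiff(foreground, universe)) > 0) {
    stop_bifate("foreground must be a subset of the universe")
  }
  rest <- setdiff(universe, foreground)
  if (length(rest) == 0) {
    stop_bifate("foreground equals the universe; the contrast is undefined")
  }
  sites <- setNames(gene_table$has_site, gene_table$gene_id)
  missing <- setdiff(universe, names(sites))
  if (length(missing) > 0) stop_bifate("gene_table does not cover the universe")
  fg_hit <- sum(sites[foreground]); bg_hit <- sum(sites[rest])
  tab <- matrix(
    c(fg_hit, bg_hit,
      length(foreground) - fg_hit, length(rest) - bg_hit),
    nrow = 2,
    dimnames = list(c("foreground", "rest"), c("site", "no_site"))
  )
  test <- contingency_chi_square(tab, yates = yates)
  structure(
    list(
      foreground_fraction = fg_hit / length(foreground),
      background_fraction = bg_hit / length(rest),
      table = tab,
      statistic = test$statistic,
      p_value = test$p_value,
      yates_corrected = yates,
      n_foreground = length(foreground),
      n_universe = length(universe)
    ),
    class = "bifate_enrichment"
  )
}
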