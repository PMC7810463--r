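#' Overlap peaks with evidence tracks by role
#'
#' For each evidence role (`enhancer_mark`, `promoter_mark`,
#' `repressive_mark`, `conservation`, `interaction`), a peak is flagged when
#' any track of that role overlaps it by at least 1 bp (OR semantics across
#' tracks of the same role).
#'
#' @param peaks Interval tibble with `peak_id`, `chrom`, `start`, `end`.
#' @param tracks Tibble with `name`, `role`, `chrom`, `start`, `end`.
#' @return Tibble with `peak_id` and one logical column per role (all five
#'   roles always present).
#' @export
overlap_evidence <- function(peaks, tracks) {
  assert_columns(peaks, c("peak_id", "chrom", "start", "end"), "peaks")
  out <- tibble(peak_id = peaks$peak_id)
  if (nrow(tracks) > 0) {
    assert_columns(tracks, c("role", "chrom", "start", "end"), "tracks")
    bad <- setdiff(unique(tracks$role), EVIDENCE_ROLES)
    if (length(bad) > 0) {
      stop_bifate("unknown evidence role(s): %s", paste(bad, collapse = ", "))
    }
  }
  peak_gr <- intervals_to_granges(peaks)
  for (role in EVIDENCE_ROLES) {
    sub <- tracks[tracks$role == role, , drop = FALSE]
    out[[role]] <- if (nrow(sub) == 0) {
      rep(FALSE, nrow(peaks))
    } else {
      GenomicRanges::countOverlaps(peak_gr, intervals_to_granges(sub),
                                   minoverlap = 1L) > 0
    }
  }
  out
}

#' Congruence between a peak's sharing class and its gene's program
#'
#' A distal peak is congruent when its accessibility pattern matches the
#' expression program of its linked gene: accessible in chondrocytes and
#' attachment (class `AC`) for a chondrogenic-mixed gene, or accessible in
#' tenocytes and attachment (class `TA`) for a tenogenic-mixed gene.
#' Attachment-only peaks (class `A`) linked to attachment-up genes are
#' flagged separately (`congruence_type = "attachment_only"`), not counted
#' as congruent. All-shared (`TAC`) peaks are never congruent: they are not
#' differential.
#'
#' @param sharing_class Character vector of sharing classes.
#' @param gene_label Character vector of gene class labels (same length).
#' @return Tibble with `congruent` (logical) and `congruence_type`
#'   (`"mixed"`, `"attachment_only"` or `NA`).
#' @export
congruence <- function(sharing_class, gene_label) {
  congruent <- (gene_label == "chondrogenic_mixed" & sharing_class == "AC") |
    (gene_label == "tenogenic_mixed" & sharing_class == "TA")
  congruent[is.na(congruent)] <- FALSE
  type <- case_when(
    congruent ~ "mixed",
    gene_label == "attachment_up" & sharing_class == "A" ~ "attachment_only",
    TRUE ~ NA_character_
  )
  tibble(congruent = congruent, congruence_type = type)
}

default_enhancer_weights <- function() {
  c(enhancer_mark = 2, conservation = 1, interaction = 1,
    motif_site = 1, promoter_mark = -1)
}

#' Score and rank candidate shared enhancers
#'
#' Hard gates first: a candidate must be distal, congruent (see
#' [congruence()]) and linked to a mixed-set gene. Surviving peaks get an
#' additive evidence score (defaults: enhancer mark +2, conservation +1,
#' chromatin interaction +1, motif site +1, promoter mark -1; repressive
#' marks carry weight 0) and are ranked by score (descending), then by
#' absolute distance to the linked TSS (ascending), then by peak id.
#'
#' @param annotated A `bifate_annotated` tibble.
#' @param evidence Output of [overlap_evidence()] for the same peaks.
#' @param gene_labels Tibble `gene_id`, `label`.
#' @param motif_peaks Optional character vector of peak ids carrying a motif
#'   site (sets the `motif_site` flag).
#' @param weights Named numeric scoring weights; unnamed roles score 0.
#' @param include_attachment_only Also emit attachment-only candidates
#'   (class `A` + attachment-up gene), marked by `congruence_type`?
#'   Default `TRUE` (they are reported, but never mixed-congruent).
#' @return A tibble of class `bifate_candidates`: one row per candidate with
#'   evidence flags, `congruence_type`, `score` and `rank`. Empty when no
#'   peak passes the gates.
#' @export
score_and_rank <- function(annotated, evidence, gene_labels,
                           motif_peaks = character(),
                           weights = default_enhancer_weights(),
                           include_attachment_only = TRUE) {
  cand <- as_tibble(annotated) %>%
    left_join(evidence, by = "peak_id") %>%
    left_join(rename(gene_labels, gene_label = "label"),
              by = c(gene1 = "gene_id")) %>%
    mutate(
      motif_site = .data$peak_id %in% motif_peaks,
      gene_label = dplyr::coalesce(.data$gene_label, "unclassified")
    )
  cong <- congruence(cand$class, cand$gene_label)
  cand <- dplyr::bind_cols(cand, cong)
  keep_type <- if (include_attachment_only) c("mixed", "attachment_only") else "mixed"
  cand <- cand %>%
    filter(.data$location == "distal", !is.na(.data$congruence_type),
           .data$congruence_type %in% keep_type)
  w <- function(nm) if (nm %in% names(weights)) weights[[nm]] else 0
  cand <- cand %>%
    mutate(
      score = w("enhancer_mark") * .data$enhancer_mark +
        w("conservation") * .data$conservation +
        w("interaction") * .data$interaction +
        w("motif_site") * .data$motif_site +
        w("promoter_mark") * .data$promoter_mark +
        w("repressive_mark") * .data$repressive_mark
    ) %>%
    arrange(desc(.data$score), abs(.data$distance1), .data$peak_id) %>%
    mutate(rank = row_number()) %>%
    select("rank", "peak_id", "chrom", "start", "end", "class", "location",
           "gene1", "distance1", "gene_label", "congruence_type", "congruent",
           all_of(EVIDENCE_ROLES), "motif_site", "score")
  structure(cand, class = c("bifate_candidates", class(cand)),
            weights = weights)
}
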