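#' Simulation configuration for the synthetic bi-fated study
#'
#' Builds and validates the configuration object consumed by
#' [simulate_genome()], [simulate_expression()], [simulate_atac()],
#' [plant_motifs()] and the one-call wrapper [simulate_study()]. Defaults
#' emulate a five-compartment bulk RNA-seq design (remote/adjacent tenocyte,
#' attachment, adjacent/remote chondrocyte) together with a three-tissue
#' ATAC-seq design (tenocyte, attachment, chondrocyte), with planted
#' tenogenic/chondrogenic/attachment-unique expression effects, planted
#' peak-sharing classes, and a KLF-like CACCC-box motif enriched in
#' attachment-linked distal peaks.
#'
#' @param seed Integer seed; all randomness in the generator derives from it.
#' @param n_chroms Number of chromosomes in the toy genome.
#' @param chrom_length Length of each chromosome in bp.
#' @param n_genes Total number of genes (0 allowed, yielding empty tables).
#' @param class_fractions Named fractions of genes planted per class
#'   (`tenogenic_mixed`, `chondrogenic_mixed`, `tenogenic_nonmixed`,
#'   `chondrogenic_nonmixed`, `attachment_up`, `attachment_down`); must sum
#'   to at most 1, the remainder is `unclassified`. The `nonmixed` classes
#'   are tenocyte/chondrocyte-differential genes that attachment does not
#'   express (their attachment mean sits far below the expression
#'   threshold), emulating the part of the differential set outside the
#'   mixed set. Defaults mirror a 320:54 mixed split plus 23 up / 24 down
#'   attachment-unique genes at 2000 genes.
#' @param n_replicates_expr Expression replicates per compartment.
#' @param n_replicates_atac ATAC replicates per tissue.
#' @param nb_dispersion Negative-binomial dispersion shared by all counts
#'   (0 gives Poisson counts; negative values are an error).
#' @param baseline_mean Baseline expected count per gene/peak unit.
#' @param planted_log2fc Planted log2 effect size; values of at least 1 put
#'   planted genes above the standard 2-fold call threshold in expectation
#'   (0 is allowed and yields a null simulation).
#' @param peak_width_range Length-2 integer vector, min/max peak width in bp.
#' @param background_peak_count Number of unlinked background peaks.
#' @param motif_consensus IUPAC consensus of the planted motif.
#' @param motif_enrichment_ratio Ratio of the attachment-linked to background
#'   motif-planting probability (must be >= 1).
#' @param motif_site_prob Probability that an attachment-linked peak carries a
#'   planted site; background peaks use `motif_site_prob /
#'   motif_enrichment_ratio`. The defaults are calibrated so that after
#'   genes aggregate their linked peaks (own promoter, neighbouring
#'   promoters, background peaks), the per-gene site fractions land near
#'   0.72 for mixed-set genes and 0.53 for the rest of the universe under
#'   the default geometry.
#' @param atac_open_mean Expected normalized count of an accessible peak.
#' @param atac_closed_mean Expected count of a closed peak; the default sits at
#'   a third of the voting threshold of 30 so closed peaks fail the vote with
#'   high probability.
#'
#' @return A list of class `bifate_sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 100)
#' sim <- simulate_study(cfg)
#' names(sim)
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_length = 2e7,
                       n_genes = 2000L,
                       class_fractions = c(
                         tenogenic_mixed = 0.16,
                         chondrogenic_mixed = 0.027,
                         tenogenic_nonmixed = 0.09,
                         chondrogenic_nonmixed = 0.09,
                         attachment_up = 0.0115,
                         attachment_down = 0.012
                       ),
                       n_replicates_expr = 5L,
                       n_replicates_atac = 3L,
                       nb_dispersion = 0.1,
                       baseline_mean = 100,
                       planted_log2fc = 2,
                       peak_width_range = c(200L, 800L),
                       background_peak_count = 500L,
                       motif_consensus = "CCACACCC",
                       motif_enrichment_ratio = 1.7,
                       motif_site_prob = 0.4,
                       atac_open_mean = 120,
                       atac_closed_mean = 10) {
  if (length(n_genes) != 1 || is.na(n_genes) || n_genes < 0) {
    stop_bifate("n_genes must be a non-negative integer")
  }
  if (chrom_length <= 0 || n_chroms <= 0) {
    stop_bifate("chrom_length and n_chroms must be positive")
  }
  if (nb_dispersion < 0) stop_bifate("nb_dispersion must be >= 0")
  if (planted_log2fc < 0) stop_bifate("planted_log2fc must be >= 0")
  bad <- setdiff(names(class_fractions), SIM_CLASSES)
  if (length(bad) > 0) stop_bifate("unknown gene class: %s", paste(bad, collapse = ", "))
  if (any(class_fractions < 0) || sum(class_fractions) > 1 + 1e-12) {
    stop_bifate("class_fractions must be non-negative and sum to at most 1")
  }
  if (length(peak_width_range) != 2 || any(peak_width_range <= 0) ||
      peak_width_range[1] > peak_width_range[2]) {
    stop_bifate("peak_width_range must be an increasing positive pair")
  }
  if (max(peak_width_range) > chrom_length) {
    stop_bifate("peak widths exceed chromosome length")
  }
  if (motif_enrichment_ratio < 1) stop_bifate("motif_enrichment_ratio must be >= 1")
  if (motif_site_prob < 0 || motif_site_prob > 1) {
    stop_bifate("motif_site_prob must be in [0, 1]")
  }
  validate_iupac(motif_consensus)
  structure(
    list(
      seed = as.integer(seed), n_chroms = as.integer(n_chroms),
      chrom_length = as.integer(chrom_length), n_genes = as.integer(n_genes),
      class_fractions = class_fractions,
      n_replicates_expr = as.integer(n_replicates_expr),
      n_replicates_atac = as.integer(n_replicates_atac),
      nb_dispersion = nb_dispersion, baseline_mean = baseline_mean,
      planted_log2fc = planted_log2fc,
      peak_width_range = as.integer(peak_width_range),
      background_peak_count = as.integer(background_peak_count),
      motif_consensus = toupper(motif_consensus),
      motif_enrichment_ratio = motif_enrichment_ratio,
      motif_site_prob = motif_site_prob,
      atac_open_mean = atac_open_mean, atac_closed_mean = atac_closed_mean
    ),
    class = "bifate_sim_config"
  )
}

validate_iupac <- function(consensus) {
  letters <- strsplit(toupper(consensus), "")[[1]]
  bad <- setdiff(letters, names(IUPAC))
  if (length(bad) > 0) {
    stop_bifate("invalid IUPAC letter(s) in consensus: %s", paste(bad, collapse = ", "))
  }
  invisible(consensus)
}

# NB sampler that degrades to Poisson at dispersion 0.
rcounts <- function(n, mu, dispersion) {
  if (dispersion == 0) rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate a toy gene annotation
#'
#' Places genes on evenly spaced, jittered slots along each chromosome with
#' random strand, so that distal peaks planted 6-9 kb from a TSS stay at least
#' 5 kb from every other TSS and promoter/distal classes are unambiguous.
#'
#' @param config A [sim_config()] object.
#' @return A list with `genes` (tibble: `gene_id`, `chrom`, `tss`, `strand`)
#'   and `chrom_sizes` (tibble: `chrom`, `size`).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "bifate_sim_config"))
  set.seed(new_seed_stream(config$seed)[1])
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  chrom_sizes <- tibble(chrom = chroms, size = config$chrom_length)
  n <- config$n_genes
  if (n == 0) {
    genes <- tibble(
      gene_id = character(), chrom = character(),
      tss = integer(), strand = character()
    )
    return(list(genes = genes, chrom_sizes = chrom_sizes))
  }
  per_chrom <- rep(n %/% config$n_chroms, config$n_chroms)
  if (n %% config$n_chroms > 0) {
    per_chrom[seq_len(n %% config$n_chroms)] <- per_chrom[seq_len(n %% config$n_chroms)] + 1L
  }
  genes <- purrr::map2_dfr(chroms, per_chrom, function(ch, k) {
    if (k == 0) return(NULL)
    spacing <- config$chrom_length %/% (k + 1L)
    jitter_max <- min(2000L, max(1L, spacing %/% 10L))
    tss <- spacing * seq_len(k) +
      sample.int(2L * jitter_max + 1L, k, replace = TRUE) - jitter_max - 1L
    tss <- pmin(pmax(tss, 0L), config$chrom_length - 1L)
    tibble(chrom = ch, tss = as.integer(tss),
           strand = sample(c("+", "-"), k, replace = TRUE))
  })
  genes <- genes %>%
    mutate(gene_id = sprintf("g%05d", row_number())) %>%
    select("gene_id", "chrom", "tss", "strand")
  list(genes = genes, chrom_sizes = chrom_sizes)
}

#' Assign planted gene-class labels
#'
#' Draws `round(fraction * n_genes)` genes per class at random (without
#' replacement); remaining genes are `unclassified`.
#'
#' @param genes Gene table from [simulate_genome()].
#' @param config A [sim_config()] object.
#' @return Tibble with `gene_id` and `label`.
#' @export
assign_gene_labels <- function(genes, config) {
  set.seed(new_seed_stream(config$seed)[2])
  labels <- rep("unclassified", nrow(genes))
  pool <- sample(seq_len(nrow(genes)))
  offset <- 0L
  for (cls in names(config$class_fractions)) {
    k <- round(config$class_fractions[[cls]] * nrow(genes))
    if (k > 0) {
      labels[pool[offset + seq_len(k)]] <- cls
      offset <- offset + k
    }
  }
  tibble(gene_id = genes$gene_id, label = labels)
}

compartment_multiplier <- function(label, compartment, lfc) {
  # Expected-count multiplier relative to the gene's baseline mean.
  teno <- compartment %in% c("remote_tenocyte", "adjacent_tenocyte")
  chon <- compartment %in% c("remote_chondrocyte", "adjacent_chondrocyte")
  att <- compartment == "attachment"
  dplyr::case_when(
    label == "tenogenic_mixed" & teno ~ 2^lfc,
    label == "tenogenic_mixed" & att ~ 2^(lfc / 2),
    label == "chondrogenic_mixed" & chon ~ 2^lfc,
    label == "chondrogenic_mixed" & att ~ 2^(lfc / 2),
    label == "tenogenic_nonmixed" & teno ~ 2^lfc,
    label == "tenogenic_nonmixed" & att ~ 0.02,
    label == "chondrogenic_nonmixed" & chon ~ 2^lfc,
    label == "chondrogenic_nonmixed" & att ~ 0.02,
    label == "attachment_up" & att ~ 2^lfc,
    label == "attachment_down" & att ~ 2^(-lfc),
    TRUE ~ 1
  )
}

#' Simulate a five-compartment bulk expression matrix
#'
#' Negative-binomial counts over the five compartments. Tenogenic genes are
#' up `2^planted_log2fc`-fold in both tenocyte compartments and elevated
#' `2^(planted_log2fc/2)`-fold in attachment (the bi-fated gradient);
#' chondrogenic genes mirror this; attachment-up/down genes are shifted only
#' in the attachment compartment; unclassified genes share one mean
#' everywhere. Per-gene baselines are log-normal around `baseline_mean` and
#' per-sample library-size factors are log-normal, so median-of-ratios
#' normalization has real work to do.
#'
#' @param config A [sim_config()] object.
#' @param gene_labels Tibble (`gene_id`, `label`) as from
#'   [assign_gene_labels()].
#' @return List with `counts` (tibble `gene_id` x samples) and `samples`
#'   (tibble `sample`, `compartment`, `replicate`).
#' @export
simulate_expression <- function(config, gene_labels) {
  stopifnot(inherits(config, "bifate_sim_config"))
  bad <- setdiff(unique(gene_labels$label), SIM_CLASSES)
  if (length(bad) > 0) stop_bifate("unknown gene label: %s", paste(bad, collapse = ", "))
  set.seed(new_seed_stream(config$seed)[3])
  n_genes <- nrow(gene_labels)
  samples <- tidyr::expand_grid(
    compartment = COMPARTMENTS,
    replicate = seq_len(config$n_replicates_expr)
  ) %>%
    mutate(sample = sprintf("%s_rep%d", .data$compartment, .data$replicate)) %>%
    select("sample", "compartment", "replicate")
  baseline <- config$baseline_mean * exp(stats::rnorm(n_genes, 0, 0.5))
  lib_factor <- exp(stats::rnorm(nrow(samples), 0, 0.15))
  counts <- matrix(0L, nrow = n_genes, ncol = nrow(samples),
                   dimnames = list(gene_labels$gene_id, samples$sample))
  for (j in seq_len(nrow(samples))) {
    mult <- compartment_multiplier(gene_labels$label, samples$compartment[j],
                                   config$planted_log2fc)
    mu <- baseline * mult * lib_factor[j]
    counts[, j] <- rcounts(n_genes, mu, config$nb_dispersion)
  }
  list(counts = matrix_to_tibble(counts, "gene_id"), samples = samples)
}

# Sharing class planted for the distal peak of each labelled gene.
planted_distal_class <- function(label) {
  dplyr::case_when(
    label == "tenogenic_mixed" ~ "TA",
    label == "chondrogenic_mixed" ~ "AC",
    label == "tenogenic_nonmixed" ~ "T",
    label == "chondrogenic_nonmixed" ~ "C",
    label == "attachment_up" ~ "A",
    TRUE ~ NA_character_
  )
}

class_has_tissue <- function(class, tissue_initial) {
  stringr::str_detect(class, stringr::fixed(tissue_initial))
}

#' Simulate replicate ATAC peak sets with planted sharing classes
#'
#' Emits one promoter peak per gene (accessible in all three tissues), one
#' distal peak 6-9 kb from the TSS of every differential or attachment-up
#' gene -- congruent with its expression program: tenogenic-mixed `TA`,
#' chondrogenic-mixed `AC`, tenogenic-nonmixed `T`, chondrogenic-nonmixed
#' `C`, attachment-up `A` -- and
#' `background_peak_count` unlinked background peaks with sharing classes
#' drawn from all seven tissue combinations. Counts are negative-binomial
#' around `atac_open_mean` in the tissues of a peak's class and
#' `atac_closed_mean` elsewhere; replicate BED intervals carry +-50 bp
#' boundary jitter and a small per-replicate dropout.
#'
#' @inheritParams simulate_expression
#' @param genome Result of [simulate_genome()].
#' @return List with `peaks` (tibble: `peak_id`, `chrom`, `start`, `end`),
#'   `replicate_beds` (named list of interval tibbles, one per
#'   `{tissue}_rep{i}`), `counts` (tibble `peak_id` x samples), `tissue_map`
#'   (tibble `sample`, `tissue`) and `truth` (list: `peak_sharing`,
#'   `peak_gene_link`).
#' @export
simulate_atac <- function(config, gene_labels, genome) {
  stopifnot(inherits(config, "bifate_sim_config"))
  set.seed(new_seed_stream(config$seed)[4])
  genes <- genome$genes
  chrom_len <- config$chrom_length
  wmin <- config$peak_width_range[1]
  wmax <- config$peak_width_range[2]
  if (wmax > chrom_len) stop_bifate("peak widths exceed chromosome length")
  rwidth <- function(n) sample(seq(wmin, wmax), n, replace = TRUE)

  # Promoter peaks: one per gene, centred on its TSS, shared by all tissues.
  prom <- genes %>%
    mutate(
      width = rwidth(dplyr::n()),
      start = pmax(0L, as.integer(.data$tss - .data$width %/% 2L)),
      end = pmin(chrom_len, .data$start + .data$width),
      peak_id = sprintf("prom_%s", .data$gene_id),
      class = "TAC", linked_gene = .data$gene_id
    )

  # Distal peaks: planted congruently with the linked gene's class.
  distal <- genes %>%
    inner_join(gene_labels, by = "gene_id") %>%
    mutate(class = planted_distal_class(.data$label)) %>%
    filter(!is.na(.data$class)) %>%
    mutate(
      offset = sample(c(-1L, 1L), dplyr::n(), replace = TRUE) *
        sample(seq(6000L, 9000L), dplyr::n(), replace = TRUE),
      width = rwidth(dplyr::n()),
      center = pmin(pmax(.data$tss + .data$offset, .data$width), chrom_len - .data$width),
      start = as.integer(.data$center - .data$width %/% 2L),
      end = .data$start + .data$width,
      peak_id = sprintf("dist_%s", .data$gene_id),
      linked_gene = .data$gene_id
    )

  # Background peaks: uniform positions kept >= 5 kb from every TSS and
  # >= 2.5 kb from every planted distal peak, so background elements are
  # distinct loci that cannot merge with, or sit inside the evidence
  # footprint of, a planted enhancer.
  n_bg <- config$background_peak_count
  bg <- NULL
  if (n_bg > 0) {
    classes7 <- c("T", "A", "C", "TA", "TC", "AC", "TAC")
    cand <- tibble(
      chrom = sample(genome$chrom_sizes$chrom, 8L * n_bg, replace = TRUE),
      center = sample.int(chrom_len - 2L * wmax, 8L * n_bg) + wmax
    )
    if (nrow(genes) > 0) {
      keep <- purrr::map2_lgl(cand$chrom, cand$center, function(ch, ce) {
        tss <- genes$tss[genes$chrom == ch]
        dc <- distal$center[distal$chrom == ch]
        (length(tss) == 0 || min(abs(tss - ce)) >= 5000) &&
          (length(dc) == 0 || min(abs(dc - ce)) >= 2500)
      })
      cand <- cand[keep, , drop = FALSE]
    }
    if (nrow(cand) < n_bg) stop_bifate("could not place background peaks away from TSSs")
    bg <- cand[seq_len(n_bg), ] %>%
      mutate(
        width = rwidth(n_bg),
        start = as.integer(.data$center - .data$width %/% 2L),
        end = .data$start + .data$width,
        peak_id = sprintf("bg_%05d", seq_len(n_bg)),
        class = sample(classes7, n_bg, replace = TRUE),
        linked_gene = NA_character_
      )
  }

  cols <- c("peak_id", "chrom", "start", "end", "class", "linked_gene")
  peaks <- bind_rows(prom[cols], distal[cols], if (!is.null(bg)) bg[cols])

  # Count matrix: open/closed NB means per tissue, with library-size noise.
  tissue_map <- tidyr::expand_grid(
    tissue = names(TISSUES), replicate = seq_len(config$n_replicates_atac)
  ) %>%
    mutate(sample = sprintf("%s_rep%d", .data$tissue, .data$replicate)) %>%
    select("sample", "tissue")
  lib_factor <- exp(stats::rnorm(nrow(tissue_map), 0, 0.1))
  counts <- matrix(0, nrow(peaks), nrow(tissue_map),
                   dimnames = list(peaks$peak_id, tissue_map$sample))
  for (j in seq_len(nrow(tissue_map))) {
    open <- class_has_tissue(peaks$class, TISSUES[[tissue_map$tissue[j]]])
    mu <- ifelse(open, config$atac_open_mean, config$atac_closed_mean) * lib_factor[j]
    counts[, j] <- rcounts(nrow(peaks), mu, config$nb_dispersion)
  }

  # Replicate BEDs: a peak appears in a replicate of tissue t iff its class
  # includes t, with boundary jitter and a 3% dropout.
  replicate_beds <- purrr::map(seq_len(nrow(tissue_map)), function(j) {
    open <- class_has_tissue(peaks$class, TISSUES[[tissue_map$tissue[j]]])
    sel <- peaks[open & runif(nrow(peaks)) > 0.03, , drop = FALSE]
    jit <- function(n) sample.int(101L, n, replace = TRUE) - 51L
    sel %>%
      mutate(
        start = pmax(0L, .data$start + jit(dplyr::n())),
        end = pmin(chrom_len, .data$end + jit(dplyr::n())),
        end = pmax(.data$end, .data$start + 50L)
      ) %>%
      select("chrom", "start", "end", name = "peak_id")
  })
  names(replicate_beds) <- tissue_map$sample

  list(
    peaks = select(peaks, "peak_id", "chrom", "start", "end"),
    replicate_beds = replicate_beds,
    counts = matrix_to_tibble(counts, "peak_id"),
    tissue_map = tissue_map,
    truth = list(
      peak_sharing = select(peaks, "peak_id", "class"),
      peak_gene_link = select(peaks, "peak_id", gene_id = "linked_gene")
    )
  )
}

#' Simulate evidence tracks and a blacklist for the prioritizer
#'
#' Enhancer marks (H3K27ac/H3K4me1-like) and conservation intervals cover
#' planted congruent distal peaks with high probability (0.95 and 0.85) and
#' background peaks at a low genomic background rate (0.02 each, roughly the
#' genome fraction such marks occupy); a promoter mark covers promoter
#' peaks; a small blacklist covers a random 2% of background peaks.
#'
#' @inheritParams simulate_atac
#' @param atac Result of [simulate_atac()].
#' @return List with `tracks` (tibble: `name`, `role`, `chrom`, `start`,
#'   `end`) and `blacklist` (interval tibble).
#' @export
simulate_evidence <- function(config, atac) {
  set.seed(new_seed_stream(config$seed)[5])
  info <- atac$peaks %>%
    left_join(atac$truth$peak_sharing, by = "peak_id") %>%
    left_join(atac$truth$peak_gene_link, by = "peak_id")
  planted_distal <- !is.na(info$gene_id) & info$class %in% c("TA", "AC", "A")
  promoter <- grepl("^prom_", info$peak_id)
  background <- grepl("^bg_", info$peak_id)

  cover <- function(idx, name, role) {
    if (sum(idx) == 0) return(NULL)
    info[idx, ] %>%
      mutate(
        mid = (.data$start + .data$end) %/% 2L,
        start = pmax(0L, .data$mid - 250L), end = .data$mid + 250L,
        name = name, role = role
      ) %>%
      select("name", "role", "chrom", "start", "end")
  }
  tracks <- bind_rows(
    cover(planted_distal & runif(nrow(info)) < 0.95, "enh_mark_sim", "enhancer_mark"),
    cover(background & runif(nrow(info)) < 0.02, "enh_mark_sim", "enhancer_mark"),
    cover(planted_distal & runif(nrow(info)) < 0.85, "cons_sim", "conservation"),
    cover(background & runif(nrow(info)) < 0.02, "cons_sim", "conservation"),
    cover(promoter & runif(nrow(info)) < 0.9, "prom_mark_sim", "promoter_mark")
  ) %>% arrange(.data$chrom, .data$start)

  blacklist <- info[background & runif(nrow(info)) < 0.02,
                    c("chrom", "start", "end"), drop = FALSE]
  list(tracks = tracks, blacklist = as_tibble(blacklist))
}

#' Plant motif occurrences into peak sequences
#'
#' Draws a random A/C/G/T sequence for every peak and plants one concrete
#' instance of the configured IUPAC consensus (random strand, random offset)
#' with probability `motif_site_prob` in attachment-linked peaks (distal
#' peaks linked to a gene and accessible in attachment) and
#' `motif_site_prob / motif_enrichment_ratio` in all other peaks.
#'
#' @inheritParams simulate_evidence
#' @return List with `sequences` (tibble: `peak_id`, `sequence`) and
#'   `planted_sites` (tibble: `peak_id`, `offset` (0-based), `strand`).
#' @export
plant_motifs <- function(config, atac) {
  validate_iupac(config$motif_consensus)
  set.seed(new_seed_stream(config$seed)[6])
  info <- atac$peaks %>%
    left_join(atac$truth$peak_sharing, by = "peak_id") %>%
    left_join(atac$truth$peak_gene_link, by = "peak_id")
  foreground <- !is.na(info$gene_id) & !grepl("^prom_", info$peak_id) &
    class_has_tissue(info$class, "A")
  p <- ifelse(foreground, config$motif_site_prob,
              config$motif_site_prob / config$motif_enrichment_ratio)
  widths <- info$end - info$start
  motif_letters <- strsplit(config$motif_consensus, "")[[1]]
  L <- length(motif_letters)
  plant <- runif(nrow(info)) < p & widths >= L

  sequences <- vapply(widths, function(w) {
    paste(sample(c("A", "C", "G", "T"), w, replace = TRUE), collapse = "")
  }, character(1))

  planted <- tibble(peak_id = character(), offset = integer(), strand = character())
  for (i in which(plant)) {
    inst <- vapply(IUPAC[motif_letters], function(s) sample(s, 1), character(1))
    inst <- paste(inst, collapse = "")
    strand <- sample(c("+", "-"), 1)
    put <- if (strand == "+") inst else revcomp(inst)
    off <- sample.int(widths[i] - L + 1L, 1) - 1L
    substr(sequences[i], off + 1L, off + L) <- put
    planted <- bind_rows(planted,
                         tibble(peak_id = info$peak_id[i], offset = off, strand = strand))
  }
  list(
    sequences = tibble(peak_id = info$peak_id, sequence = sequences),
    planted_sites = planted
  )
}

#' Run the whole synthetic-study generator
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `genes`, `chrom_sizes`, `gene_labels`,
#'   `expression`, `atac`, `evidence`, `motifs`, `truth` and `config`.
#'   `truth` gathers the planted ground truth: gene labels, peak sharing
#'   classes, peak-gene links and motif-bearing peak ids.
#' @export
simulate_study <- function(config = sim_config()) {
  genome <- simulate_genome(config)
  gene_labels <- assign_gene_labels(genome$genes, config)
  expression <- simulate_expression(config, gene_labels)
  atac <- simulate_atac(config, gene_labels, genome)
  evidence <- simulate_evidence(config, atac)
  motifs <- plant_motifs(config, atac)
  list(
    genes = genome$genes, chrom_sizes = genome$chrom_sizes,
    gene_labels = gene_labels, expression = expression, atac = atac,
    evidence = evidence, motifs = motifs,
    truth = list(
      gene_labels = gene_labels,
      peak_sharing = atac$truth$peak_sharing,
      peak_gene_link = atac$truth$peak_gene_link,
      motif_bearing_peaks = motifs$planted_sites$peak_id
    ),
    config = config
  )
}

#' Write a simulated study to disk
#'
#' Emits the on-disk layout consumed by [run_pipeline()]: `genes.tsv`,
#' `chrom_sizes.tsv`, `expression_counts.tsv`, `expression_samples.tsv`,
#' one `{tissue}_rep{i}.bed` per ATAC replicate, `atac_counts.tsv`,
#' `tissue_map.tsv`, `blacklist.bed`, `tracks.bed` + `tracks_manifest.tsv`,
#' `peak_sequences.fa` and `ground_truth.json`.
#'
#' @param sim Result of [simulate_study()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  readr::write_tsv(sim$genes, p("genes.tsv"))
  readr::write_tsv(sim$chrom_sizes, p("chrom_sizes.tsv"))
  readr::write_tsv(sim$expression$counts, p("expression_counts.tsv"))
  readr::write_tsv(sim$expression$samples, p("expression_samples.tsv"))
  readr::write_tsv(sim$atac$counts, p("atac_counts.tsv"))
  readr::write_tsv(sim$atac$tissue_map, p("tissue_map.tsv"))
  purrr::iwalk(sim$atac$replicate_beds, function(bed, nm) {
    write_bed(bed, p(sprintf("%s.bed", nm)))
  })
  write_bed(sim$evidence$blacklist, p("blacklist.bed"))
  tracks_bed <- sim$evidence$tracks %>%
    mutate(name = paste(.data$name, .data$role, sep = "|")) %>%
    select("chrom", "start", "end", "name")
  write_bed(tracks_bed, p("tracks.bed"))
  readr::write_tsv(distinct(sim$evidence$tracks[c("name", "role")]),
                   p("tracks_manifest.tsv"))
  write_fasta(sim$motifs$sequences, p("peak_sequences.fa"))
  jsonlite::write_json(
    list(
      gene_labels = sim$truth$gene_labels,
      peak_sharing = sim$truth$peak_sharing,
      peak_gene_link = sim$truth$peak_gene_link,
      motif_bearing_peaks = sim$truth$motif_bearing_peaks
    ),
    p("ground_truth.json"), dataframe = "columns"
  )
  invisible(outdir)
}
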