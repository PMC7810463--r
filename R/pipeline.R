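#' Build a pipeline configuration
#'
#' All stage parameters with their documented defaults (printed study values
#' where one exists: DE thresholds adjusted p <= 0.05 and fold change >= 2,
#' voting threshold 30 in at least 50% of replicates, minimum peak length
#' 500 bp, promoter window 2 kb upstream / 0.5 kb downstream, two nearest
#' genes within 1 Mb). `indir` must contain the file layout written by
#' [write_simulation()] (or equivalently named real inputs); all stage
#' outputs go to `outdir`.
#'
#' @param indir Input directory.
#' @param outdir Output directory.
#' @param alpha,min_fc DE selection thresholds.
#' @param attachment_expr_threshold "Expressed in attachment" cutoff.
#' @param vote_threshold,min_fraction,avg_threshold,min_peak_length Peak
#'   pipeline parameters.
#' @param promoter_upstream,promoter_downstream,max_link_distance Annotation
#'   parameters (bp).
#' @param motif IUPAC consensus scanned in the enrichment stage.
#' @param yates Yates correction for the enrichment chi-square.
#' @param weights Named scoring weights for [score_and_rank()].
#' @param seed Seed recorded in the summary (stages are deterministic given
#'   their input files).
#' @return A list of class `bifate_pipeline_config`.
#' @export
pipeline_config <- function(indir, outdir,
                            alpha = 0.05, min_fc = 2,
                            attachment_expr_threshold = 10,
                            vote_threshold = 30, min_fraction = 0.5,
                            avg_threshold = 30, min_peak_length = 500L,
                            promoter_upstream = 2000L, promoter_downstream = 500L,
                            max_link_distance = 1e6,
                            motif = "CCACACCC", yates = FALSE,
                            weights = default_enhancer_weights(),
                            seed = 1L) {
  structure(
    list(
      indir = indir, outdir = outdir, alpha = alpha, min_fc = min_fc,
      attachment_expr_threshold = attachment_expr_threshold,
      vote_threshold = vote_threshold, min_fraction = min_fraction,
      avg_threshold = avg_threshold, min_peak_length = min_peak_length,
      promoter_upstream = promoter_upstream,
      promoter_downstream = promoter_downstream,
      max_link_distance = max_link_distance,
      motif = motif, yates = yates, weights = weights, seed = as.integer(seed)
    ),
    class = "bifate_pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the [pipeline_config()]
#' defaults.
#'
#' @param path YAML file with keys matching [pipeline_config()] arguments.
#' @return A `bifate_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_bifate("config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) stop_bifate("unknown config key(s): %s", paste(bad, collapse = ", "))
  if (!is.null(vals$weights)) vals$weights <- unlist(vals$weights)
  do.call(pipeline_config, vals)
}

in_path <- function(config, name) {
  p <- file.path(config$indir, name)
  if (!file.exists(p)) stop_bifate("required input file not found: %s", p)
  p
}

out_path <- function(config, name) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  file.path(config$outdir, name)
}

#' Expression stage: classify genes and position the attachment profile
#'
#' Reads `expression_counts.tsv` + `expression_samples.tsv`, runs
#' [classify_genes()] and [compartment_similarity()], writes
#' `gene_labels.tsv`, `de_tenocyte_vs_chondrocyte.tsv` and
#' `pca_coordinates.tsv`.
#'
#' @param config A `bifate_pipeline_config`.
#' @return Invisible list with `labels`, `de`, `similarity`.
#' @export
stage_expression <- function(config) {
  counts <- read_tsv_strict(in_path(config, "expression_counts.tsv"), "counts")
  samples <- read_tsv_strict(in_path(config, "expression_samples.tsv"), "sample metadata")
  labels <- classify_genes(counts, samples, config$alpha, config$min_fc,
                           config$attachment_expr_threshold)
  de <- attr(labels, "de")
  de_genes <- de$gene_id[de$significant]
  sim <- if (length(de_genes) >= 3) {
    compartment_similarity(counts, samples, de_genes)
  } else {
    NULL
  }
  readr::write_tsv(as_tibble(labels), out_path(config, "gene_labels.tsv"))
  readr::write_tsv(as_tibble(de), out_path(config, "de_tenocyte_vs_chondrocyte.tsv"))
  if (!is.null(sim)) {
    readr::write_tsv(sim$pca, out_path(config, "pca_coordinates.tsv"))
    readr::write_tsv(sim$distances, out_path(config, "compartment_distances.tsv"))
  }
  invisible(list(labels = labels, de = de, similarity = sim))
}

#' Peak stage: consensus peaks from replicate BEDs
#'
#' Reads the replicate BEDs named in `tissue_map.tsv`, `atac_counts.tsv`,
#' `blacklist.bed` and `chrom_sizes.tsv`, runs [consensus_peaks()], writes
#' `consensus_peaks.bed`, `accessibility_flags.tsv`,
#' `peak_normalized_counts.tsv` and `filter_report.json`.
#'
#' @param config A `bifate_pipeline_config`.
#' @return Invisible `bifate_consensus`.
#' @export
stage_peaks <- function(config) {
  tissue_map <- read_tsv_strict(in_path(config, "tissue_map.tsv"), "tissue map")
  counts <- read_tsv_strict(in_path(config, "atac_counts.tsv"), "peak counts")
  chrom_sizes <- read_tsv_strict(in_path(config, "chrom_sizes.tsv"), "chrom sizes")
  beds <- purrr::map(tissue_map$sample, function(s) {
    read_bed(in_path(config, sprintf("%s.bed", s)))
  })
  names(beds) <- tissue_map$sample
  blacklist_path <- file.path(config$indir, "blacklist.bed")
  blacklist <- if (file.exists(blacklist_path) &&
                   length(readLines(blacklist_path, n = 1)) > 0) {
    read_bed(blacklist_path)
  } else {
    tibble(chrom = character(), start = integer(), end = integer())
  }
  # Coordinates of the count-matrix rows: union of named replicate peaks.
  locs <- bind_rows(beds) %>%
    group_by(peak_id = .data$name) %>%
    summarise(chrom = .data$chrom[1], start = min(.data$start),
              end = max(.data$end), .groups = "drop")
  cons <- consensus_peaks(
    beds, counts, locs, tissue_map, chrom_sizes, blacklist,
    min_length = config$min_peak_length, threshold = config$vote_threshold,
    min_fraction = config$min_fraction, avg_threshold = config$avg_threshold
  )
  write_bed(cons$peaks %>% mutate(name = .data$peak_id) %>%
              select("chrom", "start", "end", "name"),
            out_path(config, "consensus_peaks.bed"))
  readr::write_tsv(cons$peaks, out_path(config, "consensus_peak_table.tsv"))
  readr::write_tsv(cons$flags, out_path(config, "accessibility_flags.tsv"))
  readr::write_tsv(cons$normalized, out_path(config, "peak_normalized_counts.tsv"))
  readr::write_tsv(cons$provenance, out_path(config, "peak_provenance.tsv"))
  jsonlite::write_json(cons$filter_report, out_path(config, "filter_report.json"),
                       auto_unbox = TRUE)
  invisible(cons)
}

#' Classification stage: sharing classes, annotation and contingency
#'
#' Reads the peak-stage outputs plus `genes.tsv`, runs [annotate_peaks()]
#' and [summarize_sharing()] (on all retained peaks and on the subset
#' linked to tenocyte-vs-chondrocyte DE genes), writes
#' `annotated_peaks.tsv`, `peak_gene_links.tsv`, `venn_counts.json` and
#' `sharing_report.json`.
#'
#' @param config A `bifate_pipeline_config`.
#' @return Invisible list with `annotated`, `sharing_all`, `sharing_de`.
#' @export
stage_classify <- function(config) {
  genes <- read_tsv_strict(in_path(config, "genes.tsv"), "gene table")
  peaks <- read_tsv_strict(file.path(config$outdir, "consensus_peak_table.tsv"),
                           "consensus peaks")
  flags <- read_tsv_strict(file.path(config$outdir, "accessibility_flags.tsv"),
                           "flags")
  annotated <- annotate_peaks(list(peaks = peaks, flags = flags), genes,
                              config$max_link_distance,
                              config$promoter_upstream, config$promoter_downstream)
  links <- link_genes(peaks, genes, config$max_link_distance)
  de_path <- file.path(config$outdir, "de_tenocyte_vs_chondrocyte.tsv")
  de_genes <- NULL
  if (file.exists(de_path)) {
    de <- read_tsv_strict(de_path, "DE table")
    de_genes <- de$gene_id[de$significant]
  }
  sharing_all <- summarize_sharing(annotated, yates = config$yates)
  sharing_de <- if (!is.null(de_genes) && length(de_genes) > 0) {
    summarize_sharing(annotated, gene_set = de_genes, yates = config$yates)
  } else {
    NULL
  }
  readr::write_tsv(as_tibble(annotated), out_path(config, "annotated_peaks.tsv"))
  readr::write_tsv(links, out_path(config, "peak_gene_links.tsv"))
  jsonlite::write_json(attr(annotated, "venn_counts"),
                       out_path(config, "venn_counts.json"), dataframe = "columns")
  report <- list(all_peaks = sharing_summary_json(sharing_all),
                 de_linked_peaks = sharing_summary_json(sharing_de))
  jsonlite::write_json(report, out_path(config, "sharing_report.json"),
                       auto_unbox = TRUE, dataframe = "columns", digits = NA)
  invisible(list(annotated = annotated, sharing_all = sharing_all,
                 sharing_de = sharing_de))
}

sharing_summary_json <- function(s) {
  if (is.null(s)) return(NULL)
  list(
    n_peaks = s$n_peaks,
    location_table = s$location_table,
    venn_counts = s$venn_counts,
    attachment_decomposition = s$attachment_decomposition,
    contingency = if (!is.null(s$contingency)) {
      list(statistic = s$contingency$statistic, p_value = s$contingency$p_value,
           yates = s$contingency$yates_corrected)
    }
  )
}

#' Prioritization stage: score candidate shared enhancers
#'
#' Reads `annotated_peaks.tsv`, `gene_labels.tsv`, the evidence `tracks.bed`
#' + `tracks_manifest.tsv` and (when present) motif hits from the
#' enrichment stage, and writes `candidate_enhancers.tsv`.
#'
#' @param config A `bifate_pipeline_config`.
#' @return Invisible `bifate_candidates`.
#' @export
stage_prioritize <- function(config) {
  annotated <- read_tsv_strict(file.path(config$outdir, "annotated_peaks.tsv"),
                               "annotated peaks")
  labels <- read_tsv_strict(file.path(config$outdir, "gene_labels.tsv"),
                            "gene labels")
  tracks_bed <- read_bed(in_path(config, "tracks.bed"))
  tracks <- tracks_bed %>%
    tidyr::separate("name", into = c("name", "role"), sep = "\\|") %>%
    select("name", "role", "chrom", "start", "end")
  evidence <- overlap_evidence(annotated, tracks)
  hits_path <- file.path(config$outdir, "motif_hits.tsv")
  motif_peaks <- if (file.exists(hits_path)) {
    unique(read_tsv_strict(hits_path, "motif hits")$peak_id)
  } else {
    character()
  }
  cand <- score_and_rank(annotated, evidence, labels, motif_peaks,
                         weights = config$weights)
  readr::write_tsv(as_tibble(cand), out_path(config, "candidate_enhancers.tsv"))
  invisible(cand)
}

#' Enrichment stage: KLF-type motif sites in linked peaks
#'
#' Scans `peak_sequences.fa` (restricted to retained peaks) for the
#' configured consensus, builds the per-gene site table over the peak-gene
#' links, and tests the mixed-transcriptome gene set against the full gene
#' universe. Writes `motif_hits.tsv`, `gene_site_table.tsv` and
#' `enrichment.json`.
#'
#' @param config A `bifate_pipeline_config`.
#' @return Invisible list with `hits`, `site_table`, `enrichment`.
#' @export
stage_enrich <- function(config) {
  genes <- read_tsv_strict(in_path(config, "genes.tsv"), "gene table")
  labels <- read_tsv_strict(file.path(config$outdir, "gene_labels.tsv"),
                            "gene labels")
  links <- read_tsv_strict(file.path(config$outdir, "peak_gene_links.tsv"),
                           "peak-gene links")
  annotated <- read_tsv_strict(file.path(config$outdir, "annotated_peaks.tsv"),
                               "annotated peaks")
  seqs <- read_fasta(in_path(config, "peak_sequences.fa"))
  # Sequences are keyed by input peak id; map them onto retained consensus
  # peaks via the provenance table.
  prov <- read_tsv_strict(file.path(config$outdir, "peak_provenance.tsv"),
                          "provenance")
  seqs <- seqs %>%
    inner_join(prov, by = c(peak_id = "input_peak")) %>%
    filter(.data$peak_id.y %in% annotated$peak_id) %>%
    select(peak_id = "peak_id.y", "sequence")
  motif <- motif_consensus(config$motif)
  hits <- scan_peaks(seqs, motif)
  site <- gene_site_table(genes$gene_id, links, hits,
                          locations = annotated[c("peak_id", "location")])
  mixed <- labels$gene_id[labels$label %in% c("tenogenic_mixed", "chondrogenic_mixed")]
  enr <- if (length(mixed) > 0 && length(mixed) < nrow(genes)) {
    set_enrichment(mixed, genes$gene_id, site$gene_table, yates = config$yates)
  } else {
    NULL
  }
  readr::write_tsv(hits, out_path(config, "motif_hits.tsv"))
  readr::write_tsv(site$gene_table, out_path(config, "gene_site_table.tsv"))
  readr::write_tsv(site$detail, out_path(config, "gene_site_detail.tsv"))
  if (!is.null(enr)) {
    jsonlite::write_json(
      list(
        foreground_fraction = enr$foreground_fraction,
        background_fraction = enr$background_fraction,
        statistic = enr$statistic, p_value = enr$p_value,
        yates = enr$yates_corrected,
        n_foreground = enr$n_foreground, n_universe = enr$n_universe
      ),
      out_path(config, "enrichment.json"), auto_unbox = TRUE, digits = NA
    )
  }
  invisible(list(hits = hits, site_table = site, enrichment = enr))
}

#' Run the full pipeline
#'
#' Executes expression -> peaks -> classify -> enrich -> prioritize (the
#' enrichment scan runs before prioritization so candidate scoring can use
#' the motif-site flag). Every stage reads and writes files only, so stages
#' are independently re-runnable; a stage failure aborts with the failing
#' stage named, keeping earlier outputs. The machine-readable
#' `summary.json` gathers every headline count and fraction.
#'
#' @param config A `bifate_pipeline_config` or path to a YAML file.
#' @return The summary list, invisibly; also written to
#'   `<outdir>/summary.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "bifate_pipeline_config"))
  run_stage <- function(name, fun) {
    tryCatch(fun(config), error = function(e) {
      stop_bifate("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  expr <- run_stage("expression", stage_expression)
  peaks <- run_stage("peaks", stage_peaks)
  cls <- run_stage("classify", stage_classify)
  enr <- run_stage("enrich", stage_enrich)
  cand <- run_stage("prioritize", stage_prioritize)

  labels <- as_tibble(expr$labels)
  label_counts <- as.list(table(factor(labels$label, levels = GENE_CLASSES)))
  sharing <- cls$sharing_all
  summary <- list(
    parameters = config[setdiff(names(config), c("weights"))],
    weights = as.list(config$weights),
    gene_classes = label_counts,
    mixed_set_size = label_counts$tenogenic_mixed + label_counts$chondrogenic_mixed,
    n_de_genes = sum(expr$de$significant),
    closer_to = if (!is.null(expr$similarity)) expr$similarity$closer_to,
    filter_report = peaks$filter_report,
    venn_counts = setNames(as.list(sharing$venn_counts$n), sharing$venn_counts$class),
    sharing = sharing_summary_json(sharing),
    sharing_de_linked = sharing_summary_json(cls$sharing_de),
    n_candidates = nrow(cand),
    enrichment = if (!is.null(enr$enrichment)) {
      list(
        foreground_fraction = enr$enrichment$foreground_fraction,
        background_fraction = enr$enrichment$background_fraction,
        p_value = enr$enrichment$p_value
      )
    }
  )
  jsonlite::write_json(summary, out_path(config, "summary.json"),
                       auto_unbox = TRUE, dataframe = "columns", digits = NA)
  invisible(summary)
}
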