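# Shared fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small study: fast enough for unit tests, large enough to carry structure.
small_sim <- function() {
  memo("small_sim", function() {
    simulate_study(sim_config(seed = 42, n_genes = 300,
                              background_peak_count = 80))
  })
}

# Default-scale study used by the planted-recovery acceptance suite.
default_sim <- function() {
  memo("default_sim", function() simulate_study(sim_config(seed = 7)))
}

default_gene_classes <- function() {
  memo("default_gene_classes", function() {
    sim <- default_sim()
    classify_genes(sim$expression$counts, sim$expression$samples)
  })
}

default_consensus <- function() {
  memo("default_consensus", function() {
    sim <- default_sim()
    consensus_peaks(
      sim$atac$replicate_beds, sim$atac$counts, sim$atac$peaks,
      sim$atac$tissue_map, sim$chrom_sizes, sim$evidence$blacklist
    )
  })
}

# The recovered label a planted class should map to downstream.
expected_label <- function(planted) {
  ifelse(planted %in% c("tenogenic_nonmixed", "chondrogenic_nonmixed"),
         "unclassified", planted)
}
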