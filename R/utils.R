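# Internal helpers shared across modules.

# The three chromatin tissues, in canonical order. Sharing-class labels are
# built by concatenating the initials of the accessible tissues in this order.
TISSUES <- c(tenocyte = "T", attachment = "A", chondrocyte = "C")

# The five expression compartments of the dissection design.
COMPARTMENTS <- c(
  "remote_tenocyte", "adjacent_tenocyte", "attachment",
  "adjacent_chondrocyte", "remote_chondrocyte"
)

GENE_CLASSES <- c(
  "tenogenic_mixed", "chondrogenic_mixed",
  "attachment_up", "attachment_down", "unclassified"
)

# Plantable classes in the generator: the classifier's output domain plus
# tenocyte/chondrocyte-differential genes that attachment does NOT express
# (recovered as "unclassified" downstream, like their real counterparts).
SIM_CLASSES <- c(GENE_CLASSES, "tenogenic_nonmixed", "chondrogenic_nonmixed")

EVIDENCE_ROLES <- c(
  "enhancer_mark", "promoter_mark", "repressive_mark",
  "conservation", "interaction"
)

# IUPAC nucleotide codes -> the set of concrete bases each matches.
# N is deliberately absent from any subject-side match: a sequence N matches
# no motif letter (including N itself), so ambiguous sequence never produces
# a hit.
IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# Round half away from zero (reports use 86%, not banker's rounding).
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

stop_bifate <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "bifate_error")
}

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_bifate("%s is missing column(s): %s", what, paste(missing, collapse = ", "))
  }
  invisible(df)
}

# Validate a 0-based half-open interval tibble (chrom, start, end).
assert_intervals <- function(df, what = "intervals") {
  assert_columns(df, c("chrom", "start", "end"), what)
  if (nrow(df) > 0) {
    if (any(df$start < 0)) stop_bifate("%s: negative start coordinate", what)
    if (any(df$start >= df$end)) stop_bifate("%s: start must be < end (0-based half-open)", what)
  }
  invisible(df)
}

# tibble (0-based half-open) -> GRanges (1-based closed) and back.
intervals_to_granges <- function(df) {
  assert_intervals(df)
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

granges_to_intervals <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

# Extract the numeric sample matrix from a tibble whose first column is an id.
counts_to_matrix <- function(counts, id_col = names(counts)[1]) {
  m <- as.matrix(counts[setdiff(names(counts), id_col)])
  rownames(m) <- counts[[id_col]]
  storage.mode(m) <- "double"
  m
}

matrix_to_tibble <- function(m, id_col) {
  out <- as_tibble(m)
  out[[id_col]] <- rownames(m)
  select(out, all_of(id_col), dplyr::everything())
}

new_seed_stream <- function(seed) {
  # Independent sub-seeds for the generator's stages, all < 2^31.
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, 16L)
}
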