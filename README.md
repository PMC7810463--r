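# bifate

Integrative transcriptome + chromatin-accessibility analysis of **bi-fated**
cell states — transitional cell populations, such as the tendon-to-bone
attachment cells of the enthesis, that express a *mixture* of the
transcriptional programs of their two neighbouring cell types (tenocytes
and chondrocytes) and borrow open-chromatin elements from both.

The package is aimed at developmental and regulatory genomicists who have:

* a bulk RNA-seq count matrix over a five-compartment dissection design
  (remote tenocyte, adjacent tenocyte, attachment, adjacent chondrocyte,
  remote chondrocyte), and
* per-replicate ATAC-seq peak sets with a peak × sample count matrix over
  three tissues (tenocyte, attachment, chondrocyte),

and want to ask, quantitatively: is the middle population bi-fated, and is
that state driven by shared distal regulatory elements?

## What it computes

1. **Mixed-transcriptome classifier** — median-of-ratios normalization, a
   pluggable per-gene Welch test on `log2(norm + 1)` with BH adjustment,
   and the selection rule *adjusted p ≤ 0.05 and fold change ≥ 2*. Genes
   partition into `tenogenic_mixed`, `chondrogenic_mixed`,
   `attachment_up`, `attachment_down`, `unclassified`; the mixed set is
   genes differential between tenocytes and chondrocytes that attachment
   cells also express.
2. **Replicate-voting consensus peak pipeline** — merge (book-ended
   intervals fuse) → extend to ≥ 500 bp → normalize → vote (normalized
   count ≥ 30 in ≥ 50% of a tissue's replicates) → filter
   (unreproducible / blacklisted / low-signal peaks), with a removal
   report per rule.
3. **Sharing classifier** — each retained peak gets one of the 7 sharing
   classes (non-empty subsets of {T, A, C}), promoter/distal annotation
   against the strand-aware TSS window (−2 kb … +0.5 kb), two
   nearest-gene links within 1 Mb, and the promoter-vs-distal ×
   common-vs-differential chi-square (`Σ(|O−E|−c)²/E`, df = 1, optional
   Yates correction with `c = min(0.5, |O−E|)`).
4. **Shared-enhancer prioritizer** — hard gates (distal ∧ congruent with
   the linked gene's program ∧ mixed-set gene) plus a configurable
   additive evidence score (enhancer mark +2, conservation +1,
   interaction +1, motif site +1, promoter mark −1).
5. **KLF/CACCC-box motif enrichment** — a generic IUPAC/PWM scanner (both
   strands, N never matches) and a per-gene site table tested
   foreground-vs-universe by chi-square.
6. **Synthetic-data generator** — a seeded five-compartment NB expression
   matrix, replicate peak sets with planted sharing classes, evidence
   tracks and motif placements, with full ground truth; every stage of the
   package is testable against it offline.

## Worked example

```r
library(bifate)

sim <- simulate_study(sim_config(seed = 1, n_genes = 300,
                                 background_peak_count = 80))

labels <- classify_genes(sim$expression$counts, sim$expression$samples)
table(labels$label)
#>    attachment_down      attachment_up chondrogenic_mixed    tenogenic_mixed
#>                  4                  3                  8                 48
#>       unclassified
#>                237
```

The generator planted 48 tenogenic-mixed, 8 chondrogenic-mixed, 3 up- and
4 down-regulated attachment genes at this size — the classifier recovers
them exactly. The attachment profile sits closer to tenocytes, as the
48:8 imbalance predicts:

```r
de <- attr(labels, "de")   # tenocyte-vs-chondrocyte contrast
simres <- compartment_similarity(sim$expression$counts,
                                 sim$expression$samples,
                                 de$gene_id[de$significant])
glance(simres)
#> # A tibble: 1 × 3
#>   closer_to distance_tenocyte distance_chondrocyte
#>   <chr>                 <dbl>                <dbl>
#> 1 tenocyte              0.561                 1.08
```

Chromatin side — consensus peaks, sharing classes, and the
attachment-accessible decomposition of differential distal peaks
(`attachment_accessible = shared_with_one + attachment_only`):

```r
cons <- consensus_peaks(sim$atac$replicate_beds, sim$atac$counts,
                        sim$atac$peaks, sim$atac$tissue_map,
                        sim$chrom_sizes, sim$evidence$blacklist)
ann <- annotate_peaks(cons, sim$genes)
glance(summarize_sharing(ann))
#> # A tibble: 1 × 6
#>   n_peaks contingency_statistic contingency_p attachment_accessible
#>     <int>                 <dbl>         <dbl>                 <int>
#> 1     492                  451.     3.70e-100                    91
#> # ℹ 2 more variables: shared_with_one <int>, attachment_only <int>
```

Promoter peaks are overwhelmingly shared by all three cell types while
distal peaks are overwhelmingly cell-type-restricted — the chi-square
makes that contrast explicit. Finally, rank candidate shared enhancers:

```r
ev <- overlap_evidence(ann, sim$evidence$tracks)
hits <- scan_peaks(sim$motifs$sequences, motif_consensus("CCACACCC"))
cand <- score_and_rank(ann, ev, labels, motif_peaks = unique(hits$peak_id))
head(dplyr::select(tibble::as_tibble(cand),
                   rank, peak_id, class, gene1, distance1, score), 3)
#> # A tibble: 3 × 6
#>    rank peak_id     class gene1  distance1 score
#>   <int> <chr>       <chr> <chr>      <int> <dbl>
#> 1     1 peak_000368 A     g00226     -6009     3
#> 2     2 peak_000186 TA    g00113      6051     3
#> 3     3 peak_000303 TA    g00188      6227     3
```

Every result type has broom-style `tidy()`/`glance()` methods and a
ggplot2 `autoplot()` (volcano, PCA, Venn-cell bars, enrichment fractions,
candidate scores). The whole chain also runs file-to-file from one config:

```r
write_simulation(sim, "sim")
run_pipeline(pipeline_config("sim", "out"))   # writes out/summary.json
```

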