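---
title: "Methods: testing for a bi-fated cell state from transcriptome and chromatin accessibility"
author: "bifate package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: testing for a bi-fated cell state}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the package addresses

Transitional tissues such as the tendon-to-bone attachment (the enthesis)
sit between two well-defined cell types, here tenocytes (tendon
fibroblasts, markers *Scx*, *Col1a1*) and chondrocytes (cartilage cells,
markers *Sox9*, *Col2a1*). A "bi-fated" cell state is one that expresses a
mixture of both neighbours' transcriptional programs rather than a wholly
novel one, and whose open-chromatin landscape likewise borrows regulatory
elements from both sides. `bifate` implements the full analytical chain
needed to test this hypothesis on a five-compartment bulk RNA-seq design
(remote tenocyte, adjacent tenocyte, attachment, adjacent chondrocyte,
remote chondrocyte) combined with three-tissue ATAC-seq (tenocyte,
attachment, chondrocyte), plus a seeded synthetic-data generator so that
every stage is testable without any external sequencing data.

## The expression model and the mixed-transcriptome set

Counts are normalized by the median-of-ratios size-factor estimator: the
reference is the per-gene geometric mean over samples (genes with a zero
anywhere are excluded from the reference), and each sample's factor is the
median ratio of its counts to that reference. This is the standard
estimator for sequencing counts; it is reused verbatim for the ATAC peak
count matrix, so both matrices share one code path and one set of
invariants.

Differential expression between the pooled tenocyte and pooled chondrocyte
compartments uses a per-gene Welch (unequal-variance) two-sample *t* test on
`log2(normalized + 1)`, with Benjamini-Hochberg adjustment and the selection
rule *adjusted p <= alpha* (default 0.05) **and** *fold change >= min_fc*
(default 2, computed on normalized means with a pseudocount of 1). The
test statistic is deliberately pluggable (`test_fun`): the thresholds, not
the engine, define the selection rule, and a negative-binomial engine can be
swapped in without touching anything downstream. Genes with zero variance
in both groups get *p* = 1 by convention; output ordering is by gene id so
ties are deterministic.

Gene classes are then assigned, mutually exclusively:

* `tenogenic_mixed` / `chondrogenic_mixed` — differential between
  tenocytes and chondrocytes, *and* expressed by attachment cells
  (mean normalized attachment count at or above a threshold, default 10;
  the notion "expressed in attachment" has no published number, so the
  threshold is an explicit parameter).
* `attachment_up` / `attachment_down` — significant in the *same*
  direction against **both** neighbours. A gene already differential
  between tenocytes and chondrocytes is never given an attachment-unique
  label: in this design the attachment-unique clusters are disjoint from
  the tenocyte/chondrocyte axis, so the tenocyte-vs-chondrocyte call takes
  precedence.
* `unclassified` — everything else, so the five labels always partition
  the gene universe.

Designs like this are often summarized by clustering expression profiles
into five groups (tenogenic, chondrogenic, adjacent-tissue and
attachment-unique clusters); `bifate` reproduces those groups
*semantically* by the threshold rules above rather than by a clustering
algorithm. `compartment_similarity()`
quantifies the bi-fated positioning: correlation distance (1 − Pearson r of
mean log profiles over a gene set) from attachment to each neighbour, plus
a sample-level PCA of the log-normalized matrix.

## The consensus peak pipeline

Per-replicate peak interval sets (upstream peak calling is out of scope;
BED files are inputs) pass through merge → extend → normalize → vote →
filter:

1. **Merge**: maximal union; intervals that overlap or are book-ended
   (gap 0) fuse. Coordinates are 0-based half-open throughout.
2. **Extend** to a minimum length of 500 bp, symmetrically about the
   midpoint, odd remainder to the right (documented, arbitrary); at a
   chromosome edge the deficit is pushed to the other side before
   clipping.
3. **Quantify + normalize**: counts for each consensus peak are aggregated
   from the input peak count matrix (rows whose midpoint falls inside the
   consensus peak) and normalized by median-of-ratios.
4. **Vote**: a peak is accessible in a tissue when a normalized count
   >= 30 occurs in at least 50% of that tissue's replicates; both bounds
   are inclusive.
5. **Filter**, reporting removals per rule in order: peaks accessible in
   no tissue; peaks overlapping a blacklist interval by >= 1 bp (any
   overlap removes — no minimum-overlap grace); peaks whose
   mean normalized count is below 30 in every tissue.

## Sharing classes, annotation, and contingency statistics

Each retained peak's three accessibility flags define its sharing class —
one of the seven non-empty subsets of {T, A, C}, the cells of a three-way
Venn diagram. The voting flag is the single definition of "accessible";
no second differential test is layered on top.

Peaks link to their two nearest genes by absolute midpoint-to-TSS distance
within 1 Mb (ties broken lexicographically by gene id; signed distances are
strand-aware, negative upstream). A peak is a *promoter* peak when it
overlaps, by >= 1 bp, the strand-aware window from 2 kb upstream to 0.5 kb
downstream of a linked TSS; otherwise *distal* — the standard HOMER-style
promoter annotation window.

`summarize_sharing()` reports, per location, common (TAC) versus
differential counts with integer percentages (rounded half away from zero;
raw fractions always emitted alongside), the attachment-accessible
decomposition of differential distal peaks (shared-with-one, classes
TA/AC, versus attachment-only, class A), and the location × sharing
chi-square. The 2×2 chi-square is the closed form
`sum((|O − E| − c)² / E)` with df = 1; under the Yates continuity
correction `c = min(0.5, |O − E|)` per cell. Flooring the correction at
|O − E| keeps the corrected statistic from ever exceeding the uncorrected
one (the plain `c = 0.5` form violates that on cells deviating by less
than half a count) and coincides with the plain form on any
published-scale table.

## Enhancer candidate prioritization

Only distal peaks are eligible. A peak is *congruent* when its sharing
class matches its linked gene's program: class AC for a
chondrogenic-mixed gene, class TA for a tenogenic-mixed gene.
Attachment-only peaks (class A) at attachment-up genes are reported
separately, never as congruent. Evidence tracks (enhancer marks such as
H3K27ac/H3K4me1, promoter marks, repressive marks, conservation elements,
chromatin-interaction anchors) set per-role flags by >= 1 bp overlap with
OR semantics across tracks of a role.

Candidate selection for in vivo validation is, in practice, a manual
weighing of evidence lines with no canonical scoring function. `bifate`
formalizes it as an explicit,
configurable additive score — enhancer mark +2, conservation +1,
interaction +1, motif site +1, promoter mark −1, repressive mark 0 —
with histone-mark evidence weighted first, and ties broken by
absolute TSS distance then peak id. The weights are documented as
arbitrary; the hard gates (distal ∧ congruent ∧ mixed-set gene), which are
grounded, do the real work.

## Motif scanning and gene-set enrichment

The scanner is generic and self-contained: consensus mode matches IUPAC
classes position by position on both strands (an `N` in the sequence never
matches anything); PWM mode scores log-odds against a uniform background
(configurable) and calls hits at a fraction of the maximum achievable
score. Minus-strand hits are found by scanning the forward sequence with
the reverse-complemented motif, so offsets are always forward-strand
0-based. No default motif ships with the package: curated KLF matrices are
typically proprietary (commercial TFBS databases), and inventing a
biological ground truth would be worse than requiring the user to supply a
consensus or PWM.
Fixtures use a synthetic CACCC-box-like consensus (`CCACACCC`).

A gene "has a site" when any of its linked retained peaks contains a hit;
enrichment of a foreground gene set against the rest of the gene universe
("whole genome" is operationalized as the annotation's gene universe) is
the 2×2 chi-square above, with the Yates correction selectable by flag so
both flavours are computable.

## The synthetic-data generator

The generator emulates the study's statistical structure with known ground
truth; its defaults are the package's canonical test conditions.

* **Genome**: 2 chromosomes × 20 Mb, 2000 genes on evenly spaced jittered
  slots (~20 kb apart), random strand. The spacing guarantees distal peaks
  planted 6–9 kb from a TSS stay >= 5 kb from every other TSS, keeping
  promoter/distal classes unambiguous.
* **Expression**: negative-binomial counts (shared dispersion 0.1 —
  the real data's model is unknown; NB is the field standard), per-gene
  log-normal baselines around 100 and per-sample log-normal library
  factors so normalization has real work to do. Five compartments × 5
  replicates (5 per group is the scale at which the package's power
  properties are stated and tested). Planted classes: tenogenic/chondrogenic-mixed genes (fractions
  0.16 / 0.027, mirroring the 320:54 imbalance) are up 2^2-fold on their
  side and elevated 2^1-fold in attachment — the geometric midpoint,
  i.e. the bi-fated gradient; attachment-up/down genes (23 / 24 at
  n = 2000) shift only in attachment; tenogenic/chondrogenic-*nonmixed*
  genes (0.09 each) are differential but attachment-silent (multiplier
  0.02, far below the expression threshold). The nonmixed classes matter:
  without differential genes that attachment does *not* express, the
  attachment profile is exactly equidistant from both neighbours under
  correlation distance and the "closer to tenocytes" behaviour could not
  emerge from the planted imbalance.
* **ATAC**: one promoter peak per gene (class TAC), one congruent distal
  peak per labelled gene (TA, AC, T, C, or A by class), and 500 unlinked
  background peaks with random sharing classes, kept >= 5 kb from every
  TSS and >= 2.5 kb from every planted distal peak so background elements
  are distinct loci that can neither merge with nor sit inside the
  evidence footprint of a planted enhancer. Open peaks have NB mean 120,
  closed peaks 10 — a third of the voting threshold, so closed states fail
  the vote with high probability. Replicate BEDs carry ±50 bp boundary
  jitter and 3% dropout.
* **Evidence**: enhancer-mark and conservation intervals cover planted
  congruent distal peaks with probability 0.95 and 0.85 and background
  peaks at 0.02 each (roughly the genome fraction such marks occupy);
  promoter marks cover promoters at 0.9; a blacklist covers 2% of
  background peaks.
* **Motifs**: attachment-linked distal peaks carry one planted consensus
  instance with probability 0.4, all other peaks with 0.4 / 1.7. These
  per-peak values are calibrated so that after genes aggregate their
  linked peaks (own promoter, neighbouring promoters, background peaks —
  about three peaks per gene under the default geometry) the per-*gene*
  site fractions land near 72% for mixed-set genes and 53% for the rest —
  the scale of gene-level KLF-site contrasts reported for attachment
  transcriptomes.

What the generator does **not** emulate: read-level data (FASTQ/BAM),
fragment-size structure, gene-gene correlation, GC or mappability biases,
batch effects, and real motif composition of regulatory sequence
(backgrounds are i.i.d. uniform). Passing the planted-recovery suite
therefore demonstrates the pipeline's correctness and calibration on data
matching its model assumptions, not performance on real sequencing data.

## Numerical choices and degenerate inputs

* 0-based half-open intervals everywhere; BED I/O via `rtracklayer`
  converts at the boundary.
* Extension parity: the odd base goes rightward.
* Percentages round half away from zero; raw fractions accompany them.
* Zero-variance genes: *p* = 1. No gene positive in all samples:
  normalization errors rather than silently switching reference.
* All-false accessibility flags are a voting-stage concern;
  `venn_partition()` treats them as a contract violation and errors.
* `n_genes = 0` is legal and yields empty tables; negative sizes error.
* Determinism: every stochastic stage derives its stream from one seed;
  rerunning a pipeline config reproduces `summary.json` byte for byte.

## Problem sizes used by the test suite

The suites run the generator at its default scale (2000 genes, ~3200
peaks) for planted-recovery checks, 10,000 random interval sets for the
merge/extend oracles (batched over per-set chromosome namespaces), 1,000
random p-vectors for the BH oracle, and two 2000-gene null simulations
plus 200 enrichment-table simulations for calibration — sizes chosen so
the whole suite completes in a few minutes on one CPU while keeping
binomial noise well inside the stated tolerances.

## Known limitations

* The Welch-on-log test is less powerful than a shared-dispersion NB model
  at very low replicate numbers; the pluggable interface exists for that
  reason.
* Gene linking is nearest-TSS within a cap, not regulatory-domain based;
  enhancers regulating a non-nearest gene are mis-linked by construction.
* The enhancer score is a formalization of a manual choice; ranks should
  be read as a prioritization aid, not a calibrated probability.
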