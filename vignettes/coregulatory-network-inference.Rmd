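---
title: "Inferring a dual transcription-factor co-regulated network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring a dual transcription-factor co-regulated network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfcoreg)
```

## The model

`tfcoreg` formalizes a simple but strict definition of direct
co-regulation by two transcription factors A and B. A gene *g* is a
co-regulated target iff

1. *g* is down-regulated in the knockout contrast of A **and** in the
   knockout contrast of B — each at FDR ≤ 0.05 with negative log2 fold
   change — and
2. A **and** B each have a ChIP-seq peak assigned to *g* within the
   annotation window.

Both conditions are evidence filters, not parameter fits: the package
consumes per-gene (logFC, FDR) pairs from an upstream differential
expression model and peak intervals from an upstream peak caller, and
everything downstream of those inputs — thresholding, annotation,
intersection, network assembly, enrichment — is computed here. The key
assumptions are (i) that binding within 10 kb of a TSS is a reasonable
proxy for direct regulation of that gene, (ii) that the knockouts
perturb the factors specifically enough that shared down-regulation plus
shared binding implies co-regulation, and (iii) that gene-level TSS
annotation suffices (transcript-level start-site selection is not
attempted; when a gene model carries several records, their union span is
used and the TSS is derived from the span and strand).

## Peak-to-TSS annotation

Coordinates are 0-based half-open throughout (the BED convention; GTF is
converted on ingest and back on export, losslessly). The TSS is the first
transcribed base: `start` on the plus strand, `end − 1` on the minus
strand. Each peak is anchored at its summit when one was called, else at
its interval midpoint — the summit is the peak caller's best estimate of
the binding point, so it is preferred wherever available.

Candidate genes for a peak are those whose TSS lies within the TSS window
of the anchor plus those whose body overlaps the peak interval. Each
candidate is classified by precedence, most specific first:

1. `promoter` — the peak interval contains the TSS base;
2. `proximal` — the peak interval overlaps the gene body;
3. `putative_promoter` — |anchor − TSS| ≤ 3 kb;
4. `putative_distal` — 3 kb < |anchor − TSS| ≤ 10 kb.

Distances are classified by absolute value (the scheme is symmetric
around the TSS) but reported strand-signed, negative meaning upstream in
the gene's own orientation. Three conventions were genuinely open and are
fixed, documented and tested as follows:

* **Boundaries are inclusive toward the nearer class**: exactly 3,000 bp
  is `putative_promoter`; exactly 10,000 bp is still assigned. The
  boundary suite in the tests pins 2,999/3,000/3,001 and
  9,999/10,000/10,001 bp explicitly.
* **Multi-gene assignment**: a peak annotates *every* candidate gene, with
  the nearest flagged (`is_nearest_gene`); a nearest-only mode is a
  switch. Dense loci genuinely have multi-gene peaks, and dropping them
  silently would bias the bound sets.
* **Gene-body peaks beyond the TSS window** are kept (class `proximal` is
  defined by the overlap, not by distance): a body overlap is direct
  positional evidence even in a long gene.

The indexed implementation (IRanges interval queries per chromosome) is
required by the tests to agree *exactly* — classes, gene sets, signed
distances — with a quadratic brute-force classifier on a random genome of
200 genes × 1,000 peaks, and to be invariant under mirroring the
coordinate axis with all strands flipped.

## Expression preprocessing

* **CPM** = count / library size × 10⁶, on raw library sizes. The
  expression filter (keep genes with CPM ≥ 0.5 in ≥ 2 libraries) runs
  before any between-library normalization, the standard
  filter-then-normalize order; it is idempotent by construction.
* **TMM factors** implement the published trimmed-mean-of-M-values
  estimator: reference library = the one whose upper-quartile CPM is
  closest to the mean upper-quartile; per-gene M and A over genes positive
  in both libraries; two-sided trims of 30 % on M and 5 % on A; factor =
  2 to the inverse-variance-weighted mean of the retained M, with
  delta-method binomial weights; factors rescaled to geometric mean 1.
  Entrywise-proportional libraries give factors of exactly 1 (the M
  values vanish identically), which the tests assert to 10⁻¹²; on random
  matrices the estimator is cross-checked against an independent
  reference implementation to 2 %.
* **RPKM** = count / (library size/10⁶) / (length/10³); gene lengths are
  required and errors are raised when absent rather than guessed.
* **DE calls** use an *inclusive* threshold, FDR ≤ 0.05 — "achieving" a
  level includes attaining it exactly — and the sign of logFC for
  direction; a significant gene with logFC exactly 0 is directionless and
  excluded from both direction sets.

The Venn partition of two contrasts is a true partition: seven disjoint
categories (down/up in both, down/up in one contrast only, discordant)
whose union is every DE gene in either contrast — a property the tests
check directly.

## Network and enrichment

The network object is built by a constructor, `coreg_network()`, and is
the package's central classed result (print/summary/plot/as_igraph
methods). One edge per (TF, gene, peak) triple is kept — collapsing peaks
would discard the distance/class evidence — and the gene-level class is
the most specific across that gene's peaks. A co-regulated gene lacking
an annotation from either factor is an *error*: it would contradict the
membership definition, so construction refuses rather than warns.

Enrichment of the member set against supplied gene-set collections (GMT)
uses the exact hypergeometric upper tail with Benjamini–Hochberg
adjustment across sets. The default universe is the expression-filtered
gene set, not the whole catalog: down-regulation is only decidable for
expressed genes, so including never-expressed genes would inflate
significance. The tail computation is tested against exhaustive subset
enumeration for universes up to N = 15.

## Binding comparison and motif scanning

The TSS-centered matrix averages coverage in 100 bp bins across ±5 kb of
each TSS, rows oriented 5′→3′ (minus-strand rows reversed; the tests
require exact row reversal under strand flip and conservation of the
integrated window signal). Two factors are compared as
log2((A + 1)/(B + 1)); the pseudocount of 1 keeps empty bins finite and
makes the comparison antisymmetric under swapping the factors. Bin
width, window and pseudocount are all configurable; the defaults are the
conventional display scale for TSS heatmaps.

Motif occurrence in ±50 bp windows around binding-site anchors supports
two modes: exact IUPAC consensus matching (ambiguity codes expand in the
motif; N in the sequence never matches) and PWM scoring, where the best
log-odds over all positions and both strands is compared to a threshold
and N scores as the worst base of its column (a conservative choice that
can only suppress hits). Windows shorter than the motif are flagged,
never hit. Enrichment over a background — by default 10× dinucleotide-
preserving shuffles of the target windows, a standard known-motif null —
is an upper binomial tail at the background rate, with a half-count
correction (flagged) when the background has zero hits. De novo motif
discovery is out of scope. Genome sequence is optional input: the core
network pipeline never requires it.

## Clonotype dominance

Clone tables carry (clone, sample, count) rows only; all frequencies are
computed on demand. The top-10 summary orders by count with clone-id
tie-breaks (deterministic output), and "frequency per mouse" for samples
pooled from *k* mice is implemented as the relative frequency divided by
*k* — the one reading that leaves single-mouse samples unchanged. This is
a documented interpretation: the upstream convention for pooled samples
is not standardized, and callers with a different normalization can apply
their own to the returned relative frequencies.

## The synthetic benchmark

`simulate_dataset()` writes a complete dataset from one seed: a toy
genome (default 200 genes on 2 chromosomes, gene lengths 2–20 kb,
intergenic gaps 25–60 kb), two peak sets with a planted co-bound subset
(15 % co-bound, 30 % bound per factor, 400 bp peaks with central
summits, class mix 40/20/20/20 across the four classes), two DE tables
(co-bound genes planted dual-down at logFC ≈ −2, FDR 0.001; 20 genes
down in each single contrast; nulls at logFC ~ N(0, 0.25) with FDR
uniform on [0.05, 1]), plateau coverage tracks (background 0.5, peak
height 8), 20 gene sets with one planted to contain 80 % co-regulated
genes, and clonotype tables with a 60 % dominant clone. The wide
intergenic gaps are deliberate: they guarantee a planted peak can never
fall within 10 kb of a neighboring TSS, so the planted bound sets are
exact, and 50 noise peaks can be placed provably outside every
assignment window. Every placement is verified against the classifier at
generation time and re-sampled on failure.

Null FDRs drawn on [0.05, 1] separate cleanly from planted signal at the
inclusive 0.05 threshold; a `hard_mode` flag draws borderline FDRs around
the threshold to exercise the boundary in stress tests.

What the generator does *not* emulate: read-level noise, fragment-size
effects, peak-caller artifacts, correlated expression changes, antisense
or overlapping transcription, and any real sequence content. Passing the
planted-recovery benchmark therefore demonstrates the correctness of the
pipeline's logic — coordinate conventions, classification, intersections,
exports — under its own assumptions, not robustness to the failure modes
of real ChIP-seq or RNA-seq data. On real data the precision of the
co-regulated call is bounded by the quality of the upstream DE fit and
peak calls.

Problem sizes throughout the test suite (200 genes × 1,000 peaks for the
oracle equivalence, 200-gene end-to-end recovery, 500 windows for the
motif oracle, N ≤ 15 for enrichment enumeration) were chosen as the
smallest scales at which every combinatorial case — multi-gene peaks,
empty chromosomes, boundary distances, ties — occurs with comfortable
margin.

## Degenerate inputs and numerical conventions

* Empty peak sets, empty catalogs and empty co-regulated sets flow
  through: annotation returns a typed empty table, and the network keeps
  the two TF nodes (droppable by flag). Empty *bound* sets in the
  pipeline emit a warning with stage statistics — an empty network is a
  legitimate but suspicious result that should never pass silently.
* Readers reject dialect violations (wrong column counts, overlapping
  bedGraph runs, summits outside their peak, FDRs outside [0, 1]) with
  the offending line number rather than coercing.
* Chromosome names match by exact string equality; an optional
  normalizer (`normalize_chroms()`) strips or adds the `chr` prefix on
  ingest, because silent aliasing corrupts interval joins.
* All generators restore the global RNG state; pipeline outputs are
  byte-identical for identical configuration and seed (asserted by
  checksum in the tests).

## Limitations

Distal regulation beyond 10 kb, enhancer–promoter looping and chromatin
topology are out of scope by design: the 10 kb rule is a proximity
heuristic. The dual-down ∩ dual-bound rule cannot distinguish direct
co-regulation from a shared upstream effect that happens to coincide with
binding, and it treats both factors symmetrically even where one may be
dominant. Transcript-level TSS choice, dispersion estimation, p-value
computation and multiple-testing correction of the DE tables all belong
to the upstream tools whose outputs this package consumes.
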