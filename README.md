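# tfcoreg

Infer the target-gene network co-regulated by two transcription factors
from knockout expression data and ChIP-seq binding.

## The problem

When two transcription factors (say, an ETS factor and a bHLH factor
driving a leukemia) are each required for a disease phenotype, the genes
they *directly co-regulate* are defined by two independent lines of
evidence:

1. **Regulation** — the gene is down-regulated when *either* factor is
   deleted: FDR ≤ 0.05 in both knockout differential-expression contrasts,
   with negative log2 fold change in each.
2. **Binding** — both factors have a ChIP-seq peak near the gene's
   transcriptional start site (TSS).

`tfcoreg` implements this membership rule end to end. Peaks are assigned
to genes by a strand-aware, distance-classified annotation: for a peak
with anchor *a* (summit when called, else midpoint) and a gene with TSS
*t*,

| class | rule |
|---|---|
| `promoter` | the peak interval contains the TSS base |
| `proximal` | the peak overlaps the gene body (without the TSS) |
| `putative_promoter` | \|a − t\| ≤ 3 kb, upstream or downstream |
| `putative_distal` | 3 kb < \|a − t\| ≤ 10 kb |

Peaks farther than 10 kb from every TSS (and outside every gene body) are
unassigned. The co-regulated set is

```
coregulated = down_bothContrasts ∩ bound_byA ∩ bound_byB
```

and becomes a bipartite network (two TF nodes → target genes, one edge per
peak, attributed with class, signed distance and per-contrast logFC/FDR),
exportable to GraphML/SIF for Cytoscape. Membership is then tested for
gene-set enrichment with the hypergeometric upper tail,
P(X ≥ k | N, K, n), Benjamini–Hochberg adjusted across sets.

Supporting computations mirror the standard RNA-seq conventions: CPM and
RPKM conversion, the 0.5-CPM / 2-library expression filter, TMM
normalization factors, Venn partitioning of two contrasts, TSS-centered
binding matrices (±5 kb, 100 bp bins) compared as log2 ratios, known-motif
scanning in ±50 bp windows around binding sites, immunoglobulin clonotype
dominance (top-10 clone frequencies, per-mouse normalized), and 2^−ΔΔCT
relative quantification.

A synthetic-data generator plants ground truth (co-bound genes, dual-down
genes, noise peaks, an enriched gene set, dominant clones) so the whole
pipeline is testable without any external download.

## Worked example

```r
library(tfcoreg)

sim <- simulate_dataset("demo", n_genes = 200, noise_peaks = 50, seed = 1)
cfg <- pipeline_config(sim$paths, out_dir = "demo/results", seed = 1)
res <- run_pipeline(cfg)

res$network
#> Co-regulated network: TF_A + TF_B
#>   30 target genes, 60 TF->gene edges

summary(res$network)
#> Targets: 30   Edges: 60
#> Edges per TF:
#> TF_A TF_B
#>   30   30
#> Gene-level class (most specific across peaks):
#>          promoter          proximal putative_promoter   putative_distal
#>                21                 6                 1                 2
#> Mean |summit-to-TSS| distance: 3082 bp

res$venn$sizes
#>   down_both     up_both down_a_only down_b_only   up_a_only   up_b_only  discordant
#>          30           0          20          20           0           0           0

head(res$enrichment, 3)
#>    set set_size overlap expected    ratio            p            q
#> 1 GS10       30      24 5.000000 4.800000 6.467983e-19 1.293597e-17
#> 2 GS07       52      11 8.666667 1.269231 2.072693e-01 9.921349e-01
#> 3 GS08       17       4 2.833333 1.411765 3.070442e-01 9.921349e-01
```

The 30 planted dual-bound/dual-down genes are recovered exactly (the Venn
partition splits 30 shared, 20 per single-contrast); the planted gene set
(here `GS10`) ranks first by enrichment p. `demo/results/` holds the
annotation table, Venn partition, network (GraphML/SIF/TSV) and a run
manifest; identical config + seed reproduces every output byte for byte.

A thin command-line wrapper over the same functions lives at
`inst/cli/tfcoreg.R` (subcommands `simulate`, `pipeline`, `annotate`,
`enrich`, `clonotypes`, `ddct`).

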