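# promarch

Promoter-architecture analysis for strand-resolved nascent transcription
(NET-seq), nucleosome occupancy (MNase-seq), chromatin accessibility
(ATAC-seq) and RNA-seq in two-condition knockdown experiments — for example
depletion of a histone chaperone in embryonic stem cells. The package is
aimed at computational epigenomics practitioners who want the full promoter
tool-chain — tag cleanup, 1× normalisation, TSS-anchored metaprofiles, and
the promoter-level statistics below — together with a seeded multi-assay
synthetic-data generator so that every step can be validated against planted
ground truth without any sequencing download.

## What it computes

All coordinates are 0-based half-open; every window is strand-oriented
("downstream" follows transcription).

* **NET-seq cleanup** — UMI-aware PCR-duplicate removal; removal of splicing
  intermediates (tags mapping exactly to the strand-oriented last base of
  any exon or intron); promoter isolation (genes with another gene within
  2.5 kb upstream of their TSS are excluded).
* **Travelling ratio** of RNA polymerase II per gene,

  TR = d(proximal) / d(body),

  where d is sense-strand tag density (tags/bp), the proximal promoter is
  [TSS−30, TSS+250) and the gene body [TSS+300, TES−200). High TR indicates
  promoter-proximal pausing.
* **Divergent antisense transcription** — opposite-strand tag density in the
  1,000 bp upstream of the TSS, per condition, and its pseudocounted
  knockdown/control log2 fold change.
* **Coverage tracks** — per-base strand-split tracks, 1× depth (RPGC)
  normalisation (genome-wide mean per-bp signal = 1), 20-bp smoothing,
  TSS-anchored metaprofiles with SE and 95% CI, bedGraph I/O.
* **Fragment partitioning** — MNase fragments into subnucleosomal (<80 bp)
  and mononucleosome (135–170 bp) classes; ATAC nucleosome-free-region
  fragments by a deduplicate-then-length-threshold (≤100 bp) rule.
* **Expression classes** — CPM/RPKM summaries, RPKM quartile classes, and a
  transparent two-condition DE caller (CPM > 1 filter, TMM normalisation,
  per-gene Welch t on log2-CPM, Benjamini–Hochberg adjustment) feeding the
  standard classification: up (logFC > 1, adj. p < 0.01), down
  (logFC < −1, adj. p < 0.01), unchanged (adj. p > 0.05).
* **Statistics** — Welch two-sample t with Welch–Satterthwaite df;
  log–log OLS of nascent gene-body coverage on mRNA expression; and the
  slope-comparison statistic

  z = (β₁ − β₂) / √(s²β₁ + s²β₂),

  with a two-sided normal p-value.
* **Spike filter** — anchors whose signal concentrates ≥80% of the row total
  inside any 100-bp sub-window (short non-annotated RNAs) are removed from
  metaprofile matrices by a deterministic sliding-window rule.

The synthetic generator (`truth_config()`, `simulate_genome()`,
`simulate_netseq()`, `simulate_fragments()`, `simulate_counts()`) plants all
of the corresponding effects — pause peaks, condition-dependent antisense
gain at bound up-regulated genes, upstream nucleosome loss, ATAC
accessibility gain, expression fold changes, PCR duplicates and splicing
intermediates — with a per-gene truth table.

## Worked example

One seeded end-to-end run of the default synthetic experiment
(518 genes in six ground-truth classes; antisense gain 2 and 40% upstream
nucleosome loss planted only at bound up-regulated genes in the knockdown):

```r
library(promarch)
cfg <- run_config(truth = truth_config(seed = 1), seed = 1)
res <- run_pipeline(cfg)

subset(res$contrasts, class == "up")
#>                 metric class n_bound n_unbound     t        p
#> 1     antisense_log2fc    up      45        89 13.22 2.04e-25
#> 4     occupancy_log2fc    up      45        89 -7.15 2.73e-10
#> 7 accessibility_log2fc    up      45        89  8.03 1.53e-12

res$slopes
#> slope comparison: z = 0.4964, p = 0.62

head(res$antisense[, c("gene_id", "antisense_density_control",
                       "antisense_density_kd", "log2_fold_change")])
#>   gene_id antisense_density_control antisense_density_kd log2_fold_change
#> 1   g0001                     1.019                0.721           -0.500
#> 2   g0002                     0.921                1.103            0.260
#> 3   g0003                     1.009                0.882           -0.193
#> 4   g0004                     0.693                0.881            0.346
#> 5   g0005                     1.009                0.794           -0.345

median(res$travelling_ratio_control$tr, na.rm = TRUE)
#> [1] 11.6
```

Reading the contrast table: among up-regulated genes, factor-bound genes
gained antisense transcription (Welch t = 13.2 on the per-gene log2 fold
changes, bound vs unbound), lost upstream nucleosome occupancy (t = −7.2)
and gained promoter accessibility (t = 8.0) in the knockdown, while the
same contrasts in the down-regulated and unchanged classes are null — the
planted promoter phenotype. The slope comparison between bound and unbound
genes is null here because the generator plants no binding-dependent
coupling between expression and gene-body coverage. The median travelling
ratio of ~12 reflects the planted promoter-proximal pause peak over a
uniform gene-body rate.

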