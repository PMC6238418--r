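---
title: "Methods: promoter architecture metrics and their synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter architecture metrics and their synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`promarch` analyses promoter architecture in two-condition (control vs
knockdown) multi-omic experiments built around four assays:

* **NET-seq** maps the 3′ end of nascent RNA engaged by RNA polymerase II at
  single-nucleotide, strand-specific resolution. Its hallmark signals are a
  promoter-proximal pause peak on the sense strand and divergent
  (antisense) initiation upstream of the TSS on the opposite strand.
* **MNase-seq** reports nucleosome occupancy through mononucleosome-sized
  (≈147 bp) protected fragments.
* **ATAC-seq** reports accessibility; fragments shorter than a nucleosome
  footprint arise from transposition in nucleosome-free regions (NFRs).
* **RNA-seq** counts quantify steady-state expression and define the
  up / down / unchanged response classes of a knockdown.

The scientific contrast the pipeline is designed to expose is
class-specific promoter remodelling: genes that are bound by a chromatin
factor *and* up-regulated upon its depletion lose nucleosome occupancy
immediately upstream of the TSS, gain accessibility there, and gain
divergent antisense transcription — while unbound genes and other response
classes do not. `run_pipeline()` quantifies this as Welch two-sample tests
comparing bound vs unbound genes, within each response class, on per-gene
knockdown/control log2 fold changes of (i) antisense density and (ii)
upstream nucleosome occupancy (and optionally ATAC NFR density).

# Coordinate conventions

All internal coordinates are 0-based, half-open (BED arithmetic); GTF input
(1-based, closed) is converted at the boundary. The TSS and TES are stored
as *boundary* coordinates: for a + strand gene `tss = start`; for a − strand
gene `tss = end`, so the TSS base itself is `tss − 1`. This makes every
derived window an exact strand mirror:

| window | + strand | − strand | length |
|---|---|---|---|
| proximal promoter | `[tss−30, tss+250)` | `[tss−250, tss+30)` | 280 bp |
| gene body | `[tss+300, tes−200)` | `[tes+200, tss−300)` | gene − 500 bp |
| antisense window | `[tss−1000, tss)` | `[tss, tss+1000)` | 1,000 bp |

Genes too short for the body offsets are flagged unusable and excluded from
travelling-ratio summaries. Metaprofile windows place offset 0 at the TSS
base and run `−flank … flank−1`; − strand anchors are orientation-flipped
(offsets reversed, strands swapped), an involution verified by property
tests.

The promoter-isolation filter drops any gene whose strand-oriented
`[TSS − 2.5 kb, TSS)` window intersects another gene's annotated span.
Testing against full spans (rather than against other promoters only) is
the stricter reading of "overlapping within a region 2.5 kb upstream" and is
the default; `against = "promoter"` selects the other reading. The filter
is order-independent and idempotent because every gene is tested against
the complete input set.

# Pre-analysis filters

* **PCR/RT duplicates**: one tag is kept per (chrom, position, strand, UMI)
  key. This UMI-aware positional rule is the entire duplicate model; no
  further reverse-transcription-bias heuristics are applied.
* **Splicing intermediates**: NET-seq co-purifies RNAs whose 3′ end sits
  exactly at the last transcribed base of an exon or intron. A tag is
  removed iff its position equals such a strand-oriented last base on the
  same strand. Exon structure is taken from one collapsed model per
  transcript record; BED6 input (no blocks) is treated as single-exon, so
  only transcript ends contribute sites.
* **Fragment classes**: subnucleosomal `< 80 bp` (strict) and
  mononucleosome `135–170 bp` (inclusive at both ends); the boundary
  lengths 80, 134 and 171 bp belong to no class and are dropped with a
  logged count.
* **ATAC NFR selection**: duplicates (identical fragment coordinates) are
  removed, then fragments ≤ 100 bp are retained. This deterministic
  fragment-length rule is the package's NFR definition — sub-nucleosomal
  fragment length is the standard proxy for transposition in an NFR — and
  the threshold is exposed as a parameter. A trained classifier could be
  substituted by the caller; none is shipped.
* **Spike filter**: rows of a TSS-anchored signal matrix whose total is
  positive and whose maximum 100-bp sliding-window sum reaches 80% of the
  row total are removed; these are the signatures of short non-annotated
  RNAs (e.g. snoRNAs) inside the window. The rule is deterministic and
  seed-free, which we prefer to iterative clustering for reproducibility;
  both the window and the fraction are parameters.

# Normalisation and smoothing

Tracks are built at 1-bp resolution (tags: +1 at the recorded base on the
tag's strand; fragments: +1 per covered base, or midpoint mode for
dyad-resolution analyses). 1× (RPGC) normalisation scales by
`effective_genome_size / total_signal`, after which the genome-wide mean
per-bp signal equals 1 (enforced to 1e−9 in tests); the effective genome
size defaults to the full track length because synthetic genomes carry no
blacklist. Normalising an already-normalised or empty track is an error,
not a silent no-op.

The "20-bp" smoothing window is implemented as a centred 21-bin (±10 bp)
moving average — a centred window needs an odd bin count — shrinking at
chromosome edges. Signal further than the half-window from any edge is
conserved exactly.

Densities are everywhere `summed normalised signal / region length` in
tags/bp. The travelling ratio is therefore invariant to any per-sample
scaling; log transformation for display is left to callers, and genes with
zero body density are excluded as unusable rather than producing infinite
ratios.

# Statistics

* **Welch t** (`welch_t`): unequal-variance two-sample t with
  Welch–Satterthwaite degrees of freedom. Two zero-variance samples with
  equal means give t = 0, p = 1; with different means the test is
  undefined and errors.
* **BH adjustment** (`bh_adjust`): Benjamini–Hochberg step-up, verified
  against a longhand implementation on vectors up to length 8.
* **Slope comparison** (`slope_z`): z = (β₁ − β₂)/√(s²₁ + s²₂) with a
  two-sided normal p. Both SEs zero with unequal slopes is reported as
  p = 0 with a `degenerate` flag.
* **Antisense fold change**: log2((kd + ε)/(control + ε)) on densities with
  ε = 0.1 tags/kb (1e−4 tags/bp). The pseudocount keeps genes with an
  empty window in one condition finite while leaving well-covered windows
  (the default generator plants ≈20 tags per window) essentially
  untouched; the fold change is exactly antisymmetric under swapping
  conditions.
* **DE caller** (`de_call`): genes must exceed CPM 1 in at least half the
  samples; library sizes are TMM-corrected (delegated to the reference
  implementation in edgeR); per-gene Welch t on log2(CPM + 0.5); BH
  adjustment; logFC is the difference of condition means of log2-CPM. This
  is deliberately a transparent, non-moderated caller: with few replicates
  it is less powerful than shrinkage-based callers, which matters for
  borderline effect sizes (at the generator's default |logFC| = 2 with
  four replicates its recall is partial; at |logFC| = 3 it exceeds 95%).
  Its null behaviour is calibrated (type-I ≈ nominal; BH discoveries on
  all-null matrices ≈ 0), which is what the class contrasts rely on.
* **Expression classes**: RPKM quartiles with stable first-occurrence rank
  tie-breaking, so the four classes always have equal size ±1 even under
  massive ties.

# The synthetic experiment

The generator is the package's specification of the study conditions, not a
fixture. `truth_config()` defaults:

* **Gene set**: 518 genes in six classes — up (45 bound / 89 unbound),
  down (55/110), unchanged (73/145) — placed on one chromosome with
  2.6 kb intergenic gaps, so every promoter is isolated by construction
  and the 2.5-kb filter is a no-op unless violations are planted
  (`planted_overlaps` inserts a decoy gene inside chosen upstream
  windows). Gene lengths 1.5–3 kb, three exons each; classes are assigned
  to random positions.
* **NET-seq**: sense body rate 0.04 tags/bp; Gaussian pause peak (120
  expected tags, centre +40 bp, sd 15 bp) inside the first 250 bp;
  antisense rate 0.02 tags/bp upstream (≈20 tags per 1-kb window, enough
  for stable per-gene fold changes); antisense gain 2 at bound-up genes in
  the knockdown; every primary tag carries a unique UMI; duplicate rate 0.1;
  two expected splicing-intermediate tags per exon/intron 3′ end. Signal
  tags that would coincide with an intermediate site are resampled away,
  so filter exactness is testable to the tag.
* **MNase**: one upstream dyad at TSS−180 and three downstream dyads from
  TSS+100 with 185-bp spacing; midpoint fuzz sd 20 bp; 30 expected
  fragments per dyad; lengths N(147, 10) clipped to [120, 190] bp;
  upstream dyad weight × (1 − 0.4) at bound-up genes in the knockdown.
* **ATAC**: 25 expected NFR fragments (lengths ≈N(65, 15), clipped ≤100 bp)
  centred between the −1 and +1 dyads and 25 mononucleosome fragments at
  the +1 dyad; NFR rate × 1.5 at bound-up genes in the knockdown.
* **RNA-seq**: negative-binomial counts, gene baselines log-normal
  (median 150), dispersion 0.1, planted logFC ±2, four replicates per
  condition, optional library-size factors for TMM to absorb.

What the generator does **not** emulate: mappability and GC bias in read
depth, overlapping or nested transcription units, enhancer RNAs, intron
retention, replicate-level batch effects, and sequencing errors. Passing
tests therefore demonstrate the correctness of the pipeline's arithmetic
and the recoverability of planted promoter effects under clean conditions —
not robustness to every artefact of real libraries.

# Determinism and seeding

A single seed determines everything. Each simulator derives its own stream
as `stage_seed(seed, k)` (a fixed affine map kept below 2³¹), so stages can
be re-run in isolation and conditions do not share streams. Random draws
run inside a scope that saves and restores the caller's RNG state. Two runs
of `run_pipeline()` with the same configuration are identical object for
object, and the written report bundle (TSV tables plus a JSON manifest
echoing all parameters, seeds and filter counts) reproduces byte for byte.

# Problem sizes used by the test-suite

The validation suite exercises the pipeline at sizes chosen to make the
statistical assertions sharp while keeping a full run comfortable on one
core: filter-exactness on a single simulated library of >10⁵ tags;
effect-recovery on 20 replicate experiments of 1,200 genes (200 per class,
antisense gain 2, upstream loss 0.4); null calibration on 50 replicate
experiments of 360 genes with all effects off, pooling 300 null contrast
p-values, plus a 2,000-gene all-null DE matrix; regression recovery at
n = 500 (slope 1.5) and 100 replicate slope-comparison pairs. One
deliberate outcome of the null analysis is worth stating: requiring four
uniform null p-values to all exceed 0.05 in essentially every replicate is
not a property any calibrated test family can guarantee (each replicate
retains all four with probability ≈0.95⁴ ≈ 0.81), so the joint
effect-and-null recovery check is expected to fail in a handful of
replicates even though the planted effects themselves are detected at
p < 0.01 in every single one and the pooled null rejection rate sits at
its nominal 5%.

# Known limitations

* The DE caller is unmoderated; for real few-replicate data a shrinkage
  caller will have materially better power at small fold changes.
* The NFR rule is length-only; open-chromatin fragment-length mixtures in
  real ATAC libraries overlap more than the planted mixture does.
* The splicing-intermediate filter uses one collapsed exon model per
  transcript record; isoform-specific 3′ ends not present in the annotation
  are not removed.
* `region_density_matrix` correlates mean densities; it does not implement
  bin-level co-occupancy heatmaps.
* bedGraph is the only track output; no binary bigwig I/O is provided.
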