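# preplateR

An integrative analysis toolkit for early cortical neurogenesis: it joins
FACS-sorted bulk RNA-seq, histone-mark ChIP-seq peaks and single-cell
RNA-seq of preplate / Cajal-Retzius (CR) neurons across the three early
neurogenic stages of the mouse cortex (E11.5, E13.5, E15.5), and ships a
synthetic-data generator with planted ground truth so the whole pipeline
is testable without any sequencing data.

## Who this is for

Developmental neurobiologists and computational biologists who have (or
want to prototype against) three kinds of input:

* genes × samples **FPKM tables** for a reporter-positive (preplate/CR)
  versus reporter-negative (progenitor) population, 3 stages × 2
  replicates, with upstream differential-expression statistics attached;
* **H3K27ac / H3K27me3 peak sets** (BED/narrowPeak) per condition;
* a **single-cell UMI matrix** (MTX + barcodes + features) of ~3000
  reporter-positive cells with an externally computed pseudotime.

Alignment, FPKM quantification, DE testing, peak calling and pseudotime
inference stay in their upstream tools; this package implements the
analysis layer on top of their outputs.

## What it computes

* **Enrichment cascades** on the pseudocounted stage ratio
  r = (mean FPKM⁺ + 0.1)/(mean FPKM⁻ + 0.1): stage-enriched genes
  (FPKM⁺ > 1, r ≥ 2), CR-specific genes (FPKM⁺ ≥ 5 and r ≥ 2 at all
  three stages), novel candidates (minus curated exclusion lists),
  layer-1 candidates (FPKM⁻ ≤ 15 throughout), DE lncRNAs
  (FDR < 0.05, p < 0.01) and CR-specific lncRNAs.
* **Temporal trinarization**: each stage ratio maps to up (r ≥ 2) /
  unchanged (1 ≤ r < 2) / down (r < 1), giving a 27-class trajectory
  space, archetype grouping by Hamming distance, and expression-trend
  categories (increasing, low-decreasing, …).
* **Promoter chromatin states**: peak-to-gene assignment in TSS ± 5 kb
  and distal (±100 kb, outside the TSS window) windows; active /
  repressed / poised (bivalent) / none TSS states; peak genomic-feature
  annotation; TSS-vs-distal partitions; and the closed-form Pearson
  chi-squared association X² = N(ad−bc)²/((a+b)(c+d)(a+c)(b+d)) between
  consistent histone binding and expression trends.
* **Single-cell stage**: QC, log-normalization, binned-dispersion HVG
  selection, PCA, k-means++ (k = 8) clustering, rank-sum marker tests,
  the trajectory input-gene gate (>10 cells, mean >1), top-20%
  per-cluster gene sets, and early/intermediate/late pseudotime state
  groups — cross-tabulated against the bulk temporal classes and
  transcription-factor target lists.
* A one-call **pipeline** (`run_pipeline()`) that simulates every input
  with planted truth, runs all stages, cross-checks its own report, and
  returns tidy tibbles throughout (with `tidy()` / `glance()` /
  `autoplot()` methods).

## Worked example

```r
library(preplateR)

report <- run_pipeline(pipeline_config(), seed = 1)
report
#> Integration report (seed 1)
#>
#> Enrichment calls:
#>                 set   n
#>      enriched_E11.5 519
#>      enriched_E13.5 504
#>      enriched_E15.5 516
#>         cr_specific 102
#>     novel_candidate 102
#>    layer1_candidate  26
#>           de_lncRNA 108
#>  cr_specific_lncRNA   3
#>
#> Temporal classes observed: 27 of 27 (1101 DEGs)
#>
#> TSS/distal H3K27ac partition (DEG universe):
#>     category    n       pct
#>     tss_only    0  0.000000
#>         both 1028 93.369664
#>  distal_only   73  6.630336
#>      neither    0  0.000000
#>
#> Promoter H3K27ac x increasing expression: X-squared = 10.42, p = 0.00125
#>
#> Planted-truth recovery:
#>                   metric    value
#>  temporal_class_recovery 0.794000
#>     cr_specific_recovery 0.989500
#>          layer1_recovery 0.995000
#>       tss_state_recovery 1.000000
#>               kmeans_ari 0.988122
#>     state_group_recovery 1.000000
```

Reading this: on a simulated 2000-gene, 3000-cell dataset, 1101 genes
pass the DE gate; 102 are CR-specific (enriched ≥2-fold with FPKM ≥ 5 at
all three stages) of which 26 survive the layer-1 low-background filter;
all 27 temporal classes are populated. Promoter H3K27ac across the three
stages associates significantly with rising expression (p ≈ 0.001). The
recovery block compares each call against the generator's planted labels:
TSS chromatin states and pseudotime state groups are recovered perfectly,
k-means recovers the eight planted subpopulations at ARI 0.99, and with
replicate noise at its default the temporal classifier recovers 79% of
planted classes (it is exactly 100% when replicate noise is switched
off — that is an asserted test invariant, not a hope).

Individual stages are plain functions on tibbles, e.g.:

```r
tab    <- read_expression_table("fpkm.tsv")
ratios <- compute_stage_ratio(tab)
cr     <- call_cr_specific(ratios)
cls    <- classify_temporal(ratios) |> assign_groups()
```

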