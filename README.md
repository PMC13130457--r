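# fiberquant

Quantification toolkit for denervation-induced skeletal muscle fiber
remodeling. After a nerve injury, muscle fibers reprogram on several fronts
at once: the mitochondrial network re-orients from transversal to
longitudinal and fragments into smaller volumes, acetylcholine receptors
(AChRs) at the neuromuscular-junction endplate turn over faster, nuclear
levels of transcriptional co-regulators such as CtBP1 change relative to the
cytoplasm, and hundreds of genes shift expression in activity-dependent and
-independent ways. `fiberquant` implements the image- and table-level
measurements behind these phenotypes for researchers analyzing confocal
stacks of isolated fibers and three-contrast differential-expression (DE)
results — plus seeded synthetic-data generators with exact ground truth, so
every pipeline is validated as a parameter-recovery experiment.

## What it measures

* **Mitochondrial orientation (2D).** On the central frame of a TOMM20
  stack: bilateral filtering, fiber segmentation (morphological closing +
  Otsu) with principal-axis estimation, multiscale Frangi vesselness
  enhancement of tubular mitochondria, per-object orientation from second
  central moments, and the fiber-relative angle θ = min(|Δ|, 180° − |Δ|)
  binned into [0°,30°), [30°,60°), [60°,90°].
* **Mitochondrial volumes and shapes (3D / EM-style).** Smoothing + Otsu +
  26-connected components; volumes as voxel count × dz·dy·dx; median and
  cumulative frequency curves; two-sample Kolmogorov–Smirnov comparison;
  2D area and circularity 4πA/P² with a bias-corrected perimeter estimator.
* **Nuclear/cytoplasmic ratio.** Per-nucleus mean signal over one global
  cytoplasmic mean per image, aggregated to per-muscle means (the
  biological replicate) and normalized so the control group's mean is 1.
* **Endplate morphometry and AChR turnover.** Endplate volume and fragment
  count from the dual bungarotoxin labels, and per-voxel "pixel dominance":
  channels normalized to their in-mask 99th percentile, voxels assigned
  old/new/tie with a tie band, plus the tie-excluded turnover index
  new/(new+old).
* **DE gene classes.** Genes flagged DE per contrast when |log2FC| ≥
  log2(1.5) and p < 0.05, then partitioned into activity-independent
  (AIN^In, AIN^De, AIN^InDe) and activity-dependent classes signed by
  agreement of knockdown and denervation effects (AD^In±, AD^De±, AD^InDe
  and its sign-inverse), with Venn region counts and up-regulated
  fractions.

## Worked example

Generate a synthetic innervated-like central frame — 300 tubular
mitochondria in a fiber band at 20°, with exactly 88.5% of true angles in
the 60–90° bin — and recover the mixture with the full pipeline:

```r
library(fiberquant)

ff  <- make_fiber_frame(300, c(0.05, 0.065, 0.885),
                        fiber_angle_deg = 20, seed = 42)
res <- run_orientation_pipeline(plane_to_volume(ff$image))
res
#> <orientation_result> fiber axis 20.00 deg, 300 object(s) in summary
#>   0-30  30-60  60-90
#> 0.0533 0.0833 0.8633
```

The fiber axis is recovered at 20.00° and the 60–90° proportion at 86.3%
versus the injected 88.5% — within the pipeline's ±3-point recovery
envelope (the small loss is noise-driven leakage at the 60° bin edge).
`tidy(res)` returns the per-object table, `glance(res)` a one-row summary,
`autoplot(res)` the bin chart.

AChR turnover on a synthetic fragmented endplate with 25% new-dominant
voxels:

```r
ep <- make_endplate(0.25, n_fragments = 4, seed = 1)
run_endplate_pipeline(ep$image)
#>   volume_um3 fragment_count new_fraction old_fraction tie_fraction
#> 1   108.6885              4    0.2455596    0.7374239   0.01701652
#>   turnover_index n_mask_voxels
#> 1      0.2498105         16102
```

The turnover index recovers 0.2498 vs the injected 0.25; the small tie
fraction is the background–background boundary shell of the detected mask.

DE classification round trip:

```r
dt <- make_deg_table(c(AIN_InDe = 53, AD_In_pos = 150, AD_De_pos = 220,
                       AD_De_neg = 60, AD_InDe = 57), seed = 2)
classify_table(dt$records)
#> <deg_classification> 540 gene(s), |FC| >= 1.5, p < 0.05
#>      class   n
#>   AIN_InDe  53
#>  AD_In_pos 150
#>  AD_De_pos 220
#>  AD_De_neg  60
#>    AD_InDe  57
```

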