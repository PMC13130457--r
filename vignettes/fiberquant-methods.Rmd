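---
title: "Quantifying denervation-induced muscle fiber remodeling with fiberquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying denervation-induced muscle fiber remodeling with fiberquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiberquant)
```

# Scope and rationale

Cutting the sciatic nerve triggers a coordinated remodeling of skeletal
muscle fibers: the mitochondrial network re-orients from transversal to
longitudinal, individual mitochondria fragment into smaller volumes,
acetylcholine receptors (AChRs) at the neuromuscular-junction endplate turn
over faster, and transcriptional co-regulators such as CtBP1 shuttle between
myonuclei and cytoplasm while activity-dependent genes are re-programmed.
`fiberquant` packages the quantification procedures needed to measure these
phenotypes from multichannel fluorescence stacks and from tabular
differential-expression (DE) results, together with seeded synthetic-data
generators that produce every input class with exact ground truth. The
generators let every pipeline be validated end-to-end as a
parameter-recovery experiment: inject a known quantity, run the full
analysis, compare.

All images live in a single container, `volume_image`, a non-negative voxel
grid stored `(y, x, z, channel)` in R's column-major order with a physical
voxel spacing `(dz, dy, dx)` in micrometres. Spacing is always supplied by
the user — TIFF metadata is not trusted. Tabular results are tibbles;
result objects have `tidy()`, `glance()` and `autoplot()` methods.

# Mitochondrial network orientation (2D)

The orientation pipeline reproduces, stage by stage, the classical
measurement of mitochondrial angles relative to the fiber axis on the
central frame of a confocal stack of an outer-membrane marker (TOMM20):

1. **Central frame.** The plane at z-index `floor(nz/2)` (0-based). The
   floor convention makes the even-depth case deterministic.
2. **Bilateral filter** (`preprocess_frame`): edge-preserving smoothing with
   a spatial Gaussian (`sigma_spatial`, default 2 px) and a range Gaussian
   on intensity differences (`sigma_range`, default 0.1 on a unit-scaled
   image). Flat-region noise is suppressed while fiber and mitochondrial
   edges stay in place.
3. **Fiber segmentation** (`segment_fiber`): grayscale morphological closing
   (disc, default radius 5 px) merges the bright mitochondria into the fiber
   body, Otsu's threshold separates fiber from surround, and the fiber mask
   is the largest connected component. The fiber *axis* is the principal
   direction of the mask's second central moments — computed on the mask
   pixels inside the centred inscribed circle. The circular window matters:
   a square field clips an oblique fiber asymmetrically, and the raw moment
   axis of the clipped shape is biased by several degrees; inside a
   rotation-symmetric window the bias vanishes for any angle.
4. **Tubular enhancement** (`enhance_tubular`): multiscale Frangi
   vesselness. At each scale `s` (default 1–4 px) the scale-normalized
   Hessian is computed with analytic Gaussian-derivative kernels
   (zero-sum-corrected so constant images give exactly zero response);
   for bright ridges (`lambda2 < 0`) the response combines the blobness
   ratio (`beta = 0.5`) and the Frobenius structure norm with gamma set to
   half the per-scale maximum. The output is the per-pixel maximum over
   scales, in [0, 1].
5. **Object segmentation** (`segment_mitochondria`): Otsu threshold on the
   vesselness values *inside the fiber mask* (eroded by default 8 px so band
   edges do not contribute spurious ridge responses), 8-connected components,
   minimum area 10 px.
6. **Angles** (`object_orientation`, `relative_angle`, `bin_angles`): each
   object's orientation comes from its second central moments; the angle to
   the fiber is the axial fold `min(|d|, 180 - |d|)` into [0, 90]; bins are
   `[0,30) [30,60) [60,90]` with 90 closing the last bin. Objects with
   eccentricity below 0.3 (default) are kept in the per-object table but
   excluded from the angle summary: the orientation of a round object is
   noise. Summaries with fewer than `min_objects` (default 10) used objects
   are flagged unreliable; a blank frame yields zero objects and the flag
   rather than an error.

Angles require isotropic in-plane pixels (`dy == dx`); anisotropy is a
validation error because moment angles are distorted by anisotropic
sampling.

## What the synthetic frames emulate

`make_fiber_frame` renders one bright band (the fiber) at a chosen axis
angle containing non-overlapping rods with a controlled mixture of
fiber-relative angles. Per-bin counts are *exact* stratified counts
(largest-remainder apportionment), so recovery error measures the pipeline,
not the fixture. Rods are drawn by distance-to-segment thresholding with
1-pixel Gaussian edge softening; intensities are background 0.05, band
0.35, rod peak 1.0, plus additive Gaussian noise (default sd 0.05 — the
acquisition noise of the original data is unknown, so this is a documented
free parameter at a typical confocal level). Rods keep a 4-px clearance
from each other and a 14-px clearance from the band edge so that the eroded
fiber mask retains them. What the generator does *not* model: point-spread
blur, photon (Poisson) noise, curved fibers, crossing or touching
mitochondria, and out-of-focus haze. Passing recovery tests therefore shows
the pipeline measures what it claims on well-separated tubular objects;
on real data, segmentation errors from touching structures are an
additional, unquantified error source.

Recovery at the study's reported conditions (1000 objects, mixtures with
60–90° fractions of 88.5% and 18.7%) is within ±3 percentage points; the
innervated-like mixture recovers ~1 point low because measurement noise at
the 60° bin edge leaks objects from the heavily occupied top bin into the
sparse middle bin.

# Mitochondrial volumes and shapes (3D / EM-style)

`segment_mito_3d` is a deliberately classical stand-in for the commercial
machine-learning surface segmentation used interactively in the original
workflow: Gaussian smoothing, a global Otsu threshold, 26-connected
components, and a minimum size of 8 voxels. The module's contracts are
segmentation-agnostic so a learned backend can replace it. The smoothing
sigma defaults to 0.7 voxels: at sigma 1 the Otsu threshold falls below the
half-maximum surface and inflates recovered volumes of small objects by
~10–15%; at 0.7 voxelized ground-truth volumes are recovered within a few
percent. Volumes are voxel counts times the voxel volume; distribution
summaries report the median (midpoint convention for even n) and the
empirical cumulative frequency curve, and `compare_distributions` wraps the
two-sample Kolmogorov–Smirnov test.

Because the unit of the published EM comparison is a 2D section,
`shape_metrics_2d` computes area and circularity (`4*pi*A/P^2`) from label
masks. The perimeter estimator is a smoothed iso-contour length: the 0.5
iso-contour polygon of the mask, vertices smoothed by a 5-point closed
moving average before summing segment lengths. The smoothing is essential —
the raw pixel contour follows the discretization staircase and overestimates
a digital disk's perimeter by ~5% (circularity 0.91), while popular weighted
boundary-step and Crofton estimators bias disk circularity to 0.92 or square
circularity to 0.88. The smoothed contour gives disk ≈ 0.99, square ≈ 0.82
(continuum value `pi/4` ≈ 0.785), thin rod < 0.1. Circularity may exceed 1
by up to ~0.1 on small rasterized shapes; that discretization tolerance is
part of the contract.

# Nuclear/cytoplasmic intensity ratio

`run_nc_pipeline` measures, per nucleus, the mean signal (e.g. CtBP1)
intensity divided by one global cytoplasmic mean per image. Nuclei come from
the DAPI channel (smoothing, Otsu, 26-connected components, minimum 64
voxels); border-touching nuclei are dropped (partial volumes bias means);
the cytoplasm is the fiber region (Otsu on the smoothed signal channel)
minus the nuclei dilated by a 2-voxel margin. Nuclear masks are eroded by 1
voxel before averaging: the boundary shell mixes nuclear and cytoplasmic
signal and would pull every ratio toward 1. A single global cytoplasmic
reference (rather than per-nucleus annuli) is used because the measurement
is defined against *the* cytoplasmic intensity of the fiber; it is also
robust to local segmentation noise. Sub-synaptic nuclei can be excluded via
an optional exclusion mask; endplate detection itself is a separate concern.

The muscle — not the nucleus — is the biological replicate:
`aggregate_by_muscle` averages ratios within each muscle, and
`normalize_to_control` divides by the control-group grand mean so the
control mean is exactly 1. Group statistics on the muscle-level values are
deliberately left to standard tools (`aov`, `TukeyHSD`). Injected ratios of
0.5–4 at 5% noise are recovered within 5% per muscle.

# Endplate morphometry and AChR turnover

The endplate mask is an Otsu threshold on the smoothed sum of the "old" and
"new" bungarotoxin channels; volume is voxel count times voxel volume and
fragmentation is the number of 26-connected components of at least 27
voxels. "Pixel dominance" is not defined in the source material, so the
package defines it precisely: each channel is normalized to its own 99th
percentile within the mask (robust to hot pixels, and removing
acquisition-gain differences — dominance is invariant to independent
positive rescaling of either channel); a voxel is new-dominant when
normalized new exceeds normalized old by more than `tie_delta` (default
0.05), old-dominant in the mirror case, a tie otherwise. The three fractions
always sum to 1 and swap exactly under channel exchange.

Turnover is reported both as the raw new-dominant fraction of mask voxels
and as the tie-excluded `turnover_index = new / (new + old)`. The index is
the recommended measure on segmented data: voxels that the detected mask
picks up just outside the true endplate carry background in both channels
and tie, deflating the raw fraction by the boundary-shell fraction while
leaving the index unbiased. One degenerate rule is worth noting: a channel
identically zero in the mask normalizes to zero (no label present — every
voxel is dominated by the other channel), whereas a channel with nonzero
voxels but a zero 99th percentile has no defined normalization and raises an
error. The synthetic generator (`make_endplate`) constructs a fragmented
pretzel-like ring in which *exactly* `round(f * M)` voxels are new-dominant
with no ties; intermediate fractions must leave each channel at least 2% of
the mask so that each channel's 99th-percentile anchor is itself a dominant
voxel — outside [0.02, 0.98] only the exact 0 and 1 cases are constructible.
Injected fractions {0, 0.25, 0.5, 0.75, 1} are recovered by the full
pipeline within ±0.02.

# DE gene classes

Three contrasts define the class system: `den` (innervated vs denervated,
control), `sh_in` (knockdown vs control, innervated), `sh_de` (knockdown vs
control, denervated). A gene is DE in a contrast when `|log2FC| >=
log2(1.5)` (boundary inclusive on the linear scale) and `p < 0.05` (strict,
raw p-values — matching the upstream filtering; an FDR column can be used
upstream instead if desired). Classes partition genes by the DE pattern:
activity-independent (`AIN_In`, `AIN_De`, `AIN_InDe`) when the denervation
contrast is not DE; activity-dependent subclasses signed by whether the
knockdown effect has the same sign as the denervation effect (`AD_In_pos`
vs `AD_In_neg`, `AD_De_pos` vs `AD_De_neg`); genes DE in all three
contrasts are `AD_InDe`, or `AD_InDe_inverse` when the two knockdown
effects have opposite signs; genes DE only under denervation are
`AD_untouched`. "Correlation" is implemented as sign agreement of log2 fold
changes — the only per-gene notion of correlation that is well defined.
Because a DE gene has `|log2FC| >= log2(1.5) > 0`, sign-determining fold
changes are never zero at the default thresholds; a zero would only arise at
`fc_thresh = 1`, where classification stops with an error rather than
guessing.

`classify_table` additionally returns the seven Venn regions of the three DE
sets and the fraction of up-regulated genes within each knockdown DE set;
`zscore_matrix` centres and scales each gene's fold-change triple with the
population-SD convention (divisor n), flagging zero-variance rows. DE model
fitting itself is out of scope: the module consumes `(log2FC, p)` triples
from any upstream tool.

`make_deg_table` generates tables realizing requested class counts exactly,
with DE magnitudes at least 0.1 above the log2 threshold and non-DE genes
strictly below it (or with p strictly above), so a classification round trip
recovers the counts with no boundary ambiguity. The classifier is verified
gene-for-gene against an independent brute-force implementation on the full
flag/sign truth table and on 1000 random tables.

# Numerical choices and degenerate inputs

* Otsu thresholds use a 256-level histogram on the observed intensity range;
  (near-)constant inputs raise a degenerate-input error wherever a
  threshold is required, except where the contract says otherwise (blank
  vesselness gives an empty label map; a blank stack gives an unreliable
  zero-object orientation result).
* Connected components are 8-connected in 2D and 26-connected in 3D
  (two-pass union-find in compiled code); both conventions are fixed so
  counts are reproducible.
* Binary dilation margins use the Chebyshev (box) metric; fiber-mask
  erosion uses a disc.
* All generators run under `withr::with_seed`, so identical arguments and
  seed give bit-identical arrays on every platform using R's default RNG.
* CSV written by `write_records` serializes doubles with 17 significant
  digits and `read_records` parses with base R's correctly rounded reader,
  making write-then-read bit-exact.

# Problem sizes used in the validation suite

The shipped tests run the orientation recovery at 300–1000 objects on
~600–1100 px frames, volume recovery on 20 ellipsoids in ~1–2 Mvoxel
stacks, the KS power check on 100 replicate pairs of 500 draws, N/C
recovery on four muscles of 12 nuclei, turnover on ~15k-voxel endplates and
the DE oracle on 1000 random tables — sizes chosen so the whole suite
completes in about a minute while keeping every recovery criterion
statistically sharp.

# Known limitations

* The fiber axis is a single global angle per frame; curved fibers would
  need a local orientation field (out of scope).
* The 3D segmentation stand-in is threshold-based; heavily textured or
  low-contrast stacks that motivated machine-learning segmentation in the
  original workflow will not segment equally well.
* Whether the original analysis constrained mitochondria segmentation to
  the fiber mask, or excluded low-eccentricity objects, is not documented;
  both behaviours are explicit, configurable choices here and are reported
  with the result.
* EM shape metrics consume masks; segmentation of raw electron micrographs
  is not provided.
* The per-muscle vs pooled-object ambiguity of median mitochondrial volume
  is resolved by emitting both: `volume_distribution_summary` per muscle,
  and pooled summaries by concatenating volumes.
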