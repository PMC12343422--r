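---
title: "Hepatic vessel volumetry: models, phantoms, and statistical design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hepatic vessel volumetry: models, phantoms, and statistical design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepavol)
```

## The scientific problem

Chronic liver disease (CLD) progressively remodels the hepatic
microcirculation: fibrosis compresses intrahepatic vessels, portal
hypertension develops, and portosystemic shunting diverts flow away from the
hepatic veins. A candidate non-invasive imaging biomarker for this process
is the *vessel-to-volume ratio*: the volume of segmented intrahepatic
vasculature expressed as a percentage of total liver volume, computed
separately for the hepatic venous system (HVVR, including the intrahepatic
inferior vena cava), the intrahepatic portal venous system (PVVR), and their
sum (TVVR = HVVR + PVVR). In diseased livers these ratios fall — most
markedly for the hepatic veins — and they correlate with established
markers of liver dysfunction (albumin, bilirubin, ALBI, MELD-Na) and of
fibrosis / portal hypertension (FIB-4, liver stiffness, HVPG, platelet
count, spleen volume).

`hepavol` implements that analysis end to end as a testable pipeline:

1. a **synthetic-data module** that grows liver phantoms with two labelled
   vascular trees at controllable volume fractions, and simulates clinical
   cohorts with calibrated biomarker marginals and rank-correlation
   structure;
2. a **3D U-Net** for voxelwise vessel/organ segmentation, trained
   patch-wise and applied by sliding-window inference;
3. a **volumetry module** computing distance-transform vessel calibres,
   calibre-stratified Dice scores, organ volumes and VVRs;
4. a **statistics module** reproducing the nonparametric group-comparison
   and correlation layer;
5. a **pipeline orchestrator** tying the stages into one reproducible run.

Because no imaging data ship with the package, every empirical claim in the
test suite is made on synthetic data whose construction is itself part of
the package contract.

## Units and conventions

* All geometry is in **millimetres**; voxel `(i, j, k)` (1-based) has its
  center at `(i - 1/2, j - 1/2, k - 1/2) * spacing`. Volumes are reported
  in cc (1 cc = 1000 mm³).
* Label maps use 0 background, 1 portal vein, 2 hepatic veins (with the
  intrahepatic IVC), 3 liver parenchyma, 4 spleen. Vessels are part of the
  liver, so the liver denominator of every VVR **includes** vessel voxels;
  the source analysis normalises to "total liver volume" without stating an
  exclusion, and including the vessels keeps TVVR = HVVR + PVVR an exact
  identity of the label map.
* VVRs are percentages. The group medians being calibrated against (3.9 /
  2.8 / 2.3 for TVVR in controls / non-ACLD / ACLD) are only physically
  plausible as percent of liver volume, and are treated as such.
* The per-voxel vessel "diameter" is the raw Euclidean-distance-transform
  value — the distance in mm from a vessel voxel to the nearest background
  voxel center. Geometrically this is a radius-like quantity, but the field
  reports it as a diameter and stratifies it into 0–5 mm, 5–10 mm and
  > 10 mm bins; we follow that convention verbatim, with half-open
  left-closed bins (a value of exactly 5 mm falls in the middle bin). A
  consequence worth knowing: a thick vessel's surface shell has small EDT
  values and therefore contributes voxels to the smallest bin; calibre bins
  mix structures at boundaries.

## The phantom generator

`make_liver_phantom()` builds one subject's ground truth:

* **Organs.** An ellipsoidal liver (default semi-axes 58 × 42 × 34 mm on a
  64 × 48 × 32 grid at 2.5 × 2.5 × 3 mm spacing, ≈ 350 cc) and a smaller
  disjoint spleen. This is a desk-scale liver — about a quarter of a
  clinical liver volume — chosen so that a full train/evaluate cycle runs
  on one CPU; ratios are scale-free, so VVR calibration is unaffected.
* **Vessels.** `grow_vascular_tree()` bifurcates tube segments recursively
  from a boundary root (inferior for the portal system — a hilum
  surrogate — superior for the hepatic system, whose root trunk stands in
  for the intrahepatic IVC), steering segments back toward the liver
  centroid when they would exit the mask. Radii taper by a factor of
  0.65–0.8 per generation. All radii are then rescaled so the *rasterized*
  tree (voxel centers within the segment radius, or within half the
  minimum spacing — the thin-vessel guarantee that keeps sub-voxel branches
  visible) occupies the target fraction of the liver volume; the
  construction contract is ±10 % relative, and the builder verifies ±6 %
  internally, floored at about one voxel of volume because the rasterized
  volume is quantized (on coarse demonstration grids a small vascular
  system is only a dozen voxels). When the target volume sits below the
  rasterization floor of a full-depth tree, deeper generations are pruned —
  down to a single trunk if necessary — until it is reachable.
* **Intensities.** Noise-free plateaus follow the portal-venous-phase
  ordering: background 0, parenchyma 0.5, spleen 0.65, vessels 1.0.
  Optional multiplicative low-order cosine shading (default ±10 %) emulates
  coil inhomogeneity, and additive Gaussian noise emulates acquisition
  noise. No MR physics (relaxation, k-space, motion) is modelled.
* **Ground truth.** The returned VVRs are computed *from the emitted label
  map* by `vessel_to_volume_ratios()`, never from the analytic tree, so
  ground truth and downstream metrics share one convention. Portal/hepatic
  rasterization overlaps are resolved in favour of the portal label, and
  the hepatic tree is grown measuring only voxels not already portal, so
  both systems hit their targets after resolution.

## The cohort simulator

`simulate_cohort()` draws per-subject records in three groups (healthy
controls, non-ACLD, ACLD; default sizes 35 / 44 / 118). Design choices:

* **Marginals.** Skewed biomarkers are log-normal, matched to published
  median and interquartile range (`meanlog = log(median)`,
  `sdlog = (log q3 − log q1) / (2 z₀.₇₅)`); age is Gaussian. The table of
  levels lives in `group_marginals()`. The printed albumin unit (g/dL with
  magnitudes ≈ 40) is internally inconsistent with clinical g/dL; the
  simulator stores g/dL values a tenth of the printed levels, so that the
  ALBI formula's g/dL → g/L conversion reproduces the published ALBI range.
  AST and ALT are not published group-wise; their levels were chosen
  clinically plausible and such that the implied FIB-4 medians match the
  published 0.8 (non-ACLD) and 3.5 (ACLD).
* **Dependence.** A Gaussian copula with Spearman targets
  (`copula_spearman_targets()`), converted to latent Pearson correlations
  via `2 sin(πρ/6)`. The sign structure encodes the reported correlation
  map: the latent per-subject HVVR correlates positively with albumin and
  platelets and negatively with bilirubin, AST, INR, liver stiffness and
  spleen volume; PVVR similarly but weaker. Derived scores (FIB-4, ALBI,
  MELD-Na) are *computed* from the drawn labs, never simulated directly, so
  their correlations with the VVRs arise mechanistically — partly within
  groups through the copula and partly between groups through the shifted
  marginals, as in real cohorts.
* **Availability.** Liver stiffness and HVPG are missing at random at the
  published per-variable rates (14/44 and 51/118 for LSM; 50/118 for HVPG,
  ACLD only); correlation analyses are pairwise-complete.
* **What passing tests do not show.** The simulator makes no claim that
  real biomarkers are log-normal or Gaussian-coupled; it is a calibration
  stand-in that reproduces the published location/spread and correlation
  signs. Tests passing on these cohorts validate the *statistical
  machinery*, not any distributional claim about patients.

Per-subject VVR targets are drawn from group-specific log-normals centred
on the published group medians, and `phantom_spec_for_subject()` carries
them into the imaging arm.

## The segmentation network

`unet_config()` describes a compact 3D U-Net: per resolution level two
3×3×3 convolutions, each followed by group normalisation (8 groups,
clamped to the channel count) and a rectified linear unit; 2×2×2 max
pooling between levels; nearest-neighbour upsampling with skip
concatenation on the way up; and a 1×1×1 classifier. Channel widths double
per level from `base_channels`. Optimisation is Adam at 10⁻³, batch size 1,
on patches sampled on a regular stride grid with the last patch clamped to
the boundary and vessel-containing patches oversampled 2×.

Choices where the design was open:

* **Depth.** `n_levels` counts resolution levels; the default 3 (two
  poolings) is the desk-scale profile with 64 × 48 × 32 patches and
  16 × 12 × 8 stride. The full-scale profile (128 × 96 × 64 patches,
  32 × 24 × 16 stride, `n_levels = 4`) is a configuration away.
* **Loss.** Mean per-voxel cross-entropy plus soft multi-class Dice
  (squared denominator), equally weighted and configurable — the standard
  combination for class-imbalanced vessel maps.
* **Stopping.** A fixed epoch budget with best-loss checkpointing.
* **Block order.** conv → GroupNorm → ReLU.
* **Ties.** Per-voxel argmax breaks ties toward the lowest class index,
  for determinism.
* **Augmentation.** Elastic deformation (a coarse random displacement grid
  upsampled with cubic splines — the order-3 spline acts on the
  displacement field — applied by trilinear resampling, labels
  nearest-neighbour), axis flips, 90° rotations on equal-length axis pairs,
  small ±15° rotations, contrast scaling, Gaussian and Poisson noise.
  Geometric transforms are shared between image and label; intensity
  transforms touch the image only.
* **Organs.** By default the synthetic pipeline keeps ground-truth organ
  masks when quantifying predictions, so vessel metrics isolate
  vessel-segmentation error; a 5-class network can predict organs instead.

The engine is single-precision C++ (Armadillo/BLAS). Convolutions are
evaluated as 27 shifted GEMM accumulations with explicit boundary
corrections rather than im2col, which keeps the working set cache-resident
— on a single CPU the im2col buffers cost more in memory traffic than the
arithmetic they feed. Analytic gradients match finite differences to
~10⁻⁴ relative in configurations without pooling; with pooling,
perturbation can switch argmax selections, which is a property of the
subgradient, not an implementation error.

Cross-validation (`crossvalidate()`) uses seeded stratified k-fold
partitions by group label. The published fold arithmetic for the 24
annotated cases is internally inconsistent (three disjoint test sets of 4
non-ACLD cannot be drawn from 6); a stratified partition is this package's
reading. Whether control cases join training is decided by which cases the
caller passes.

## Calibre-stratified Dice

`dice_by_bin()` partitions the *ground-truth* foreground by EDT bins, then
scores the prediction inside each bin's region: the bin mask dilated by one
voxel (absorbing boundary predictions) minus ground-truth voxels of other
bins. With that regioning a perfect prediction scores exactly 1 in every
bin; a plain dilated region would not, because neighbouring bins overlap
after dilation. Bins without ground-truth voxels are `NA` and excluded
from averages. How predictions should map to bins is not defined by the
source analysis; this construction is the package's own and is stated here
so results are interpretable.

## Statistical layer

Group comparisons use the Kruskal–Wallis test (base R `kruskal.test`, tie
corrected) followed by two-sided pairwise Mann–Whitney U tests
(`wilcox.test`, normal approximation with continuity correction; exact
enumeration automatically when both groups have ≤ 8 observations and no
ties) with Bonferroni correction `p = min(1, 3 p_raw)` for the three-group
design. Percent decreases between group medians are reported to one
decimal. Spearman correlations are computed as Pearson correlations of
midranks with a t-approximation p-value, uncorrected for multiplicity,
mirroring the source analysis's reporting. Quartiles use linear
interpolation (type 7). Staging applies the FIB-4 rule — ACLD iff
FIB-4 ≥ 1.75 (the cutoff itself counts as ACLD; the published rule states
no inequality direction) and/or decompensation history — with FIB-4 risk
categories low < 1.3 ≤ intermediate ≤ 2.67 < high. Subgroup analyses rerun
the same machinery on (non-ACLD, compensated ACLD, decompensated ACLD) and
on the FIB-4 categories; empty subgroups yield explicit `NA`s.

## Problem sizes in the shipped tests

The test suite exercises the full method at sizes chosen for a single-CPU
desk run: phantoms on 64 × 48 × 32 grids; the learning check trains the
desk-scale network (base 16 channels) for 200 epochs on 6 noise-free
phantoms and evaluates 2 held-out phantoms; power and size of the
statistical pipeline are estimated with 500 simulation replicates at the
published group sizes; marginal and sign recovery use 10,000 draws. The
acceptance script repeats a lighter version of each computation
(`scripts/acceptance.R`).

## Known limitations

* Phantoms are geometric idealisations: ellipsoidal organs, circular
  vessel cross-sections, no arterial or biliary trees, no motion or MR
  physics. Segmentation performance on them overstates performance on
  clinical images.
* The per-voxel EDT "diameter" under-reports true vessel diameter by about
  a factor of two (it is a radius), and bins mix calibres at structure
  surfaces; both are properties of the followed convention.
* MELD-Na is computed continuously (no integer rounding of the MELD
  score), clamped to [6, 40].
* The copula's correlation magnitudes are design targets, not estimates;
  only the sign structure and rough magnitude are calibrated.
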