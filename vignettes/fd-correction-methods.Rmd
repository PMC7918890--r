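---
title: "Fermi-Dirac correction functions: model, parameters, and validation strategy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fermi-Dirac correction functions: model, parameters, and validation strategy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdcorrect)
```

## The model

Skull-stripped multimodal brain MRI (T1, T1-CE, T2, T2-FLAIR) arrives with
arbitrary, scanner-dependent intensity scales, and segmentation networks
train faster and generalize better when intensities are normalized and
uninformative tissue is suppressed. `fdcorrect` treats each voxel intensity
$\varepsilon$ as a pseudo-energy in a non-interacting particle system and
applies the Fermi-Dirac (FD) occupation form as a correction function:

$$\mathrm{FD2}(\varepsilon) =
  \frac{1}{e^{-(\varepsilon - \varepsilon_F)/|\varepsilon_b|} + 1},$$

where $\varepsilon_F$ (the pseudo-Fermi energy) is the global mean intensity
of the testing set and $\varepsilon_b$ is *minus* its global standard
deviation. The construction fuses two familiar operations: the kernel
$(\varepsilon - \varepsilon_F)/|\varepsilon_b|$ is exactly a z-score, and the
skeleton is the logistic sigmoid, so

```{r identity}
set.seed(1)
v <- array(runif(60, 1, 255), dim = c(3, 4, 5))
p <- estimate_fd_params(v, exclude_zeros = FALSE)
all.equal(fd_correct(v, p), array(plogis(zscore_normalize(v, p)), dim(v)),
          tolerance = 1e-15)
```

Consequences used throughout the package and its tests:

* the output lies strictly in $(0, 1)$ and is strictly increasing in the
  input intensity (a normalization);
* a voxel exactly at the mean maps to $1/2$; below-mean ("insignificant")
  components are squeezed toward 0 and above-mean components are enhanced
  toward 1 (a filter);
* `FD1` is the variant with $|\varepsilon_b|$ fixed to 1 — the raw sigmoid of
  the centered intensity — kept for comparative analysis of the kernel
  scaling.

The companion Bose-Einstein form $1/(e^{(\varepsilon-\varepsilon_F)/\varepsilon_b} - 1)$
diverges at the mean intensity and turns negative above it, and the
Maxwell-Boltzmann form $e^{-(\varepsilon-\varepsilon_F)/\varepsilon_b}$ is
unbounded; `be_transform()` and `mb_transform()` implement them only to make
the comparative argument executable. All three forms agree within $10^{-3}$
relative once the kernel exceeds 10 (the classical limit), which the test
suite checks directly.

## Parameters and conventions

* **$\varepsilon_b$ sign.** Stored $\le 0$, as "minus the global standard
  deviation" dictates; the FD2 denominator uses $|\varepsilon_b|$, which
  makes the correction an *increasing* sigmoid. The signed kernel
  $(\varepsilon-\varepsilon_F)/\varepsilon_b$ with $\varepsilon_b < 0$ gives
  the identical function, so the occupation form and the correction form are
  one object.
* **Statistics scope** (`stats_scope`). The defining statistics are global —
  one mean and one standard deviation per testing set — because per-subsystem
  means are impractical to estimate. `"dataset"` (default) pools every
  supplied channel volume; `"volume"` is available for single-volume work.
* **Zero exclusion** (`exclude_zeros`, default `TRUE`). Skull-stripped
  volumes are mostly exact zeros; including them collapses
  $\varepsilon_F$ toward 0 and destroys the intended regime (a mean
  around mid-range intensity, e.g. $\varepsilon_F = 125$ on a 1–255 scale).
  Corrected outputs keep the zero background at exactly 0 so downstream code
  can still recognise it. Both modes are exposed because the choice is a
  genuine degree of freedom for non-skull-stripped data.
* **Population standard deviation** (divide by $N$): the parameters describe
  the full voxel population of the set, not a sample; the choice is fixed for
  reproducibility and is numerically irrelevant at MRI voxel counts.
* **Gamma correction** (`gamma_correct`) min-max normalizes each volume to
  $[0,1]$ before exponentiation; the exponent default 0.6 is the grid-search
  optimum over $\{0.2, 0.4, 0.6, 0.8, 1.0, 1.2, 1.5, 2\}$, and
  `gamma_sweep()` re-runs that search with a user-supplied evaluator,
  breaking ties toward the smaller exponent so selection is deterministic.
* **3D global histogram equalization** (`histogram_equalize_3d`) builds one
  256-bin histogram over the whole volume (never per slice) and maps voxels
  through the normalized CDF into $(0, 1]$; the mapping preserves voxel rank
  order, and the value of a voxel is the participating-voxel fraction at or
  below its bin, so the top occupied bin maps to exactly 1.
* **Rescaling** (`rescale_to_input`) takes native 240×240 axial slices to the
  network input size of 160×160: bilinear interpolation for intensities,
  nearest-neighbour for labels — the only convention that cannot fabricate
  label codes.
* **Printed-precision rounding.** Published confusion-matrix tables print
  accuracy to 4 decimals and recall/precision to 2 with half-up rounding;
  `round_half_up()`/`reported_metrics()` isolate that rule so comparisons
  against printed rows are explicit about it (base `round()` is half-even and
  would disagree on e.g. 0.905).

## Evaluation machinery

`soft_dice_loss()` implements
$DL = 1 - (2\sum_i p_i g_i + \epsilon)/(\sum_i p_i^2 + \sum_i g_i^2 + \epsilon)$
with $\epsilon = 10^{-5}$ to avoid divergence on empty masks; for a perfect
binary prediction the $\epsilon$ cancels and the loss is exactly zero.
`confusion_counts()` tallies voxel-wise TP/TN/FP/FN (the four always
partition the voxel total), `pool_counts()` sums them over cases, and
accuracy/recall/precision follow the standard pooled-count formulas.
`label_decompose()` maps the integer label codes {0 background, 1 necrotic/
non-enhancing core, 2 edema, 4 enhancing} to the nested evaluation regions
ET = {4} ⊆ TC = {1, 4} ⊆ WT = {1, 2, 4}.

Training-stage constants of the segmentation experiments this package's
evaluation layout mirrors (30 epochs, batch size 32, Adam with initial
learning rate 0.00015, sigmoid/softmax output activations) are provenance
metadata only: no training code ships here, and a trivial
`threshold_segmenter()` — tumor iff the channel-maximum intensity exceeds a
cut — stands in for a trained network so that the preprocess → segment →
evaluate loop is exercisable on one CPU in seconds.

## The phantom generator

`phantom_spec()`/`generate_case()` emulate a skull-stripped multimodal case:
nested ellipsoidal compartments (enhancing core inside a necrotic shell
inside edema) within a brain ellipsoid, an exact-zero background outside the
brain, per-channel class contrasts mimicking real modality behaviour (the
FLAIR-like channel brightens edema, the T1-CE-like channel brightens
enhancing tumor), additive Gaussian noise inside the brain, and a per-case
in-plane tilt emulating affine augmentation. Defaults were chosen once as
field-plausible study conditions and are not tuned: shape (32, 160, 160)
puts one case at 819,200 voxels, the order of the ~812,535-voxel pooled
validation tallies the evaluation tables report; radius fractions
0.85/0.37/0.25/0.14 give a whole tumor of roughly 21k voxels, the order of
the reported TP+FN ≈ 21,191; contrasts sit on a uint8-like 0–255 scale with
noise σ = 5. Ellipsoids carry a fixed 0.75 in-plane anisotropy so the tilt
is geometrically meaningful. Seeding derives one reproducible stream per
`(seed, case_index)`, so any case can be regenerated independently.

What the phantom does *not* model: anatomy, bias fields, partial-volume
effects, Rician noise statistics (the noise hook is Gaussian by design,
documented and pluggable at the spec level), or inter-scanner variation.
Tests passing on phantoms therefore validate the *mechanics* of the
pipeline — parameter estimation, the correction algebra, label handling,
metric bookkeeping — not clinical performance on real BraTS data, which
requires trained networks and GPUs and is out of scope here.

## Numerical choices and edge cases

* FD outputs saturate to exactly 0 or 1 in double precision once the kernel
  magnitude exceeds ~36; with the FD2 scaling this needs intensities ~36
  standard deviations from the mean and is unreachable on real data, but
  FD1's unit kernel can saturate on wide intensity ranges. The property
  tests therefore probe strict monotonicity within the representable band.
* Degenerate inputs fail loudly: a constant volume has zero standard
  deviation (FD2/z-score undefined), an all-zero volume has no foreground
  after zero exclusion, the Bose-Einstein transform refuses any voxel at
  exactly the mean (its pole), and Gamma correction refuses constant volumes
  it cannot min-max normalize.
* A constant *participating* volume under histogram equalization maps to 1
  (the CDF at its single level), not an error.
* Dice of two empty masks is 1 by convention (correct prediction of
  absence); indicators with vanishing denominators are reported `NA` and
  flagged rather than silently dropped.
* Evaluation pools counts over cases before computing indicators. Published
  tables whose recall/precision cells are inconsistent with their own pooled
  counts (per-case averaging is the likely cause) are not used as
  references; only internally consistent rows are pinned in the tests.

## Problem sizes used in the test suite

The suite runs on phantoms of shape (12, 24, 24) to (10, 32, 32) and 1–4
cases — large enough to exercise nesting, contrast, noise, and pooling, and
small enough that the whole suite completes in a few seconds. The acceptance
script uses the full default case shape (32, 160, 160), two cases, roughly
2.1 million foreground voxels per parameter estimate.
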