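---
title: "Plan-conditioned dose prediction for online adaptive radiotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plan-conditioned dose prediction for online adaptive radiotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptdose)
```

## The problem

In online adaptive radiotherapy (ART) for head-and-neck cancer, the plan is
re-optimized at every treatment session to track daily anatomical change:
tumours shrink, parotid and submandibular glands lose volume, and the
spinal cord shifts relative to the external contour as the patient loses
weight. A dose-prediction model that proposes a physically plausible 3D
dose distribution for the day's anatomy shortens the on-couch planning
loop. Conventional population models predict from the session's anatomy
alone, which discards a crucial signal: the physician-approved
pre-treatment plan already encodes this patient's organ-sparing trade-offs.
Two patients with near-identical anatomy can have deliberately different
parotid doses because their physicians weighted xerostomia risk
differently; anatomy-only models can only predict the population average
of that choice.

`adaptdose` implements two models for this task:

* **U-Net** — a single-head 3D encoder–decoder predicting the adaptive
  session dose from a 90-channel anatomical stack (44 organ-at-risk masks,
  their 44 distance maps, the merged PTV prescription map, and the CT).
* **MHU-Net** — a dual-head variant whose secondary encoder additionally
  ingests the pre-treatment plan (same 90 anatomical channels for the
  pre-treatment anatomy plus the approved dose, 91 channels). Feature maps
  from the secondary head are copied and concatenated into the primary
  encoder at each of the first three levels, and both streams merge into a
  shared bottleneck, so per-patient sparing intent conditions the adaptive
  prediction.

## Input representation

Sessions are resampled to a common working grid (5 mm isotropic by
default; output shape is `ceiling(shape * spacing / target)`). Masks and
the PTV prescription map use nearest-neighbour interpolation because labels
and prescription levels are categorical; CT and dose are trilinear. The
channel stack is fixed by the canonical 44-structure roster
(`oar_roster()`), so tensors are comparable across patients: structures the
clinic never contoured become all-zero mask and distance channels rather
than shifting the layout.

Distance maps give the convolutional layers long-range spatial context that
binary masks lack. Each structure contributes a normalized map equal to 1.0
inside the structure and decaying with the exact Euclidean distance `d`
(mm) to its surface as `exp(-d / tau)`, with `tau = 50` mm by default — at
that scale the map still separates 10 mm from 30 mm from a structure, the
range over which dose gradients matter clinically, while staying bounded in
`[0, 1]`. The decay form and scale are this package's choice: the
endpoints (1 inside, 0 far away) are the established convention, but no
standard fixes the falloff in between. A structure-surface reference is the
default because one map is computed per structure; a variant measuring
distance to the structure's centre of mass is available
(`distance_map_spec(mode = "isocenter")`) for workflows that prefer a
single-reference-point encoding. CT is rescaled as `(HU + 1000)/2000`
clipped to `[0, 1]`; the PTV map and dose are divided by a cohort
normalization constant (default 72 Gy, the top of the prescription range).

## Architecture

Both networks share the same backbone. Encoder levels apply two
`3×3×3` convolutions (stride 1, ReLU), each followed by group
normalization and block dropout. Downsampling concatenates 2×2×2 max
pooling and 2×2×2 average pooling, halving the spatial dimensions and
doubling the channel count — at base width 64 the first level's 64-channel
feature map becomes a 128-channel map at half resolution. Decoder levels
upsample by concatenating three branches — nearest-neighbour interpolation,
trilinear interpolation, and a stride-2 `2×2×2` transposed
convolution — merge the encoder skip at the same level, and apply two
convolutions that project back to the level's nominal width. A final
`1×1×1` convolution produces the single-channel dose map; a ReLU follows it
by default because dose is non-negative (configurable).

In MHU-Net the secondary encoder mirrors the primary's first three levels.
After each downsampling, the secondary head's feature maps are concatenated
with the primary head's before the next primary block; the block's first
convolution projects the doubled channel count back to the nominal level
width, which keeps the printed channel schedule intact — with base width 64
and four levels on a 96×96×64 patch the merged bottleneck is 512 channels
at 12×12×8, identical to the single-head network. `model_summary()` prints
the full per-stage shape table; `net_forward(..., trace = TRUE)` records
the same shapes from a live forward pass.

Choices the architecture description leaves open, and what this package
does about them:

* **Fusion bookkeeping.** Only endpoint shapes are fixed by the design;
  after every concatenation (cross-head or three-branch upsampling) the
  next convolution projects to the nominal level width.
* **Group normalization at reduced widths.** The normalizer uses the
  largest divisor of the channel count not exceeding the configured group
  count (32), so desk-scale configurations with 4–8 channels normalize
  cleanly; at full scale this reduces to 32 groups exactly. Decoder blocks
  are normalized like encoder blocks (flag `decoder_norm` to disable).
* **Dropout** follows the width-scaled power law
  `rate = max_rate * (width / max_width)^power` with `max_rate = 0.05`,
  `power = 0.25`: deeper (wider) layers are regularized more. Placement is
  per block, after conv + norm + activation, disabled at inference.
* **Bypass stream.** An optional skip-free stream (off by default,
  `bypass_stream = TRUE`) carries the bottleneck through trilinear
  upsampling and 1×1×1 projections and is concatenated before the output
  head, for experiments on how much the skip connections contribute.
* **Initialization** is He-style fan-in scaling, seedable. The output
  head's bias starts at a small positive value (0.1 in normalized dose
  units): with a ReLU on the output and a zero bias, an unlucky draw can
  initialize the whole network dead — output identically zero and a zero
  gradient through the output mask — which surfaced as training runs whose
  loss froze at the variance of the target.

## Training protocol

Training uses Adam at a constant learning rate (default `1e-4`), MSE loss
(sum of squared voxel differences over the voxel count), and batch size 1.
Patches of 96×96×64 voxels (configurable) are drawn with their centre
sampled from a Gaussian around the PTV centre of mass and augmented by
in-plane flips and rotations restricted to 90/180/270 degrees, each applied
with probability 0.5; the same geometric transform is applied to every
input channel and the target, and transforms are pure voxel permutations.
The translation spread defaults to 5 voxels per axis — wide enough that
patch boundaries move across the dose gradient, narrow enough that the
PTV stays in view. One epoch draws one patch from each training plan in
shuffled order. Validation loss is computed on whole stitched volumes
(sliding window, half-patch stride, overlap averaging) rather than random
patches so checkpoint selection is deterministic; the checkpoint with the
lowest validation loss is retained. For MHU-Net, pre-treatment plans can
additionally serve as self-conditioned training samples — the pre-treatment
session feeds both heads and its own dose is the target — which enlarges
the sample count at no annotation cost (`include_pretreatment`, on by
default, excluded from matched model comparisons).

Runs are bit-reproducible from the configuration seed: patch draws,
augmentation, dropout and initialization all flow from R's RNG.

## The phantom simulator

The clinical cohorts this method targets cannot be redistributed, so the
package ships a synthetic phantom cohort generator whose *statistical*
structure reproduces the learning problem: persistent per-patient intent
plus session-to-session anatomical change. It is a test harness, not a
beam-physics simulator.

Each patient is an ellipsoidal body containing 1–5 ellipsoidal PTVs with
prescriptions drawn from 42.5–72 Gy, and a default set of ten analytically
placed OARs (cord-like tubes for spinal cord/canal/esophagus, paired
parotid and submandibular blobs, larynx, brainstem, oral cavity). The dose
model assigns each PTV voxel its prescription and decays outside as
`exp(-d / lambda)` with `lambda = 20` mm (head-and-neck photon falloff is a
few cm to half-dose) with voxels taking the maximum over PTVs. Each organ
`o` carries a latent sparing strength `sigma_o ~ U(0, 0.6)` — the
physician-intent surrogate — that multiplies the field by
`1 - sigma_o * exp(-d_o / lambda)`, carving a dose valley of depth
`sigma_o` centred on the organ. Smooth zero-mean noise (0.8 Gy SD,
generated at quarter resolution and trilinearly upsampled; the same field
for both sessions of a patient, emulating a systematic per-patient planning
style) is added and the result clipped at zero and masked to the body.

The adaptive session re-rasterizes a deformed copy of the analytic
geometry — PTVs shrunk by a sampled volume factor (0.7–0.95), structures
shifted by 3 mm Gaussian offsets, gland volumes reduced by 0.75–0.95 —
and synthesizes its ground-truth dose from the *same* sparing profile.
Deformation is analytic rather than voxel-warped so deformed ground truth
is exact. Because `sigma_o` is constant within a patient but varies across
patients, the pre-treatment dose is informative about the adaptive dose
beyond anatomy alone; a regression test verifies the sparing strengths are
recoverable from the pre-treatment dose (correlation > 0.8), i.e. the
conditioning task is well-posed by construction.

What the phantom does not emulate: realistic CT texture and heterogeneity
corrections, beam geometry (no beam directions, no penumbra anisotropy),
contouring noise, or registration error between sessions (inputs are
co-registered by construction). Passing the mechanism test therefore shows
that the dual-head architecture can exploit plan conditioning when the
signal exists; it does not quantify clinical accuracy on real patients.

## The scaled mechanism study

`run_conditioning_study()` is the package's end-to-end check that
conditioning helps: 24 training + 4 validation phantom patients on a
48×48×32 grid at 5 mm, both networks at base width 8 with 3 levels,
32-cubed patches, 12 epochs (288 optimizer steps) at Adam `1e-3`, matched
seeds. These sizes were chosen once so a replicate trains both models in
minutes on one CPU while leaving the networks expressive enough to use the
secondary head; the batch-1, few-step regime motivates the larger constant
learning rate than the full-scale default. The acceptance suite runs three
replicates and requires the median best validation MSE of MHU-Net to be
below that of U-Net — the qualitative direction of the architectural claim,
not its clinical magnitude.

## Numerical choices

* Convolutions are evaluated as per-kernel-offset GEMMs on single-precision
  buffers (activations, parameters and optimizer state stay double); an
  all-double reference implementation backs the unit-test oracles, and the
  fast path agrees with it to ~1e-6 relative.
* The Euclidean distance transform is the exact separable lower-envelope
  algorithm with anisotropic spacing, verified against an all-pairs oracle.
* `Dx%` uses linear interpolation between adjacent sorted voxel doses
  (`stats::quantile` type 7); conventions differ across planning systems,
  so this is documented rather than assumed. `Dmax` is the maximum voxel
  dose, with no volume qualifier. Reading `Dx%` off a binned DVH curve
  returns the largest grid dose still covering x% of the volume, which is
  within one grid bin of the exact threshold.
* The paired Wilcoxon signed-rank comparison drops zero differences,
  mid-ranks ties, and reports p = 1 with a degeneracy flag when every
  difference is zero; `stats::wilcox.test` provides the exact small-sample
  distribution.
* Max-pooling ties resolve to the first block element in a fixed traversal
  order, keeping backward passes deterministic.
* Trilinear 2x upsampling uses the half-voxel (align-corners-false)
  convention, clamped at the boundary.

## Limitations

The networks are CPU-bound R/C++ implementations intended for method
development, desk-scale experiments and audit of the architecture; a
full-scale clinical training run (thousands of epochs on 96×96×64 patches
at base width 64) is configured identically but is compute-limited here.
The phantom's simplifications listed above mean quantitative error rates
on real cohorts cannot be inferred from it. Sessions are assumed
co-registered; DICOM-RT parsing and deformable registration are out of
scope (inputs arrive as NIfTI bundles or serialized sessions).

## Package shape

Volumetric containers (sessions, assemblies, fitted networks) are plain R
lists and arrays, as is usual for imaging toolkits; every tabular result —
shape tables, training histories, DVH curves, dose-metric reports, model
comparisons — is a tibble, with `autoplot()`, `tidy()` and `glance()`
methods, so downstream analysis composes with dplyr/ggplot2 pipelines.
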