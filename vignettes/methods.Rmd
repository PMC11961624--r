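---
title: "Automated AAOCA screening on cardiac CT: models, phantoms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated AAOCA screening on cardiac CT: models, phantoms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Anomalous aortic origin of a coronary artery (AAOCA) is a rare congenital
variant in which a coronary artery arises from the wrong aortic sinus or
at an abnormal ostium position. Most variants — pre-pulmonic, retro-aortic
or high take-off courses — are low anatomical risk, but an interarterial
course (the proximal vessel squeezed between the aorta and the pulmonary
artery) or a sub-pulmonic intraseptal course is associated with ischemia
and sudden cardiac death, so detection and risk stratification on coronary
CT angiography (CCTA) matter clinically. `coroscreen` implements a fully
automated screening pipeline for 3D CCTA volumes:

1. **Localization.** A rough segmentation of the aorta and left ventricle
   is all that is needed to find the aortic root. The reference point is
   the centroid of the aorto-ventricular contact set, shifted 1 cm to the
   patient's right and 1 cm superior so more of the curved ascending aorta
   enters the field, and an 8 × 8 × 6 cm³ physical box around it is
   cropped. The origin and proximal course of the anomaly — the decisive
   anatomy — lie inside this box.
2. **Preprocessing.** The crop is resampled by spline interpolation to
   215 × 215 × 85 voxels, clipped to the Hounsfield window [−1024, 1024],
   discretized into 256 intensity levels, and min–max scaled to [0, 1].
3. **Classification.** A 3D squeeze-and-excitation (SE) residual network
   scores three cascaded binary tasks: anomaly detection (normal vs
   AAOCA), origin classification (right vs left anomalous vessel), and
   anatomical risk (low vs high). The origin and risk models are trained
   only on the AAOCA-positive subset, initialised from the anomaly
   model's backbone. Five identically split, differently initialised
   trainings are averaged into an ensemble.
4. **Evaluation and interpretability.** Metrics (ROC AUC, sensitivity,
   specificity, F1, PPV, AUPR, accuracy) with percentile-bootstrap
   confidence and tolerance intervals, confusion matrices over a
   0.1–0.9 cutoff sweep, sex-disaggregated reports, Grad-CAM++ volumetric
   saliency and t-SNE maps of the penultimate-layer embeddings.

Because clinical CCTA with AAOCA labels is restricted data, the package
ships a first-class synthetic phantom generator so that every stage is
exercised and tested end to end without any patient data.

# The phantom generator

`generatePhantom()` builds labeled CCTA look-alikes from analytic
primitives in a canonical patient frame (+x = right, +y = anterior,
+z = superior): an elliptical-cylinder body, ellipsoidal lungs, an
ellipsoidal LV (8 mm myocardial shell around a contrast-filled cavity,
joined to the aortic root through a narrow outflow-tract channel),
vertical cylinders with a root sphere for the ascending aorta and the
pulmonary artery (PA), and a Catmull–Rom spline tube for one coronary
artery. The image is the sum of per-tissue mean attenuation (air −1000,
lung −800, soft tissue 40, myocardium 80, contrast blood pool 400, PA
blood 150, coronary 350 HU — typical CCTA values, all inside the clip
window) and Gaussian noise (default σ = 25 HU).

The coronary course realises the risk taxonomy, and each course is
backed by a geometric predicate evaluated on the returned centerline:

* **interarterial** (high risk): the proximal 2 cm projects between the
  two vessel surfaces along the line joining their centroids;
* **sub-pulmonic** (high risk): the proximal segment stays inferior to
  the PA centroid and anterior to the aorta;
* **pre-pulmonic** (low risk): within the PA's sagittal slab and z-span
  the centerline stays anterior to the PA centroid;
* **retro-aortic** (low risk): within the aorta's sagittal span the
  centerline stays posterior to the aortic centroid;
* **high take-off** (low risk): the ostium sits at least a configured
  height (default 12 mm) above the sinotubular junction.

Right- vs left-sided anomalies (R-AAOCA / L-AAOCA) share the proximal
course geometry and differ in the distal territory the tube supplies;
the risk label derives mechanically from the course, with no per-case
override. Anatomical variability is emulated by a seeded uniform
translation of the whole heart complex (±4 mm), a small independent PA
offset (±1 mm) and a ±10% coronary radius scale. Multi-phase
reconstructions are emulated by warping phase 0 with smooth random
displacement fields whose maximum norm is bounded by the configured
amplitude (trilinear upsampling of a coarse control grid is a convex
combination, so the bound is exact).

**What the phantoms do not model** — and hence what passing tests do not
show about clinical data: photon/reconstruction physics (beam hardening,
streaks), real anatomical topology (valve leaflets, atria, coronary
branching), plaque, stents, pathology other than the coronary course,
and the intensity statistics of real contrast protocols. Phantom results
demonstrate that the pipeline's machinery is correct and that the
architecture can learn course geometry at desk scale; they are not
evidence of clinical performance.

# Localization details

Label maps assign one label per voxel, so aorta and LV abut rather than
overlap; "the point where the segments intersect" is operationalised as
the dilated-contact set (aorta voxels whose dilation meets the LV, union
the symmetric set, trying radii 1..3), with literal shared voxels taking
precedence if present. Whether the offset's "right" means patient-right
or image-right is not determinable from the description we follow; we
take patient axes (+10 mm right, +10 mm superior), which matches the
stated anatomical intent of including more ascending aorta, and expose
the vector as a configurable argument. Crop boxes are realised as
0-based half-open voxel ranges with `ceiling(extent / spacing)` voxels
per axis, so the physical size equals the request to within one voxel;
out-of-field portions are padded with −1024 HU, the clip floor, making
padding neutral after preprocessing.

`naiveSegment()` is a deliberately rough phantom-only segmenter
(threshold, morphological closing, erosion-split of the blood pool at
the narrow outflow tract, capped geodesic regrowth, and an opened
muscle-window mask for the myocardium). It exists because cropping only
needs a rough segmentation; it is not a clinical model, and the
ground-truth label map is the default localization input in phantom
pipelines.

# Preprocessing decisions

"256 levels ranging from 0 to 256" is internally inconsistent (257
values); we resolve it as integer levels 0..255 with the top window edge
mapped to 255, the standard 8-bit convention, configurable via
`nLevels`. Spline order defaults to cubic (Catmull–Rom, interpolating,
constant-preserving, separable per axis); orders 0 and 1 are available.
Min–max scaling is per-volume, after per-volume discretization; constant
volumes map to all zeros by contract. Cropping precedes resampling,
following the stage order of the clinical pipeline description. The
pipeline is RNG-free and monotone (for volumes whose extrema pin the
window), and those properties are asserted in the test suite.

# Augmentation models

The acquisition-artifact augmentations are minimal physically motivated
emulations (the clinical pipeline's exact parameterisations are not
published): cardiac-motion ghosting as a convex combination of randomly
shifted copies (d₀ = 0), and the step-and-shoot table misregistration as
a rigid in-plane shift of all slices above a random slab boundary.
Intensity transforms are Gaussian noise (re-clamped to [0, 1]), a
physical-units Gaussian blur with unit-sum kernels, and gamma contrast.
The fixed order contrast → blur → noise → motion → step keeps the noise
statistics interpretable (intensity before geometry). Transforms with
zero probability consume no randomness, so the all-zero configuration is
bitwise identical to the deterministic pipeline. Out-of-field voxels
created by shifts are filled with 0, the post-normalisation air value.

# Network and training

The classifier family is a 3D SE-ResNet: a stride-2 3×3×3 stem with
batch norm and 2×2×2 max pooling, stages of SE-residual blocks (first
block of each stage downsamples and doubles the channels; SE gates are a
squeeze–excite bottleneck with sigmoid output multiplying each channel),
global average pooling, and a single sigmoid logit. "4 blocks" is read
as 4 stages, consistent with saliency being reported "at block 2 (out of
4)". The full-scale preset follows the SE-ResNet-152 stage pattern
(3/8/36/3 bottleneck blocks, 64 base channels, 215 × 215 × 85 input);
`networkLayerCount()` reports the realised weighted depth (152 counting
stem, block convolutions and head — projection shortcuts and SE layers
excluded, the usual ResNet counting convention). The everyday preset is
"tiny" (2 stages × 1 basic block, 8 base channels, 64 × 64 × 48 input),
sized so a full training run fits a single desktop CPU core.

There is no deep-learning framework in this stack, so the network — the
im2col+GEMM convolutions, batch-norm, pooling, SE gating, the backward
pass, and Adam — is implemented from first principles (C++ kernels for
convolution/pooling, R for the rest). The backward pass is verified
against central finite differences for both the basic and bottleneck
block variants in the test suite.

Training follows the reference recipe: binary cross entropy, cosine
annealing from lr₀ = 0.001 over 300 epochs with early stopping, Kaiming
initialisation, patient-wise 90:10 train/validation split (all phases of
a patient on one side), and a 5-member ensemble sharing one split and
differing only in the initialisation seed, averaged at prediction time.
Unstated details we fixed: the optimizer is Adam (β₁ = 0.9, β₂ = 0.999);
early-stopping patience defaults to 20 epochs on validation loss;
checkpoint selection takes the lowest validation loss with validation
accuracy as tie-break; the validation draw is stratified by class so
small subsets keep both classes on both sides; multi-phase inference
averages per-member probabilities over phases (symmetric with member
ensembling; `max` is available). Desk-scale runs shrink only the scale
knobs (tiny preset, 12–15 epochs, lr₀ = 0.01, 3 members), never the
contracts.

The task cascade transfers the anomaly backbone: `fineTune()` copies all
member weights, re-initialises the classification head, and trains on
the AAOCA-positive subset. At screening time origin/risk heads are
evaluated only for flagged cases (ensemble anomaly probability ≥ 0.5 by
default), mirroring the conditional task structure; `alwaysEvaluate`
disables the gate.

# Evaluation

The canonical AUC is the Mann–Whitney pair statistic (ties ½), computed
from average ranks and tested against exhaustive pair counting; AUPR is
step integration of the precision–recall curve over distinct-score
thresholds. The decision boundary counts probability = cutoff as
positive. Bootstrap intervals resample at case (patient) level with
percentile 2.5/97.5 limits; single-class resamples are redrawn with a
bounded retry and counted. Tolerance intervals are pointwise percentile
bands of the resampled ROC curves on a common FPR grid. Metrics with
empty denominators are reported as `NA`, never 0, so degenerate groups
cannot silently inflate specificity or PPV.

# Interpretability

Grad-CAM++ uses the positive higher-order gradient weighting
α = G²/(2G² + Σ_vox A·G³) per voxel and channel, channel weights
Σ_vox α·relu(G), a rectified weighted activation sum, trilinear
upsampling to the input grid and per-volume min–max normalisation; a
zero-gradient network yields an all-zero map with a warning. Saliency is
computed per ensemble member — which member to display must be chosen
explicitly. Embeddings are the global-average-pool features (a pure
function of image and weights; labels are attached only as plotting
metadata). t-SNE is the exact O(n²) algorithm with perplexity 30 and PCA
pre-reduction to 50 dimensions when the feature width exceeds 50,
deterministic given its seed.

# Problem sizes and numerical choices

Defaults used by the tests and the acceptance script, chosen as
desk-scale study conditions: phantom grids 128 × 128 × 96 at 1.25 mm
(the 80 × 80 × 60 mm crop is then exactly 64 × 64 × 48 voxels); cohorts
of 240 cases, half normal, the anomalous half spread over all five
courses with both origins; a 25% patient-wise held-out test set; the
tiny network trained 12–15 epochs at lr₀ = 0.01 with 3 members. Bootstrap
defaults are 1000 iterations in reports (10,000 is the full-scale
setting) and 200 in coverage simulations. Tolerances: closed-form
checks at 1e−12; gradient checks at 1e−4 relative; geometric predicates
at 1e−6 mm. Degenerate inputs are all defined contracts rather than
errors where a sensible value exists (constant volume → zero tensor,
zero-gradient saliency → zero map); genuine contract violations (single
class, disjoint masks, too-small grids) raise errors naming the cause.

# Known limitations

Phantom realism is explicitly not validated against clinical images;
the full-scale network preset is provided and auditable but not
trainable at desk scale; the naive segmenter is phantom-only; clinical
performance figures are out of scope by design (they require restricted
multi-centre data and GPU-scale training).
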