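---
title: "Collateral perfusion mapping from DSC-MR perfusion: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collateral perfusion mapping from DSC-MR perfusion: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Dynamic susceptibility contrast MR perfusion (DSC-MRP) records the passage
of a gadolinium bolus through the brain as a transient T2\* signal drop,
sampled here as 40 frames of 20 slices at 1.6 s temporal resolution
(native in-plane size 230×230). Collateral-flow assessment in acute
ischemic stroke divides this passage into five temporal phases anchored on
two reference vessels: the bolus arrives at the middle cerebral artery
(MCA), peaks there (arterial phase), transits the capillary bed to the
venous peak in the superior sagittal sinus (SSS), settles onto a venous
plateau (early/late venous phases), and washes out (delay phase). A map of
peak baseline-subtracted signal per phase visualizes where and *when*
tissue is perfused — delayed, diminished filling distal to an occlusion is
the collateral signature clinicians read.

The package implements two routes to these maps: the deterministic
semi-automatic procedure (subtract, project, read landmarks off ROI
curves, compose per-phase maps), and a trained volumetric
regression network that predicts all five maps from the raw 4D series in
one forward pass.

# Preprocessing conventions

The chain is: brain mask → series normalization → (targets: clip/scale,
median filter) → center crop.

* **Mask**: the series is summed over time, min–max normalized, and
  thresholded at 0.1; the binary mask is refined by morphological closing,
  then erosion, then dilation with a discrete Euclidean ball of radius 6
  voxels. The listed order of the three operations is taken as the
  application order. Morphology uses replicate-padded borders: a brain
  spanning all 20 slices would otherwise be eaten from the volume walls by
  the erosion. Thresholding a min–max-normalized image makes the mask
  invariant to any positive rescaling of the scanner intensities.
* **Series normalization**: min and max are taken *globally* over all
  masked voxels and all time points (not per frame), then mapped to
  [0, 1]; voxels outside the mask are zeroed. Per-frame statistics would
  destroy the temporal bolus dynamics that the phase maps encode, which is
  why the global convention is used.
* **Targets**: raw maps are min–max scaled to [0, 1] with statistics over
  the whole five-phase set (preserving relative phase amplitudes); maps
  already on the unit scale have outliers clipped to 0 or 1; the affine
  map v → 1.8 v − 0.9 then carries [0, 1] bijectively onto [−0.9, 0.9],
  leaving headroom inside the Tanh codomain of the network head. A 5×5
  per-slice median filter denoises the maps; it is applied in 2D because
  slice spacing (5 mm + 2 mm gap) is an order of magnitude coarser than
  in-plane resolution. Because the median commutes with monotone affine
  maps, filtering before or after the affine rescaling yields identical
  results.
* **Crop**: symmetric center crop to 224×224 (230 → 224 keeps the 0-based
  index range [3, 227) on each spatial axis); when the margin is odd the
  extra dropped pixel comes from the high-index side.

# Phase ground truth

All temporal indices are 0-based; frame 0 is the pre-contrast baseline.
Baseline subtraction is `max(0, I0 − I_t)` for T2\* bolus data (the drop
becomes a positive quantity; a `rise` variant covers signal-increasing
acquisitions). The subtracted maximum-intensity projection over any frame
window is the voxelwise temporal maximum.

Landmark detection replaces the expert-in-the-loop step by deterministic
rules, each landmark manually overridable:

* arterial/venous peaks: argmax of the MCA/SSS ROI mean curves;
* arrival: first frame where the MCA curve exceeds 10% of its maximum;
* plateau start: first frame after the venous peak whose forward
  difference falls below 5% of the SSS maximum;
* venous end: the last frame reached by the maximal run of consecutive
  plateau-satisfying steps, capped at T−2 so the delay phase is never
  empty.

The five windows are `Art = [arrival, arterial peak]`,
`Cap = (arterial peak, venous peak]`, `EVen = (venous peak, plateau
start]`, `LVen = (plateau start, venous end]`, `Del = (venous end, T−1]`;
they are contiguous, disjoint, and all must be non-empty (an error names
the offending phase otherwise). The ambiguous "first/second half of the
venous phase" is resolved as the split at plateau onset; this is an
interpretation, recorded here, not an external fact. Each phase map is the
temporal maximum of the subtracted series within its window — consistent
with the subtracted-MIP construction; mean and sum variants are available
(`stat` argument) since the reference implementation's exact per-phase
statistic is not published.

# The network

`model_config()` fixes the architecture; `build_model()` assembles it.
The encoder has four groups:

1. a 1×3×3 convolution stem with spatial stride 2 (depth is never strided
   anywhere in the network — the printed 512×20×6×6 bottleneck forces
   spatial-only downsampling);
2. two sets of two stride-1 3D MV2 blocks plus one stride-2 3D MV2 block.
   An MV2 block is the MobileNetV2 inverted residual in 3D: pointwise
   expansion (×4), depthwise 3×3×3 convolution carrying the stride,
   pointwise projection, identity shortcut when shapes allow;
3. two sets of a 3D MViT block followed by a stride-2 MV2 block. The MViT
   block runs depthwise + pointwise convolutions, unfolds the feature map
   into non-overlapping 2×2×2 volumes (`N = D·H·W/8` tokens, `P = 8`
   positions), applies `L_M` Transformer layers (4 heads, pre-norm,
   MLP ratio 2, SiLU) attending across the N axis independently at each
   position, adds the Transformer input back (a global residual around the
   stack), folds, projects back, concatenates with the block input and
   fuses pointwise. `L_M` is 2 for the first block and 4 for the second;
4. pointwise conv → slice-wise ViT block (one token per slice, `N = D`,
   `P = H·W`, learned positional embedding per token, `L_V` Transformer
   layers) → pointwise conv to 512 channels.

For 224 input the resolution ladder is 112, 56, 28, 14, 6; the final
stride-2 stage is unpadded, since five same-padded halvings would give 7,
not the printed 6. The decoder applies five sets of a 3×3×3 transposed
convolution (spatial stride 2; per-stage padding/output-padding are solved
automatically so the sizes 6→14→28→56→112→224 are hit exactly — "doubling"
is approximate at the first stage) and a residual layer (3×1×1, 3×3×3,
3×1×1 convolutions with a shortcut), with skip concatenations from the
encoder outputs at resolutions 14, 28, 56 and 112; the full-resolution
stage has no skip because no encoder feature exists there. A 1×1×1
convolution to five channels plus Tanh produces the real-valued maps in
(−1, 1).

## Calibration of the open widths

The published description fixes kernel sizes, block layout, `L_M`, the
patch size, head count and the bottleneck, but not the stage widths or
`L_V`. The reference configuration uses a MobileViT-S-style width ladder
(stem 40; 64, 96, 128, 295; attention widths 192, 256; ViT width 256;
decoder 452, 256, 128, 79, 42; `L_V = 4`), chosen by an integer
sensitivity search so that the trainable-parameter count and the static
FLOP count at full input size reproduce the published complexity budget of
the architecture: 26.736 M parameters and 7.140×10¹¹ FLOPs (the package
computes 26.735771 M and 7.145×10¹¹, i.e. within 0.08%). FLOPs are counted
as 2 per multiply-accumulate over convolution, linear and attention matrix
products; biases, normalizations and activations are excluded. The
parameter table header's unit is inconsistent with its own model-size
column (size in MB equals count/2²⁰ across models only if counts are in
millions), so counts are read as millions.

Normalizations and activations inside blocks are not published: conv paths
use batch normalization + SiLU and Transformer layers use layer
normalization, the conventions of the MobileViT family. Because samples
are processed one at a time (a 40×20×224×224 volume per sample bounds
memory), batch-norm statistics during training are per-sample (batch-1
semantics) with running moments for inference.

Initialization starts the network close to an
identity-plus-background-prior: residual-branch final BN gains begin at
zero (each residual block starts as the identity, or its shortcut); the
Tanh head bias begins at `atanh(−0.9)` — the lower edge of the target
interval, the no-bolus background value — and `train_collnet()` refines
it to the atanh of each phase's mean target over the training set
(intercept initialization, as one initializes a GLM intercept at the base
rate); and the first stem channels begin as temporal band-contrast
filters (mean over a band of frames minus the pre-contrast frame, center
tap only), seeding the bolus-passage contrasts that phase maps are built
from. These choices shorten early optimization transients without
changing what the converged network can represent.

# Loss, metrics, training protocol

The training loss is the reverse Huber (BerHu): `|r|` for `|r| ≤ c`,
`(r² + c²)/(2c)` otherwise, with `c = 0.2`; both branches meet at `c` with
slope 1, giving L1 behavior near zero and amplified (but not exploding)
gradients for outliers. Evaluation reports per-phase R², MAE, Tanimoto
measure and SSIM over brain-mask voxels (background is constant and would
inflate R² and SSIM; pass a full mask for whole-volume metrics). SSIM is
implemented as the printed *global* form — one statistic from the masked
voxel population with dynamic range L = 1.8 and stabilizers (0.01 L)² and
(0.03 L)²; a windowed Gaussian variant is provided but non-default.
Aggregation over subjects reports mean and sample standard deviation
(n − 1), overall and by diagnostic group and center.

Training uses Adam at lr 0.001, multiplied by 0.75 whenever the validation
loss fails to improve by more than 1e-6 for 3 consecutive epochs (the
plateau watches *validation* loss, consistent with the model-selection
rule); joint left–right flips with probability 0.5 are the only
augmentation (brains are approximately left–right symmetric); the reported
model is always the minimum-validation-loss epoch, never the last. One
master seed drives initialization, shuffling and augmentation, so runs
replay bit-identically.

# The phantom

`make_phantom()` emulates the acquisition at reduced in-plane scale
(default 40×20×64×64, dt = 1.6 s): an ellipsoidal brain containing an
anterior midline arterial tube (MCA), a posterior midline venous tube
(SSS) and capillary tissue elsewhere, over a dark background. Each
compartment follows peak-normalized gamma-variate kinetics
(`c(t) = K u^α e^{α(1−u)}`, `u = (t−t0)/(αβ)`, peak at `t0 + αβ`): artery
t0 = 6.4 s, α = 3, β = 1.6; capillary t0 = 8 s, α = 3, β = 2.2 plus a
small blood-pool steady state; vein t0 = 11.2 s, α = 3.5, β = 2 plus a
recirculation plateau and a late washout so the venous plateau ends before
the acquisition does (a non-trivial delay phase). Vessel tubes have radius
3 voxels — wide enough to survive the 5×5 median filter of the
preprocessing chain. A smooth multiplicative field (±30%) modulates
perfusion amplitude across the brain, standing in for gray/white-matter
blood-volume variation, so the target maps carry learnable spatial
structure rather than piecewise-constant compartments. The signal model is
a multiplicative T2\* drop, `baseline · (1 − drop_fraction · c(t))` with
drop_fraction 0.4 and baseline 100, plus iid additive Gaussian noise
(default SD: 1% of the peak signal drop). Stroke lesions are spheres of
tissue following *arterial* kinetics delayed by 4.8 s and scaled by 0.55 —
the delayed/diminished collateral signature. `make_cohort()` jitters all
kinetic parameters by ±10% per subject and adds lesions only in stroke
subjects.

Ground truth is exact by construction: landmarks come from the
deterministic detection rules applied to the *noiseless* analytic ROI
curves, and phase maps are the windowed temporal maxima of the noiseless
subtracted series; at zero noise the full pipeline reproduces both
identically (this closure is tested). What the phantom does *not* emulate:
MR physics (relaxometry, partial-volume, motion), realistic vascular
anatomy, inter-subject anatomical variability, and the difficulty of real
patient data — a model that excels on phantoms is shown to be trainable
and pipeline-consistent, not clinically validated.

# Problem sizes and numerical choices

The test suite and the acceptance script run everything at sizes chosen
for a single CPU: phantoms at 64×64 (the native 230×230 geometry is
exercised once through the preprocessing pipeline), the reference
configuration verified by static shape tracing plus a live reduced-grid
forward pass, and training sanity on an 8-subject cohort with the
reduced-width configuration (`reduced_config()`, whose decoder is kept
relatively wide because spatial-detail reconstruction dominates the
residual error at this scale), a train/validation split stratified over
stroke and control subjects (`cohort_split()`), mini-batch 1 (more
optimizer steps per epoch, which matters far more than batch smoothing at
cohort size 6) and at most 50 epochs. Full-size training (batch 4,
224×224) is the documented configuration for accelerator-scale hardware.

Numerical details worth knowing: convolutions run either through a fused
direct C++ kernel (small channel counts) or im2col + BLAS gemm with output
chunked over slices to bound the patch-matrix at ~240 MB; transposed
convolutions are implemented as the exact adjoint gather/scatter of the
matching forward convolution, so deconv/conv gradients share one code
path; unfold/fold are pure index permutations (bijective, tested exactly);
softmax subtracts row maxima; batch-norm uses eps 1e-5 and momentum 0.1;
all gradients are verified against central differences in the test suite.
Landmark detection fails loudly ("no bolus detected") on flat or monotone
curves, and phase partitioning rejects any empty window by name.

# Known limitations

A structural caveat on per-phase R² as a phantom training target: the
delay-phase map depends *discontinuously* on the venous-end landmark — a
one-frame shift under the ±10% kinetic jitter moves the whole (very
low-variance) Del map — so a validation subject whose landmark falls
across that boundary can score a deeply negative Del R² at small absolute
error, dragging the phase-averaged R² down while the BerHu validation
loss is indistinguishable from well-scoring cohorts. Together with the
small optimizer-step budget (an epoch over a six-subject split is six
Adam steps at the fixed learning rate), this makes phase-averaged R² on
small phantom cohorts a noisy, seed-sensitive target; MAE and the
validation loss are the stabler summaries at this scale.

* No GPU path: full-size (224×224) training is impractical in this
  implementation; the reduced grid is the tested configuration.
* Batch normalization uses per-sample statistics; with large-memory
  hardware true mini-batch statistics could behave slightly differently.
* DICOM import requires a Python with pydicom/nibabel on the PATH; NIfTI
  is the native format.
* The semi-automatic procedure's published description leaves the
  per-phase statistic and landmark rules partly open; the defaults here
  are deterministic interpretations, selectable and documented above.
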