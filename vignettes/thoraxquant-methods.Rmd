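---
title: "Methods: radiation-free thoracic volume and spinal length from sparse chest MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiation-free thoracic volume and spinal length from sparse chest MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Adolescent idiopathic scoliosis (AIS) deforms the spine and trunk in three
dimensions during the adolescent growth spurt. Progression is usually
monitored with radiographs, which carry a radiation burden that matters in
children followed over years. Sparse axial T2-weighted chest MRI offers a
radiation-free alternative: stacks of 12–17 thin (4 mm) axial slices
separated by 20–25 mm gaps, with isotropic in-plane pixels of roughly
0.47–0.63 mm. From a 3-class segmentation of such a stack — background,
thoracic volume within the chest wall, and spine — two scalar deformity
markers can be measured: the **thoracic volume** (liters) and the **3D
spinal length** (cm).

`thoraxquant` implements that pipeline end to end: a volumetric
encoder–decoder segmentation network, the resampling and postprocessing
around it, the two physical measurements, spacing-aware validation metrics,
and paired study statistics. Because clinical MRI of this kind cannot be
redistributed, the package also ships a synthetic phantom generator that
reproduces the acquisition geometry with exact labels and analytic truth
values, so every stage is testable offline.

## The phantom model

A phantom is a stack of axial sample planes at slice centers $z_k$. Each
plane holds a thoracic ellipse with semi-axes $(a_k, b_k)$ (mm) containing a
circular spine cross-section of radius $r$ whose center follows a parametric
curve

$$c(z) = c_0 + \big(A_x \sin(2\pi z/\lambda + \varphi),\;
                    A_y \sin(2\pi z/\lambda + \varphi)\big),$$

a lateral/anteroposterior deviation emulating a scoliotic curve. Every
`vertebra_period`-th slice additionally renders a posterior spinous-process
bar: sparse stacks sample alternately vertebral bodies (with processes) and
disk levels (without), and that alternation shifts the per-slice center of
mass — a known failure mode of COM-based length measurement that the tests
exercise explicitly.

Intensities are piecewise constant per class (background 30, thorax 120,
spine 200, arbitrary units) plus additive Gaussian noise of standard
deviation `noise_sigma` (default 10), reproducible under the spec seed.
This deliberately omits bias fields, Rician noise, ribs, organs and T2
contrast physics: the phantom is a geometric and statistical stand-in that
makes the pipeline testable, not an MRI simulation. Passing tests therefore
demonstrate correct geometry handling, learnability and measurement
recovery — not clinical segmentation accuracy on real T2w data.

Two details matter downstream:

* **Gaps are not rendered.** Only the sample planes exist, exactly as in the
  acquisition, so the volume-integration rule is owned by the quantification
  module, not baked into the data.
* **Cohorts.** `make_cohort()` draws adult chests with semi-axes of roughly
  85–105 × 60–75 mm over 14–17 slices, and scales child chests by a factor
  in [0.6, 0.75] over 12–14 slices. This reproduces the study-like spread of
  thoracic volumes (children ≈ 2–4 L, adults ≈ 5–10 L and above). The
  analytic thoracic volume is $\sum_k \pi a_k b_k\,\Delta z_k$ and the
  analytic spinal length is the polyline length of $c(z_k)$ samples — both
  exact for the rendered geometry up to rasterization.

The default in-plane matrix is chosen per subject as the smallest multiple
of 32 whose field of view clears the chest by 10 mm at the drawn pixel
spacing; the acquisition matrix of the source data before resampling is not
public, so this is a package choice. The `tiny` preset keeps the same
physical anatomy on a 64×64 grid of 4 mm pixels for fast CPU training
tests; the study pixel-spacing range [0.46875, 0.625] mm is enforced only
for study-preset specs.

## Preprocessing

Volumes are min–max normalized to $[0,1]$ (a constant volume maps to zeros
with a warning — degenerate but harmless). Images are resampled to the
fixed model grid (240×240×16 by default) with separable cubic convolution
(Catmull–Rom, $a=-0.5$) and clamped back to $[0,1]$, because cubic
interpolation can overshoot; masks use nearest neighbour on every axis, so
no class code can be fabricated. Depth is resampled in both directions —
native stacks of 12–17 slices all map onto depth 16 and back — using the
same interpolation rules as in-plane; the alternative (padding) would make
the inverse mapping ill-defined for stacks deeper than the model grid.
Coordinates follow the pixel-center convention, indices are 0-based in
physical formulas, and all distances are mm.

Training augmentation rotates all axial slices of a volume by one angle
drawn uniformly from ±10° per volume per epoch (fresh angles each epoch,
under the run seed); the image is interpolated bicubically, the mask by
nearest neighbour, and out-of-field voxels become background.

## The network

A 3D U-Net-style encoder–decoder with `depth` (default 3) encoder blocks of
two 3×3×3 convolutions + ReLU followed by 2×2×2 max pooling, a
two-convolution bottleneck, and a mirrored decoder of kernel-2 stride-2
transpose convolutions with skip concatenations, ending in a 1×1×1
convolution to 3 channels and a voxelwise softmax. In-plane axes pool at
every block; the depth axis pools only while it remains even (16 → 8 → 4 →
2), since a 16-deep grid cannot pool isotropically three times otherwise.
Channels start at `base_channels` (default 16; tiny preset 8) and double
per level.

No deep-learning framework is assumed: convolutions are im2col gathers plus
dense BLAS multiplications, and every layer carries a hand-derived backward
pass, verified against central finite differences in the test suite. This
keeps the package dependency-free and deterministic — training under a
fixed seed is bit-reproducible on a given platform.

Loss, optimizer and schedule are not dictated by the measurement method, so
they are configuration with defaults chosen for class-imbalanced 3-class
segmentation: cross-entropy plus soft Dice, Adam at initial learning rate
$10^{-3}$ with global gradient-norm clipping at 5 and a single ×0.3 decay
step at 85 % of the epoch schedule (on cohorts this small a constant rate
oscillates late in training, while decaying earlier can freeze the spine
class before its learning takes off), gradient accumulation over batches
of 2. The spine occupies
roughly half a percent of the voxels, and an unweighted objective leaves
its softmax output saturated near zero, where both loss terms have
vanishing gradients; the cross-entropy term is therefore weighted by
inverse class frequency per volume (capped at 50), the standard remedy,
after which the spine class trains reliably. Hard labels take the argmax;
exact probability ties resolve to the lowest class code (deterministic and
background-favoring).

## Postprocessing

Predictions are resampled back to the native slice count with nearest
neighbour first, then smoothed — matching the stated processing order — by
a (5, 5, 5) median filter. A median across the integer codes {0, 1, 2}
could fabricate label 1 between background and spine, so the filter is
per-class binary majority voting merged with priority spine > thorax >
background; voxels claimed by no class become background. The window
applies in index space despite the extreme slice-direction anisotropy,
matching the stated operator size; border windows are clipped. One
consequence of the index-space window deserves a warning: the majority vote
needs the structure to fill more than half the 125-voxel window, so on
coarse grids where the spine cross-section is only a few pixels wide — the
64×64 tiny test preset at 4 mm pixels, for instance — the filter can erase
the spine outright. At acquisition resolution (0.47–0.63 mm pixels, spine
radius ≈ 25–30 px) the structure easily dominates its window and the filter
behaves as intended; smoothing is therefore a separate, optional step
rather than being fused into back-resampling. No hole
filling or largest-component selection is applied — those would hide
exactly the failure modes (isolated far-off false positives) the validation
metrics are supposed to expose.

## Quantification

**Thoracic volume.** $V=\sum_k \text{area}_k\,\Delta z_k$, where area is
the in-plane area of thorax-plus-spine voxels (the chest-wall volume
contains the spine; the exclusive 3-class coding carves it out of label 1)
and $\Delta z_k$ are center-to-center slab widths: interior slices take
half the distance between their neighbours, end slices the full distance to
their single neighbour, so a uniform stack of $n$ slices spaced $s$
integrates a height of $ns$. With 20–25 mm of anatomy unobserved between
slices, this rectangle rule is the least-assumption estimator; absolute
volumes from any other gap treatment would differ by a roughly constant
factor, which is why the rule is logged with every report. A single-slice
mask falls back to the slice thickness with a warning.

**Spinal length.** For each slice with at least one spine voxel, the center
of mass of the spine voxels (mean voxel-center position × pixel spacing) is
paired with the slice's physical z-position; the length is the summed 3D
Euclidean distance over consecutive spine-bearing slices, in cm. Spine-free
interior slices are skipped and the polyline connects across them, which
makes the measurement robust to single-slice prediction dropouts. Fewer
than two spine-bearing slices is an explicit undefined-length error, never
a silent zero.

## Validation metrics

* **DSC** $=2|P\cap G|/(|P|+|G|)$; both-empty scores 1 (a slice correctly
  predicted as all background is a success).
* **Hausdorff.** Boundaries are foreground voxels with a background face
  neighbour (array borders count as boundary); distances are Euclidean in
  physical coordinates, using the true per-slice z-positions. `hd` is the
  symmetric maximum of directed distances. `hd95` pools the directed
  point-distance multisets of both directions and takes the 95th percentile
  with linear interpolation — the most common convention, adopted because
  the variant used in the source tables is unstated, and logged as such.
  One-empty masks give an undefined-distance error (reported as missing,
  never 0 or infinity).
* **Precision/recall** at voxel level, with empty denominators reported as
  `NA`.
* **Thorax row convention.** Per-subject evaluation scores the thorax as
  labels {1, 2} against ground-truth {1, 2} (chest wall including spine);
  `thorax_labels = "exclusive"` switches to label 1 only.
* Confusion overlays (TN/TP/FP/FN) support qualitative review.

All metric implementations are checked against independent brute-force
all-pairs/count oracles on hundreds of random anisotropic fixtures, and the
Dice–F1 identity is asserted to 1e-12.

## Study statistics

`percent_difference()` is the signed $100\,(\text{model}-\text{manual})/
\text{manual}$; `cohens_dz()` is the paired effect size
$\bar d/\mathrm{sd}(d)$ with the sample standard deviation. The reference
per-participant validation tables ship with the package and every derivable
summary — means, ranges, percent differences, both effect sizes — is
recomputed from the cells rather than restated. Two printed cells of the
source tables are not consistent with their own rows (one percent-difference
entry and the volume-table mean percent difference); the package reports the
recomputed column statistics and treats the printed per-subject percentages
as the input of record for the column means. The 95 % CI of Cohen's dz is
deliberately not part of the standard output: the method behind the
published intervals is unstated, so only a clearly-labelled normal
approximation is available behind `ci = TRUE`.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use sizes chosen to make every
property measurable on a single CPU: metric oracles run on ≥ 200 random
masks of ≤ 10³ voxels; phantom parameter recovery uses noise-free
study-geometry phantoms at 0.47–0.5 mm pixels (up to 512² in-plane), where
the slab-rule volume recovers the analytic ellipse-stack integral within
3 % and the COM polyline recovers the analytic arc length within 5 %; and
the learnability check trains the tiny preset (64×64×16, base 8, depth 3,
~350 k parameters) on 12 phantoms for 32 epochs and evaluates 4 held-out
subjects. Soft-Dice smoothing uses $\varepsilon = 1$; softmax is computed
with per-voxel max subtraction; He initialization scales with fan-in; Adam
uses $\beta = (0.9, 0.999)$, $\varepsilon = 10^{-8}$.

## Known limitations

* The phantom's piecewise-constant intensity model makes the classes
  intensity-separable; real T2w contrast, bias fields and partial-volume
  effects are harder, so held-out phantom Dice values do not transfer to
  clinical data.
* COM-based length is sensitive to the vertebra/disk alternation of sparse
  stacks; the package measures and documents this shift rather than
  correcting it (anterior/posterior vertebral landmarks would be the next
  step).
* Anatomical boundary selection (sternum top, kidney top, T12) is upstream
  of this package; inputs are assumed pre-cropped.
* The volume integration rule across unobserved gaps is a documented
  choice; absolute volumes are comparable within this package, not across
  tools with different slab conventions.
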