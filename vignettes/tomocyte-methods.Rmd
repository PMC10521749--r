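---
title: "Label-free WBC profiling from RI tomograms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free WBC profiling from RI tomograms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomocyte)
```

## The measurement model

Optical diffraction tomography reconstructs the 3D refractive index (RI)
field $n(x, y, z)$ of a single cell. Because the nonaqueous content of a
cell (mostly protein) raises its RI linearly over the medium,

$$n = n_0 + \alpha C,$$

with $n_0$ the medium RI and $\alpha$ the refractive index increment
(0.2 mL/g here), an RI tomogram is simultaneously a morphological and a
biochemical measurement. `tomocyte` computes six parameters from a
segmented tomogram:

* **cellular volume** $V$ (fL): voxel count times voxel volume;
* **surface area** $S$ (µm²): area of the triangulated isosurface of the
  segmented component;
* **sphericity** $\pi^{1/3}(6V)^{2/3}/S$: 1 for a sphere, smaller
  otherwise (isoperimetric inequality);
* **protein density** (g/dL): mean of $C = (n - n_0)/\alpha$ over the
  mask, times 100;
* **dry mass** (pg): $\sum C \cdot v_\text{voxel}$, using
  1 g/mL = 1 pg/fL, identically equal to $\text{pd}/100 \times V$;
* **mean RI**: mean voxel RI over the mask, identically
  $n_0 + \alpha\,\text{pd}/100$.

The last two identities are *algebraic*, not statistical: they are
computed from the same mask and the same concentration field, and the
package treats any violation beyond floating-point error as a bug (the
test suite asserts them at $10^{-9}$ relative). For the same reason
negative per-voxel concentrations (noise below $n_0$) are kept, not
clipped; clipping would silently break both identities. A QC column
reports the fraction of negative-concentration voxels instead.

Segmentation thresholds the volume at RI 1.35 — above the ~1.33 culture
medium plus experimental noise — applies an optional radius-1 closing
(off by default; intended for noisy real data) and keeps the largest
26-connected component, so debris or noise specks cannot inflate the
features. An empty mask is an error, never a zero-feature record.

### Surface extraction

Counting exposed voxel faces overestimates the area of a curved surface
by tens of percent (a voxelized sphere has the surface area of its
bounding staircase), which would corrupt sphericity. `tomocyte`
therefore triangulates the isosurface by marching tetrahedra (each
lattice cell split into six tetrahedra sharing the main diagonal, with
linearly interpolated edge crossings). The field that is contoured is
the Gaussian-smoothed *indicator* of the segmented component, extracted
at its symmetric 0.5 level. Contouring the raw RI at 1.35 would place
the surface at whatever fraction of the medium-to-interior transition
1.35 happens to be — a bias of a fixed fraction of a voxel in the
surface normal direction — whereas the 0.5 level of the smoothed
indicator sits on the binarization boundary itself. The smoothing width
(`smoothSigma`) defaults to $0.8 \cdot (0.2\,\mu m / \text{pitch})^{1/3}$
voxels — 0.8 voxel at the reference 0.2 µm pitch, where the sphere area
error is about 0.2%. The two error sources pull in opposite directions:
too little smoothing leaves voxelization jaggedness (~10% area excess at
$\sigma = 0.5$ voxel), too much shrinks curved surfaces (bias
$\propto \sigma_{phys}^2/r$). The exponent makes the *physical* width
vanish while the *voxel* width grows as pitch decreases, so both terms
go to zero and the estimate is consistent; the reference width was fixed
once against the analytic sphere and spheroid oracles. The
sphere-convergence test (pitches 0.4/0.2/0.1 µm, error strictly
decreasing) guards this choice.

A mask touching the volume boundary triggers a warning and a one-voxel
pad before extraction. Note that sphericity mixes the voxel-count volume
with the mesh area; a mesh sphericity can exceed 1 by up to the
discretization allowance (0.02) on coarse grids.

## The synthetic phantom generator

The package is developed and validated against synthetic single-cell
phantoms with exact analytic ground truth, parameterized per class by
the published bone-marrow WBC statistics (B and T lymphocytes,
monocytes, myelocytes): mean ± SD of cellular volume, sphericity and
protein density. `defaultClassSpecs()` carries those numbers.

Each cell is an **oblate spheroid**. Volume is drawn from the class
Normal truncated at ±3 SD (and at zero); sphericity likewise (clipped
into (0, 1]); the flattening $k = a/c$ is then solved numerically so the
*closed-form* spheroid sphericity equals the drawn value — hence truth
values are exact, not fitted. Spheroids were chosen because the
published statistics constrain only volume/surface/sphericity, and
spheroids give closed-form $S$ and $V$; oblate rather than prolate
because, at equal sphericity, the oblate maximum extent is much smaller,
which keeps low-sphericity monocyte draws on practical grids. Draws that
still cannot fit the grid with a two-voxel margin, or whose polar
semi-axis falls under two voxels, raise a generation error naming the
offending draw rather than silently clipping the shape.

Composition: the interior concentration $C$ is drawn from the class
protein-density Normal; a concentric nuclear spheroid occupying
`nucleusVolumeFraction` (default 0.4) of the volume carries an RI
contrast `nucleusRiOffset` (default +0.004). The cytoplasm RI is lowered
by `fraction × offset` so the volume-weighted interior mean RI is
*exactly* $n_0 + \alpha C$ — without this compensation the nucleus would
bias measured protein density upward by ~0.8 g/dL and the generator
would contradict the package's own mean-RI identity. No nuclear
statistics are published for these data; the nucleus parameters are
plausibility defaults for making images nontrivial, not validated
biology, and they deliberately do not enter the ground-truth table.

Voxelization evaluates the analytic surface at voxel centres
($(i + 0.5) \cdot \text{pitch}$, 0-based): a voxel is interior iff its
centre is inside. A uniform random 3D rotation and a sub-voxel centre
jitter decorrelate the lattice from the shape. Additive Gaussian RI
noise (default SD 0.002) is applied last; the truth table stores the
analytic pre-voxelization, pre-noise values. Every cell consumes its own
splittable RNG substream indexed by its cohort position, so a given
`(spec, seed, index)` is bitwise reproducible independently of cohort
size.

The medium RI defaults to 1.337 (RPMI-like). The source data state only
"approximately 1.33"; 1.337 is the value that makes the published
protein-density and mean-RI columns mutually consistent
($(1.371 - 1.337)/0.2 \times 100 = 17.0 \approx 17.09$ g/dL for
myelocytes).

**What the phantoms do not emulate:** diffraction and missing-cone
reconstruction artifacts, surface ruffles and pseudopodia (the "more
irregular" myeloid morphology is representable only through the
sphericity distribution, plus an optional low-order perturbation that is
excluded from validation), intracellular texture beyond a two-compartment
nucleus, and real-data correlations between volume and protein density.
Consequently the published *dry-mass* and *surface-area* class means are
not generator targets — they are functions of the targeted quantities
and of those correlations — and passing the round-trip statistics says
nothing about classifier accuracy on clinical tomograms.

### Grids

The default common grid is 112³ voxels at 0.2 µm isotropic pitch, the
smallest multiple-of-8 cube holding the worst-case truncated draw (a
+3 SD-volume monocyte flattened to −3 SD sphericity) under arbitrary
rotation. `defaultClassSpecs(gridShape = "fit")` instead sizes each
class's grid individually (B/T 80³, My 96³, Mono 112³ at 0.2 µm), which
roughly halves the cost of single-class morphometry cohorts;
classifier cohorts must use the common grid (mixed shapes in one cohort
are a validation error). Desk-scale classifier experiments in the tests
use 64³ and 32³ grids with proportionally scaled cells.

## The classifier

The 3D network follows a downsample–upsample–downsample topology with a
classifier head: two DS stages (batch norm → leaky rectifier → 3³
convolution → 2³ max pool), an US block (nearest-neighbour ×2 upsampling,
concatenation of the first DS stage's features, an entry convolution and
residual refinement blocks), a second DS block (same op family, plus an
additive skip from the first block at matching resolution), and a head
(batch norm → leaky rectifier → 1×1×1 convolution to class logits →
global adaptive average pooling). The residual wiring — skips from each
first-block stage into the US refinement and into the second DS block at
matching resolution — is one consistent reading of "residual blocks that
connect all three blocks"; the op families and block order are fixed,
while channel widths (base 16, doubling twice; tests use 2), kernel
sizes and the number of residual blocks are configuration. All layers
and their gradients are implemented in this package (C++ kernels for
convolution/pooling/upsampling, R for normalization and bookkeeping);
the backward pass is verified against central finite differences in the
test suite.

Training uses ADAM (β₁ = 0.9, β₂ = 0.999) with cross-entropy loss,
learning rate 0.004 and multiplicative decay 0.9999 **per optimizer
step** — applied per epoch the stated decay would be indistinguishable
from none at realistic epoch counts. "Momentum 0.9" is read as ADAM's
β₁, since ADAM has no classical momentum term. He initialization, seeded
shuffling and seeded augmentation make runs bit-reproducible; there are
no nondeterministic kernels. Batch-norm running moments are stored as
debiased exponential averages (momentum 0.1 with an Adam-style
bias-correction), so evaluation behaves sensibly even after very short
desk-scale runs; inference always uses the stored moments, which is what
makes prediction batch-invariant (asserted at 10⁻⁵) and softmax rows sum
to 1 (10⁻⁶).

Model selection over epochs maximizes validation accuracy by default.
Monitoring "validation accuracy based on MSE" under cross-entropy
training is ambiguous, so the softmax-vs-one-hot MSE criterion is also
implemented (`selection = "mse"`); no claim is made about which the
original authors used. Augmentation (random translation ≤10% of extent,
crop-and-pad, optional elastic warp, Gaussian RI noise 0.002) is
label-preserving by construction; magnitudes are configuration because
none are published.

The 2D baseline reuses the identical training loop with singleton-z
volumes, which turns every kernel, pool and upsampling into its 2D
analogue. Its inputs are maximum intensity projections, or synthetic
phase (projection approximation,
$\varphi = (2\pi/\lambda)\sum_z (n - n_0)\,\Delta z$, default
λ = 0.532 µm) and an exponential-attenuation amplitude proxy. The
original 2D phase/amplitude images were interferometric measurements;
these proxies exist so the input-modality comparison is reproducible
synthetically, and their absolute accuracies are explicitly not
comparable to published ones.

### Classical baselines

The five classical models consume the six-feature table only:
one-vs-one linear SVMs (six binary learners for four classes) combined
by error-correcting-output-code voting, k-nearest neighbours (k = 5,
Euclidean), linear discriminant, Gaussian naive Bayes, and a Gini
decision tree. Features are z-scored with train-split statistics only —
unstated in the source but necessary, as the raw features span five
orders of magnitude — and the no-leakage property is asserted by
perturbing test rows and requiring identical fits. KNN votes break ties
by smallest mean distance, then class order, making predictions
deterministic; the SVM kernel is linear by default (RBF available)
since no kernel is published. The binary lymphoid/myeloid task is a
label mapping ({B,T} → lymphoid, {Mono,My} → myeloid) over the same
pipeline.

The cohort used for the ordering property (3D ≥ 2D MIP ≥ best ML − 2 pp,
means over three seeds) is constructed so that each input modality has a
distinct ceiling. One class pair shares every six-feature distribution
and differs only in nuclear volume fraction (mean-RI preserved), so the
feature table cannot separate it while any image can. The second pair
shares the volume distribution; one class carries a *dark* nucleus whose
cytoplasm RI is equalized to the other's at the class mean, so a maximum
projection along z occludes the nucleus completely — every projection
column through it terminates on brighter cytoplasm — while the 3D volume
shows the dark core outright and the feature table sees only a ~2.6 SD
protein-density gap. This is a designed synthetic condition exercising
genuinely three-dimensional information, not a claim about clinical
data.

## Learned-feature embedding

Features are tapped at the last layer of the second downsampling block,
immediately before the head, and globally average-pooled (the same
pooling family as the head), giving one vector of 4 × `baseChannels`
per cell. The 2D visualization is UMAP, implemented in this package:
exact k-nearest neighbours (cohort-scale inputs make exact search
cheap), per-point bandwidth calibration to log₂(k), fuzzy union,
kernel parameters (a, b) fitted from `minDist`, PCA initialization and
a seeded per-edge stochastic layout with negative sampling. Defaults
n_neighbors = 15, min_dist = 0.1, Euclidean; hyperparameters are
library-standard since none are published. Fixed seeds give identical
coordinates. The quantitative stand-in for "clearly clustered" is a
mean silhouette > 0.5 of the 2D coordinates against the true labels for
a model trained to ≥95% accuracy on the separable cohort; cluster
*counts* are deliberately not asserted.

## Problem sizes and numerical choices at a glance

* Round-trip class statistics: 500 phantoms per class, noise-free,
  0.2 µm pitch, fitted per-class grids; sample means compared at 3 SEM
  (sphericity with a 2% mesh allowance; mean RI with a half-print-step
  allowance of 5×10⁻⁴, since the published value carries three
  decimals).
* Separable classifier cohort: 100 cells/class at 64³, base width 2,
  early stop at validation accuracy 1. Ordering cohort: 60 cells/class at
  32³ (0.6/0.2/0.2 split for less noisy selection and evaluation), three
  seeds, 24 epochs for the 3D model and 48 for the far cheaper 2D one.
  The 2D baseline runs at double width (its 3×3 kernels carry a third
  of the taps of a 3³ kernel, which roughly matches parameter counts)
  and gets 40 of its far cheaper epochs. Desk-scale runs halve the
  learning rate to 0.002 and select on the softmax MSE: at batch size 8
  on a few hundred cells the full 0.004 recipe oscillates between
  epochs, and the MSE criterion is a smoother selection signal than
  accuracy over a small validation split.
* Truncation at ±3 SD everywhere a class Normal is sampled; rejection
  sampling with a hard failure after 1000 draws.
* Ties: KNN as above; ECOC votes and argmax predictions break ties by
  class order; max-pool argmax takes the first maximum in z-fastest
  order.
* Degenerate inputs: empty masks, sub-resolution draws, non-RI-like
  volumes (min < 1), missing pitch metadata and mixed projection kinds
  are errors with named causes, never silent defaults.

## Known limitations

* Tomogram I/O is multi-page 32-bit float TIFF with a JSON sidecar; no
  HDF5 binding is linked in this build, so `format = "hdf5"` raises an
  informative error.
* The phantom family is smooth and convex; measured surface areas of
  real, ruffled WBCs would be systematically larger than spheroid truth,
  which is why absolute surface-area comparisons are out of scope.
* The conv net is CPU-oriented and desk-scale; paper-scale
  150×150×100 inputs are supported by configuration (center-crop/pad
  with medium fill for mismatched shapes) but training at that scale on
  one CPU is slow, and clinical accuracies are not reproducible from
  synthetic cohorts by construction.
* The UMAP layout is a compact reimplementation tuned for hundreds to a
  few thousand points; for much larger cohorts an approximate-neighbour
  implementation would be preferable.
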