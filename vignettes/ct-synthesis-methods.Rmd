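---
title: "Diffeomorphic planning-CT synthesis: models, losses, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffeomorphic planning-CT synthesis: models, losses, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Radiotherapy planning for lung cancer starts from a dedicated planning CT
(pCT) acquired on a flat couch, often under breath hold, days after the
diagnostic PET/CT whose CT component (dCT) already shows the tumor. The two
scans differ systematically: couch shape, body contour, and above all the
diaphragm level under the breath-hold protocol. `dvfsynth` synthesizes a
planning-like CT (sCT) from the diagnostic CT by *deforming* it: a conditional
adversarial network predicts a dense deformation vector field (DVF), the field
is made diffeomorphic, and the original scan is resampled through it. Because
every synthesized voxel is a trilinear interpolation of measured Hounsfield
values, the intensity calibration that dose calculation depends on is never
fabricated — the network moves anatomy, it does not paint it.

## Model

### Velocity fields and the diffeomorphic warp

The generator is a 3D U-Net that maps a normalized single-channel patch of the
dCT to a three-channel stationary velocity field $v$ (mm). The displacement
applied to the image is the group exponential $u = \exp(v) - \mathrm{id}$,
computed by scaling and squaring: $u_0 = v / 2^N$, then $N$ self-compositions

$$u_{k+1}(p) = u_k(p) + u_k(p + u_k(p)),$$

with trilinear interpolation and $N = 7$ by default. For fields whose scaled
step $v/2^N$ is well resolved by the grid this construction is a
diffeomorphism: the Jacobian determinant of $p \mapsto p + u(p)$ stays
positive, so anatomy cannot fold or tear. Folding is monitored explicitly:
`jacobian_determinant()` evaluates $\det(I + \nabla u)$ with central
differences (one-sided at borders, in mm/mm), and `folding_fraction()` reports
the fraction of interior voxels at or below zero. The test suite and the
acceptance script confirm a folding fraction of exactly 0 for every field the
pipeline produces, for randomly initialized as well as trained generators.

The DVF uses the pull-back (resampling) convention — the warped image at $p$
samples the source at $p + u(p)$ — because it composes directly with
interpolation; displacements are stored in mm on physical axes. Out-of-domain
samples replicate the nearest edge value rather than injecting −1000 HU air.

### Objective

The generator minimizes

$$\mathcal{L} = \mathcal{L}_{adv} + \lambda_1\, \mathcal{L}_{L1}
  + \lambda_2\, \mathcal{L}_{cf} + \lambda_3\, \mathcal{L}_{curv}.$$

* **Image similarity** $\mathcal{L}_{L1}$: mean absolute difference between
  the warped source and the target. The warped image is produced *inside* the
  loss path (velocity → integration → warp), so the similarity term trains the
  deformation, not a CT painter. The "input/output" of the L1 is read as
  (warped source, registration target): comparing the warped image against the
  unwarped input would make the identity deformation optimal.
* **Contrast fidelity** $\mathcal{L}_{cf}$: the same L1 after both images pass
  the *soft contrast window* $I_{out} = c\,/\,(1 + e^{-(I_{in}-a)/b})$ with
  defaults $a = 500$, $b = 500$, $c = 3000$. This differentiable window/level
  mapping makes the optimizer see the image the way a physician reading a lung
  window does: differences near the window center are weighted at slope
  $c/(4b)$, differences deep in the tails are compressed. The printed
  parameter values are kept verbatim and applied on the stored intensity
  scale; they are fully configurable per anatomical site.
* **Curvature smoothness** $\mathcal{L}_{curv}$: mean over interior voxels of
  $\sum_j \|\Delta v_j\|^2$ with the spacing-aware 6-neighbor Laplacian.
  Affine fields — including rigid motions — incur zero penalty.
* **Adversarial term**: binary cross-entropy of a conditional patch
  discriminator that scores (source, target) pairs as real and (source,
  warped) pairs as fake, the standard conditional pairing of image-to-image
  adversarial translation.

The weights $\lambda_1 = \lambda_2 = 100$, $\lambda_3 = 1$ follow the common
practice of letting reconstruction terms dominate the adversarial one; they
are exposed in `train_config()` and nothing in the package's validation
depends on their exact values.

### Networks, from scratch

No deep-learning framework is used: the 3D convolutions, per-channel
normalization, pooling/upsampling, skip connections, and the Adam optimizer
are implemented in this package (compiled kernels for the convolutions,
explicit backward passes everywhere). Backpropagation is verified against
central-difference numerical gradients in the test suite. The encoder applies
conv–norm–leaky-ReLU then average pooling per level; the decoder mirrors it
with nearest-neighbor upsampling and skip concatenation; a final 1×1×1
projection emits the velocity components, scaled by `vel_scale` (20 mm by
default). The last layer is initialized near zero so an untrained generator
predicts a near-identity deformation — standard for registration networks and
the reason untrained models are already folding-free.

One deliberate approximation keeps training tractable: the derivative of the
scaling-and-squaring exponential with respect to the velocity is taken as the
identity, which is its first-order Taylor term and accurate for the
moderate-amplitude fields involved; the warp itself is differentiated exactly
through the trilinear interpolation gradient, and the smoothness gradient
(the biharmonic adjoint) is exact. The parameter-recovery results below are
obtained under this approximation.

## The synthetic phantom: what it emulates and what it does not

No public paired dCT/pCT dataset exists for this task, so the package ships a
first-class phantom generator. Each case is an elliptical thorax with a spine
cylinder, two lungs bounded below by a diaphragm dome, a spherical GTV
(default 9.05 mm radius ≈ 3.1 cc, jittered ±10% across a cohort), soft
tissue/lung/bone/air at their nominal HU values, and Gaussian noise (20 HU).
The diagnostic state has a curved couch and the exhale diaphragm; the planning
state has a flat couch, the dome displaced by `diaphragm_shift` (default
15 mm, jittered 10–20 mm; breath-hold inflation, so the planning lungs are
larger), and the body contour scaled radially by `body_scale` (default 3%).
The inter-scan diaphragm excursion is a module parameter, not a literature
claim.

The two states are linked by an analytic ground-truth deformation: a z-directed
Gaussian bump at the dome apex plus a radial contour scaling about the spine
axis, both windowed to zero at the volume border and at the spine (the spine
is rigid across acquisitions). The planning volume is *defined* as the
diagnostic anatomy evaluated at the deformed coordinates, so
`warp(dct, true_dvf)` reproduces `pct` up to interpolation error and noise —
a property the tests assert (RASSD below twice the noise SD on the body).
Tissue interfaces are blurred over ~6 mm (4 mm at the skin and tumor) to
emulate partial-volume softening; this also keeps the analytic ground truth
consistent with interpolated warps. The couch is excluded from the deformation,
as in the clinic, and noise is drawn independently for the two states so the
pair is never related by an exact intensity identity.

What the phantom does **not** model: airway and vessel trees, cardiac motion,
4D respiratory phases, PET activity, metal artifacts, or truly different scan
lengths. Passing tests on the phantom therefore demonstrate that the
machinery — losses, integration, warping, metrics, training dynamics — behaves
as specified, not that clinical-grade synthesis accuracy is achieved on real
patients.

## Evaluation

`rassd()` is the RMS intensity discrepancy; `dsc()` the Dice overlap
$2|X \cap Y| / (|X| + |Y|)$ (two empty masks score 1, one empty scores 0);
`hausdorff()` the exact symmetric max–min Euclidean distance between surface
voxel sets (foreground voxels with a background 6-neighbor), spacing-aware in
mm — the exact maximum, not a percentile variant. Because the two scans can
cover different superior–inferior extents, `evaluate_case()` restricts the
body comparison to the overlapping z-slice interval of the two body masks;
body RASSD uses the whole overlapping volume and other structures use their
union mask, a choice the package makes explicit since averaging regions are
often left unstated. All three metrics are validated against independent
brute-force oracles.

## Preprocessing

Couch removal is realized as: threshold at −300 HU, keep the largest
6-connected 3D component, morphological closing (ball radius 2 voxels), and
per-axial-slice hole filling so lungs remain inside the body mask; voxels
outside the mask are set to −1000 HU. `add_couch()` re-inserts an analytic
couch model for downstream dose work (dose calculation itself is out of
scope). Resampling to a common 2.5 mm grid preserves the physical extent
within one voxel — when the extent is not an exact multiple of the target
spacing, the sample count is rounded rather than the extent truncated. Network
inputs are normalized from [−1000, 1000] HU to [−1, 1]; the window spans lung
to bone without saturating soft tissue.

## Problem sizes and numerical choices

The full-fidelity configuration (128-voxel patches, 7 levels, 16 base
channels) matches the published architecture but is not what the tests run:
the package's *desk profile* (`desk_train_config()`) uses 48-voxel patches,
5 levels, 3 base channels, a 3-stage half-resolution discriminator, and 30
epochs over 8 jittered 64-voxel phantom pairs, which completes a training run
in about two minutes on one CPU core. The parameter-recovery experiment in
the test suite repeats that training for five seeds and requires held-out
lung Dice to improve and held-out body-masked L1 to fall versus the unwarped
baseline in at least four of them; in development runs all five seeds improved
(Dice ≈ 0.90 → 0.95–0.97, masked L1 ≈ 80 → 40 HU).

Other numerical choices: one discriminator and one generator update per batch
of one patch; Adam (learning rate 10⁻³ for both networks); trilinear
interpolation everywhere except nearest-neighbor warping where requested;
mask warping interpolates the 0/1 indicator linearly and thresholds at 0.5
for sub-voxel boundary accuracy; full-volume inference runs the fully
convolutional generator directly when the volume fits one patch (padding by
edge replication to the required divisibility), otherwise overlapping patches
with 50% stride are blended with a Hann window before one global integration.
Patch sides must be divisible by $2^{levels-1}$ and keep at least two voxels
at the coarsest level. Folding statistics exclude the one-voxel border where
one-sided differences are less trustworthy. Both-empty Dice is defined as
perfect agreement. All randomness in a run flows from a single seed, and the
tests assert bit-identical phantoms, training histories, and reports across
repeated runs.

## Known limitations

* The identity approximation of the exponential's derivative biases gradients
  for large velocities; fields here stay in the 10–20 mm range where it is
  benign.
* The phantom's two deformation modes (diaphragm, contour) are far simpler
  than real inter-scan anatomy; results on it bound the machinery, not
  clinical accuracy.
* The discriminator contributes little at the default weighting; the package
  keeps it because the architecture is conditional-adversarial by design, but
  reconstruction terms do the heavy lifting at desk scale.
* Hausdorff distances are exact maxima and thus sensitive to single-voxel
  outliers, as the definition demands.
* DICOM-RT structure sets, PET channels, 4D-CT, registration to externally
  acquired ground truth, and dose/DVH analysis are out of scope; externally
  produced alignments can be supplied as NIfTI displacement fields.
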