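---
title: "Building developmental growth maps by deformable registration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building developmental growth maps by deformable registration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

During prenatal joint morphogenesis the cartilaginous rudiments of the knee
acquire their adult shapes. Given 3D grayscale volumes of the same anatomical
site (proximal tibia or distal femur epiphysis) imaged in different specimens
at two consecutive developmental stages — Theiler stage 23 (~E14.5) and 24
(~E15.5) of the mouse, at an isotropic voxel size of 14.63 µm — we want a
spatial map of how much and where the rudiment grew between the stages.
Because the same embryo cannot be imaged twice (specimens are fixed and
stained), every early-stage specimen must be registered to every late-stage
specimen, and the resulting displacement fields averaged into a mean
"developmental map". `devomap` implements this protocol end to end, together
with the comparison metrics (Modified Hausdorff Distance, Average
Displacement Difference) and precision/repeatability analyses used to judge
it, and a synthetic phantom generator that provides ground-truth growth
fields for validation.

## Data model and conventions

* Volumes are 3D arrays with `dim = c(nx, ny, nz)` read as (x, y, z), with
  0-based voxel indices in all documentation and serialized output. Voxel
  `(i, j, k)` is centred at `origin_um + c(i, j, k) * voxel_size_um`; all
  lengths are micrometres; voxels are isotropic (anisotropic metadata is
  rejected at load time).
* Bounding boxes are half-open (`lo` inclusive, `hi` exclusive).
* A `registration_grid` has nodal spacing `NS` voxels. When `NS` does not
  divide `dim − 1`, the node extent exceeds the image; the overhang is split
  equally between the two faces of each axis. This symmetric placement
  matters: with a one-sided overhang the smoothness term is asymmetric at
  the two faces and we measured a systematic field bias of about half a
  voxel at `NS = 4` on a 48³ image. At `NS = 1` the padding is zero and
  nodes coincide with voxel centres.
* Displacement fields are stored at early-stage node positions, pointing
  from the early to the late configuration (the convention needed to morph
  the early-stage control mesh).

## Preprocessing

Segmentation is a single intensity threshold followed by retention of the
largest connected component — a deterministic surrogate for the interactive
clean-up of the original protocol. The threshold level is a required
parameter (it is specimen- and staining-dependent and no universal value
exists). Masks are eroded by one voxel with a 6-connected structuring
element (the most conservative reading of "a 3D erosion of 1 voxel";
26-connected is available via `connectivity = 26`). Resampling uses a
separable Lanczos kernel with window `a = 3`, normalised so constants are
reproduced exactly in the interior; samples beyond the source extent fade to
the background value 0 and interpolation undershoot is clamped at 0.

## Rigid pre-alignment

Each moving specimen is aligned by translating its mask centroid onto the
fixed specimen's mask centroid. The original protocol follows this with a
manual orientation adjustment; `refine_orientation()` replaces it with a
deterministic coordinate-descent search over three Euler angles and three
translations maximising normalised mutual information (32-bin joint
histogram over the fixed foreground, Studholme normalisation). The search
uses a fixed parameter order, halving step sizes, bounds of ±30° and ±20
voxels, so results are exactly reproducible. Two caveats found during
development and encoded in the defaults:

* For *same-stage* pairs (repeated scans, rotated copies) the NMI search is
  reliable: self-registration stays at identity and a 10° rotation is
  recovered within 1°.
* For *early-vs-late* pairs there is no well-defined rigid "truth" (the
  shapes genuinely differ) and the NMI landscape can have optima several
  voxels from the centroid alignment. The pipeline therefore defaults to
  centre-of-mass alignment only (`refine_orientation = FALSE`); the
  repeatability driver perturbs the initial orientation directly, which is
  the operator-variability model of the protocol.

## The deformable engine

The solver estimates node displacements `u` and a per-node intensity offset
`c` minimising the intensity-matching residual

```
r(x) = late(x) − early(x + u(x)) − c(x)
```

with `u` and `c` interpolated trilinearly between grid nodes. Each iteration
linearises `r` in per-node updates `(δu, δc)`, assembles the Gauss–Newton
normal equations (assembled directly in C++ over the 27-node stencil), adds
a smoothness penalty, and solves the sparse system with a supernodal
Cholesky factorisation. Key numerical choices:

* **Intensity normalisation.** Both images are scaled to a common unit
  dynamic range, so all weights below are contrast-independent.
* **Smoothness.** The penalty is `α L` with `L` the 6-neighbour graph
  Laplacian on the node lattice and `α = lambda_s × mean(diag(data Gram)) /
  500`. Tying `α` to the data term's mean diagonal makes `lambda_s`
  dimensionless across images, spacings and levels; the default
  `lambda_s = 50` sits in a broad plateau (5–500 give similar phantom
  recovery, with roughness decreasing monotonically in `lambda_s`).
  Constant fields are unpenalised (row sums of `L` are zero), so rigid
  translations are never shrunk.
* **Intensity offset.** The offset block receives a much stronger penalty
  (`offset_penalty_factor = 50000` in the same units, *not* scaled by
  `lambda_s`). The offset exists to absorb slow stain/exposure differences
  between stages; with a weak penalty it can explain edge residuals that
  are really motion — in phantom experiments a weak offset penalty doubled
  the field error while "improving" the residual.
* **Step control.** Plain Gauss–Newton overshoots when the residual is
  large. Updates are capped so the largest node motion per iteration is one
  nodal spacing (trust region), then a backtracking line search on the
  penalised SSD accepts the first step in `1, 1/2, …, 1/64` that decreases
  the objective; if none does, the level has converged.
* **Coarse-to-fine.** Spacings halve from the largest power of two ≤
  min(dim)/4 ("a few times smaller than the image size") down to the
  requested `NS`. Each spacing runs two passes on Gaussian pre-smoothed
  images (σ = NS and NS/2 voxels) and the finest spacing a final pass at
  σ = 1; fields transfer between levels by trilinear interpolation (exact
  for the continuous field). The final pass is deliberately not run on the
  raw images: warping interpolates — and thereby smooths — the moving
  image, so on noisy data *any* off-lattice displacement lowers the raw
  SSD. This interpolation artifact dragged repeated-scan precision to
  ~0.4 voxel; a light common blur equalises the smoothing of the two
  images and removes the reward, restoring precision to ~0.1 voxel with no
  measurable accuracy cost on ground-truth phantoms.
* **Registration domain.** The data term can be restricted to a voxel
  domain (`domain_mask`), by default in the pipeline the union of the two
  stage masks dilated by 3 voxels — the counterpart of the protocol
  feeding the late-stage binary image into the solver. Background voxels
  contain only noise; without the restriction they measurably perturb the
  field near the object.
* **Iteration budget.** Each pass stops at a 0.01-voxel maximum node
  update, at an objective plateau (relative improvement below 1e-4 twice
  in a row), or at the iteration cap. `register_deformable()` defaults to
  50 iterations per pass; the cohort pipeline caps at 6, because on
  phantom cohorts the recovered field is identical (to well below the
  tolerance) from iteration ~6 on — the long tail only chases
  inter-specimen texture — while tripling the runtime.
* **Quality.** NMI of the warped pair is tracked per level and the
  best-NMI state is kept, so the reported quality never decreases within a
  level; the final quality is computed on the unsmoothed images.
* **Output convention.** The solver's natural unknown is the pull-back
  field (`late(x) = early(x + u_pb(x))`). The stored field is the forward
  early→late displacement at early node positions, obtained by fixed-point
  inversion of `u_pb`. For growth-scale deformations (10 voxels) the
  distinction matters: the two fields differ by `|∇u|·|u|`, several voxels
  at the condyles.
* **Degenerate inputs.** Constant images (no gradient information) and
  mismatched lattices raise errors; a singular normal system is reported as
  missing gradient information. A tiny ridge (`1e-8` of the diagonal
  maximum) keeps the factorisation stable when the offset block is locally
  unobserved.

Convergence is declared when the largest node update falls below 0.01 voxel
(or after `max_iter = 50` iterations per level, flagged in `converged`).

## Maps, meshes, metrics

All specimens of a site share one lattice after rigid resampling, so
pairwise fields share their grid node-for-node. Grid cells whose 8 nodes all
fall outside the early-stage mask are dropped; averaging combines validity
by *intersection* (every reported node is supported by all K registrations;
`validity = "union"` is available). The developmental map averages the
`(early − control) × late` fields, the single map the `control × late`
fields, both expressed on the control specimen's filtered grid.

Valid cells convert to an 8-node hexahedral mesh (VTK corner ordering,
shared nodes merged); maps are applied as pure kinematic nodal
displacements — no mechanics. Surface nodes are the nodes of faces
referenced by exactly one element. Shape agreement uses the Modified
Hausdorff Distance — the symmetrised *mean* of nearest-neighbour distances,
`max(mean_a min_b ‖a−b‖, mean_b min_a ‖b−a‖)` — which discards the
outlier sensitivity of the classic Hausdorff maximum, on the surface-node
sets of the deformed control mesh. The Average Displacement Difference is
the per-axis mean of *absolute* component differences over common valid
nodes; a signed mean could cancel to zero for visibly different maps, which
would defeat its use as a repeatability error. All spreads are population
(÷n) standard deviations. Nearest neighbours use an in-package k-d tree,
verified in the test suite against an all-pairs oracle.

## The phantom

The phantom stands in for the OPT data: an implicit-surface body (base
ellipsoid united with two condylar lobes at ±x — medial and lateral — minus
a Gaussian intercondylar notch above the midline), mapped through a sigmoid
to a soft-edged intensity profile spanning 0–200, modulated by a smooth
seeded internal texture (amplitude 15%, correlation length 4 voxels —
stained cartilage is not homogeneous, and a perfectly flat interior would
make interior and tangential displacements unobservable to any
intensity-based method), Gaussian-blurred (σ = 1 voxel) and corrupted with
additive Gaussian noise (default SD 10 ≈ 5% of the dynamic range, the level
used in the precision study). The texture belongs to the specimen: repeated
scans (`scan_seed`) share it and growth carries it along, while different
specimens have independent textures — which is exactly why cross-specimen
registrations are harder than same-specimen ones, as in the real protocol.
Per-specimen shape variability is a seeded low-order perturbation
(log-normal scaling of the semi-axes and lobe radius, SD 3%, and jitter of
the lobe centres), which keeps the foreground volume within ±10% across
specimens.

The ground-truth growth field is radial about the body centre; its magnitude
ramps linearly from 0 at the centre to the surface and is modulated by an
angular weight peaking on the condylar directions: amplitude `g_c` at the
condyle apices decaying to `g_n` at the notch. Defaults `g_c = 150`,
`g_n = 60` µm reproduce the displacement magnitudes reported for the
proximal tibia (a 160/80 choice gives the femur preset). Two construction
details matter:

* **COM preservation.** The protocol aligns early to late specimens by
  centre of mass *before* registration, so any net COM motion in the true
  field would be subtracted by the pipeline and alias into every map. The
  field is therefore built so the rudiment's mask centre of mass is
  unchanged by growth (an iterative constant-offset correction), then
  rescaled so its peak magnitude over the rudiment is exactly `g_c`.
* **Exact late stages.** Because the field is radial with a piecewise-linear
  ramp plus a constant offset, its inverse is available in closed form; the
  late image is the early image Lanczos-sampled at the exact pull-back
  coordinates. (A generic fixed-point inversion diverges wherever
  `‖∇u‖ > 1`, which this field reaches near the condyles — with it the
  synthetic "truth" would not match the generated images.)

The growth mapping is verified non-folding (positive Jacobian determinant on
the lattice) in the test suite.

What the phantom does *not* emulate: OPT physics (scattering, reconstruction
artefacts), staining variability, anisotropic noise, the diaphysis and its
ossification front, or realistic anatomical shape detail. A green phantom
test therefore establishes that the numerical machinery recovers known
fields under realistic noise, cohort sizes and displacement magnitudes — not
that the protocol is accurate on real OPT data.

## Choices made where the design was open

* Threshold level: exposed as a required parameter (specimen-dependent, no
  value is published).
* Erosion element: 6-connected by default (minimal erosion), 26 optional.
* Averaging across specimens: intersection of valid cells (union optional);
  the alternative was never specified in the source protocol.
* Random control pick: seeded and recorded in the manifest; an explicit
  control id is accepted for reproducibility.
* Configs are JSON (the environment provides no YAML parser); every
  protocol parameter has an explicit key with its reference value as
  default (voxel size 14.63 µm, NS = 1, erosion 1, Lanczos a = 3,
  `lambda_s = 50`).
* The similarity question — the source protocol names mutual information as
  "the comparison metric" while its solver family is a linearised
  intensity-matching scheme — is resolved as: linearised SSD with intensity
  offset as the solver objective, NMI reported as the quality metric and
  used for the per-level keep-best safeguard.

## Limitations

* No diffeomorphic guarantee or inverse consistency; non-folding is only
  verified for the phantom's analytic field.
* `NS = 1` on large volumes is expensive in this implementation (the sparse
  normal system has 4 unknowns per voxel); the validation studies run at
  `NS = 4`, where the trilinear representation error of smooth growth
  fields is below 0.3 voxel.
* The interior of a textureless rudiment is determined by the smoothness
  term, not by data; fields whose interior deviates from the harmonic
  extension of their boundary values are not recoverable there.
* Orientation refinement by NMI is unreliable across stages (see above);
  between-operator variability is modelled by explicit initial-orientation
  perturbations instead.
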