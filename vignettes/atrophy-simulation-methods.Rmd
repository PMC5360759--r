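---
title: "Simulating longitudinal brain MRI with prescribed volume changes: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating longitudinal brain MRI with prescribed volume changes: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atrophysim)
```

## Why simulate atrophy

Brain morphometry pipelines estimate tissue volume change from longitudinal
MRI, but on real scans the true change is unknown, so their bias and
variance cannot be measured directly.  This package generates synthetic
longitudinal images in which the voxel-wise volume change is prescribed
exactly — ground truth for evaluating, training and stress-testing such
pipelines — while intensity characteristics (noise, smooth inhomogeneity)
can be made to vary realistically between time points by resampling
intensities from alternate scans rather than by modelling noise explicitly.

## The deformation model

Inputs are a baseline scalar image, a three-regime segmentation, and an
atrophy map `a` giving the fractional volume loss per voxel and per time
step, `a = (V0 - V1)/V0` (positive = shrinkage, negative = growth).  The
segmentation's regimes are:

* **label 0** — skull and background: zero displacement (Dirichlet),
* **label 1** — CSF: volume change free, to compensate globally,
* **label 2** — parenchyma: divergence prescribed by `a`.

A single step solves, for displacement `u` and an auxiliary pressure `p`,

* label 1: `mu Lap(u) - grad p = 0` and `div u + k p = 0`,
* label 2: `mu Lap(u) - grad p = (mu + lam) grad a` and `div u = -a`,

so incompressibility is relaxed where `k > 0` and exact where the atrophy
is prescribed.  The model is a creep flow: each step's strain is fully
relaxed before the next step begins, so steps chain by composition rather
than by accumulating stress.  Because volume removed in label 2 must appear
somewhere, a segmentation that prescribes nonzero atrophy without any
label-1 voxel is rejected up front.

Parameters (`model_params()`): `mu` (kPa), `lam` (kPa), `k` (1/kPa);
defaults `mu = 1, lam = 0, k = 1`.  Displacements are invariant under
`(mu, lam, k) -> (c mu, c lam, k/c)`; only pressure rescales, so the
defaults fix a gauge more than a physics.  The per-step `a` must be small
enough that `div u = -a ~ J - 1` holds to first order (the package checks
`max |(J-1)+a|` stays below `2 max(a)^2` in its tests with `max(a) = 0.02`);
large total atrophy should be reached through several small steps.

## Discretization

The system is discretized on a staggered (MAC) grid: displacement
components live on cell faces, pressure and atrophy at cell centres.  This
placement makes the discrete divergence the exact negative adjoint of the
discrete pressure gradient and avoids checkerboard pressure modes.  The
momentum operator is the standard 7-point second difference per face
lattice, with spacing-aware coefficients; a face is eliminated at zero when
either adjacent cell is label 0 or it lies on the domain boundary.  The
right-hand-side term `(mu + lam) grad a` is differenced face-wise from the
adjacent cell values (with `a = 0` on label 1), collocating the forcing
where momentum rows live.

Two divergence stencils are offered for the constraint rows
(`model_params(scheme = ...)`):

* `six_point` — the native face difference
  `(u_{i+1/2} - u_{i-1/2})/h_x + ...`;
* `twelve_point` — the centered difference of face-averaged values,
  `(u_{i+3/2} + u_{i+1/2} - u_{i-1/2} - u_{i-3/2})/(4 h_x) + ...`.

The solver's output field is reported at voxel centres by averaging the two
bounding faces.  External tools (and `divergence_centered()`,
`jacobian_determinant()`) differentiate that centre-sampled field with
centered differences — which is algebraically identical to the
`twelve_point` stencil on the faces.  Hence a `twelve_point` solve yields
zero mismatch between prescribed atrophy and externally measured
divergence, while a `six_point` solve shows an artifactual error
concentrated at atrophy discontinuities.  Ground-truth volume maps must be
computed with the same stencil as the algorithm under evaluation; for
Jacobian-based (TBM-style) consumers that means `scheme = "twelve_point"`,
which is what the package's own volume-accounting checks use.

### Linear solver

Assembly produces one sparse saddle-point system over interior face
velocities and fluid-cell pressures (ordering: x-, y-, z-face unknowns,
then pressures, each lexicographic, so matrices are reproducible).
Backends:

* `direct` — sparse LU.  Deterministic and exact to rounding; used by
  default below ~8000 unknowns.  R's sparse LU suffers heavy fill-in on 3D
  saddle-point problems, so it is not the default at realistic sizes.
* `schur_gmres` (default above ~8000 unknowns) — restarted GMRES on the
  full system, right-preconditioned by a block upper-triangular operator:
  the face Laplacian block is factored once by sparse Cholesky, and the
  Schur complement is approximated by its diagonal (`k` on label-1 rows
  plus a `1/mu` pressure-mass scale).  This clusters the spectrum so that
  a 32^3 phantom converges in 12 (six-point) to 55 (twelve-point)
  iterations.  Convergence is verified against the true residual; the
  default tolerance is a relative residual of 1e-9, and the solve aborts
  with the achieved residual if it cannot be met.

Both backends are cross-checked against a dense LAPACK factorization of the
same assembled matrix on an 8^3 problem (agreement to 1e-8 relative and
better).  A label-2 component with no path to label 1 would make its
pressure block singular; such components receive a tiny (1e-8) diagonal
regularization with a warning rather than failing obscurely.

## Field calculus and warping

Deformations are stored as displacement fields in world millimetres at
voxel centres, `Phi(x) = x + u(x)`.  Composition
(`compose_fields(outer, inner)`) samples the outer field trilinearly at the
inner-displaced positions — vector fields need no intensity-model
smoothness, and trilinear sampling is the convention of the standard
transform-composition tools this output is meant to interoperate with.
Inversion uses the fixed-point iteration `v <- -u(y + v)` from `v = 0`,
with tolerance `1e-3 * min(spacing)` mm and an iteration cap of 100
(declared defaults; the iteration converges geometrically for the
small-gradient fields the model produces, typically in well under ten
iterations).  Out-of-domain samples use zero extension, consistent with
fields that vanish at the boundary by construction.

Images are warped by backward mapping only: the output value at voxel `y`
is the input interpolated at `y + u_inv(y)`.  If the caller holds the
forward field, `warp_image()` inverts it first (`field_is_inverse = FALSE`);
the command-line `warp` subcommand defaults to *not* inverting, matching
the convention that users pre-invert once and reuse the inverse.
Intensities use B-spline interpolation of order 0–3 (default 3) with the
standard recursive prefilter (mirror boundary, exact initialization for
short signals) so the spline interpolates rather than approximates the
samples; orders 4–5 are not offered, as nothing in the pipeline exercises
them.  Labels use nearest-neighbour pulls with a fixed
round-half-toward-lower-index tie break for cross-platform determinism.
Order-3 interpolation can overshoot near edges by design; tests document a
10%-of-range bound rather than hiding it.

## Longitudinal sequences

Multi-step simulation follows the scheme: solve on `(a_0, L_0)`; then for
each step `t`, warp the previous atrophy map `a_{t-1}` and the *original*
labels `L_0` with the accumulated composed field `u_{t-1} o ... o u_0`,
solve on the warped inputs, and extend the accumulated field.  Two
numerical choices:

* the atrophy map is warped with trilinear (not cubic) interpolation, so
  overshoot cannot create spurious negative/positive atrophy at the moving
  tissue edge;
* after warping, atrophy is clamped to zero outside the warped label-2
  region — trilinear interpolation inevitably bleeds a one-voxel skirt of
  values across the edge, and the solver (correctly) refuses atrophy
  outside label 2.

Because the map is rewarped every step, the global atrophy rate prescribed
initially is not necessarily preserved at intermediate time points; a
`rescale_atrophy = "preserve_total"` hook exists but is off by default,
keeping the documented drift visible rather than silently renormalizing.
The asymmetry — warping `a_{t-1}` but always `L_0` — is kept as specified
for the procedure this package implements.

Images for every time point are always resampled from original source
scans through accumulated fields, never by re-warping warped images, so
interpolation blur does not compound.  All intensity variants of one time
point share a single simulated field; their ground-truth volume change is
identical by construction, and the per-time-point fields are emitted once.

## Realistic intensity variation by resampling

Given the simulated field `Phi_sim`:

* resampling from the baseline gives the noise-correlated variant
  (`I_s0`);
* resampling from a same-session repeat scan gives identical morphology
  with independent noise and different smooth inhomogeneity (`I_s1`);
* resampling from a later scan `I_r` with known or estimated registration
  `Phi_reg` (mapping `I_r`'s anatomy onto the baseline) uses the composed
  field `Phi_sim o Phi_reg` (`I_s2`).

Registration error propagates directly into `I_s2`'s morphology; the
package's tests degrade a known true registration field deliberately and
verify the morphological agreement falls monotonically, which is the
behaviour users should expect with imperfect registrations.  Interpolation
slightly reduces noise variance; in the tests the voxelwise
difference between `I_s0` and `I_s1` keeps a standard deviation between
0.5 and 1.1 times `sqrt(2)` times the injected noise SD.

## The phantom generator

Real pipelines need skull-stripped, segmented, co-registered inputs; the
phantom generator stands in for all of that so every stage is testable
without MRI data.  It builds a concentric-sphere head: background and a
skull shell (label 0), a sulcal-CSF shell and central ventricle (label 1),
parenchyma between them (label 2) with optional spherical ROI blobs
(a crude hippocampus stand-in).  Default geometry is a 32^3 grid at 1 mm
with radii 15/13/11/3 mm; tissue means (background 0, skull 60, CSF 30,
parenchyma 110) give CSF–parenchyma contrast typical of T1-weighted scans;
Gaussian noise of SD 4 (~5% of tissue contrast) is the default, with a
Rician option implementing the classical magnitude-of-complex-Gaussian
recipe for comparison studies.  Repeat scans add an independent noise
realization and a separable polynomial bias field (order 2, relative
amplitude 0.1 by default, i.e. intensity ratios within about [0.9, 1.1];
0.2 yields [0.8, 1.2]).  Follow-up scans warp the noiseless anatomy by a
caller-supplied true field and return the exact registration field a
perfect registration would recover, so registration can be bypassed or
perturbed deliberately.  All randomness flows from explicit seeds; equal
specs give bit-identical phantoms.

What the phantom does *not* emulate: cortical folding and anatomical
detail, partial-volume mixtures, MR acquisition physics (k-space, motion,
distortion), or spatially correlated noise.  Passing tests on phantoms
therefore validates the numerics and the pipeline plumbing — constraint
satisfaction, conservation, scheme consistency, morphology preservation
under resampling — not anatomical realism.

## Problem sizes and numerical conventions

The shipped tests and the acceptance script run on 8^3 blocks (oracle
comparisons), 16^3–24^3 phantoms (unit tests) and the standard 32^3 phantom
(end-to-end properties), sizes chosen so the whole suite completes in a few
minutes on one CPU while still exercising every regime interface.  Key
conventions, all declared rather than inferred:

* voxel (i,j,k), 0-based, has its centre at
  `origin + direction * (i h_x, j h_y, k h_z)`; displacement fields are
  world-mm vectors (interoperable with external registration tools);
* metadata equality tolerance 1e-4 mm (absorbs header rounding without
  masking misalignment); direction matrices must be orthonormal to 1e-6;
* centered stencils use first-order one-sided differences at the domain
  boundary; comparisons restrict to interior voxels;
* scalar and vector data are written as 64-bit floats (labels as 32-bit
  integers), so I/O round trips are exact.

## Known limitations

* Homogeneous, isotropic `mu`, `lam` within the three-regime pattern; no
  hyperelasticity or skull contact mechanics.
* The fixed-point inverse requires `|grad u| < 1` per step; prescribing
  very large per-step atrophy will fail (by design — split the step).
* Nearest-neighbour label warping over many accumulated steps can develop
  staircase artifacts; the per-step constraint diagnostics expose any
  resulting drift.
* The non-rigid registration that produces `Phi_reg` for real data is out
  of scope; any tool emitting a displacement field works.
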