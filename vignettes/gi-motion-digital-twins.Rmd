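---
title: "Modeling peristaltic gastrointestinal motion as a patient-specific digital twin"
author: "gitwin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling peristaltic gastrointestinal motion as a patient-specific digital twin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gitwin)
```

## The problem

Deformable image registration (DIR) in the upper abdomen is hard to
validate: luminal gastrointestinal organs (stomach, large bowel) move by
millimeters to centimeters between and within radiotherapy fractions, and
there are no reliably identifiable landmarks inside their walls. `gitwin`
synthesizes that motion instead of trying to measure it: starting from one
static 3D scan and a binary organ mask, it builds a geometric organ model,
animates it with an analytical peristaltic wave, and emits the
corresponding dense displacement fields (DVFs) as *known ground truth*.
Any registration algorithm can then be scored voxel-by-voxel against the
truth — geometrically (target registration error, Dice, 95th-percentile
Hausdorff distance), mechanically (log-Jacobian of the deformation), and
dosimetrically (dose-warping error, displacement RMSE binned by motion
magnitude or dose level).

## The model

### From mask to tubular surface

1. **Thinning.** The organ mask is reduced to a one-voxel-wide skeleton by
   topology-preserving 3D thinning: border voxels that are *simple points*
   (removal changes neither foreground nor background connectivity) and not
   curve endpoints are deleted in six directional subpasses until
   stability. The two user-chosen centerline endpoints are pinned during
   thinning; without anchoring, thinning retreats from tapering organ tips
   (we verified the same retreat in an independent implementation of the
   same algorithm), and the skeleton would not span the anatomy the user
   selected.
2. **Centerline.** Skeleton voxels are joined by 26-adjacency. Cycles
   (from holes in the mask) are broken by keeping, per cycle, the passage
   that runs deepest inside the organ — a maximum-depth spanning tree with
   the edge depth taken from the distance transform — after which the
   endpoint-to-endpoint path is unique and found by breadth-first search;
   all side branches are discarded. The voxel polyline is then smoothed
   with a per-coordinate smoothing spline (df = n/4) and resampled at
   equidistant arc-length steps. Smoothing matters more than it looks: the
   raw voxel zigzag inflates arc length by ~2% and jitters the arc
   coordinate that the traveling wave is evaluated at; for the default
   stomach wave the radial error is roughly 1 mm per mm of arc error.
3. **Sectional curves.** At every resampled centerline point, rays are
   cast in the plane orthogonal to the local tangent (rotation-minimizing
   frames, so the angular parameterization does not twist along the organ)
   until they first cross the mask boundary; the crossing is located
   sub-voxel by linear interpolation of the mask's signed distance.
4. **NURBS surface.** The boundary points are used directly as the control
   net of a tensor-product B-spline surface: clamped cubic along the
   organ, periodic cubic around each section, unit weights. Inner *shells*
   are obtained by linearly interpolating every control point toward its
   section center, parameterized by a radial factor `p` (0 = surface,
   1 = centerline).

### The peristaltic wave

Each sectional curve at arc-length station $L_i$ is displaced radially at
time $t$ by

$$F_\mathrm{PS}(L_i, t) = \frac{1}{\sqrt{3}}\, A \sin\!\Big(2\pi\,
\frac{L_i - c\,t}{\lambda}\Big), \qquad D(u) = e^{-\alpha u},$$

applied to every control point $P_{i,j}$ along its unit radial direction
$\vec d$ from the section center:
$P'_{i,j} = P_{i,j} + F\cdot D_s \cdot D_t \cdot \vec d$. Positive $F$
expands the section, negative $F$ contracts it; contraction is clamped so
no point crosses its section center (post-deformation radius at least
0.25 mm — the printed model would otherwise push thin sections through
their own axis). The optional exponential dispersion attenuates the wave
in the spatial ($u = L_i$) or temporal ($u = t$) domain.

Defaults follow gastric physiology as used for the study conditions:
stomach $A = 16$ mm, $\lambda = 55$ mm, $c = 5$ mm/s; large bowel
$A = 16$ mm, $\lambda = 40$ mm, $c = 8$ mm/s; $\alpha = 0$ (strong,
non-dispersive motion); 21 phases spanning exactly one wave period
$\lambda/c$, so phase 0 and phase 20 coincide — a property the tests
exploit. When several organs are animated in one run they share the first
organ's phase clock, each with its own wave parameters.

### From surfaces to displacement fields

For every phase, original and deformed shell stacks are sampled on a
common $(u, v, p)$ grid; the per-sample displacement is the difference of
corresponding points. Vectors are binned into the voxel containing their
*original* position (collisions averaged), and the remaining zero-motion
voxels inside a support region are filled by synchronous (Jacobi)
averaging of their nonzero 6-neighbors until the mean per-voxel update
falls below 0.001 mm. In the limit this solves the discrete Laplace
problem with the seeds as Dirichlet data, so filled magnitudes never
exceed the largest seed (a maximum principle the tests assert).

The support region is a dilation of the organ by
$\max(A)/\sqrt{3} + 2\,\text{voxels}$: the dilation must contain the
largest outward surface excursion, otherwise the voxelized field would
clip expansion. (A fixed small dilation — we first tried 3 voxels — fails
exactly this way for the default amplitude at 2 mm voxels.)

### Warping: one subtlety worth knowing

The DVF is a *forward* map (vectors anchored at undeformed positions), so
resampling needs the backward map. Three facts shaped the design:

* The harmonically filled forward field decays outside the organ with a
  decay length of roughly $\lambda/2\pi \approx 9$ mm — shorter than the
  peak excursion $A/\sqrt{3} \approx 9.2$ mm — so the extended forward map
  *folds* outside the organ and fixed-point inversion converges to the
  wrong branch: warps computed that way never realize the expansion.
* A backward field scattered from the deformed sample positions fixes
  expansion but degenerates where the lumen collapses: vectors from all
  around the section collide in the few collapsed voxels and cancel
  angularly, leaving ghost foreground in the vacated annulus.
* Pushing the (supersampled) foreground forward handles both collapse and
  expansion but dilates every boundary by about half a sub-voxel.

`warpVolume()` therefore resamples images and dose maps trilinearly
through the backward map (the pipeline carries an exact
correspondence-built backward field per phase; for external DVFs a
fixed-point inverse is computed), and warps *masks* as the conjunction of
pull-back membership (trilinearly interpolated mask $\ge 0.5$ at the
preimage) and push-forward coverage. A zero field reproduces every input
exactly.

## Evaluation metrics

* **TRE** at NURBS surface and inner-shell points:
  $\lVert u_\mathrm{gt}(x) - u_\mathrm{cand}(x)\rVert$ with trilinear
  field sampling (symmetric in its arguments).
* **DSC** and **HD95** between candidate-warped and ground-truth-warped
  masks; HD95 is computed on boundary voxels, spacing-aware, with the
  percentile linearly interpolated.
* **DWE** — the signed relative difference of accumulated doses over ROI
  voxels above a 0.5 Gy floor, reported as a mean percentage (the raw sum
  is attached as an attribute, since a bare sum grows with ROI size).
  Dose accumulation uses direct dose mapping: the planned dose is warped
  by each phase's field and averaged.
* **Binned RMSE** of the displacement error, by ground-truth motion
  magnitude (default 1 mm bins) or by dose (default 10 Gy bins), plus a
  voxelwise error heatmap volume.
* Registration direction follows the evaluation convention of comparing
  phase 0 against the phase with the largest mean displacement over the
  organ (`maxDeformationPhase()`).

## The synthetic phantoms

Two presets stand in for patient anatomy at desk scale, on a $96^3$ grid
at 2 mm spacing: a *stomach-like* C-arc whose tube radius tapers from 12
to 6 mm, and a *bowel-like* three-quarter torus arc of 8 mm radius. Both
taper to 2.5 mm at their ends: organs terminate anatomically, and a blunt
swept-sphere cap would lie outside the domain of a sectional motion model
— no cross-section along the centerline can ever animate it. The tube is
kept at least $A$ + 2 voxels away from the grid edge so voxelized motion
never clips. Intensities are three-level (lumen/wall/background) with
seeded Gaussian noise; dose maps are Gaussian blobs.

What the phantoms do *not* emulate: realistic MR/CT texture, organ-organ
contact mechanics, respiratory baseline drift, and intensity changes from
content redistribution. Passing tests on phantoms therefore demonstrates
the geometric and dosimetric machinery, not robustness to clinical image
quality.

The analytic comparator used by the self-consistency tests deforms the
true tube geometry *sectionally*: a voxel is judged against the deformed
radius at its nearest axis station. The generator's swept union-of-balls
rule would instead smear a strongly expanded section ±R along the axis,
which is not what a model of independent sectional curves prescribes.

## Numerical choices

* Section step: the largest in-plane spacing. A cubic control polygon
  attenuates a sampled sinusoid by $(4 + 2\cos(2\pi\,\Delta L/\lambda))/6$;
  at $\Delta L = 4$ mm and $\lambda = 55$ mm that already costs 0.33 mm of
  the 9.24 mm peak, at 2 mm it costs 0.08 mm.
* Rays per section: 36; shells at $p \in \{0, 0.25, 0.5, 0.75, 1\}$;
  $(u, v)$ sampling density about one sample per voxel length along and
  around the organ.
* Smoothing tolerance 0.001 mm (mean per-voxel update); fixed-point
  inversion runs 10 iterations or to a 0.05 mm residual; mask push-forward
  supersampling 4³ per voxel; contraction clamp 0.25 mm.
* Ties in cycle pruning are broken by edge order, so re-runs are
  bit-identical. The only randomness anywhere is the phantom intensity
  noise, which is seeded.

## Known limitations

* **Self-consistency ceiling.** Warping the *voxelized* organ mask with
  even an exact analytic displacement field reproduces the analytically
  deformed continuum tube only up to DSC ≈ 0.96 at 2 mm voxels, because
  the mask's voxelization noise is magnified by the expansion ratio
  (up to 2.4× at the default amplitude). The full pipeline measures
  DSC ≈ 0.89–0.93 at maximum deformation; the residual comes from ~0.6 mm
  RMS surface noise (radii cast on a voxelized boundary, arc-station
  mapping). At milder amplitudes or finer grids the agreement tightens.
* The model animates the organ wall and interior only; surrounding tissue
  motion is a smooth numerical extension, not mechanics, and the vacated
  space behind a strong contraction is treated as revealed background.
* Organs whose skeleton is a net (e.g. a bowel-bag segmentation) are out
  of scope, as is respiratory/cardiac motion and any DIR algorithm itself.

## Problem sizes used by the test-suite and the acceptance script

The suite exercises small analytic grids (≤ 20³) against brute-force
oracles, and the full stomach preset (96³, 2 mm, 21 phases) once for the
end-to-end properties; the acceptance script re-runs the complete
21-phase synthesis. These sizes were chosen as the smallest that leave
every geometric regime (expansion, collapse, curvature) represented.
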