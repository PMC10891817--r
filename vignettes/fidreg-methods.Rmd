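---
title: "Landmark rigid registration for CT/US valve fusion and jaw mirror reconstruction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fidreg methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and design choices behind
`fidreg`: what each stage computes, which knobs matter, what the synthetic
phantoms do and do not emulate, and where the design was genuinely open and
a choice had to be made.

## 1. Coordinate conventions

All physical coordinates in the package are **LPS millimetres** (the
DICOM/ITK convention). NIfTI stores RAS affines and Slicer's legacy FCSV
files store RAS points; both are converted at the I/O boundary by negating
the first two axes. One internal frame with documented boundary conversion
avoids the class of bugs where half a pipeline works in RAS and half in
LPS. A `volume3d` maps 0-based voxel index `i` to physical space as
`p = origin + D (s * i)` with orthonormal direction matrix `D` and spacing
`s`; geometry always comes from file headers and is never guessed.

## 2. The rigid fit

`fit_rigid()` solves the absolute-orientation problem: centre both point
sets, take the SVD of the cross-covariance, and compose
`R = V diag(1, 1, det(VU'))U'` so the result is a proper rotation even when
the unconstrained optimum would be a reflection (noisy near-planar
configurations exercise this branch in the tests). The translation is
`t = mean(fixed) - R mean(moving)`. The returned transform maps **moving
into fixed** space; the opposite convention exists in the wild, so the
direction is stated in the API and `rt_inverse()` is provided rather than
guessed at.

Degenerate inputs are refused loudly: fewer than 3 pairs, or moving points
whose second singular value is below `1e-9` of the first (collinear —
rotation about the common axis is unobservable), raise errors instead of
returning an arbitrary solution.

Transform parameters are reported as intrinsic Z-Y-X Euler angles in
degrees plus translations in mm, in that order. Any fixed convention works
as long as both transforms in a comparison use it; this one is stated,
round-trip tested, and the gimbal-lock branch (`|ry| = 90` degrees) is
flagged with a warning and resolved canonically (`rx = 0`).

## 3. Error metrics

* `fre` — RMS Euclidean residual of the registered pairs (mm). By
  least-squares optimality, no rigid transform scores lower on the same
  pairing than the fitted one; the suite checks this against random
  perturbations, and checks the classical localization-error law
  `E[FRE^2] = (1 - 2/N) * 3 sigma^2` by Monte-Carlo (10,000 replicates,
  within 5%) — the strongest external oracle for the fit and the metric
  combined.
* `rmse1` — RMS difference of the six pose parameters, rotation (degrees)
  and translation (mm) reported **separately**, never summed: the units
  differ, and folding them together makes the number uninterpretable.
  Angle differences are wrapped into (-180, 180] before squaring.
* `rmse2` — RMS distance between the moving landmarks mapped by the trial
  transform and by the gold standard. Unlike `rmse1` it measures the
  difference in *action* on the anatomy, which is what clinically matters;
  two poses with quite different Euler parameters can act almost
  identically on a compact landmark cloud.

The gold standard on synthetic data is the generator's true transform; on
real data it is a user-supplied reference transform file. No attempt is
made to reproduce expert manual alignment.

## 4. Temporal alignment

The gated CT contributes frames at known phases 0.0..0.9. The US series is
not synchronized with the ECG, so one cardiac cycle is delimited between
two consecutive "fully open" valve states and phases are assumed uniform
across it. CT phase `p` maps to US frame
`start + round(p * (end - start))` with round-half-even; the mapping is
deterministic, monotone, and endpoint-faithful. A subtlety worth stating:
with a 10-frame cycle, `round(0.5 * 9) = 4`, so two CT phases share US
frame 4 — exact one-to-one matching is only possible when the cycle length
is a multiple of the gating count.

Cycle delimitation supports three paths, in order of authority: explicit
frame indices (the interactive path — on real data the fully-open state is
a visual judgement); on phantoms, the generator's known frame phases (the
synthetic surrogate for that judgement); and automatic detection on a
per-frame scalar openness signal (mean intensity in a user-chosen ROI box),
where a cycle is the first pair of consecutive local maxima whose
intervening valley drops at least 25% of the signal range below both. The
automatic path works well on clean signals; on the speckled phantom the
~6% intensity modulation of the pulsing annulus is at the edge of
detectability, which is precisely why the interactive path is primary.

## 5. Resampling, centering, mirroring

`resample_volume()` interpolates onto a grid with the requested spacing
(operational default 0.342 x 0.342 x 0.37 mm, linear), preserving origin
and direction and choosing the output shape to cover the input extent.
Boundary handling is clamp-to-edge, so no background intensity is invented
near volume borders. Interpolators: trilinear, nearest-neighbour, and a
separable Keys cubic-convolution kernel (accepted under the name
`"bspline"` since that is what users of the upstream tooling ask for; the
Keys kernel interpolates rather than smooths, which is the behaviour the
pipeline needs). Linear resampling of a constant is constant, of a linear
ramp exact to 1e-6, and never exceeds the input range — all tested.

`center_volume()` translates the origin so the bounding-box centre of the
voxel grid is at (0,0,0); it changes no data, is idempotent, and preserves
all pairwise distances.

`mirror_volume()` reflects across a sagittal plane `x = x0` by resampling
the reflected positions on the original grid. The default interpolator is
nearest-neighbour: mirroring is then an exact involution when the plane
lies on a voxel column, and bone intensities pass through unchanged so
threshold masks survive a mirror round-trip. Linear interpolation is
available by flag. The default plane is the bounding-box centre x — the
anatomical mid-sagittal plane need not coincide with it, which is exactly
why the downstream local registration exists.

## 6. The validation harness

`run_sweep()` implements the reproducibility protocol: users x trials x
landmark counts N in [3, 12], fitting on the **first N pairs** of each
trial's placements. Prefix nesting — landmark k's placement does not change
as N grows — is a deliberate choice: it makes per-N curves comparable
within a trial and is the only reading that is reproducible from a seed.
The observer model is i.i.d. per-coordinate Gaussian localization noise of
SD `sigma_mm` per user, with optional index inflation
`sigma_k = sigma (1 + gamma k)` emulating the observation that later
landmarks sit on less evident anatomy. Under index inflation mean FRE
rises with N; under homoscedastic noise mean RMSE2 falls with N — both
patterns are asserted at 10,000-record aggregates.

`select_optimal_n()` encodes the accuracy-versus-effort compromise as a
computable rule: the smallest N whose pooled mean RMSE2 is within a
configurable tolerance (default 5%) of the sweep minimum, ties toward
smaller N. A narrative choice made from inspecting curves cannot be
reproduced; a tolerance-on-minimum rule can, and the tolerance is in
config. Boxplot summaries use linear-interpolation quantiles (R type 7)
and the 1.5 IQR outlier rule, both stated because plotting tools differ.
Bounds checking is inclusive (`<=` 15 mm RMSE2, `<=` 8 mm FRE at the
chosen N).

## 7. The synthetic phantoms

**Cardiac.** The scene is built from additive geometric primitives: a
torus annulus (mean diameter 35 mm, 15% peak-to-peak sinusoidal pulsation
over the cycle — configuration defaults representative of the mitral
annulus), two ellipsoidal chamber shells with contrast-intensity blood
pool, and a tube outflow tract. CT frames render the scene at ten gated
phases on a grid with clinically typical spacing defaults
(0.47 x 0.47 x 1.0 mm); US frames render it through the ground-truth probe
pose on an independent grid (0.50 x 0.50 x 0.27 mm defaults), spanning
more than one cycle starting at a consumer-unknown phase offset, cropped
to a probe cone (35 degree half-angle), mildly blurred and degraded with
unit-mean multiplicative Rayleigh-derived speckle (`noise_sd` is the SD of
that factor — a relative, dimensionless strength). Thirteen labelled
landmark positions per frame (annulus ring points, trigone analogues,
outflow, atrium, apex) are carried in the truth record; US-frame truth is
the CT truth through the inverse pose by construction.

What the phantom does **not** emulate: real speckle correlation and
shadowing, leaflet morphology, contrast kinetics, probe-dependent
point-spread anisotropy, or ECG irregularity. Passing tests therefore
demonstrate correctness of the *registration machinery and statistics*
under controlled noise — not clinical performance on patient data, whose
headline numbers depend on image quality and observer skill.

**Jaw.** A U-shaped mandible analogue (half-torus body, two rami with
condyle knobs) in soft tissue. Asymmetry is produced by rigidly displacing
the entire healthy half relative to perfect mirror symmetry — so every
landmark's mirrored counterpart carries the displacement and the local
registration problem is exactly identifiable — and a spherical defect
region on the other side is replaced by tumour intensity. The truth record
stores the intact pre-defect bone mask, the asymmetry transform, and
landmark pairs on defect-side structures outside the defect. The two
halves meet with a seam at the midline; this is a crude but sufficient
analogue of anatomic asymmetry for exercising every pipeline stage. Bone
thresholds for real data are a required input (they are scanner- and
patient-specific); the phantom's thresholds are the midpoint between soft
tissue and bone intensity.

## 8. Mirror reconstruction

`reconstruct_unilateral()` chains mirror, rigid local fit
(mirrored-volume landmarks as moving, original-volume landmarks as fixed),
resampling through the fitted transform onto the original grid, and
re-segmentation with thresholds asserted bit-identical to the original
bone segmentation. "Local" means the registration is driven only by
landmarks near the target; no image-region masking is added. The
reconstructed mask is restricted to the defect side of the mirroring
plane. Components use 26-connectivity; overlap reports give Dice and
symmetric surface-distance percentiles computed by exhaustive
nearest-surface-voxel search in physical space.

## 9. Numerical and testing choices

Grids in the test suite and acceptance script are reduced (CT 48x48x24 at
1.2 x 1.2 x 2.2 mm; US 40-cube at about 1 mm) so the full suite runs in
about 90 seconds; the phase structure, protocol settings, observer noise
and all tolerances are the full study conditions. Monte-Carlo checks use
10,000 replicates for expectation laws (5% tolerance) and 1,000
repetitions for the bound-satisfaction rate (> 99% required). The
brute-force oracle for the rigid fit is a multi-start Nelder-Mead/BFGS
minimization over the six pose parameters, independent of the closed-form
path, and must agree within 1e-6 mm FRE. Determinism is enforced
end-to-end: pipelines rerun from the same resolved config and seed must
produce bit-identical artifacts, which is tested via file checksums.

## 10. Known limitations

* DICOM series input is not supported; convert to NRRD/NIfTI first.
* No affine, similarity or deformable registration — deliberately: warping
  distorts the anatomy whose position is the quantity of interest.
* Automatic US cycle detection needs a clean openness signal; heavy
  speckle defeats simple ROI proxies, and the interactive path is then
  the right tool.
* The observer model is Gaussian and unbiased per default; systematic
  observer bias (a constant offset) is supported but correlated placement
  errors are not modelled.
* Surface-distance computation is exhaustive (O(n^2) in surface voxels);
  fine for the phantom scales used here, slow for full-resolution clinical
  masks.
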