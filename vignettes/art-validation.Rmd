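---
title: "Reverse transformation of generic ROIs for DSC perfusion MRI: methods and phantom validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse transformation of generic ROIs: methods and phantom validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the method

Region-wise assessment of dynamic susceptibility contrast (DSC) perfusion
MRI needs ROIs in every subject. Transforming each subject's parameter
maps into a common template space solves the ROI problem at the cost of
resampling the measured values; manual native-space segmentation preserves
the values but does not scale. Automatic reverse transformation (arT)
keeps the measurements untouched by moving the *ROIs* instead: generic
ROIs drawn once on a template are pulled back into each subject's native
space through the inverse of the spatial-normalization deformation.

The pipeline implemented by `run_art()` has four stages, in a fixed order:

1. **Co-registration** (`coregister_affine`): the time-averaged DSC signal
   (the "mean-TDC" image, which has enough anatomical contrast to
   register) is rigidly aligned to the subject's anatomical reference.
2. **Reverse transformation** (`reverse_transform_rois`): the template ROI
   label map is warped to the anatomical native grid through a dense
   template-to-native displacement field. The package consumes such fields
   as inputs (phantom-generated or exported from an external
   normalization); estimating nonlinear registrations is out of scope.
3. **Tissue filtering** (`filter_rois`): per voxel, the gray- plus
   white-matter probability must exceed 10% (strict `>`, configurable) for
   the voxel to stay in its ROI. For the two cerebral-hemisphere labels the
   CSF probability joins the sum, because ventricles and sulcal CSF are
   legitimately part of a hemisphere ROI. Filtering is idempotent,
   monotone in the threshold, and never adds voxels.
4. **DSC-grid projection** (`to_dsc_grid`): the filtered labels are
   resampled onto the acquisition grid through the inverse of the
   co-registration, so ROI means can be read from the unresampled maps.

## Geometric conventions

All geometry flows through 4x4 voxel-to-world affines (RAS+ mm, 0-based
voxel indices); there are no axis-flipping heuristics. Displacement fields
follow the pull-back convention: the output voxel at world position `x`
samples the source at `x + u(x)`, with offsets stored in world mm on the
field's own grid — the common convention for deformation-field NIfTI
exports. Label maps are never interpolated directly: each label's binary
indicator is interpolated trilinearly and re-binarized at 0.5, competing
claims resolve to the highest weight and ties to the lowest label id (for
determinism). This was preferred over nearest-neighbour label warping,
which is robust but produces block artifacts. Samples leaving a field of
view receive the background value 0 and are counted, never raised as
errors, so warped ROIs truncate silently but accountably at the FOV.

Rigid co-registration minimizes either mean squares (same-modality) or
negative normalized mutual information (32-bin joint histogram; the
default, since the mean-TDC and anatomical images differ in contrast) by
Nelder-Mead over a two-level multiresolution pyramid (downsampling factors
4 and 2), initialized at centre-of-mass alignment with rotations about the
fixed-image centre. Up to two simplex restarts per level precede a
registration error. The final level at factor 2 keeps the residual well
below the DSC in-plane voxel and costs a fraction of a full-resolution
optimization.

Displacement fields are inverted by fixed-point iteration
(`v <- -u(x + v(x))`, up to 30 iterations, 1e-3 mm update tolerance);
for the smooth fields used here the forward-inverse composition residual
is below 0.05 mm at the 99th percentile of brain voxels.

## Perfusion parameter maps

`compute_perfusion_maps()` derives, per slice of the 4D series:

- **Event window**: the slice-mean drop curve (baseline = median over
  frames, robust because the bolus occupies a minority of the 81-frame
  acquisition) is thresholded at 10% of its peak drop and the contiguous
  run around the peak is extended to the nearest baseline crossings. A
  flat slice raises an error naming the slice.
- **TTP**: `tr_seconds` times the (1-based) frame of maximal drop within
  the window; ties break to the earliest frame.
- **stdTTP**: TTP referenced to a slice-specific offset and clipped at
  zero. The offset is the 5th percentile of in-mask TTP in that slice — a
  robust "earliest regular arrival". The precise offset rule of the
  original map software is not public; the quantile is configurable and
  validation is by parameter recovery against the phantom's ground truth,
  not by matching a proprietary implementation. stdTTP is invariant to
  adding a constant to all TTP values of a slice.
- **CBV**: trapezoidal integral of the concentration proxy
  `-log(S/S0)` (S0 = pre-window baseline mean) over the window, scaled so
  the in-mask whole-brain mean is 1000 a.u. The published values use an
  unstated arbitrary-unit scale; fixing the brain mean to 1000 lands
  phantom ROI values in the same magnitude range (roughly 700-1400 a.u.)
  and makes CBV invariant to global signal scaling by construction.
- **Brain mask**: Otsu threshold on the mean image followed by the largest
  6-connected component.

## The phantom: what it emulates

The generator (`phantom_spec`, `make_template`, `make_subject`,
`make_cohort`) reproduces the study conditions: a 1 mm isotropic template,
a DSC grid of 1.154 x 1.154 x 6 mm with 20 slices, 81 frames at
TR = 0.689 s, 36 subjects by default, and seven ROIs per subject. The
brain is an analytic ellipsoid composite of about 70 x 85 x 65 mm — a
deliberately scaled-down head, chosen so a full cohort (36 subjects,
roughly 250 ROI pairs) generates and evaluates in minutes on one CPU. What
is matched to the clinical ROI set is the *rank structure*: hemispheres >>
cerebella >> pons ~ basal ganglia, with a hemisphere/basal-ganglia volume
ratio above 40, basal ganglia spanning only ~2 of the 6 mm slices, and a
ventricular CSF compartment inside the hemisphere labels that exercises
the CSF branch of the tissue filter.

Key generator parameters (all in `phantom_spec()`):

- `deformation_amplitude_mm` (default 4): maximum of the smooth random
  subject deformation, built from normal control-point vectors (16 mm
  spacing), smoothed, trilinearly upsampled and rescaled. Invertibility is
  guaranteed by keeping the amplitude below half the control spacing and
  verified numerically per subject via the Jacobian determinant.
- `manual_jitter_mm` (default 2.5): the ground-truth native ROIs are the
  analytic geometry seen through a second, independent smooth perturbation
  of at most 2.5 mm (about 1 mm typically — one in-plane voxel, well under
  half the slice thickness). This models the inter-observer boundary
  uncertainty of manual segmentation on thick-slice, low-contrast native
  images, which the clinical study identifies as a main error source.
  Without it the pipeline, which consumes the exact deformation, would
  differ from truth only by interpolation effects and the characteristic
  size-dependence of the overlap error would be under-represented. The
  expected Dice loss of a boundary perturbation is proportional to the
  surface-to-volume ratio, which is what produces the hemispheres >
  cerebella > basal-ganglia SDI ordering and the SDI-volume / SDI-SVR
  correlations in cohort summaries. Setting it to 0 (together with zero
  deformation) defines the perfect-alignment regime in which the pipeline
  must recover truth ROIs at SDI >= 0.95, degraded only by grid
  resampling.
- `tissue_params`: per-tissue baseline `s0` (a.u.), fractional peak drop
  `amplitude`, peak-time offset `ttp_offset` (s), rise time and
  gamma-variate shape. Defaults (GM 1300/0.35/1.0 s, WM 1100/0.18/2.5 s,
  CSF 1500/0.04/4.0 s, bolus peak near 19 s of the 56 s acquisition) give
  gray matter the earliest, deepest first pass, regular-range stdTTP far
  below the 7 s critical threshold, and a GM > WM > CSF blood-volume
  ordering. The first-pass dip is a gamma-variate — the standard DSC
  first-pass shape — because the study's own curve model lives in software
  that is not public; the phantom therefore defines its own ground truth
  and the pipeline is validated by recovering it.
- `noise_sd` (default 12, about 1% of baseline): additive Gaussian signal
  noise.
- `artifact_csf_flow`: corrupts the CSF probability map in a contiguous
  8 mm patch centred on the left cerebellum (GM+WM collapses below the
  filter threshold there), emulating a normalization tissue-map outlier;
  the filter report flags the affected ROI when its removed-voxel fraction
  exceeds `outlier_fraction` (default 0.2).

Per-subject reproducibility: subject `i` uses seed `master_seed + i`, so
any subject regenerates in isolation.

**What the phantom does not emulate**: MR physics (coils, EPI distortion,
T2* decay details), recirculation and leakage, arterial input structure,
pathological perfusion, realistic cortical folding, or errors of the
normalization estimate itself (the deformation consumed by the pipeline is
the true one; only the truth-ROI jitter plays the role of independent
spatial error). Passing phantom tests therefore demonstrates that the
implementation is faithful and numerically sound, and that the evaluation
statistics behave as they do on clinical data — not that clinical accuracy
would equal the phantom's.

## Evaluation statistics

`evaluate_pair()` compares the arT output against the truth ROIs on the
DSC grid: volumes, signed volume error (difference over mean volume,
antisymmetric, bounded by ±2), Sørensen-Dice index, the native mask's
surface-to-volume ratio, and the mean stdTTP/CBV over the finite voxels of
each mask (the difference convention is generic − native everywhere).
`summarize_cohort()` reduces a cohort to per-ROI and pooled median ± MAD
tables (MAD unscaled, no 1.4826 consistency factor), per-ROI Pearson and
Lin concordance coefficients, pooled Bland-Altman statistics, and the
cohort SDI-volume (Spearman) and SDI-SVR (Pearson) correlations.

Numerical choices worth stating:

- Dice uses the standard `2|A∩B|/(|A|+|B|)` denominator.
- Lin's CCC uses population (1/n) moments; the sample-moment variant
  differs at O(1/n). It never exceeds |PCC| in magnitude.
- Limits of agreement are the 2.5th/97.5th percentiles with
  linear-interpolation quantiles (R type 7); the bias CI95 is
  normal-theory `bias ± 1.96 sd/√n`.
- NRMSE divides the RMS of (fitted − native) by the native mean, with the
  fit an ordinary least squares of generic on native.
- The SVR surface is exposed-voxel-face area (face area = product of the
  two in-plane spacings). Face counting is exact for axis-aligned shapes
  (a cube of side `s` at 1 mm gives exactly `6/s`) but overestimates
  smooth oblique surfaces by up to ~1.5-1.6x — the known digital-surface
  bias, confirmed in the tests against a coarea (smoothed-gradient)
  estimator. Since SVR enters the analysis only as a shape covariate and
  the bias is shared across ROIs, it affects the scale of SVR, not the
  sign or ordering of its correlation with overlap.

## Problem sizes and runtime

Default problem sizes, chosen as the package's working point: template and
native grids 72 x 88 x 72 at 1 mm (~456k voxels), DSC grid 63 x 77 x 20 at
1.154 x 1.154 x 6 mm with 81 frames (~9.5M samples per subject). One
subject generates, maps, registers and evaluates in about 6 s; the default
36-subject study takes around 4 minutes on one CPU.

## Known limitations

- Registration is rigid only; an affine extension would be straightforward
  but the study design (scanner-matched sequences) does not need it.
- The stdTTP slice offset is a quantile heuristic; different offset rules
  shift all values in a slice jointly and cancel in native-vs-generic
  comparisons, but absolute stdTTP values depend on it.
- The event-window rule (10% of peak drop, baseline extension) is a
  package decision where the original processing chain delegates to
  unpublished software.
- CBV omits deconvolution, arterial input functions and leakage
  correction by design; it is a first-pass integral in arbitrary units.
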