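# artroi

Quantitative perfusion MRI reads out parameters such as the standardized
time-to-peak (stdTTP, with values > 7 s considered critical) and the
cerebral blood volume (CBV) inside anatomically defined regions of
interest (ROIs). Drawing those ROIs by hand in every patient is the gold
standard but does not scale, while the usual alternative — warping each
patient's parameter maps into a common template space — resamples and
interpolates the measured values themselves.

`artroi` implements the opposite strategy, *automatic reverse
transformation* (arT): a single set of generic ROIs defined on an MNI-like
template is projected **into each subject's native space** through the
inverse of the spatial-normalization deformation, filtered by
gray/white-matter probability, and resampled onto the DSC acquisition grid,
so the perfusion maps are read exactly where they were measured and their
absolute values are never touched. The package also provides the complete
validation suite used to quantify what this costs:

- **Spatial overlap** of generic vs native ROIs: volume error
  `VE = (V_nat − V_gen) / (½(V_nat + V_gen))`, Sørensen–Dice index
  `SDI = 2|A∩B| / (|A|+|B|)`, and surface-to-volume ratio (SVR).
- **Functional agreement** of the mean stdTTP/CBV per ROI: Bland–Altman
  bias with normal-theory CI95 and percentile (2.5th/97.5th) limits of
  agreement, Pearson/Spearman correlation, Lin's concordance coefficient
  `CCC = 2·cov(x,y) / (var x + var y + (x̄ − ȳ)²)`, and the NRMSE of the
  linear fit, `RMS(ŷᵢ − xᵢ) / x̄`.

Because clinical DSC data cannot ship with a package, `artroi` includes a
first-class synthetic phantom: an ellipsoid-composite brain with seven
labelled structures (left/right basal ganglia, pons, left/right cerebellum,
left/right hemisphere) whose volume ranks mirror the clinical ROI set,
smooth invertible random deformations per subject, tissue probability maps,
gamma-variate first-pass DSC signal with known per-ROI ground truth, and a
"manual segmentation" boundary-uncertainty model. The whole pipeline is
validated by parameter recovery against that ground truth.

## Worked example

```r
library(artroi)

spec     <- phantom_spec(seed = 7)           # study conditions: 1 mm template,
template <- make_template(spec)              # DSC 1.154 x 1.154 x 6 mm, 20
subject  <- make_subject(spec, template, 1)  # slices, 81 frames, TR 0.689 s

maps    <- compute_perfusion_maps(subject$dsc)        # mean-TDC, stdTTP, CBV
result  <- run_art(subject, template$rois, art_config())
records <- evaluate_pair(subject$rois_truth_dsc,
                         result$rois_generic_native, maps)
print(records[, c("roi", "v_native", "ve", "sdi", "stdttp_nat", "stdttp_gen")],
      digits = 3)
```

```
                  roi v_native       ve   sdi stdttp_nat stdttp_gen
1 right_basal_ganglia      967  0.05085 0.814      0.672      0.665
2  left_basal_ganglia     1175  0.13818 0.873      0.642      0.630
3    right_cerebellum     3588  0.02252 0.917      0.786      0.759
4     left_cerebellum     4107  0.03564 0.925      0.754      0.738
5                pons     1270 -0.03704 0.840      1.313      1.265
6    right_hemisphere    40735  0.00867 0.955      0.906      0.908
7     left_hemisphere    41390  0.03636 0.957      0.916      0.911
```

Reading the output: `sdi` is the spatial overlap between the arT-projected
generic ROI and the subject's ground-truth native ROI on the DSC grid —
highest for the hemispheres and lowest for the small basal ganglia, the
size dependence the method is known for. `ve` is the signed volume error
(fraction; positive = native larger). The stdTTP columns show that despite
imperfect overlap the *functional* read-out agrees to a few hundredths of
a second, i.e. far below the 7 s clinical decision threshold.

A full cohort study with summary tables (per-ROI median ± MAD of volume,
SVR, VE, SDI; stdTTP and CBV agreement with PCC/CCC; pooled Bland–Altman
statistics) is one call:

```r
report <- run_study(out_dir = "report", n_subjects = 36,
                    spec = phantom_spec(seed = 1))
validate_study("report")
```

A thin command-line wrapper lives at `inst/cli/artroi.R`
(`Rscript $(Rscript -e 'cat(system.file("cli/artroi.R", package="artroi"))') study --seed 1 --out report`).

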