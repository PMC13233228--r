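# Synthetic brain phantom: template with seven labelled structures, per-subject
# smooth invertible deformations, tissue probability maps, and a first-pass
# gamma-variate DSC bolus with known per-ROI ground truth.

#' Phantom study specification
#'
#' Defaults reproduce the study conditions: a 1 mm isotropic MNI-like
#' template grid, a DSC grid of 1.154 x 1.154 x 6 mm with 20 slices, 81 time
#' points at TR = 0.689 s, and seven ROIs per subject. The phantom brain is a
#' compact ellipsoid composite (about 70 x 85 x 65 mm) so that a full cohort
#' is computable at desk scale; structure volume *ratios*, not absolute
#' brain size, are matched to the clinical ROI set.
#'
#' @param seed master RNG seed; subject `i` derives seed `seed + i`.
#' @param grid_template list(dim, spacing) of the template/native grid (mm).
#' @param grid_dsc list(dim, spacing) of the DSC grid (mm).
#' @param n_timepoints DSC frames.
#' @param tr_seconds repetition time (s).
#' @param deformation_amplitude_mm maximum subject deformation; must stay
#'   below half the deformation control-point spacing so the field remains
#'   invertible by construction (verified numerically per subject).
#' @param control_spacing_mm spacing of the random-deformation control grid.
#' @param noise_sd additive Gaussian signal noise (signal units; baselines
#'   are around 1100-1500).
#' @param manual_jitter_mm amplitude of the smooth random boundary
#'   perturbation applied to the ground-truth ("manually drawn") native
#'   ROIs, emulating expert inter-observer uncertainty when delineating on
#'   thick-slice, low-contrast native images; 0 makes the truth ROIs the
#'   exact analytic geometry.
#' @param artifact_csf_flow inject a focal CSF-probability artifact into the
#'   left cerebellum (emulates a normalization tissue-map outlier).
#' @param bolus_peak_s reference bolus peak time; per-tissue peaks sit at
#'   `bolus_peak_s + ttp_offset`.
#' @param tissue_params per-tissue bolus parameters: baseline `s0`, peak
#'   fractional signal drop `amplitude`, peak-time offset `ttp_offset` (s),
#'   rise time `rise` (s) and gamma-variate shape `alpha`.
#' @return a `PhantomSpec`.
#' @export
phantom_spec <- function(seed = 1L,
                         grid_template = list(dim = c(72L, 88L, 72L),
                                              spacing = c(1, 1, 1)),
                         grid_dsc = list(dim = c(63L, 77L, 20L),
                                         spacing = c(1.154, 1.154, 6)),
                         n_timepoints = 81L,
                         tr_seconds = 0.689,
                         deformation_amplitude_mm = 4,
                         control_spacing_mm = 16,
                         noise_sd = 12,
                         manual_jitter_mm = 2.5,
                         artifact_csf_flow = FALSE,
                         bolus_peak_s = 18,
                         tissue_params = default_tissue_params()) {
  stopifnot(n_timepoints >= 3, tr_seconds > 0,
            all(unlist(grid_template$spacing) > 0),
            all(unlist(grid_dsc$spacing) > 0),
            deformation_amplitude_mm >= 0, noise_sd >= 0,
            manual_jitter_mm >= 0)
  if (deformation_amplitude_mm >= control_spacing_mm / 2)
    stop("spec error: deformation amplitude must stay below half the ",
         "control-point spacing to guarantee invertibility", call. = FALSE)
  structure(list(seed = as.integer(seed),
                 grid_template = grid_template, grid_dsc = grid_dsc,
                 n_timepoints = as.integer(n_timepoints),
                 tr_seconds = tr_seconds,
                 deformation_amplitude_mm = deformation_amplitude_mm,
                 control_spacing_mm = control_spacing_mm,
                 noise_sd = noise_sd,
                 manual_jitter_mm = manual_jitter_mm,
                 artifact_csf_flow = isTRUE(artifact_csf_flow),
                 bolus_peak_s = bolus_peak_s,
                 tissue_params = tissue_params),
            class = "PhantomSpec")
}

#' Default per-tissue bolus parameters
#'
#' Gray matter arrives earliest with the deepest first-pass dip, white
#' matter about 1.5 s later with roughly half the blood volume, CSF carries
#' only a trace signal change. Values give regular-range stdTTP (well below
#' the 7 s critical threshold) and a GM > WM > CSF blood-volume ordering.
#' @return named list of per-tissue parameter lists.
#' @export
default_tissue_params <- function() {
  list(gm  = list(s0 = 1300, amplitude = 0.35, ttp_offset = 1.0,
                  rise = 5, alpha = 3),
       wm  = list(s0 = 1100, amplitude = 0.18, ttp_offset = 2.5,
                  rise = 6, alpha = 3),
       csf = list(s0 = 1500, amplitude = 0.04, ttp_offset = 4.0,
                  rise = 7, alpha = 3))
}

#' The seven phantom ROIs
#' @return named character vector, names are label ids.
#' @export
phantom_registry <- function() {
  c("1" = "right_basal_ganglia", "2" = "left_basal_ganglia",
    "3" = "right_cerebellum", "4" = "left_cerebellum",
    "5" = "pons", "6" = "right_hemisphere", "7" = "left_hemisphere")
}

#' Labels treated as cerebral hemispheres in tissue filtering
#' @return integer vector of label ids.
#' @export
hemisphere_labels <- function() c(6L, 7L)

# Structure geometry in template world mm (RAS+, brain centred at origin).
# Volume rank order hemispheres >> cerebella >> pons ~ basal ganglia, with
# hemisphere/basal-ganglia ratio > 40, mirrors the clinical ROI set.
phantom_geometry <- function() {
  list(
    brain = list(centre = c(0, 0, 0), semi = c(33, 42, 32)),
    hemi = list(centre = c(0, 4, 8), semi = c(30, 34, 20), gap = 1),
    bg_r = list(centre = c(14, 4, 2), semi = c(5.5, 7.5, 5.5)),
    bg_l = list(centre = c(-14, 4, 2), semi = c(5.5, 7.5, 5.5)),
    cereb_r = list(centre = c(11, -24, -15), semi = c(10, 10, 9)),
    cereb_l = list(centre = c(-11, -24, -15), semi = c(10, 10, 9)),
    pons = list(centre = c(0, -14, -13), semi = c(6.5, 6, 8.5)),
    vent_r = list(centre = c(6, -2, 6), semi = c(3, 9, 4)),
    vent_l = list(centre = c(-6, -2, 6), semi = c(3, 9, 4)),
    csf_rim = c(0.95, 1.02),       # normalized brain radii of the CSF shell
    wm_core_hemi = 0.72,           # hemisphere WM core (normalized radius)
    wm_core_cereb = 0.65)
}

# Normalized ellipsoid radius of points (n x 3) for one structure.
ell_rho <- function(pts, s) {
  sqrt(((pts[, 1] - s$centre[1]) / s$semi[1])^2 +
       ((pts[, 2] - s$centre[2]) / s$semi[2])^2 +
       ((pts[, 3] - s$centre[3]) / s$semi[3])^2)
}

# Analytic label membership at arbitrary world points. Small structures take
# priority over the hemispheres that geometrically contain them.
phantom_labels_at <- function(pts) {
  g <- phantom_geometry()
  lab <- integer(nrow(pts))
  in_hemi <- ell_rho(pts, g$hemi) <= 1
  lab[in_hemi & pts[, 1] > g$hemi$gap] <- 6L
  lab[in_hemi & pts[, 1] < -g$hemi$gap] <- 7L
  lab[ell_rho(pts, g$cereb_r) <= 1] <- 3L
  lab[ell_rho(pts, g$cereb_l) <= 1] <- 4L
  lab[ell_rho(pts, g$pons) <= 1] <- 5L
  lab[ell_rho(pts, g$bg_r) <= 1] <- 1L
  lab[ell_rho(pts, g$bg_l) <= 1] <- 2L
  lab
}

# Analytic tissue composition (GM, WM, CSF fractions) at world points.
phantom_tissue_at <- function(pts, labels = NULL) {
  g <- phantom_geometry()
  if (is.null(labels)) labels <- phantom_labels_at(pts)
  n <- nrow(pts)
  gm <- numeric(n); wm <- numeric(n); csf <- numeric(n)
  rho_brain <- ell_rho(pts, g$brain)
  inside <- rho_brain <= g$csf_rim[1]
  rim <- rho_brain > g$csf_rim[1] & rho_brain <= g$csf_rim[2]
  csf[rim] <- 1
  # unlabeled deep tissue between structures
  deep <- inside & labels == 0L
  gm[deep] <- 0.40; wm[deep] <- 0.55
  hemi <- labels %in% c(6L, 7L)
  core <- ell_rho(pts, g$hemi) <= g$wm_core_hemi
  gm[hemi & !core] <- 0.85; wm[hemi & !core] <- 0.15
  gm[hemi & core] <- 0.10; wm[hemi & core] <- 0.90
  cereb <- labels %in% c(3L, 4L)
  ccore <- (ell_rho(pts, g$cereb_r) <= g$wm_core_cereb) |
           (ell_rho(pts, g$cereb_l) <= g$wm_core_cereb)
  gm[cereb & !ccore] <- 0.85; wm[cereb & !ccore] <- 0.15
  gm[cereb & ccore] <- 0.15; wm[cereb & ccore] <- 0.85
  pons <- labels == 5L
  gm[pons] <- 0.20; wm[pons] <- 0.80
  bg <- labels %in% c(1L, 2L)
  gm[bg] <- 0.85; wm[bg] <- 0.15
  vent <- ell_rho(pts, g$vent_r) <= 1 | ell_rho(pts, g$vent_l) <= 1
  gm[vent] <- 0; wm[vent] <- 0; csf[vent] <- 1
  csf[gm + wm > 0] <- 0   # structures override the CSF rim where they touch
  list(gm = gm, wm = wm, csf = csf)
}

# Protoneus-like anatomical contrast from tissue fractions.
anat_intensity <- function(gm, wm, csf) 110 * gm + 85 * wm + 150 * csf

#' Build the generic template: anatomy plus the seven-ROI label map
#'
#' Deterministic (no randomness): evaluates the analytic phantom geometry on
#' the template grid. Structure volumes rank as
#' hemispheres >> cerebella >> pons ~ basal ganglia.
#'
#' @param spec a `PhantomSpec`.
#' @return list with `anat` (`VolumeImage`) and `rois` (`RoiLabelMap`), both
#'   in template space.
#' @export
make_template <- function(spec = phantom_spec()) {
  grid <- make_grid(spec$grid_template$dim, spec$grid_template$spacing)
  g <- phantom_geometry()
  half_extent <- (grid$dim - 1) * spec$grid_template$spacing / 2
  if (any(g$brain$semi * g$csf_rim[2] > half_extent))
    stop("spec error: template grid too small to contain the phantom brain",
         call. = FALSE)
  pts <- grid_world_coords(grid)
  lab <- array(phantom_labels_at(pts), grid$dim)
  tis <- phantom_tissue_at(pts)
  anat <- array(anat_intensity(tis$gm, tis$wm, tis$csf), grid$dim)
  anat <- smooth_gaussian(anat, 1)
  list(anat = volume_image(anat, grid$affine, space = "template"),
       rois = roi_label_map(lab, grid$affine, phantom_registry()))
}

# Smooth random displacement field on the native grid: normal control-point
# vectors, smoothed, trilinearly upsampled and rescaled to the requested
# maximum displacement. Invertibility is checked via the Jacobian.
make_deformation <- function(spec, grid, amplitude = NULL,
                             control_spacing = NULL) {
  amp <- if (is.null(amplitude)) spec$deformation_amplitude_mm else amplitude
  ctrl <- if (is.null(control_spacing)) spec$control_spacing_mm
          else control_spacing
  d <- grid$dim
  if (amp == 0) {
    return(displacement_field(array(0, c(d, 3)), grid$affine,
                              direction = "template->native"))
  }
  spacing <- grid_spacing(grid)
  extent <- spacing * (d - 1)
  cdim <- pmax(4L, as.integer(ceiling(extent / ctrl)) + 3L)
  cspacing <- extent / (cdim - 3)   # one control point of margin each side
  cgrid <- make_grid(cdim, cspacing)
  offs <- array(rnorm(prod(cdim) * 3), c(cdim, 3))
  for (c in 1:3) offs[, , , c] <- smooth_gaussian(offs[, , , c], 0.8)
  up <- array(0, c(d, 3))
  w2v <- solve(cgrid$affine)
  for (c in 1:3) {
    up[, , , c] <- array(as.numeric(
      c_resample(as.numeric(offs[, , , c]), cdim, w2v, d, grid$affine,
                 NULL, 0L, 0)), d)
  }
  mags <- sqrt(rowSums(matrix(up, ncol = 3)^2))
  up <- up * (amp / max(mags))
  field <- displacement_field(up, grid$affine, direction = "template->native")
  jac <- field_jacobian(field)
  folds <- sum(jac <= 0.05)
  if (folds > 0)
    stop(sprintf("spec error: requested deformation folds at %d voxels", folds),
         call. = FALSE)
  field
}

# Gamma-variate bolus shape, unit peak at t = tp.
gamma_variate <- function(t, tp, rise, alpha) {
  tau <- t - (tp - rise)
  out <- numeric(length(t))
  pos <- tau > 0
  out[pos] <- (tau[pos] / rise)^alpha * exp(alpha * (1 - tau[pos] / rise))
  out
}

# Fractional signal-drop curves (3 x length(t)): row k is s0_k * A_k * g_k(t).
tissue_drop_curves <- function(spec, t) {
  tp <- spec$tissue_params
  do.call(rbind, lapply(tp, function(p)
    p$s0 * p$amplitude * gamma_variate(t, spec$bolus_peak_s + p$ttp_offset,
                                       p$rise, p$alpha)))
}

# Analytic per-ROI ground truth on the DSC grid: per-voxel noise-free mixture
# curves on a fine time grid; stdTTP is referenced to the earliest tissue
# (GM) peak, CBV is the integral of -log(S/S0).
phantom_truth <- function(spec, W, s0_vox, rois_dsc) {
  dt <- 0.05
  tfine <- seq(spec$bolus_peak_s - 10, spec$bolus_peak_s + 20, by = dt)
  G <- tissue_drop_curves(spec, tfine)
  ref_peak <- spec$bolus_peak_s + spec$tissue_params$gm$ttp_offset
  reg <- rois_dsc$registry
  out <- lapply(names(reg), function(id) {
    vox <- which(rois_dsc$labels == as.integer(id) & s0_vox > 0)
    drop <- W[vox, , drop = FALSE] %*% G
    ttp_vox <- tfine[max.col(drop, ties.method = "first")]
    conc <- -log(pmax(1 - drop / s0_vox[vox], 1e-12))
    cbv_vox <- rowSums(conc) * dt
    data.frame(label = as.integer(id), roi = reg[[id]],
               n_voxels = length(vox),
               stdttp_true = mean(ttp_vox) - ref_peak,
               cbv_true_raw = mean(cbv_vox))
  })
  do.call(rbind, out)
}

#' Generate one phantom subject
#'
#' Draws a smooth invertible random deformation, evaluates the analytic
#' template geometry through it to obtain native-space anatomy, tissue
#' probability maps and ground-truth ROIs, then synthesizes the DSC series
#' on the DSC grid as per-voxel baseline minus tissue-mixture gamma-variate
#' bolus dips plus Gaussian noise. Ground-truth per-ROI stdTTP/CBV are
#' recorded analytically from the generating parameters.
#'
#' @param spec a `PhantomSpec`.
#' @param template output of [make_template()] (rebuilt when `NULL`).
#' @param subject_index subject number; RNG seed is `spec$seed +
#'   subject_index` so any subject regenerates in isolation.
#' @return a `SubjectBundle` list: `anat`, `tpm_gm`, `tpm_wm`, `tpm_csf`,
#'   `rois_truth_native`, `rois_truth_dsc`, `dsc`,
#'   `field_template_to_native`, `truth` (data.frame), `seed`.
#' @export
make_subject <- function(spec = phantom_spec(), template = NULL,
                         subject_index = 1L) {
  if (is.null(template)) template <- make_template(spec)
  set.seed(spec$seed + as.integer(subject_index))
  grid <- as_grid(template$rois)
  field <- make_deformation(spec, grid)
  pts <- grid_world_coords(grid) + matrix(field$offsets, ncol = 3)
  lab <- phantom_labels_at(pts)
  tis <- phantom_tissue_at(pts, lab)
  # ground-truth ("manually drawn") ROIs: the same analytic geometry seen
  # through a small independent boundary perturbation, emulating expert
  # delineation uncertainty on thick-slice native images
  if (spec$manual_jitter_mm > 0) {
    jit <- make_deformation(spec, grid, amplitude = spec$manual_jitter_mm,
                            control_spacing = 12)
    jm <- matrix(jit$offsets, ncol = 3)
    pts_truth <- grid_world_coords(grid) + jm + sample_field_at(field, jm)
    lab_truth <- phantom_labels_at(pts_truth)
  } else {
    lab_truth <- lab
  }
  gm <- smooth_gaussian(array(tis$gm, grid$dim), 1)
  wm <- smooth_gaussian(array(tis$wm, grid$dim), 1)
  csf <- smooth_gaussian(array(tis$csf, grid$dim), 1)
  if (spec$artifact_csf_flow) {
    # focal tissue-map corruption (CSF-flow-like) centred on the left
    # cerebellum: GM+WM collapses below the 10% filter threshold there
    g <- phantom_geometry()
    ctr <- g$cereb_l$centre
    r2 <- rowSums(sweep(grid_world_coords(grid), 2, ctr, "-")^2)
    patch <- array(r2 <= 8^2, grid$dim)
    csf[patch] <- pmax(csf[patch], 0.95)
    gm[patch] <- gm[patch] * 0.05
    wm[patch] <- wm[patch] * 0.05
  }
  anat <- volume_image(anat_intensity(gm, wm, csf), grid$affine,
                       space = "anat-native")
  rois_native <- roi_label_map(array(lab_truth, grid$dim), grid$affine,
                               phantom_registry())

  dsc_grid <- make_grid(spec$grid_dsc$dim, spec$grid_dsc$spacing)
  W <- sapply(list(gm, wm, csf), function(a) {
    as.numeric(c_resample(as.numeric(a), grid$dim, solve(grid$affine),
                          dsc_grid$dim, dsc_grid$affine, NULL, 0L, 0))
  })
  tp <- spec$tissue_params
  s0_vox <- as.numeric(W %*% c(tp$gm$s0, tp$wm$s0, tp$csf$s0))
  t_acq <- seq_len(spec$n_timepoints) * spec$tr_seconds
  G <- tissue_drop_curves(spec, t_acq)
  S <- matrix(s0_vox, nrow = length(s0_vox), ncol = spec$n_timepoints) - W %*% G
  if (spec$noise_sd > 0) S <- S + rnorm(length(S), sd = spec$noise_sd)
  S <- pmax(S, 0)
  dsc <- dynamic_series(array(S, c(dsc_grid$dim, spec$n_timepoints)),
                        dsc_grid$affine, tr_seconds = spec$tr_seconds)
  rois_truth_dsc <- resample_labels(rois_native, dsc_grid)
  truth <- phantom_truth(spec, W, s0_vox, rois_truth_dsc)

  structure(list(anat = anat,
                 tpm_gm = volume_image(gm, grid$affine, "anat-native"),
                 tpm_wm = volume_image(wm, grid$affine, "anat-native"),
                 tpm_csf = volume_image(csf, grid$affine, "anat-native"),
                 rois_truth_native = rois_native,
                 rois_truth_dsc = rois_truth_dsc,
                 dsc = dsc,
                 field_template_to_native = field,
                 truth = truth,
                 seed = spec$seed + as.integer(subject_index)),
            class = "SubjectBundle")
}

#' Generate a phantom cohort
#'
#' @param spec a `PhantomSpec`.
#' @param n_subjects cohort size (study default 36).
#' @param template optional precomputed template.
#' @return list of `SubjectBundle`s; fully reproducible from the master seed.
#' @export
make_cohort <- function(spec = phantom_spec(), n_subjects = 36L,
                        template = NULL) {
  stopifnot(n_subjects >= 1)
  if (is.null(template)) template <- make_template(spec)
  lapply(seq_len(n_subjects), function(i)
    make_subject(spec, template, subject_index = i))
}

#' Write a phantom subject to a BIDS-flavoured directory
#'
#' @param subject a `SubjectBundle`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_subject <- function(subject, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_nifti(subject$anat, file.path(dir, "anat.nii.gz"))
  write_nifti(subject$tpm_gm, file.path(dir, "tpm_gm.nii.gz"))
  write_nifti(subject$tpm_wm, file.path(dir, "tpm_wm.nii.gz"))
  write_nifti(subject$tpm_csf, file.path(dir, "tpm_csf.nii.gz"))
  write_nifti(subject$rois_truth_native, file.path(dir, "rois_native.nii.gz"))
  write_nifti(subject$dsc, file.path(dir, "dsc.nii.gz"))
  write_nifti(subject$field_template_to_native, file.path(dir, "field.nii.gz"))
  jsonlite::write_json(subject$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(dir)
}
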