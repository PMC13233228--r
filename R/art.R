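# The arT pipeline: linear co-registration of the DSC mean image to the
# anatomical reference, reverse transformation of generic template ROIs into
# native space, tissue-probability filtering, and projection onto the DSC
# grid.

#' arT pipeline configuration
#'
#' @param tissue_threshold keep ROI voxels whose summed tissue probability is
#'   strictly above this value (default 0.10).
#' @param hemisphere_labels labels for which the CSF probability joins the
#'   GM+WM sum (the cerebral hemispheres enclose the ventricles).
#' @param outlier_fraction flag an ROI in the filter report when the removed
#'   voxel fraction exceeds this value.
#' @param registration list: `metric` (`"nmi"` for normalized mutual
#'   information or `"mean-squares"`), `type` (`"rigid"` or
#'   `"translation"`), `max_iterations`, `convergence_tol`, `levels`
#'   (multiresolution downsampling factors, coarse to fine), `bins` (joint
#'   histogram bins for NMI), `restarts` (Nelder-Mead restarts per level
#'   before a registration error is raised).
#' @return an `ArtConfig`.
#' @export
art_config <- function(tissue_threshold = 0.10,
                       hemisphere_labels = artroi::hemisphere_labels(),
                       outlier_fraction = 0.2,
                       registration = list()) {
  stopifnot(tissue_threshold > 0, tissue_threshold < 1)
  reg <- utils::modifyList(
    list(metric = "nmi", type = "rigid", max_iterations = 1000,
         convergence_tol = 1e-6, levels = c(4, 2), bins = 32,
         restarts = 2),
    registration)
  structure(list(tissue_threshold = tissue_threshold,
                 hemisphere_labels = as.integer(hemisphere_labels),
                 outlier_fraction = outlier_fraction,
                 registration = reg),
            class = "ArtConfig")
}

world_bbox <- function(img) {
  g <- as_grid(img)
  corners <- as.matrix(expand.grid(c(0, g$dim[1] - 1), c(0, g$dim[2] - 1),
                                   c(0, g$dim[3] - 1)))
  w <- sweep(corners %*% t(g$affine[1:3, 1:3]), 2, g$affine[1:3, 4], "+")
  rbind(apply(w, 2, min), apply(w, 2, max))
}

centre_of_mass <- function(img) {
  w <- pmax(img$data, 0)
  pts <- grid_world_coords(img)
  colSums(pts * as.vector(w)) / sum(w)
}

downsample_grid <- function(grid, factor) {
  g <- as_grid(grid)
  if (factor == 1) return(g)
  A <- g$affine
  A[1:3, 1:3] <- A[1:3, 1:3] * factor
  structure(list(dim = pmax(as.integer(ceiling(g$dim / factor)), 2L),
                 affine = A), class = "vox_grid")
}

metric_value <- function(fx, mv, metric, bins, rng_f, rng_m) {
  if (metric == "mean-squares") return(mean((fx - mv)^2))
  # negative normalized mutual information (minimized)
  bi_f <- pmin(pmax(floor((fx - rng_f[1]) / diff(rng_f) * bins), 0), bins - 1)
  bi_m <- pmin(pmax(floor((mv - rng_m[1]) / diff(rng_m) * bins), 0), bins - 1)
  joint <- tabulate(bi_f * bins + bi_m + 1, nbins = bins * bins)
  p <- joint / sum(joint)
  pf <- rowSums(matrix(p, bins, bins, byrow = TRUE))
  pm <- colSums(matrix(p, bins, bins, byrow = TRUE))
  h <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  -(h(pf) + h(pm)) / max(h(p), 1e-12)
}

#' Linearly co-register two volumes
#'
#' Rigid (or translation-only) registration of `moving` onto `fixed`,
#' initialized at centre-of-mass alignment, optimized by Nelder-Mead over a
#' multiresolution pyramid. Deterministic given the inputs and
#' configuration.
#'
#' @param moving,fixed `VolumeImage`s with overlapping fields of view.
#' @param config an `ArtConfig` (its `registration` entry is used).
#' @return an `AffineTransform` mapping moving-world into fixed-world
#'   coordinates, with attributes `"metric"` (final value) and `"params"`.
#' @export
coregister_affine <- function(moving, fixed, config = art_config()) {
  reg <- config$registration
  bf <- world_bbox(fixed); bm <- world_bbox(moving)
  if (any(bf[1, ] > bm[2, ] | bm[1, ] > bf[2, ]))
    stop("registration error: disjoint fields of view", call. = FALSE)
  centre <- colMeans(world_bbox(fixed))
  init_t <- centre_of_mass(fixed) - centre_of_mass(moving)
  n_par <- if (reg$type == "translation") 3L else 6L
  par <- c(init_t, 0, 0, 0)[seq_len(n_par)]
  rng_m <- range(moving$data, finite = TRUE)
  final_metric <- NA_real_
  for (f in reg$levels) {
    g <- downsample_grid(fixed, f)
    fx_img <- resample(fixed, g)
    fx <- as.vector(fx_img$data)
    rng_f <- range(fx, finite = TRUE)
    obj <- function(p) {
      p6 <- c(p, rep(0, 6 - length(p)))
      Tr <- rigid_transform(p6[1:3], p6[4:6], centre = centre)
      mv <- as.vector(resample(moving, g, transform = Tr)$data)
      metric_value(fx, mv, reg$metric, reg$bins, rng_f, rng_m)
    }
    parscale <- c(rep(1, 3), rep(0.01, 3))[seq_len(n_par)]
    fit <- NULL
    for (attempt in seq_len(reg$restarts + 1)) {
      fit <- stats::optim(if (is.null(fit)) par else fit$par, obj,
                          method = "Nelder-Mead",
                          control = list(maxit = reg$max_iterations,
                                         reltol = reg$convergence_tol,
                                         parscale = parscale))
      if (fit$convergence == 0) break
    }
    if (fit$convergence != 0)
      stop(sprintf(
        "registration error: no convergence within %d iterations (metric %.6g)",
        reg$max_iterations * (reg$restarts + 1), fit$value), call. = FALSE)
    par <- fit$par
    final_metric <- fit$value
  }
  p6 <- c(par, rep(0, 6 - length(par)))
  out <- rigid_transform(p6[1:3], p6[4:6], centre = centre)
  attr(out, "metric") <- final_metric
  attr(out, "params") <- p6
  out
}

#' Reverse-transform generic template ROIs into native space
#'
#' Applies [warp_labels()] with the inverse (template-to-native) deformation
#' so the generic ROIs land on the subject's anatomical grid. Refuses fields
#' tagged in the wrong direction.
#'
#' @param rois_template `RoiLabelMap` in template space.
#' @param field_inverse `DisplacementField` with direction
#'   `"template->native"` defined on the anatomical native grid.
#' @param anat_grid optional grid to validate the field against.
#' @return `RoiLabelMap` in native anatomical space.
#' @export
reverse_transform_rois <- function(rois_template, field_inverse,
                                   anat_grid = NULL) {
  if (field_inverse$direction != "template->native")
    stop("direction error: field must map template->native ",
         "(got ", field_inverse$direction, ")", call. = FALSE)
  if (!is.null(anat_grid) && !same_grid(field_inverse, anat_grid))
    stop("geometry error: field grid does not match the anatomical grid",
         call. = FALSE)
  warp_labels(rois_template, field_inverse)
}

#' Filter reverse-transformed ROIs by tissue probability
#'
#' Keeps ROI voxels whose gray + white matter probability is strictly above
#' the threshold; for hemisphere labels the CSF probability is added to the
#' sum (ventricles and sulcal CSF belong to the hemisphere ROIs). The
#' operation is idempotent and monotone in the threshold and never adds
#' voxels.
#'
#' @param rois `RoiLabelMap`.
#' @param tpm_gm,tpm_wm,tpm_csf probability `VolumeImage`s on the same grid.
#' @param config an `ArtConfig`.
#' @return list with `rois` (filtered `RoiLabelMap`) and `report`
#'   (data.frame: label, roi, n_before, n_after, n_removed, frac_removed,
#'   flagged).
#' @export
filter_rois <- function(rois, tpm_gm, tpm_wm, tpm_csf, config = art_config()) {
  if (!(same_grid(rois, tpm_gm) && same_grid(rois, tpm_wm) &&
        same_grid(rois, tpm_csf)))
    stop("geometry error: probability maps must share the ROI grid",
         call. = FALSE)
  p_tissue <- tpm_gm$data + tpm_wm$data
  p_hemi <- p_tissue + tpm_csf$data
  lab <- rois$labels
  keep <- array(FALSE, dim(lab))
  is_hemi_lab <- as.integer(names(rois$registry)) %in% config$hemisphere_labels
  for (i in seq_along(rois$registry)) {
    l <- as.integer(names(rois$registry)[i])
    sel <- lab == l
    p <- if (is_hemi_lab[i]) p_hemi else p_tissue
    keep <- keep | (sel & p > config$tissue_threshold)
  }
  out <- lab
  out[!keep] <- 0L
  report <- do.call(rbind, lapply(seq_along(rois$registry), function(i) {
    l <- as.integer(names(rois$registry)[i])
    nb <- sum(lab == l); na <- sum(out == l)
    data.frame(label = l, roi = unname(rois$registry[i]),
               n_before = nb, n_after = na, n_removed = nb - na,
               frac_removed = ifelse(nb > 0, (nb - na) / nb, 0))
  }))
  report$flagged <- report$frac_removed > config$outlier_fraction
  list(rois = roi_label_map(out, rois$affine, rois$registry),
       report = report)
}

#' Project native-space ROIs onto the DSC grid
#'
#' Resamples the filtered label map through the inverse of the co-registration
#' (indicator interpolation, 0.5 threshold).
#'
#' @param rois_native_anat `RoiLabelMap` on the anatomical grid.
#' @param coreg `AffineTransform` mapping DSC world to anatomical world (as
#'   returned by [coregister_affine()] with the DSC mean image as moving).
#' @param dsc_grid target grid.
#' @return `RoiLabelMap` on the DSC grid.
#' @export
to_dsc_grid <- function(rois_native_anat, coreg, dsc_grid) {
  resample_labels(rois_native_anat, dsc_grid,
                  transform = invert_transform(coreg))
}

#' Run the full arT pipeline for one subject
#'
#' Stages, in order: (1) co-register the DSC mean-TDC image to the
#' anatomical reference, (2) reverse-transform the generic template ROIs to
#' native space through the inverse deformation, (3) filter by tissue
#' probability, (4) project onto the DSC grid. Per-stage voxel accounting is
#' collected in the result's `log`.
#'
#' @param subject a `SubjectBundle` (or any list providing `anat`, `tpm_gm`,
#'   `tpm_wm`, `tpm_csf`, `dsc`, `field_template_to_native`).
#' @param rois_template generic `RoiLabelMap` in template space.
#' @param config an `ArtConfig`.
#' @return an `ArtResult` list: `rois_generic_native` (`RoiLabelMap` on the
#'   DSC grid), `rois_generic_anat`, `coreg`, `filter_report`, `log`,
#'   `config`.
#' @export
run_art <- function(subject, rois_template, config = art_config()) {
  log <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("arT stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  mean_tdc <- stage("mean-image", compute_mean_tdc(subject$dsc))
  coreg <- stage("co-registration",
                 coregister_affine(mean_tdc, subject$anat, config))
  log$coreg_params <- attr(coreg, "params")
  rois_native <- stage("reverse-transform",
                       reverse_transform_rois(rois_template,
                                              subject$field_template_to_native,
                                              as_grid(subject$anat)))
  log$voxels_native <- table(rois_native$labels[rois_native$labels > 0])
  filt <- stage("tissue-filter",
                filter_rois(rois_native, subject$tpm_gm, subject$tpm_wm,
                            subject$tpm_csf, config))
  rois_dsc <- stage("dsc-projection",
                    to_dsc_grid(filt$rois, coreg, as_grid(subject$dsc)))
  log$voxels_dsc <- table(rois_dsc$labels[rois_dsc$labels > 0])
  structure(list(rois_generic_native = rois_dsc,
                 rois_generic_anat = filt$rois,
                 coreg = coreg,
                 filter_report = filt$report,
                 log = log,
                 config = config),
            class = "ArtResult")
}
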