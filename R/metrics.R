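# Spatial-overlap and functional-agreement statistics: volume error,
# Sorensen-Dice, surface-to-volume ratio, Lin's concordance, Bland-Altman
# with percentile limits of agreement, regression NRMSE, and cohort
# median/MAD summaries.

#' Signed volume error between native and generic ROI volumes
#'
#' `VE = (V_native - V_generic) / (0.5 * (V_native + V_generic))`, the
#' difference normalized by the mean volume: dimensionless, antisymmetric
#' under argument swap, bounded by \[-2, 2\]. Multiply by 100 for percent.
#'
#' @param v_native,v_generic volumes (mm^3); their sum must be positive.
#' @return signed dimensionless error.
#' @export
volume_error <- function(v_native, v_generic) {
  if (any(v_native + v_generic <= 0))
    stop("undefined error: both volumes are zero", call. = FALSE)
  (v_native - v_generic) / (0.5 * (v_native + v_generic))
}

#' Sorensen-Dice index of two binary masks
#'
#' `SDI = 2 |A intersect B| / (|A| + |B|)`: 1 for identical nonempty masks,
#' 0 for disjoint ones.
#'
#' @param mask_a,mask_b logical/0-1 arrays on the same grid.
#' @return dimensionless overlap in \[0, 1\].
#' @export
dice <- function(mask_a, mask_b) {
  stopifnot(identical(dim(mask_a), dim(mask_b)))
  a <- mask_a > 0; b <- mask_b > 0
  denom <- sum(a) + sum(b)
  if (denom == 0) stop("undefined error: both masks are empty", call. = FALSE)
  2 * sum(a & b) / denom
}

#' Surface-to-volume ratio of a binary mask
#'
#' The surface is the summed area of exposed voxel faces (each face weighted
#' by the product of its two in-plane spacings); the volume is the voxel
#' count times the voxel volume. Face counting slightly overestimates the
#' area of smooth surfaces (up to ~1.5x for oblique orientations), which is
#' shared by both masks of a comparison and documented rather than
#' corrected.
#'
#' @param mask logical/0-1 3D array; must be nonempty.
#' @param spacing voxel spacing in mm (length 3).
#' @return ratio in 1/mm.
#' @export
surface_to_volume <- function(mask, spacing = c(1, 1, 1)) {
  m <- mask > 0
  if (!any(m)) stop("undefined error: empty mask", call. = FALSE)
  face_area <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
                 spacing[1] * spacing[2])
  surf <- 0
  for (axis in 1:3) {
    # interior faces between in/out voxel pairs, plus grid-boundary faces
    d <- dim(m)
    idx_lo <- idx_hi <- lapply(d, seq_len)
    idx_lo[[axis]] <- 1L; idx_hi[[axis]] <- d[axis]
    n_border <- sum(do.call(`[`, c(list(m), idx_lo))) +
      sum(do.call(`[`, c(list(m), idx_hi)))
    surf <- surf + face_area[axis] * (count_exposed(m, axis) + n_border)
  }
  surf / (sum(m) * prod(spacing))
}

# Count interior exposed faces along one axis (both directions).
count_exposed <- function(m, axis) {
  d <- dim(m)
  idx_a <- idx_b <- lapply(d, seq_len)
  idx_a[[axis]] <- seq_len(d[axis] - 1L)
  idx_b[[axis]] <- seq_len(d[axis] - 1L) + 1L
  a <- do.call(`[`, c(list(m), idx_a))
  b <- do.call(`[`, c(list(m), idx_b))
  sum(a & !b) + sum(b & !a)
}

#' Lin's concordance correlation coefficient
#'
#' `CCC = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)` with
#' population (1/n) moments; penalizes both decorrelation and location or
#' scale shift, so |CCC| <= |PCC| always.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return dimensionless concordance.
#' @export
concordance <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  denom <- vx + vy + (mx - my)^2
  if (denom == 0) stop("undefined error: zero variance and equal means",
                       call. = FALSE)
  2 * cxy / denom
}

#' Bland-Altman agreement of paired measurements
#'
#' Differences are `y - x`. The bias confidence interval is normal-theory
#' `bias +/- 1.96 sd/sqrt(n)`; the limits of agreement are the 2.5th and
#' 97.5th percentiles of the differences (linear-interpolation quantiles),
#' not the parametric 1.96-sd limits.
#'
#' @param x reference values (native).
#' @param y comparison values (generic).
#' @return list with `n`, `bias`, `ci95_bias` (length 2), `loa` (length 2).
#' @export
bland_altman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  d <- y - x
  n <- length(d)
  bias <- mean(d)
  s <- sd(d)
  ci <- bias + c(-1, 1) * 1.96 * s / sqrt(n)
  loa <- unname(quantile(d, c(0.025, 0.975), type = 7))
  list(n = n, bias = bias, ci95_bias = ci, loa = loa)
}

#' Linear agreement fit with normalized RMSE
#'
#' Ordinary least squares of `y` (generic) on `x` (native); the NRMSE
#' compares the fitted values against the native reference:
#' `NRMSE = sqrt(mean((fit_i - x_i)^2)) / mean(x)`. Pearson and Spearman
#' correlations of the raw pairs are returned alongside.
#'
#' @param x native values (nonzero variance, n >= 3).
#' @param y generic values.
#' @return list with `slope`, `intercept`, `nrmse`, `pcc`, `srcc`.
#' @export
fit_and_nrmse <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0) stop("undefined error: zero variance in x", call. = FALSE)
  fit <- lm(y ~ x)
  yhat <- fitted(fit)
  nrmse <- sqrt(mean((yhat - x)^2)) / mean(x)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       nrmse = nrmse,
       pcc = cor(x, y), srcc = cor(x, y, method = "spearman"))
}

#' Evaluate one native/generic ROI pair set on the DSC grid
#'
#' For every registry label: native and generic volumes, signed volume
#' error, Sorensen-Dice index, native-mask surface-to-volume ratio, and the
#' mean stdTTP and CBV over the finite in-ROI voxels of each mask. Labels
#' empty in either map are recorded with `missing = TRUE` rather than
#' failing.
#'
#' @param rois_truth native ("gold standard") `RoiLabelMap` on the DSC grid.
#' @param rois_art arT-generated `RoiLabelMap` on the same grid.
#' @param maps a `PerfusionMaps` object on the same grid.
#' @return data.frame, one row per ROI.
#' @export
evaluate_pair <- function(rois_truth, rois_art, maps) {
  stopifnot(same_grid(rois_truth, rois_art))
  vv <- voxel_volume(rois_truth)
  spacing <- grid_spacing(rois_truth)
  reg <- rois_truth$registry
  roi_mean <- function(map, mask) {
    v <- map$data[mask]
    v <- v[is.finite(v)]
    if (length(v)) mean(v) else NA_real_
  }
  out <- lapply(names(reg), function(id) {
    l <- as.integer(id)
    a <- rois_truth$labels == l
    b <- rois_art$labels == l
    if (!any(a) || !any(b)) {
      return(data.frame(label = l, roi = unname(reg[[id]]), missing = TRUE,
                        v_native = sum(a) * vv, v_generic = sum(b) * vv,
                        ve = NA_real_, sdi = NA_real_, svr = NA_real_,
                        stdttp_nat = NA_real_, stdttp_gen = NA_real_,
                        cbv_nat = NA_real_, cbv_gen = NA_real_))
    }
    v_nat <- sum(a) * vv
    v_gen <- sum(b) * vv
    data.frame(label = l, roi = unname(reg[[id]]), missing = FALSE,
               v_native = v_nat, v_generic = v_gen,
               ve = volume_error(v_nat, v_gen),
               sdi = dice(a, b),
               svr = surface_to_volume(a, spacing),
               stdttp_nat = roi_mean(maps$stdttp, a),
               stdttp_gen = roi_mean(maps$stdttp, b),
               cbv_nat = roi_mean(maps$cbv, a),
               cbv_gen = roi_mean(maps$cbv, b))
  })
  do.call(rbind, out)
}

med_mad <- function(x) {
  x <- x[is.finite(x)]
  unname(c(median(x), median(abs(x - median(x)))))
}

roi_parameter_table <- function(records, nat_col, gen_col) {
  rois <- unique(records$roi)
  rows <- lapply(rois, function(r) {
    rec <- records[records$roi == r & !records$missing, ]
    nat <- rec[[nat_col]]; gen <- rec[[gen_col]]
    ok <- is.finite(nat) & is.finite(gen)
    nat <- nat[ok]; gen <- gen[ok]
    mn <- med_mad(nat); mg <- med_mad(gen); mb <- med_mad(gen - nat)
    data.frame(roi = r, n = length(nat),
               nat_median = mn[1], nat_mad = mn[2],
               gen_median = mg[1], gen_mad = mg[2],
               bias_median = mb[1], bias_mad = mb[2],
               pcc = if (length(nat) >= 3) cor(nat, gen) else NA_real_,
               ccc = if (length(nat) >= 3) concordance(nat, gen) else NA_real_)
  })
  tab <- do.call(rbind, rows)
  rec <- records[!records$missing, ]
  nat <- rec[[nat_col]]; gen <- rec[[gen_col]]
  ok <- is.finite(nat) & is.finite(gen)
  nat <- nat[ok]; gen <- gen[ok]
  mn <- med_mad(nat); mg <- med_mad(gen); mb <- med_mad(gen - nat)
  rbind(tab, data.frame(roi = "total", n = length(nat),
                        nat_median = mn[1], nat_mad = mn[2],
                        gen_median = mg[1], gen_mad = mg[2],
                        bias_median = mb[1], bias_mad = mb[2],
                        pcc = if (length(nat) >= 3) cor(nat, gen) else NA_real_,
                        ccc = if (length(nat) >= 3) concordance(nat, gen)
                              else NA_real_))
}

#' Summarize a cohort of evaluated ROI pairs
#'
#' Builds the per-ROI and pooled median/MAD tables for spatial overlap
#' (mean volume, SVR, VE%, SDI) and for the stdTTP and CBV agreement
#' (native, generic, bias, PCC, CCC), pooled Bland-Altman and regression
#' statistics, plus the cohort-level SDI-volume (Spearman, on the
#' double-logarithmic scale) and SDI-SVR (Pearson) correlations.
#'
#' @param records rbind of [evaluate_pair()] outputs over subjects.
#' @return list with `spatial`, `stdttp`, `cbv` (data.frames),
#'   `agreement_stdttp`, `agreement_cbv` (pooled lists: Bland-Altman, fit,
#'   NRMSE), and `correlations` (`srcc_sdi_volume`, `pcc_sdi_svr`).
#' @export
summarize_cohort <- function(records) {
  stopifnot(nrow(records) >= 1)
  rec <- records[!records$missing & is.finite(records$sdi), ]
  rois <- unique(records$roi)
  spatial <- do.call(rbind, lapply(rois, function(r) {
    rc <- rec[rec$roi == r, ]
    v_mean <- (rc$v_native + rc$v_generic) / 2
    mv <- med_mad(v_mean); ms <- med_mad(rc$svr)
    mve <- med_mad(100 * rc$ve); md <- med_mad(rc$sdi)
    data.frame(roi = r, n = nrow(rc),
               v_mean_median = mv[1], v_mean_mad = mv[2],
               svr_median = ms[1], svr_mad = ms[2],
               ve_pct_median = mve[1], ve_pct_mad = mve[2],
               sdi_median = md[1], sdi_mad = md[2])
  }))
  v_mean_all <- (rec$v_native + rec$v_generic) / 2
  correlations <- list(
    srcc_sdi_volume = cor(rec$sdi, v_mean_all, method = "spearman"),
    pcc_sdi_svr = cor(rec$sdi, rec$svr))
  agreement <- function(nat_col, gen_col) {
    ok <- is.finite(records[[nat_col]]) & is.finite(records[[gen_col]]) &
      !records$missing
    x <- records[[nat_col]][ok]; y <- records[[gen_col]][ok]
    if (length(x) < 3)
      return(list(n = length(x), bias = mean(y - x),
                  ci95_bias = c(NA_real_, NA_real_),
                  loa = c(NA_real_, NA_real_), slope = NA_real_,
                  intercept = NA_real_, nrmse = NA_real_, pcc = NA_real_,
                  srcc = NA_real_))
    c(bland_altman(x, y), fit_and_nrmse(x, y))
  }
  list(spatial = spatial,
       stdttp = roi_parameter_table(records, "stdttp_nat", "stdttp_gen"),
       cbv = roi_parameter_table(records, "cbv_nat", "cbv_gen"),
       agreement_stdttp = agreement("stdttp_nat", "stdttp_gen"),
       agreement_cbv = agreement("cbv_nat", "cbv_gen"),
       correlations = correlations)
}

#' Bland-Altman plot of paired ROI values
#'
#' @param x,y native and generic values.
#' @param xlab,ylab,main plot annotation.
#' @return the [bland_altman()] statistics, invisibly.
#' @export
plot_bland_altman <- function(x, y, xlab = "mean of methods",
                              ylab = "generic - native", main = "") {
  ba <- bland_altman(x, y)
  graphics::plot((x + y) / 2, y - x, pch = 16, cex = 0.6,
                 xlab = xlab, ylab = ylab, main = main)
  graphics::abline(h = ba$bias, lwd = 2)
  graphics::abline(h = ba$loa, lty = 2)
  invisible(ba)
}
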