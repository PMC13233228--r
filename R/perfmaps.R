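# Perfusion parameter maps from a 4D DSC series: brain mask, per-slice
# first-pass event window, absolute and slice-standardized time-to-peak, and
# normalized cerebral blood volume.

#' Brain mask from a mean-TDC image
#'
#' Otsu threshold on the intensity histogram followed by the largest
#' 6-connected component.
#'
#' @param mean_tdc a `VolumeImage` (time-averaged DSC signal).
#' @return binary `VolumeImage`.
#' @export
brain_mask <- function(mean_tdc) {
  v <- mean_tdc$data
  rng <- range(v, finite = TRUE)
  if (diff(rng) <= 0) stop("mask error: constant image", call. = FALSE)
  norm <- (v - rng[1]) / diff(rng)
  thr <- EBImage::otsu(matrix(norm, ncol = 1), range = c(0, 1))
  m <- c_largest_component(as.vector(norm > thr), dim(v))
  volume_image(array(as.numeric(m), dim(v)), mean_tdc$affine, mean_tdc$space)
}

#' Voxelwise time-average of a DSC series (the anatomical "mean image")
#' @param dsc a `DynamicSeries`.
#' @return a `VolumeImage`.
#' @export
compute_mean_tdc <- function(dsc) {
  d <- dim(dsc$data)
  m <- rowMeans(matrix(dsc$data, nrow = prod(d[1:3]), ncol = d[4]))
  volume_image(array(m, d[1:3]), dsc$affine, space = "dsc-native")
}

#' Detect the first-pass perfusion event window per slice
#'
#' For each slice with in-mask voxels the slice-mean signal is reduced to a
#' drop curve (baseline minus signal, baseline = median over frames, which
#' is robust because the bolus occupies a minority of the acquisition). The
#' event window is the contiguous run around the peak drop where the drop
#' exceeds 10% of its maximum, extended outward to the nearest baseline
#' crossings. Slices without mask voxels get an `NA` window.
#'
#' @param dsc a `DynamicSeries` (>= 3 frames).
#' @param mask binary `VolumeImage` on the DSC grid.
#' @param rel_threshold window threshold as a fraction of peak drop.
#' @return data.frame with `slice`, `t_start`, `t_end` (frame indices).
#' @export
detect_event <- function(dsc, mask, rel_threshold = 0.1) {
  d <- dim(dsc$data)
  stopifnot(d[4] >= 3, same_grid(dsc, mask))
  nz <- d[3]
  out <- data.frame(slice = seq_len(nz), t_start = NA_integer_,
                    t_end = NA_integer_)
  for (z in seq_len(nz)) {
    mz <- mask$data[, , z] > 0
    if (!any(mz)) next
    sl <- matrix(dsc$data[, , z, ], nrow = prod(d[1:2]), ncol = d[4])
    m <- colMeans(sl[as.vector(mz), , drop = FALSE])
    s0 <- median(m)
    drop <- s0 - m
    peak <- max(drop)
    ipk <- which.max(drop)
    base_sd <- sd(drop[drop <= 0.05 * max(peak, 1e-12)])
    if (!is.finite(base_sd)) base_sd <- 0
    if (peak <= max(4 * base_sd, 1e-6 * max(s0, 1)))
      stop(sprintf("event error: no detectable perfusion event in slice %d", z),
           call. = FALSE)
    above <- drop > rel_threshold * peak
    a <- ipk; while (a > 1 && above[a - 1]) a <- a - 1
    b <- ipk; while (b < d[4] && above[b + 1]) b <- b + 1
    # extend to the nearest baseline crossings
    while (a > 1 && drop[a - 1] > 0) a <- a - 1
    while (b < d[4] && drop[b + 1] > 0) b <- b + 1
    out$t_start[z] <- a
    out$t_end[z] <- b
  }
  if (all(is.na(out$t_start)))
    stop("event error: mask is empty in every slice", call. = FALSE)
  out
}

# Pre-event baseline per voxel of one slice: mean over frames before the
# window (falls back to the first frame when the window starts at frame 1).
slice_baseline <- function(sl, a) {
  if (a >= 2) rowMeans(sl[, seq_len(a - 1), drop = FALSE]) else sl[, 1]
}

#' Absolute time-to-peak map
#'
#' Per voxel, TTP is `tr_seconds` times the (1-based) frame index of the
#' maximum signal drop within the slice's event window; ties break to the
#' earliest frame. Masked-out voxels and slices without a window are `NaN`.
#'
#' @param dsc a `DynamicSeries`.
#' @param event_window output of [detect_event()].
#' @param mask binary `VolumeImage`.
#' @return `VolumeImage` of TTP in seconds.
#' @export
compute_ttp <- function(dsc, event_window, mask) {
  d <- dim(dsc$data)
  ttp <- array(NaN, d[1:3])
  for (z in seq_len(d[3])) {
    a <- event_window$t_start[z]; b <- event_window$t_end[z]
    if (is.na(a)) next
    mz <- which(mask$data[, , z] > 0)
    if (!length(mz)) next
    sl <- matrix(dsc$data[, , z, ], nrow = prod(d[1:2]), ncol = d[4])[mz, ,
                                                                     drop = FALSE]
    s0 <- slice_baseline(sl, a)
    drop <- s0 - sl[, a:b, drop = FALSE]
    idx <- max.col(drop, ties.method = "first")
    plane <- ttp[, , z]
    plane[mz] <- (a - 1 + idx) * dsc$tr_seconds
    ttp[, , z] <- plane
  }
  volume_image(ttp, dsc$affine, space = "dsc-native")
}

#' Slice-standardized time-to-peak (stdTTP) map
#'
#' References each slice's absolute TTP values to a slice-specific offset --
#' a low quantile of the in-mask TTP distribution, approximating the
#' earliest regular bolus arrival in that slice -- and clips at zero:
#' `stdTTP = max(TTP - offset, 0)`. Invariant to adding a constant to all
#' TTP values of a slice.
#'
#' @param ttp_abs `VolumeImage` of absolute TTP (s).
#' @param mask binary `VolumeImage`.
#' @param offset_quantile quantile defining the slice offset (default 0.05).
#' @return `VolumeImage` of stdTTP in seconds (NaN outside mask).
#' @export
compute_stdttp <- function(ttp_abs, mask, offset_quantile = 0.05) {
  d <- dim(ttp_abs$data)
  out <- array(NaN, d)
  for (z in seq_len(d[3])) {
    plane <- ttp_abs$data[, , z]
    mz <- mask$data[, , z] > 0 & is.finite(plane)
    if (!any(mz)) next
    offset <- quantile(plane[mz], offset_quantile, names = FALSE)
    res <- array(NaN, d[1:2])
    res[mz] <- pmax(plane[mz] - offset, 0)
    out[, , z] <- res
  }
  volume_image(out, ttp_abs$affine, space = ttp_abs$space)
}

#' Cerebral blood volume (CBV) map
#'
#' Per voxel the concentration proxy `c(t) = -log(S(t)/S0)` (S0 = pre-window
#' baseline mean) is integrated over the slice's event window by the
#' trapezoidal rule and scaled so the in-mask whole-brain mean equals
#' `target_mean` arbitrary units. Voxels with nonpositive signal inside the
#' window become `NaN`; their count is attached as attribute `"n_invalid"`,
#' the scale factor as `"scale"`.
#'
#' @param dsc a `DynamicSeries`.
#' @param event_window output of [detect_event()].
#' @param mask binary `VolumeImage`.
#' @param target_mean normalization constant (default 1000 a.u.).
#' @return `VolumeImage` of CBV in arbitrary units.
#' @export
compute_cbv <- function(dsc, event_window, mask, target_mean = 1000) {
  d <- dim(dsc$data)
  cbv <- array(NaN, d[1:3])
  n_invalid <- 0L
  tr <- dsc$tr_seconds
  for (z in seq_len(d[3])) {
    a <- event_window$t_start[z]; b <- event_window$t_end[z]
    if (is.na(a)) next
    mz <- which(mask$data[, , z] > 0)
    if (!length(mz)) next
    sl <- matrix(dsc$data[, , z, ], nrow = prod(d[1:2]), ncol = d[4])[mz, ,
                                                                     drop = FALSE]
    s0 <- slice_baseline(sl, a)
    seg <- sl[, a:b, drop = FALSE]
    bad <- rowSums(seg <= 0) > 0 | s0 <= 0
    n_invalid <- n_invalid + sum(bad)
    conc <- -log(seg / s0)
    integ <- tr * (rowSums(conc) - 0.5 * (conc[, 1] + conc[, ncol(conc)]))
    integ[bad] <- NaN
    plane <- cbv[, , z]
    plane[mz] <- integ
    cbv[, , z] <- plane
  }
  inmask <- mask$data > 0 & is.finite(cbv)
  mu <- mean(cbv[inmask])
  scale <- if (is.finite(mu) && mu != 0) target_mean / mu else 1
  out <- volume_image(cbv * scale, dsc$affine, space = "dsc-native")
  attr(out, "n_invalid") <- n_invalid
  attr(out, "scale") <- scale
  out
}

#' Compute the full set of perfusion maps for one DSC series
#'
#' Convenience wrapper running [compute_mean_tdc()], [brain_mask()],
#' [detect_event()], [compute_ttp()], [compute_stdttp()] and
#' [compute_cbv()].
#'
#' @param dsc a `DynamicSeries`.
#' @param mask optional binary `VolumeImage`; computed from the mean image
#'   when `NULL`.
#' @param offset_quantile passed to [compute_stdttp()].
#' @param cbv_target_mean passed to [compute_cbv()].
#' @return a `PerfusionMaps` list: `mean_tdc`, `brain_mask`, `event_window`,
#'   `ttp_abs`, `stdttp`, `cbv`.
#' @export
compute_perfusion_maps <- function(dsc, mask = NULL, offset_quantile = 0.05,
                                   cbv_target_mean = 1000) {
  mean_tdc <- compute_mean_tdc(dsc)
  if (is.null(mask)) mask <- brain_mask(mean_tdc)
  windows <- detect_event(dsc, mask)
  ttp <- compute_ttp(dsc, windows, mask)
  stdttp <- compute_stdttp(ttp, mask, offset_quantile)
  cbv <- compute_cbv(dsc, windows, mask, cbv_target_mean)
  structure(list(mean_tdc = mean_tdc, brain_mask = mask,
                 event_window = windows, ttp_abs = ttp, stdttp = stdttp,
                 cbv = cbv),
            class = "PerfusionMaps")
}
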