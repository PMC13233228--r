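test_that("NIfTI round-trip preserves data and affine for every image type", {
  d <- withr::local_tempdir()
  aff <- diag(4); aff[1, 1] <- 1.154; aff[1:3, 4] <- c(-2, -3, -4)

  v <- volume_image(array(rnorm(125), c(5, 5, 5)), aff)
  p <- file.path(d, "vol.nii.gz")
  write_nifti(v, p)
  v2 <- read_nifti(p)
  expect_s3_class(v2, "VolumeImage")
  expect_equal(v2$data, v$data, tolerance = 1e-6)  # float32 storage
  expect_equal(v2$affine, v$affine, tolerance = 1e-5)

  r <- roi_label_map(array(sample(0:3, 64, TRUE), c(4, 4, 4)), aff,
                     c("1" = "a", "2" = "b", "3" = "c"))
  write_nifti(r, file.path(d, "roi.nii.gz"))
  r2 <- read_nifti(file.path(d, "roi.nii.gz"))
  expect_s3_class(r2, "RoiLabelMap")
  expect_identical(r2$labels, r$labels)
  expect_identical(unname(r2$registry), unname(r$registry))

  f <- displacement_field(array(rnorm(4 * 4 * 4 * 3), c(4, 4, 4, 3)), aff,
                          direction = "template->native")
  write_nifti(f, file.path(d, "field.nii.gz"))
  f2 <- read_nifti(file.path(d, "field.nii.gz"))
  expect_s3_class(f2, "DisplacementField")
  expect_identical(f2$direction, "template->native")
  expect_equal(f2$offsets, f$offsets, tolerance = 1e-6)
})

test_that("a 4D file loads as a DynamicSeries with TR and frame count", {
  d <- withr::local_tempdir()
  s <- dynamic_series(array(runif(4 * 4 * 2 * 81), c(4, 4, 2, 81)), diag(4),
                      tr_seconds = 0.689)
  p <- file.path(d, "dsc.nii.gz")
  write_nifti(s, p)
  s2 <- read_nifti(p)
  expect_s3_class(s2, "DynamicSeries")
  expect_identical(s2$n_timepoints, 81L)
  expect_equal(s2$tr_seconds, 0.689, tolerance = 1e-6)
})

test_that("a singular affine is rejected as a geometry error", {
  expect_error(volume_image(array(0, c(3, 3, 3)),
                            diag(c(1, 1, 0, 1))), "singular")
  # and on read of a file carrying a singular sform
  d <- withr::local_tempdir()
  img <- RNifti::asNifti(array(rnorm(27), c(3, 3, 3)))
  img <- RNifti::`sform<-`(img, structure(diag(c(1, 1, 0, 1)), code = 2L))
  img <- RNifti::`qform<-`(img, structure(diag(4) * 0, code = 0L))
  p <- file.path(d, "bad.nii")
  RNifti::writeNifti(img, p)
  expect_error(read_nifti(p), "singular")
})

test_that("resample honours identity, integer shifts, and constants", {
  g <- make_grid(c(7, 7, 7))
  img <- volume_image(array(rnorm(343), c(7, 7, 7)), g$affine)
  out <- resample(img, g)
  expect_equal(out$data, img$data, tolerance = 1e-12)

  # translation by exactly one voxel along x, nearest interpolation
  tr <- rigid_transform(c(1, 0, 0))
  sh <- resample(img, g, transform = tr, interpolation = "nearest")
  expect_equal(sh$data[2:7, , ], img$data[1:6, , ], tolerance = 1e-12)

  # linear resampling of a constant is that constant inside the FOV
  cimg <- volume_image(array(3.5, c(7, 7, 7)), g$affine)
  g2 <- make_grid(c(5, 5, 5), spacing = c(1.3, 0.9, 1.1))
  for (interp in c("linear", "nearest")) {
    rs <- resample(cimg, g2, interpolation = interp)
    expect_true(all(abs(rs$data - 3.5) < 1e-12))
  }
})

test_that("warping with the zero field is the identity; uniform fields shift", {
  g <- make_grid(c(9, 9, 9))
  img <- volume_image(array(rnorm(729), c(9, 9, 9)), g$affine)
  zf <- displacement_field(array(0, c(9, 9, 9, 3)), g$affine)
  for (interp in c("linear", "nearest"))
    expect_equal(warp(img, zf, interpolation = interp)$data, img$data,
                 tolerance = 1e-12)

  uf <- displacement_field(
    array(rep(c(2, 0, 0), each = 729), c(9, 9, 9, 3)), g$affine)
  sh <- warp(img, uf)
  expect_equal(sh$data[1:7, , ], img$data[3:9, , ], tolerance = 1e-12)
})

test_that("warping by a field then its numerical inverse restores a smooth image", {
  spec <- default_spec()
  grid <- make_grid(spec$grid_template$dim)
  set.seed(5)
  field <- artroi:::make_deformation(spec, grid)
  finv <- invert_field(field)
  pts <- artroi:::grid_world_coords(grid)
  img <- volume_image(
    array(sin(pts[, 1] / 9) + cos(pts[, 2] / 11) + sin(pts[, 3] / 7),
          grid$dim), grid$affine)
  back <- warp(warp(img, field), finv)
  # interior comparison (borders lose support under the warp)
  core <- 6:(grid$dim[1] - 6)
  err <- abs(back$data[core, core, core] - img$data[core, core, core])
  expect_lt(mean(err), 0.01)
})

test_that("label warping conserves the registry, volumes, and Jacobian bounds", {
  tpl <- fixture_template()
  g <- as_grid(tpl$rois)
  zf <- displacement_field(array(0, c(g$dim, 3)), g$affine)
  w0 <- warp_labels(tpl$rois, zf)
  expect_identical(w0$labels, tpl$rois$labels)
  expect_identical(w0$registry, tpl$rois$registry)

  # integer-voxel translation conserves per-label volumes (modulo FOV)
  uf <- displacement_field(
    array(rep(c(3, 0, 0), each = prod(g$dim)), c(g$dim, 3)), g$affine)
  wt <- warp_labels(tpl$rois, uf)
  expect_identical(as.vector(table(wt$labels[wt$labels > 0])),
                   as.vector(table(tpl$rois$labels[tpl$rois$labels > 0])))
  expect_true(all(unique(as.vector(wt$labels)) %in%
                    c(0L, as.integer(names(tpl$rois$registry)))))

  # smooth random field: volume change bounded by the Jacobian range
  set.seed(17)
  field <- artroi:::make_deformation(default_spec(), g)
  jac <- field_jacobian(field)
  wr <- warp_labels(tpl$rois, field)
  v0 <- table(factor(tpl$rois$labels[tpl$rois$labels > 0], levels = 1:7))
  v1 <- table(factor(wr$labels[wr$labels > 0], levels = 1:7))
  ratio <- as.numeric(v1) / as.numeric(v0)
  # pull-back: volume scales with 1/detJ over the structure, plus a small
  # discretization margin at the boundary
  expect_true(all(ratio > 1 / max(jac) - 0.08))
  expect_true(all(ratio < 1 / min(jac) + 0.08))
})

test_that("field inversion yields sub-voxel round-trip residuals", {
  subj <- fixture_subject()
  f <- subj$field_template_to_native
  finv <- invert_field(f)
  res <- compose_fields(f, finv)
  mag <- sqrt(rowSums(matrix(res$offsets, ncol = 3)^2))
  brain <- as.vector(fixture_template()$rois$labels > 0)
  expect_lt(quantile(mag[brain], 0.99), 0.5)
})
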