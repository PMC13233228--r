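test_that("tissue filtering branches on hemisphere membership as specified", {
  aff <- diag(4)
  reg <- c("3" = "right_cerebellum", "6" = "right_hemisphere",
           "5" = "pons")
  lab <- array(0L, c(3, 1, 1))
  lab[1, 1, 1] <- 5L   # pons voxel
  lab[2, 1, 1] <- 6L   # hemisphere voxel
  lab[3, 1, 1] <- 3L   # cerebellum voxel
  rois <- roi_label_map(lab, aff, reg)
  mk <- function(v) volume_image(array(v, c(3, 1, 1)), aff)

  # pons voxel with GM 0.06 + WM 0.05 = 0.11 > 0.10 is kept
  f <- filter_rois(rois, mk(0.06), mk(0.05), mk(0), art_config())
  expect_identical(f$rois$labels[1, 1, 1], 5L)
  # GM 0.04 + WM 0.05 = 0.09 is removed
  f2 <- filter_rois(rois, mk(0.04), mk(0.05), mk(0), art_config())
  expect_identical(f2$rois$labels[1, 1, 1], 0L)
  # pure-CSF voxel (p = 0.20): kept in the hemisphere, removed elsewhere
  f3 <- filter_rois(rois, mk(0), mk(0), mk(0.20), art_config())
  expect_identical(f3$rois$labels[2, 1, 1], 6L)
  expect_identical(f3$rois$labels[3, 1, 1], 0L)
  # boundary is strict: sum exactly at the threshold is removed
  f4 <- filter_rois(rois, mk(0.05), mk(0.05), mk(0), art_config())
  expect_identical(sum(f4$rois$labels), 0L)
})

test_that("filtering is idempotent and monotone in the threshold", {
  set.seed(31)
  aff <- diag(4)
  reg <- c("1" = "a", "2" = "b", "6" = "right_hemisphere")
  for (rep in 1:20) {
    lab <- array(sample(c(0L, 1L, 2L, 6L), 12^3, TRUE), c(12, 12, 12))
    rois <- roi_label_map(lab, aff, reg)
    gm <- volume_image(array(runif(12^3, 0, 0.4), c(12, 12, 12)), aff)
    wm <- volume_image(array(runif(12^3, 0, 0.4), c(12, 12, 12)), aff)
    csf <- volume_image(array(runif(12^3, 0, 0.4), c(12, 12, 12)), aff)
    cfg <- art_config(tissue_threshold = 0.10)
    f1 <- filter_rois(rois, gm, wm, csf, cfg)
    f2 <- filter_rois(f1$rois, gm, wm, csf, cfg)
    expect_identical(f2$rois$labels, f1$rois$labels)
    expect_true(all(f1$report$n_after <= f1$report$n_before))
    # raising the threshold never resurrects a removed voxel
    prev <- rois$labels
    for (thr in c(0.05, 0.15, 0.30)) {
      ft <- filter_rois(rois, gm, wm, csf,
                        art_config(tissue_threshold = thr))$rois$labels
      expect_true(all(ft[prev == 0L] == 0L) || thr == 0.05)
      if (thr > 0.05) expect_true(all(ft[prev == 0L] == 0L))
      prev <- ft
    }
  }
})

test_that("co-registration returns identity for self-registration", {
  subj <- fixture_clean_subject()
  cfg <- art_config(registration = list(metric = "mean-squares"))
  co <- coregister_affine(subj$anat, subj$anat, cfg)
  p <- attr(co, "params")
  expect_lt(max(abs(p[1:3])), 0.1)                  # mm
  expect_lt(max(abs(p[4:6])) * 180 / pi, 0.1)       # degrees
})

test_that("reverse transformation refuses wrong-direction fields", {
  tpl <- fixture_template()
  g <- as_grid(tpl$rois)
  wrong <- displacement_field(array(0, c(g$dim, 3)), g$affine,
                              direction = "native->template")
  expect_error(reverse_transform_rois(tpl$rois, wrong), "direction error")
  # and mismatched grids are a geometry error
  ok <- displacement_field(array(0, c(g$dim, 3)), g$affine)
  g2 <- make_grid(c(10, 10, 10))
  expect_error(reverse_transform_rois(tpl$rois, ok, g2), "geometry error")
  # identity field reproduces the template ROIs on the anatomical grid
  out <- reverse_transform_rois(tpl$rois, ok, g)
  expect_identical(out$labels, tpl$rois$labels)
})

test_that("DSC-grid projection preserves labels under identity and translation", {
  tpl <- fixture_template()
  g <- as_grid(tpl$rois)
  ident <- affine_transform()
  same <- to_dsc_grid(tpl$rois, ident, g)
  expect_identical(same$labels, tpl$rois$labels)
  # pure translation by 2 voxels along y
  tr <- rigid_transform(c(0, -2, 0))   # DSC world -> anat world
  shifted <- to_dsc_grid(tpl$rois, tr, g)
  expect_identical(shifted$labels[, 3:88, ], tpl$rois$labels[, 1:86, ])
  # anat (1 mm) -> DSC grid (6 mm slices): volumes agree per ROI up to a
  # boundary layer of coarse voxels
  dsc_grid <- make_grid(default_spec()$grid_dsc$dim,
                        default_spec()$grid_dsc$spacing)
  coarse <- to_dsc_grid(tpl$rois, ident, dsc_grid)
  v_fine <- table(factor(tpl$rois$labels[tpl$rois$labels > 0], 1:7)) *
    voxel_volume(tpl$rois)
  v_coarse <- table(factor(coarse$labels[coarse$labels > 0], 1:7)) *
    voxel_volume(coarse)
  expect_true(all(abs(as.numeric(v_coarse) / as.numeric(v_fine) - 1) < 0.15))
})

test_that("the filter report flags the CSF-flow artifact as an outlier", {
  spec <- phantom_spec(seed = 101L, artifact_csf_flow = TRUE)
  subj <- make_subject(spec, fixture_template(), 1L)
  f <- filter_rois(subj$rois_truth_native, subj$tpm_gm, subj$tpm_wm,
                   subj$tpm_csf, art_config())
  flagged <- f$report$roi[f$report$flagged]
  expect_true("left_cerebellum" %in% flagged)
  # the healthy counterpart raises no flag
  ref <- fixture_subject()
  f0 <- filter_rois(ref$rois_truth_native, ref$tpm_gm, ref$tpm_wm,
                    ref$tpm_csf, art_config())
  expect_false(any(f0$report$flagged))
})

test_that("run_art is deterministic and accounts voxels per stage", {
  subj <- fixture_clean_subject()
  tpl <- fixture_template()
  r1 <- run_art(subj, tpl$rois, art_config())
  r2 <- run_art(subj, tpl$rois, art_config())
  expect_identical(r1$rois_generic_native$labels, r2$rois_generic_native$labels)
  expect_identical(r1$filter_report, r2$filter_report)
  expect_true(all(r1$filter_report$n_after <= r1$filter_report$n_before))
  expect_named(r1$log, c("coreg_params", "voxels_native", "voxels_dsc"))
})
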