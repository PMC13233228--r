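test_that("dice is symmetric with exact bounds at identity and disjointness", {
  set.seed(7)
  for (i in 1:25) {
    a <- array(runif(216) > 0.6, c(6, 6, 6))
    b <- array(runif(216) > 0.6, c(6, 6, 6))
    if (!any(a | b)) next
    expect_identical(dice(a, b), dice(b, a))
    expect_gte(dice(a, b), 0)
    expect_lte(dice(a, b), 1)
  }
  a <- array(FALSE, c(4, 4, 4)); a[1:2, , ] <- TRUE
  expect_identical(dice(a, a), 1)
  expect_identical(dice(a, !a), 0)
  expect_error(dice(a & !a, a & !a), "empty")
})

test_that("volume error is antisymmetric and bounded", {
  set.seed(8)
  v1 <- runif(200, 0, 100); v2 <- runif(200, 0, 100)
  expect_equal(volume_error(v1, v2), -volume_error(v2, v1), tolerance = 1e-14)
  expect_true(all(abs(volume_error(v1, v2)) <= 2))
  expect_identical(volume_error(5, 5), 0)
  expect_equal(volume_error(10, 12.5), -0.22222222, tolerance = 1e-7)
  expect_error(volume_error(0, 0), "zero")
})

test_that("|CCC| never exceeds |PCC| and location shifts are penalized", {
  set.seed(9)
  for (i in 1:200) {
    n <- sample(3:60, 1)
    x <- rnorm(n); y <- 0.5 * x + rnorm(n, sd = runif(1, 0.1, 2)) + runif(1, -3, 3)
    expect_lte(abs(concordance(x, y)), abs(cor(x, y)) + 1e-12)
  }
  x <- rnorm(50)
  expect_equal(concordance(x, x), 1, tolerance = 1e-12)
  expect_lt(concordance(x, x + 1), 1)
  expect_equal(cor(x, x + 1), 1, tolerance = 1e-12)
})

test_that("percentile limits of agreement cover ~95% of large samples", {
  set.seed(10)
  x <- rnorm(5000); y <- x + rnorm(5000)
  ba <- bland_altman(x, y)
  inside <- mean(y - x >= ba$loa[1] & y - x <= ba$loa[2])
  expect_lt(abs(inside - 0.95), 0.01)   # binomial tolerance at n = 5000
  expect_lte(ba$loa[1], ba$loa[2])
  # exact agreement and constant offset
  ba0 <- bland_altman(x, x)
  expect_identical(ba0$bias, 0)
  expect_identical(unname(ba0$loa), c(0, 0))
  ba5 <- bland_altman(x, x + 0.5)
  expect_equal(ba5$bias, 0.5, tolerance = 1e-12)
  expect_equal(ba5$ci95_bias, c(0.5, 0.5), tolerance = 1e-12)
})

test_that("the agreement fit is exact on y = x and rank-invariant for SRCC", {
  x <- sort(rnorm(30))
  f <- fit_and_nrmse(x, x)
  expect_equal(f$slope, 1, tolerance = 1e-12)
  expect_equal(f$intercept, 0, tolerance = 1e-12)
  expect_equal(f$nrmse, 0, tolerance = 1e-12)
  y <- 0.8 * x + rnorm(30, sd = 0.2)
  f1 <- fit_and_nrmse(x, y)
  f2 <- fit_and_nrmse(exp(x), exp(y))   # strictly monotone transform of both
  expect_equal(f1$srcc, f2$srcc, tolerance = 1e-12)
  expect_error(fit_and_nrmse(rep(1, 5), rnorm(5)), "variance")
})

test_that("SVR decreases with object size and matches a smoothed-gradient estimate", {
  # nested cubes
  svrs <- sapply(c(6, 12, 24), function(s) {
    m <- array(FALSE, c(30, 30, 30)); m[1:s, 1:s, 1:s] <- TRUE
    surface_to_volume(m, c(1, 1, 1))
  })
  expect_true(all(diff(svrs) < 0))
  # anisotropic spacing: a single voxel of 1.154 x 1.154 x 6 mm
  m1 <- array(FALSE, c(3, 3, 3)); m1[2, 2, 2] <- TRUE
  sp <- c(1.154, 1.154, 6)
  expect_equal(surface_to_volume(m1, sp),
               (2 * sp[1] * sp[2] + 2 * sp[1] * sp[3] + 2 * sp[2] * sp[3]) /
                 prod(sp), tolerance = 1e-12)
  # blob: face counting against the coarea (smoothed-gradient) estimator;
  # digital face counting overestimates smooth surfaces by up to ~1.6x
  g <- make_grid(c(40, 40, 40))
  pts <- artroi:::grid_world_coords(g)
  ball <- function(c3, r) sqrt(rowSums(sweep(pts, 2, c3, "-")^2)) <= r
  m <- array(ball(c(-4, 0, 2), 8) | ball(c(5, 3, -2), 7) |
               ball(c(0, -6, -4), 6), g$dim)
  face <- surface_to_volume(m, c(1, 1, 1)) * sum(m)
  sm <- artroi:::smooth_gaussian(array(as.numeric(m), g$dim), 1.5)
  grad <- 0
  for (ax in 1:3)
    grad <- grad + ((artroi:::shift_array(sm, ax, -1L) -
                       artroi:::shift_array(sm, ax, 1L)) / 2)^2
  coarea <- sum(sqrt(grad))
  expect_gt(face / coarea, 1.0)
  expect_lt(face / coarea, 1.7)
})

test_that("evaluate_pair returns exact agreement for identical label maps", {
  subj <- fixture_subject()
  maps <- compute_perfusion_maps(subj$dsc)
  rec <- evaluate_pair(subj$rois_truth_dsc, subj$rois_truth_dsc, maps)
  expect_identical(nrow(rec), 7L)
  expect_true(all(rec$sdi == 1))
  expect_true(all(rec$ve == 0))
  expect_equal(rec$stdttp_gen, rec$stdttp_nat, tolerance = 1e-12)
  # a missing label is recorded, not fatal
  dropped <- subj$rois_truth_dsc
  dropped$labels[dropped$labels == 5L] <- 0L
  rec2 <- evaluate_pair(subj$rois_truth_dsc, dropped, maps)
  expect_true(rec2$missing[rec2$label == 5])
  expect_false(any(rec2$missing[rec2$label != 5]))
})

test_that("cohort summaries reduce to the record itself for n = 1 and use raw MAD", {
  # MAD convention: median absolute deviation without consistency scaling
  x <- c(1, 2, 9)
  expect_identical(artroi:::med_mad(x), c(2, 1))
  rec <- data.frame(subject = 1, label = 1, roi = "right_basal_ganglia",
                    missing = FALSE, v_native = 1000, v_generic = 900,
                    ve = volume_error(1000, 900), sdi = 0.9, svr = 0.5,
                    stdttp_nat = 1.2, stdttp_gen = 1.1, cbv_nat = 800,
                    cbv_gen = 790)
  s <- summarize_cohort(rec)
  expect_equal(s$spatial$sdi_median, 0.9)
  expect_equal(s$spatial$sdi_mad, 0)
  expect_equal(s$spatial$v_mean_median, 950)
})
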