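test_that("in-plane 3x3 erosion keeps only fully surrounded voxels", {
  m3 <- array(1, c(3, 3, 1))
  e3 <- erode_inplane(m3)
  expect_identical(sum(e3), 1L)
  expect_identical(e3[2, 2, 1], 1L)

  m5 <- array(1, c(5, 5, 1))
  e5 <- erode_inplane(m5)
  expect_identical(sum(e5), 9L)
  expect_true(all(e5[2:4, 2:4, 1] == 1L))

  # result is always a subset of the input
  set.seed(3)
  r <- array(rbinom(5 * 5 * 2, 1, 0.7), c(5, 5, 2))
  er <- erode_inplane(r)
  expect_true(all(er <= r))
})

test_that("erosion acts slice by slice with no through-plane coupling", {
  m <- array(1, c(4, 4, 2))
  e <- erode_inplane(m)
  expect_identical(e[, , 1], e[, , 2])
  # knocking out a voxel in slice 2 must not change slice 1
  m2 <- m; m2[2, 2, 2] <- 0
  e2 <- erode_inplane(m2)
  expect_identical(e2[, , 1], e[, , 1])
  expect_identical(sum(erode_inplane(array(0, c(4, 4, 2)))), 0L)
})

test_that("NAWM ROI is roi AND wm AND NOT lesions", {
  shape <- c(4, 4, 1)
  roi <- array(0L, shape); roi[1:2, 1:4, 1] <- 1L          # 8 voxels
  wm <- array(0L, shape); wm[1:2, 1:3, 1] <- 1L            # covers 6 of them
  les <- array(0L, shape); les[1:2, 1, 1] <- 1L            # 2 of those
  nawm <- build_nawm_roi(roi, wm, les)
  expect_identical(sum(nawm), 4L)

  expect_identical(sum(build_nawm_roi(roi, wm, NULL)), 6L)
  expect_warning(empty <- build_nawm_roi(roi, wm, roi), "empty")
  expect_identical(sum(empty), 0L)
  expect_error(build_nawm_roi(roi, array(1L, c(5, 5, 1))), "shapes")
})

test_that("affine mismatches between masks are refused", {
  shape <- c(3, 3, 1)
  a <- array(1L, shape); attr(a, "affine") <- diag(4)
  b <- array(1L, shape); attr(b, "affine") <- diag(c(2, 2, 2, 1))
  expect_error(build_nawm_roi(a, b), "affine")
})

test_that("MHI is the coefficient of variation of in-ROI MWF", {
  m <- array(NaN, c(2, 1, 1)); m[] <- c(0.1, 0.2)
  r <- array(1L, c(2, 1, 1))
  st <- compute_mhi(m, r, min_voxels = 2)
  expect_equal(st$mean_mwf, 0.15, tolerance = 1e-12)
  expect_equal(st$sd_mwf, 0.070711, tolerance = 1e-5)   # n-1 denominator
  expect_equal(st$mhi, 0.471405, tolerance = 1e-5)

  # zero variance -> MHI 0; scale invariance of the CV
  mc <- array(0.1, c(60, 1, 1)); rc <- array(1L, c(60, 1, 1))
  expect_identical(compute_mhi(mc, rc)$mhi, 0)
  set.seed(9)
  mv <- array(runif(60, 0.05, 0.2), c(60, 1, 1))
  h1 <- compute_mhi(mv, rc)$mhi
  h3 <- compute_mhi(mv * 3, rc)$mhi
  expect_equal(h1, h3, tolerance = 1e-12)
})

test_that("MHI responds correctly to mean and SD changes", {
  rc <- array(1L, c(100, 1, 1))
  set.seed(12)
  base <- runif(100, 0.08, 0.16)
  h0 <- compute_mhi(array(base, c(100, 1, 1)), rc)$mhi
  # lower mean at fixed SD -> larger MHI
  h_lower_mean <- compute_mhi(array(base - 0.03, c(100, 1, 1)), rc)$mhi
  expect_gt(h_lower_mean, h0)
  # larger SD at fixed mean -> larger MHI
  spread <- mean(base) + 2 * (base - mean(base))
  h_spread <- compute_mhi(array(spread, c(100, 1, 1)), rc)$mhi
  expect_gt(h_spread, h0)
})

test_that("undersized or degenerate ROIs yield NaN MHI with a warning", {
  m <- array(0.1, c(10, 1, 1)); r <- array(1L, c(10, 1, 1))
  expect_warning(st <- compute_mhi(m, r, min_voxels = 50), "min_voxels")
  expect_true(is.nan(st$mhi))
  expect_identical(st$n_voxels, 10L)

  mn <- array(NaN, c(10, 1, 1))
  expect_warning(st2 <- compute_mhi(mn, r), "no finite")
  expect_true(is.nan(st2$mhi))

  # NaN voxels are excluded before statistics
  mm <- array(NaN, c(60, 1, 1)); mm[1:55] <- 0.1
  rr <- array(1L, c(60, 1, 1))
  st3 <- compute_mhi(mm, rr)
  expect_identical(st3$n_voxels, 55L)
  expect_equal(st3$mean_mwf, 0.1, tolerance = 1e-12)
})

test_that("roi_stats assembles per-ROI rows with lesion subtraction", {
  shape <- c(8, 8, 1)
  wm <- array(1L, shape)
  roi_a <- array(0L, shape); roi_a[2:7, 2:4, 1] <- 1L
  roi_b <- array(0L, shape); roi_b[2:7, 5:7, 1] <- 1L
  mwf <- array(0.12, shape)
  tab <- suppressWarnings(
    roi_stats(mwf, wm, list(a = roi_a, b = roi_b), min_voxels = 2,
              subject_id = "s1"))
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$subject_id, c("s1", "s1"))
  # eroded WM (8x8 slice -> 6x6 interior) clips the ROIs
  expect_identical(tab$n_voxels, c(sum(roi_a[2:7, 2:4, 1]), sum(roi_b[2:7, 5:7, 1])))
  expect_equal(tab$mhi, c(0, 0), tolerance = 1e-12)
})
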