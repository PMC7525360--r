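sq <- grase_sequence()

test_that("phantom generation is bit-identical under the same seed", {
  ps <- phantom_spec(shape = c(8L, 8L, 2L), snr = 100, seed = 5L)
  a <- generate_phantom(ps, sq)
  b <- generate_phantom(ps, sq)
  expect_identical(a$volume4d, b$volume4d)
  expect_identical(a$truth$mwf, b$truth$mwf)
  c_ <- generate_phantom(phantom_spec(shape = c(8L, 8L, 2L), snr = 100,
                                      seed = 6L), sq)
  expect_false(identical(a$volume4d, c_$volume4d))
})

test_that("noiseless constant-MWF phantom voxels follow the closed-form decay", {
  ps <- phantom_spec(
    shape = c(4L, 4L, 1L),
    regions = list(list(label = "wm", geometry = geom_box(c(1, 1, 1), c(4, 4, 1)),
                        mwf_mean = 0.15, mwf_sd = 0)),
    flip_field = 180, snr = Inf, seed = 1L)
  ph <- generate_phantom(ps, sq)
  tt <- echo_times(sq)
  expected <- 0.15 * exp(-tt / 0.02) + 0.85 * exp(-tt / 0.08)
  for (i in 1:4) for (j in 1:4)
    expect_equal(ph$volume4d[i, j, 1, ], expected, tolerance = 1e-12)
  expect_identical(ph$noise_sd, 0)
})

test_that("generated region SD/mean matches the spec ratio at large voxel counts", {
  ps <- phantom_spec(shape = c(16L, 16L, 8L),
                     regions = list(list(label = "wm",
                                         geometry = geom_box(c(1, 1, 1), c(16, 16, 8)),
                                         mwf_mean = 0.12, mwf_sd = 0.024)),
                     snr = Inf, seed = 9L)
  ph <- generate_phantom(ps, sq)
  v <- ph$truth$mwf[ph$masks$wm > 0]
  expect_gte(length(v), 2000)
  cv <- sd(v) / mean(v)
  expect_lt(abs(cv - 0.024 / 0.12), 0.02)
})

test_that("later regions win overlaps and lesions override tissue", {
  ps <- phantom_spec(
    shape = c(6L, 6L, 1L),
    regions = list(
      list(label = "a", geometry = geom_box(c(1, 1, 1), c(6, 6, 1)),
           mwf_mean = 0.10, mwf_sd = 0),
      list(label = "b", geometry = geom_box(c(1, 1, 1), c(3, 6, 1)),
           mwf_mean = 0.20, mwf_sd = 0)),
    lesions = list(list(geometry = geom_box(c(5, 5, 1), c(6, 6, 1)),
                        mwf_mean = 0.04, mwf_sd = 0)),
    snr = Inf, seed = 2L)
  ph <- suppressMessages(generate_phantom(ps, sq))
  expect_equal(ph$truth$mwf[2, 2, 1], 0.20)   # region b overwrote a
  expect_equal(ph$truth$mwf[5, 2, 1], 0.10)
  expect_equal(ph$truth$mwf[5, 5, 1], 0.04)   # lesion overrode tissue
  expect_identical(sum(ph$masks$lesions), 4L)
})

test_that("cohort generation honors the null, the target r, and missingness", {
  null_tests <- list(sdmt = list(control_mean = 62, control_sd = 10,
                                 patient_mean = 56, b = 0, missingness = 0))
  rs <- vapply(1:60, function(i) {
    tab <- generate_cohort(cohort_spec(tests = null_tests, target_r = NULL,
                                       seed = i))
    ms <- tab[tab$group == "MS", ]
    cor(ms$mhi_slf, ms$sdmt)
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.05)

  rs2 <- vapply(1:200, function(i) {
    tab <- generate_cohort(cohort_spec(seed = 1000L + i))
    ms <- tab[tab$group == "MS", ]
    cor(ms$mhi_slf, ms$sdmt, use = "complete.obs")
  }, numeric(1))
  expect_lt(abs(mean(rs2) - (-0.49)), 0.04)

  tabs <- lapply(1:50, function(i) generate_cohort(cohort_spec(seed = 2000L + i)))
  bv_complete <- mean(vapply(tabs, function(t) mean(is.finite(t$bvmtr)),
                             numeric(1)))
  expect_lt(abs(bv_complete - 0.86), 0.05)

  expect_error(cohort_spec(target_r = 0), "target_r")
})

test_that("cohort tables are well-formed and deterministic", {
  tab <- generate_cohort(cohort_spec(seed = 3L))
  expect_identical(nrow(tab), 95L)
  expect_identical(anyDuplicated(tab$subject_id), 0L)
  expect_setequal(unique(tab$group), c("MS", "control"))
  expect_true(all(c("mhi_slf", "mhi_cc", "mhi_cingulum", "sdmt") %in% names(tab)))
  expect_true(all(tab$mhi_slf > 0))
  expect_identical(tab, generate_cohort(cohort_spec(seed = 3L)))
})

test_that("the toy fixture regenerates bit-identically and is internally consistent", {
  fx1 <- make_toy_fixture()
  fx2 <- make_toy_fixture()
  expect_identical(fx1$phantom$volume4d, fx2$phantom$volume4d)
  expect_identical(fx1$cohort, fx2$cohort)
  expect_setequal(setdiff(names(fx1$phantom$masks), c("wm", "lesions")),
                  c("cingulum", "slf", "cc"))
  expect_gt(sum(fx1$phantom$masks$lesions), 0)
  # lesion voxels sit inside the slf box
  expect_true(all(fx1$phantom$masks$slf[fx1$phantom$masks$lesions > 0] == 1))

  # lesion subtraction removes exactly the overlap from the NAWM ROI
  wm_e <- erode_inplane(fx1$phantom$masks$wm)
  with_les <- build_nawm_roi(fx1$phantom$masks$slf, wm_e,
                             fx1$phantom$masks$lesions)
  without <- build_nawm_roi(fx1$phantom$masks$slf, wm_e, NULL)
  overlap <- sum(without * fx1$phantom$masks$lesions)
  expect_identical(sum(without) - sum(with_les), overlap)
  expect_gt(overlap, 0)
})

test_that("Rician noise keeps magnitudes non-negative with the expected floor", {
  base <- phantom_spec(shape = c(6L, 6L, 2L), snr = 50, seed = 13L)
  ric <- phantom_spec(shape = c(6L, 6L, 2L), snr = 50,
                      noise_model = "rician", seed = 13L)
  vr <- generate_phantom(ric, sq)$volume4d
  expect_true(all(vr >= 0))
  # late echoes (near-zero true signal) average above zero under Rician noise
  vg <- generate_phantom(base, sq)$volume4d
  expect_gt(mean(vr[, , , 48]), mean(vg[, , , 48]))
})
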