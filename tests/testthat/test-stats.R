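test_that("Pearson correlation handles perfect and hand-computed cases", {
  res <- pearson_with_ci(c(1, 2, 3), c(6, 4, 2))
  expect_equal(res$r, -1, tolerance = 1e-12)
  expect_identical(res$p, 0)
  expect_equal(res$ci_low, -1)
  expect_equal(res$ci_high, -1)

  res2 <- pearson_with_ci(c(1, 2, 3), c(1, 3, 2))
  expect_equal(res2$r, 0.5, tolerance = 1e-12)

  expect_warning(bad <- pearson_with_ci(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_true(is.na(bad$r))
  expect_warning(pearson_with_ci(c(1, 2), c(3, 4)), "fewer than 3")
})

test_that("two-sided p matches numerical integration of the t density", {
  res <- pearson_with_ci(c(1, 2, 3), c(1, 3, 2))   # r = 0.5, df = 1
  tstat <- 0.5 * sqrt(1 / (1 - 0.25))
  p_quad <- 2 * integrate(function(u) dt(u, df = 1), tstat, Inf)$value
  expect_equal(res$p, p_quad, tolerance = 1e-6)

  set.seed(4)
  x <- rnorm(20); y <- 0.4 * x + rnorm(20)
  res2 <- pearson_with_ci(x, y)
  t2 <- res2$r * sqrt(18 / (1 - res2$r^2))
  p2 <- 2 * integrate(function(u) dt(u, df = 18), abs(t2), Inf)$value
  expect_equal(res2$p, p2, tolerance = 1e-6)
  # agreement with the standard implementation
  ct <- cor.test(x, y)
  expect_equal(res2$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res2$p, ct$p.value, tolerance = 1e-12)
  expect_equal(c(res2$ci_low, res2$ci_high), as.numeric(ct$conf.int),
               tolerance = 1e-12)
})

test_that("correlation is symmetric and affine-invariant", {
  set.seed(6)
  x <- rnorm(30); y <- -0.5 * x + rnorm(30)
  a <- pearson_with_ci(x, y); b <- pearson_with_ci(y, x)
  expect_equal(a$r, b$r, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
  c2 <- pearson_with_ci(3 * x - 7, 0.5 * y + 11)
  expect_equal(a$r, c2$r, tolerance = 1e-12)
  expect_equal(c(a$ci_low, a$ci_high), c(c2$ci_low, c2$ci_high),
               tolerance = 1e-12)
})

test_that("Bonferroni thresholds divide the family level, displayed truncated", {
  b3 <- bonferroni_alpha(0.05, 3)
  expect_equal(b3$alpha, 0.05 / 3, tolerance = 1e-12)
  expect_equal(b3$alpha_display, 0.016, tolerance = 1e-12)
  expect_identical(b3$display, ".016")
  expect_equal(bonferroni_alpha(0.05, 1)$alpha, 0.05)
  expect_equal(bonferroni_alpha(0.05, 5)$alpha, 0.01)
  expect_error(bonferroni_alpha(0.05, 0), "m")
})

test_that("z-scores are control-referenced and standardization-invariant", {
  expect_equal(cognitive_z_scores(70, c(40, 60)), sqrt(2), tolerance = 1e-5)
  expect_equal(cognitive_z_scores(50, c(40, 60)), 0)
  ctrl <- c(41, 55, 62, 48, 59)
  z1 <- cognitive_z_scores(c(50, 70), ctrl)
  z2 <- cognitive_z_scores(2 * c(50, 70) + 3, 2 * ctrl + 3)
  expect_equal(z1, z2, tolerance = 1e-12)
  expect_error(cognitive_z_scores(1, c(5)), "at least 2")
  expect_warning(z <- cognitive_z_scores(1, c(5, 5)), "zero control SD")
  expect_true(all(is.nan(z)))
})

test_that("group comparisons: Welch t, chi-squared on sex, assumption flags", {
  tab <- data.frame(
    group = rep(c("MS", "control"), each = 10),
    age = c(1:10, 1:10), education = c(1:10, 11:20),
    sex = rep(c("F", "M"), 10))
  gc <- group_comparisons(tab)
  age_row <- gc$continuous[gc$continuous$variable == "age", ]
  expect_equal(age_row$t, 0, tolerance = 1e-12)
  expect_equal(age_row$p, 1, tolerance = 1e-12)
  edu_row <- gc$continuous[gc$continuous$variable == "education", ]
  expect_gt(abs(edu_row$t), 5)
  expect_lt(edu_row$p, 0.001)

  # chi-squared against direct computation from expected counts,
  # sex table 14 F / 8 M in controls vs 48 F / 25 M in patients
  counts <- matrix(c(14, 48, 8, 25), 2, dimnames = list(c("control", "MS"),
                                                        c("F", "M")))
  long <- data.frame(
    group = rep(rep(c("control", "MS"), 2), times = as.vector(counts)),
    sex = rep(c("F", "F", "M", "M"), times = as.vector(counts)),
    age = 0, education = 0)
  long$age <- rnorm(nrow(long)); long$education <- rnorm(nrow(long))
  gc2 <- group_comparisons(long)
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  chi2_hand <- sum((counts - expected)^2 / expected)
  expect_equal(gc2$sex$statistic, chi2_hand, tolerance = 1e-10)
  expect_identical(gc2$sex$df, 1L)

  expect_error(group_comparisons(data.frame(group = c("a", "a", "b"),
                                            age = 1:3, sex = "F")),
               ">= 2")
})

test_that("non-normal data raises the assumption flag and adds Mann-Whitney", {
  set.seed(8)
  tab <- data.frame(group = rep(c("MS", "control"), each = 30),
                    age = c(rexp(30, 0.1)^2, rnorm(30, 50, 2)),
                    sex = "F")
  gc <- group_comparisons(tab, variables = "age")
  expect_false(gc$continuous$assumptions_ok[1])
  expect_true(is.finite(gc$continuous$mann_whitney_p[1]))
})

test_that("the correlation matrix applies per-domain Bonferroni and listwise deletion", {
  spec1 <- cohort_spec(seed = 42L)
  tab <- generate_cohort(spec1)
  res <- run_correlation_matrix(tab, rois = c("slf", "cc", "cingulum"),
                                tests = c("sdmt", "srt"))
  expect_identical(nrow(res), 2L * 2L * 3L)
  expect_true(all(abs(res$alpha_adjusted - 0.05 / 3) < 1e-12))
  # listwise deletion: srt pair counts reflect missing scores
  ms_srt <- res[res$group == "MS" & res$test == "srt", ]
  expect_true(all(ms_srt$n == sum(is.finite(tab$srt[tab$group == "MS"]))))
  expect_true(all(res$significant == (res$p < res$alpha_adjusted)))

  res1 <- run_correlation_matrix(tab, rois = "slf", tests = "sdmt",
                                 family_alpha = 0.05)
  expect_equal(unique(res1$alpha_adjusted), 0.05, tolerance = 1e-12)

  # missing column combinations are skipped with a log entry
  res2 <- run_correlation_matrix(tab, rois = c("slf", "nope"), tests = "sdmt")
  expect_true(any(grepl("nope", attr(res2, "skipped"))))
})
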