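#' Pearson correlation with Fisher-z confidence interval
#'
#' Product-moment correlation between two paired vectors, with a two-sided
#' p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom and a confidence interval from the Fisher z transform with the
#' normal quantile (the construction used by [stats::cor.test()]).
#' Incomplete pairs are dropped listwise.
#'
#' Edge cases: a perfect correlation (`|r| = 1`) gives `p = 0` and a
#' degenerate interval at `r`; the interval requires `n >= 4` and is `NA`
#' otherwise; zero variance in either variable leaves everything undefined
#' with a warning.
#'
#' @param x,y paired numeric vectors.
#' @param conf confidence level (default 0.95).
#' @param alpha_adjusted significance threshold used for the `significant`
#'   flag (e.g. a Bonferroni-corrected level).
#' @return one-row data.frame: `n`, `r`, `ci_low`, `ci_high`, `p`,
#'   `alpha_adjusted`, `significant`.
#' @examples
#' pearson_with_ci(c(1, 2, 3, 4), c(2, 4, 5, 9))
#' @export
pearson_with_ci <- function(x, y, conf = 0.95, alpha_adjusted = 0.05) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  out <- data.frame(n = n, r = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, p = NA_real_,
                    alpha_adjusted = alpha_adjusted, significant = NA)
  if (n < 3L) {
    warning("fewer than 3 complete pairs: correlation undefined", call. = FALSE)
    return(out)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined", call. = FALSE)
    return(out)
  }
  r <- stats::cor(x, y)
  out$r <- r
  if (abs(r) >= 1 - 1e-14) {
    # perfect linear association: t statistic diverges
    out$p <- 0
    out$ci_low <- out$ci_high <- sign(r)
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    out$p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    if (n >= 4L) {
      z <- atanh(r)
      half <- stats::qnorm(1 - (1 - conf) / 2) / sqrt(n - 3)
      out$ci_low <- tanh(z - half)
      out$ci_high <- tanh(z + half)
    }
  }
  out$significant <- is.finite(out$p) && out$p < alpha_adjusted
  out
}

#' Bonferroni-adjusted significance threshold
#'
#' Divides the family-wise level by the number of comparisons. Also returns
#' the threshold truncated to three decimals, the display convention used
#' when reporting e.g. `alpha/3` as ".016".
#'
#' @param family_alpha family-wise level in (0, 1).
#' @param m number of comparisons (>= 1).
#' @return list with `alpha` (exact) and `alpha_display` (truncated to three
#'   decimals, as a number) plus `display` (formatted string).
#' @examples
#' bonferroni_alpha(0.05, 3)  # alpha 0.016667, displayed ".016"
#' @export
bonferroni_alpha <- function(family_alpha, m) {
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("m must be >= 1", call. = FALSE)
  if (!is.finite(family_alpha) || family_alpha <= 0 || family_alpha >= 1)
    stop("family_alpha must lie in (0, 1)", call. = FALSE)
  a <- family_alpha / m
  trunc3 <- floor(a * 1000) / 1000
  list(alpha = a, alpha_display = trunc3,
       display = sub("^0", "", sprintf("%.3f", trunc3)))
}

#' Control-referenced cognitive z-scores
#'
#' Standardizes scores against the control sample: `z = (score - control
#' mean) / control SD` (sample SD). Negative z means performance below the
#' control average.
#'
#' @param scores numeric scores to standardize.
#' @param control_scores scores of the control group (>= 2 finite values).
#' @return numeric vector of z-scores (NA where `scores` is NA).
#' @export
cognitive_z_scores <- function(scores, control_scores) {
  cs <- control_scores[is.finite(control_scores)]
  if (length(cs) < 2L)
    stop("need at least 2 finite control scores", call. = FALSE)
  m <- mean(cs); s <- stats::sd(cs)
  if (s == 0) {
    warning("zero control SD: z-scores undefined", call. = FALSE)
    return(rep(NaN, length(scores)))
  }
  (scores - m) / s
}

#' Group comparison report for a cohort table
#'
#' Compares the two groups on the continuous demographics with the Welch
#' (unequal-variance, Satterthwaite) t test and on sex with a Pearson
#' chi-squared test (no continuity correction by default). Shapiro-Wilk
#' normality (per group) and Levene homogeneity-of-variance p-values
#' (centered on the mean, as in SPSS) are reported per variable as
#' assumption flags; when either assumption fails at `assumption_alpha`,
#' the Mann-Whitney (Wilcoxon rank-sum) p-value is reported alongside.
#'
#' @param table cohort data.frame with a `group` column ("MS"/"control")
#'   and a `sex` column, plus the continuous variables.
#' @param variables continuous variables to compare (default age and
#'   education).
#' @param yates apply Yates continuity correction to the chi-squared test.
#' @param assumption_alpha level at which an assumption flag is raised.
#' @return list with `continuous` (data.frame: variable, group means, Welch
#'   t, df, p, shapiro p per group, levene p, assumptions_ok flag,
#'   mann_whitney_p) and `sex` (chi-squared statistic, df, p, counts).
#' @export
group_comparisons <- function(table, variables = c("age", "education"),
                              yates = FALSE, assumption_alpha = 0.05) {
  if (!all(c("group") %in% names(table)))
    stop("table needs a 'group' column", call. = FALSE)
  groups <- sort(unique(as.character(table$group)))
  if (length(groups) != 2L)
    stop("exactly two groups required", call. = FALSE)
  g1 <- table$group == groups[1]; g2 <- table$group == groups[2]

  rows <- lapply(intersect(variables, names(table)), function(v) {
    x <- table[[v]][g1]; y <- table[[v]][g2]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 2L || length(y) < 2L)
      stop(sprintf("variable '%s': each group needs >= 2 values for the t test", v),
           call. = FALSE)
    tt <- stats::t.test(x, y, var.equal = FALSE)
    sw1 <- tryCatch(stats::shapiro.test(x)$p.value, error = function(e) NA_real_)
    sw2 <- tryCatch(stats::shapiro.test(y)$p.value, error = function(e) NA_real_)
    lev <- car::leveneTest(c(x, y),
                           factor(rep(groups, c(length(x), length(y)))),
                           center = mean)
    lev_p <- lev[["Pr(>F)"]][1]
    ok <- all(c(sw1, sw2, lev_p) > assumption_alpha, na.rm = TRUE)
    mw <- if (!ok)
      suppressWarnings(stats::wilcox.test(x, y)$p.value) else NA_real_
    data.frame(variable = v,
               mean_1 = mean(x), mean_2 = mean(y),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value,
               shapiro_p_1 = sw1, shapiro_p_2 = sw2, levene_p = lev_p,
               assumptions_ok = ok, mann_whitney_p = mw,
               stringsAsFactors = FALSE)
  })
  continuous <- do.call(rbind, rows)

  sex <- NULL
  if ("sex" %in% names(table)) {
    tab <- base::table(table$group, table$sex)
    cs <- stats::chisq.test(tab, correct = yates)
    sex <- list(statistic = unname(cs$statistic), df = unname(cs$parameter),
                p = cs$p.value, counts = tab)
  }
  list(groups = groups, continuous = continuous, sex = sex)
}

#' Per-ROI, per-test correlation matrix
#'
#' Runs [pearson_with_ci()] for every (group, cognitive test, ROI)
#' combination in a cohort table, with the Bonferroni threshold across the
#' ROIs applied within each cognitive domain. Subjects missing either value
#' in a pair are dropped listwise for that pair only, so the pair counts
#' mirror differing test completion.
#'
#' Expects MHI columns named `mhi_<roi>` and test scores in columns named
#' after each test.
#'
#' @param table cohort data.frame (see [generate_cohort()]).
#' @param rois ROI labels, e.g. `c("cingulum", "slf", "cc")`.
#' @param tests cognitive test column names.
#' @param family_alpha family-wise level per cognitive domain.
#' @param groups group labels to analyze.
#' @param conf confidence level for the Fisher interval.
#' @return data.frame with one row per (group, test, roi): `n`, `r`,
#'   `ci_low`, `ci_high`, `p`, `alpha_adjusted`, `significant`. Skipped
#'   (empty) combinations are recorded in the `skipped` attribute.
#' @export
run_correlation_matrix <- function(table, rois, tests, family_alpha = 0.05,
                                   groups = c("MS", "control"), conf = 0.95) {
  alpha_adj <- bonferroni_alpha(family_alpha, length(rois))$alpha
  rows <- list(); skipped <- character(0)
  for (g in groups) {
    sub <- table[table$group == g, , drop = FALSE]
    for (te in tests) {
      for (ro in rois) {
        mcol <- paste0("mhi_", ro)
        if (!all(c(mcol, te) %in% names(sub))) {
          skipped <- c(skipped, sprintf("%s/%s/%s: missing column", g, te, ro))
          next
        }
        ok <- is.finite(sub[[mcol]]) & is.finite(sub[[te]])
        if (sum(ok) < 3L) {
          skipped <- c(skipped, sprintf("%s/%s/%s: <3 complete pairs", g, te, ro))
          next
        }
        res <- pearson_with_ci(sub[[mcol]][ok], sub[[te]][ok], conf = conf,
                               alpha_adjusted = alpha_adj)
        rows[[length(rows) + 1L]] <-
          cbind(data.frame(group = g, test = te, roi = ro,
                           stringsAsFactors = FALSE), res)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group = character(0), test = character(0), roi = character(0))
  attr(out, "skipped") <- skipped
  out
}
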