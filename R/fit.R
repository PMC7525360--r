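#' Decay basis matrix for spectrum fitting
#'
#' Column `j` is the EPG echo train of a unit-amplitude species with
#' `grid$t2[j]`, at the given refocusing flip angle and the sequence's
#' assumed T1. The measured voxel signal is modelled as a non-negative
#' combination of these columns.
#'
#' @param grid a [t2_grid()].
#' @param refocus_flip refocusing flip angle in degrees, in (0, 180].
#' @param seq a [grase_sequence()].
#' @return `n_echoes x n_points` matrix.
#' @export
build_basis <- function(grid, refocus_flip, seq) {
  stopifnot(inherits(grid, "t2_grid"), inherits(seq, "grase_sequence"))
  if (!is.finite(refocus_flip) || refocus_flip <= 0 || refocus_flip > 180)
    stop("refocus_flip must lie in (0, 180] degrees", call. = FALSE)
  epg_decay_matrix(grid$t2, seq$t1_assumed, refocus_flip, seq)
}

#' Non-negative least-squares spectrum fit
#'
#' Solves `min ||B x - y||^2` subject to `x >= 0` by the Lawson-Hanson
#' active-set algorithm (compiled kernel). This is the unregularized core of
#' the T2 spectrum fit.
#'
#' @param signal numeric decay curve, length `nrow(basis)`.
#' @param basis decay basis matrix from [build_basis()].
#' @return list with `spectrum` (non-negative amplitudes, one per basis
#'   column) and `chi2` (attained squared misfit).
#' @export
fit_nnls <- function(signal, basis) {
  signal <- as.numeric(signal)
  if (!is.matrix(basis)) basis <- as.matrix(basis)
  if (length(signal) != nrow(basis))
    stop("signal length must equal nrow(basis)", call. = FALSE)
  if (!all(is.finite(signal)) || !all(is.finite(basis)))
    stop("signal and basis must be finite", call. = FALSE)
  if (all(signal == 0))
    return(list(spectrum = numeric(ncol(basis)), chi2 = 0))
  fit <- .nnls_lh(basis, signal)
  list(spectrum = as.numeric(fit$x), chi2 = as.numeric(fit$chi2))
}

#' Regularized non-negative least-squares spectrum fit
#'
#' Solves `min ||B x - y||^2 + mu ||x||^2` with `x >= 0`, implemented by
#' augmenting the design with `sqrt(mu) * I` rows and zero targets. The
#' ridge weight `mu` is chosen so that the *data* misfit `||B x - y||^2`
#' lands inside `chi2_window * chi2_min`, where `chi2_min` is the
#' unregularized misfit: the conventional misfit-window rule for smoothing
#' T2 spectra. The search brackets `mu` geometrically and bisects in
#' `log(mu)`; among all window-satisfying weights encountered, the smallest
#' is returned.
#'
#' A noiseless exactly-representable signal has `chi2_min = 0`, leaving the
#' window empty; the unregularized solution is returned with `mu = 0` and
#' `note = "unregularized"`.
#'
#' @param signal numeric decay curve.
#' @param basis decay basis matrix.
#' @param chi2_window numeric `c(low, high)` with `1 <= low < high`:
#'   admissible data-misfit inflation relative to `chi2_min`.
#' @param max_iter maximum bracket/bisection steps.
#' @return list with `spectrum`, `mu`, `chi2` (data misfit of the returned
#'   solution), `chi2_min`, `in_window` (logical) and `note`.
#' @export
fit_nnls_regularized <- function(signal, basis, chi2_window = c(1.02, 1.025),
                                 max_iter = 60L) {
  if (length(chi2_window) != 2L || chi2_window[1] < 1 ||
      chi2_window[2] <= chi2_window[1])
    stop("chi2_window must be c(low, high) with 1 <= low < high", call. = FALSE)
  base <- fit_nnls(signal, basis)
  chi2_min <- base$chi2
  p <- ncol(basis)

  # exactly representable: no admissible window, return unregularized
  if (chi2_min <= 1e-12 * max(sum(signal^2), .Machine$double.eps)) {
    return(list(spectrum = base$spectrum, mu = 0, chi2 = chi2_min,
                chi2_min = chi2_min, in_window = TRUE,
                note = "unregularized (chi2_min ~ 0)"))
  }

  aug_fit <- function(mu) {
    A <- rbind(basis, diag(sqrt(mu), p))
    f <- .nnls_lh(A, c(signal, numeric(p)))
    x <- as.numeric(f$x)
    r <- basis %*% x - signal
    list(spectrum = x, chi2 = sum(r * r))
  }

  lo <- chi2_window[1] * chi2_min
  hi <- chi2_window[2] * chi2_min
  best <- NULL   # smallest in-window mu seen
  consider <- function(mu, f) {
    if (f$chi2 >= lo && f$chi2 <= hi && (is.null(best) || mu < best$mu))
      best <<- list(spectrum = f$spectrum, mu = mu, chi2 = f$chi2)
  }

  # geometric bracket: grow mu until the data misfit exceeds the window
  mu_scale <- mean(colSums(basis^2))
  mu_lo <- 1e-8 * mu_scale          # misfit ~ chi2_min here
  f <- aug_fit(mu_lo)
  it <- 0L
  while (f$chi2 > hi && mu_lo > 1e-300) {   # start already above window
    mu_lo <- mu_lo / 100; f <- aug_fit(mu_lo); it <- it + 1L
    if (it > 20L) break
  }
  consider(mu_lo, f)
  mu_hi <- mu_lo
  f_hi <- f
  while (f_hi$chi2 < lo && it < max_iter) {
    mu_hi <- mu_hi * 4; f_hi <- aug_fit(mu_hi); it <- it + 1L
    consider(mu_hi, f_hi)
  }

  # bisection in log(mu); data misfit is monotone increasing in mu
  if (is.null(best)) {
    a <- mu_lo; b <- mu_hi
    while (it < max_iter) {
      m <- sqrt(a * b)
      fm <- aug_fit(m); it <- it + 1L
      consider(m, fm)
      if (!is.null(best)) break
      if (fm$chi2 < lo) a <- m else b <- m
      if (b / a < 1 + 1e-12) break
    }
  }

  if (is.null(best)) {
    # window could not be hit within the iteration budget; return the
    # closest bracket end and flag it
    f_final <- aug_fit(mu_hi)
    return(list(spectrum = f_final$spectrum, mu = mu_hi, chi2 = f_final$chi2,
                chi2_min = chi2_min, in_window = FALSE,
                note = "misfit window not attained"))
  }
  list(spectrum = best$spectrum, mu = best$mu, chi2 = best$chi2,
       chi2_min = chi2_min, in_window = TRUE, note = "")
}

#' Estimate the refocusing flip angle from a decay curve
#'
#' The effective refocusing flip varies across the brain (B1
#' inhomogeneity); fitting with the wrong flip biases the spectrum. The
#' flip is estimated from the decay curve itself: each candidate angle gets
#' an EPG basis, the candidate minimizing the unregularized NNLS misfit
#' wins, and one parabolic refinement step over the three best candidates
#' sharpens the estimate (clamped to the candidate range). Ties are broken
#' toward the larger angle.
#'
#' @param signal numeric decay curve.
#' @param grid a [t2_grid()].
#' @param seq a [grase_sequence()].
#' @param candidates candidate flip angles in degrees, each in (0, 180].
#' @param bases optional precomputed list of basis matrices, one per
#'   candidate (used by [fit_volume()] to share bases across voxels).
#' @return estimated flip angle in degrees.
#' @export
estimate_flip <- function(signal, grid, seq, candidates = seq(90, 180, by = 5),
                          bases = NULL) {
  if (length(candidates) == 0L)
    stop("candidates must be non-empty", call. = FALSE)
  if (any(candidates <= 0 | candidates > 180))
    stop("candidate flips must lie in (0, 180]", call. = FALSE)
  if (is.null(bases))
    bases <- lapply(candidates, function(a) build_basis(grid, a, seq))
  chi2 <- vapply(seq_along(candidates),
                 function(i) fit_nnls(signal, bases[[i]])$chi2, numeric(1))
  best <- max(which(chi2 == min(chi2)))   # tie -> larger angle
  if (length(candidates) < 3L) return(candidates[best])
  # refinement only sharpens an interior minimum; a boundary winner (the
  # global minimum sits at the edge of the search range) is returned as is
  if (best == 1L || best == length(candidates)) return(candidates[best])

  ord <- order(chi2, -candidates)[1:3]
  a <- candidates[ord]; f <- chi2[ord]
  # parabola through the three best (angle, misfit) pairs
  d <- (a[1] - a[2]) * (a[1] - a[3]) * (a[2] - a[3])
  A <- (a[3] * (f[2] - f[1]) + a[2] * (f[1] - f[3]) + a[1] * (f[3] - f[2])) / d
  B <- (a[3]^2 * (f[1] - f[2]) + a[2]^2 * (f[3] - f[1]) + a[1]^2 * (f[2] - f[3])) / d
  if (!is.finite(A) || A <= 0) return(candidates[best])
  vertex <- -B / (2 * A)
  min(max(vertex, min(candidates)), max(candidates))
}

#' Myelin water fraction of a T2 spectrum
#'
#' MWF is the ratio of the area under the T2 distribution at times strictly
#' below the cutoff (default 40 ms) to the total area. The comparison is
#' strict and applied to the grid node values; amplitude sitting exactly at
#' the cutoff does not count as myelin water.
#'
#' @param spectrum non-negative amplitude vector aligned to `grid`.
#' @param grid a [t2_grid()].
#' @param cutoff myelin/intra-extracellular boundary in seconds.
#' @return fraction in `[0, 1]`, or `NaN` (with a warning) if the spectrum
#'   has zero total amplitude.
#' @examples
#' g <- t2_grid(n_points = 3, t2_min = 0.02, t2_max = 0.2)
#' compute_mwf(c(1, 0, 0), g)  # all amplitude below 40 ms -> 1
#' @export
compute_mwf <- function(spectrum, grid, cutoff = 0.040) {
  stopifnot(inherits(grid, "t2_grid"))
  spectrum <- as.numeric(spectrum)
  if (length(spectrum) != grid$n_points)
    stop("spectrum length must equal grid$n_points", call. = FALSE)
  total <- sum(spectrum)
  if (!is.finite(total) || total <= 0) {
    warning("zero total spectrum amplitude: MWF undefined", call. = FALSE)
    return(NaN)
  }
  sum(spectrum[grid$t2 < cutoff]) / total
}
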