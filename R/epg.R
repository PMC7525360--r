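#' @title Extended phase graph forward model for a CPMG echo train
#'
#' @description
#' Computes the echo-top amplitudes of a multi-echo spin-echo train for a
#' single T2 species when the refocusing pulses deviate from 180 deg, using
#' the extended phase graph (EPG) formalism. Imperfect refocusing stores
#' magnetization in longitudinal configuration states that later return as
#' stimulated echoes, so the measured decay is not mono-exponential; the EPG
#' recursion tracks every dephased transverse (`F+`, `F-`) and longitudinal
#' (`Z`) configuration order through the train.
#'
#' Conventions: ideal 90 deg excitation with the transverse magnetization
#' along the refocusing axis (CPMG condition, refocusing about y); crushers
#' impart one unit of dephasing per half echo-spacing; relaxation acts over
#' each half interval with no longitudinal recovery term; `n_echoes + 1`
#' configuration orders are retained, which is exact for this train length.
#' At `refocus_flip = 180` the recursion collapses to
#' `exp(-n * echo_spacing / t2)` to machine precision and is independent of
#' `t1`.
#'
#' @param t2 transverse relaxation time in seconds (> 0).
#' @param t1 longitudinal relaxation time in seconds (> 0).
#' @param refocus_flip refocusing flip angle in degrees, in (0, 180].
#' @param seq a [grase_sequence()].
#' @return numeric vector of `seq$n_echoes` non-negative echo amplitudes,
#'   normalized so the signal immediately after ideal excitation is 1.
#' @examples
#' sq <- grase_sequence()
#' epg_decay_curve(0.02, 1, 180, sq)[1]  # = exp(-0.008/0.02)
#' epg_decay_curve(0.08, 1, 120, sq)[1]  # < exp(-0.1): stimulated echo loss
#' @export
epg_decay_curve <- function(t2, t1, refocus_flip, seq) {
  stopifnot(inherits(seq, "grase_sequence"))
  if (!is.finite(t2) || t2 <= 0) stop("t2 must be > 0", call. = FALSE)
  if (!is.finite(t1) || t1 <= 0) stop("t1 must be > 0", call. = FALSE)
  if (!is.finite(refocus_flip) || refocus_flip <= 0 || refocus_flip > 180)
    stop("refocus_flip must lie in (0, 180] degrees", call. = FALSE)
  as.numeric(epg_decay_matrix(t2, t1, refocus_flip, seq))
}

# Vectorized EPG recursion: one echo train per column, columns share the
# flip angle but have independent T2 (and optionally T1). Used to build
# whole fitting bases in a single pass.
#
# State storage: Fp[k+1, ] = F(+k), Fm[k+1, ] = conj(F(-k)), Z[k+1, ] = Z(k)
# for configuration orders k = 0..n_echoes+1. One dephasing unit per half
# interval; pulse mixing for rotation about y (CPMG phase convention).
epg_decay_matrix <- function(t2, t1, refocus_flip, seq) {
  n <- seq$n_echoes
  tau <- seq$echo_spacing
  nt <- length(t2)
  if (length(t1) == 1L) t1 <- rep(t1, nt)
  K <- n + 1L                       # retained configuration orders

  e2 <- matrix(exp(-tau / (2 * t2)), K + 1L, nt, byrow = TRUE)
  e1 <- matrix(exp(-tau / (2 * t1)), K + 1L, nt, byrow = TRUE)

  a <- refocus_flip * pi / 180
  c2h <- cos(a / 2)^2; s2h <- sin(a / 2)^2
  sa <- sin(a); ca <- cos(a)

  Fp <- matrix(0 + 0i, K + 1L, nt)
  Fm <- matrix(0 + 0i, K + 1L, nt)
  Z  <- matrix(0 + 0i, K + 1L, nt)
  Fp[1L, ] <- 1i                    # 90x excitation: M0 along the y (CPMG) axis

  out <- matrix(0, n, nt)
  for (echo in seq_len(n)) {
    # relax half interval, dephase +1 order
    Fp <- Fp * e2; Fm <- Fm * e2; Z <- Z * e1
    Fp[2:(K + 1L), ] <- Fp[1:K, ]
    Fp[1L, ] <- Conj(Fm[2L, ])
    Fm[1:K, ] <- Fm[2:(K + 1L), ]
    Fm[K + 1L, ] <- 0 + 0i

    # refocusing pulse about y
    Fp_new <- c2h * Fp - s2h * Fm + sa * Z
    Fm_new <- -s2h * Fp + c2h * Fm + sa * Z
    Z_new  <- -0.5 * sa * Fp - 0.5 * sa * Fm + ca * Z
    Fp <- Fp_new; Fm <- Fm_new; Z <- Z_new

    # relax half interval, dephase +1 order; echo forms at order 0
    Fp <- Fp * e2; Fm <- Fm * e2; Z <- Z * e1
    Fp[2:(K + 1L), ] <- Fp[1:K, ]
    Fp[1L, ] <- Conj(Fm[2L, ])
    Fm[1:K, ] <- Fm[2:(K + 1L), ]
    Fm[K + 1L, ] <- 0 + 0i

    out[echo, ] <- Mod(Fp[1L, ])
  }
  out
}

#' Multi-compartment echo train
#'
#' Weighted sum of per-compartment EPG decay curves: the forward model of a
#' voxel mixing several water pools (e.g. myelin water at ~20 ms, intra- and
#' extracellular water at ~60-80 ms, CSF at ~2 s), each with its own T2 and
#' T1, all experiencing the same refocusing flip angle. Linear and
#' homogeneous in the compartment fractions.
#'
#' @param compartments a list of `c(fraction, t2, t1)` triples, or a numeric
#'   matrix/data.frame with columns `fraction`, `t2`, `t1`. Fractions must be
#'   >= 0 (they need not sum to 1: the curve scales linearly).
#' @param refocus_flip refocusing flip angle in degrees, in (0, 180].
#' @param seq a [grase_sequence()].
#' @return numeric vector of `seq$n_echoes` echo amplitudes.
#' @examples
#' sq <- grase_sequence()
#' # 15% myelin water, 85% intra/extracellular water, ideal refocusing:
#' y <- multi_compartment_curve(list(c(0.15, 0.02, 1), c(0.85, 0.08, 1)), 180, sq)
#' @export
multi_compartment_curve <- function(compartments, refocus_flip, seq) {
  stopifnot(inherits(seq, "grase_sequence"))
  if (is.data.frame(compartments)) compartments <- as.matrix(compartments)
  if (is.matrix(compartments)) {
    compartments <- lapply(seq_len(nrow(compartments)),
                           function(i) as.numeric(compartments[i, ]))
  }
  if (!is.list(compartments) || length(compartments) == 0L)
    stop("compartments must be a non-empty list of (fraction, t2, t1)",
         call. = FALSE)
  frac <- vapply(compartments, function(cc) cc[[1]], numeric(1))
  t2 <- vapply(compartments, function(cc) cc[[2]], numeric(1))
  t1 <- vapply(compartments, function(cc) {
    if (length(cc) >= 3) cc[[3]] else seq$t1_assumed
  }, numeric(1))
  if (any(frac < 0)) stop("compartment fractions must be >= 0", call. = FALSE)
  if (any(t2 <= 0) || any(t1 <= 0))
    stop("compartment t2 and t1 must be > 0", call. = FALSE)
  if (!is.finite(refocus_flip) || refocus_flip <= 0 || refocus_flip > 180)
    stop("refocus_flip must lie in (0, 180] degrees", call. = FALSE)
  curves <- epg_decay_matrix(t2, t1, refocus_flip, seq)
  as.numeric(curves %*% frac)
}
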