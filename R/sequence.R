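#' Multi-echo sequence parameters
#'
#' Describes the CPMG-style echo train of a GRASE T2 relaxation acquisition:
#' number of echoes, echo spacing, the (assumed ideal) excitation flip and
#' the longitudinal relaxation time assumed during fitting.
#'
#' Defaults reproduce a 48-echo acquisition with 8 ms echo spacing, the
#' standard myelin water protocol at 3 T. `t1_assumed` defaults to 1 s; at a
#' refocusing flip of 180 deg the echo amplitudes are exactly independent of
#' T1, and sensitivity remains weak at the flip angles encountered in
#' practice.
#'
#' @param n_echoes number of echoes in the train (>= 1).
#' @param echo_spacing echo spacing in seconds (> 0).
#' @param excitation_flip excitation flip angle in degrees (treated as ideal).
#' @param t1_assumed longitudinal relaxation time in seconds assumed when
#'   building fitting bases (> 0).
#' @return an object of class `grase_sequence`.
#' @examples
#' grase_sequence()                      # 48 echoes, 8 ms spacing
#' grase_sequence(n_echoes = 32, echo_spacing = 0.010)
#' @export
grase_sequence <- function(n_echoes = 48L, echo_spacing = 0.008,
                           excitation_flip = 90, t1_assumed = 1.0) {
  n_echoes <- as.integer(n_echoes)
  if (is.na(n_echoes) || n_echoes < 1L)
    stop("n_echoes must be an integer >= 1", call. = FALSE)
  if (!is.finite(echo_spacing) || echo_spacing <= 0)
    stop("echo_spacing must be > 0 (seconds)", call. = FALSE)
  if (!is.finite(t1_assumed) || t1_assumed <= 0)
    stop("t1_assumed must be > 0 (seconds)", call. = FALSE)
  structure(
    list(n_echoes = n_echoes, echo_spacing = echo_spacing,
         excitation_flip = excitation_flip, t1_assumed = t1_assumed),
    class = "grase_sequence"
  )
}

#' @export
print.grase_sequence <- function(x, ...) {
  cat(sprintf("GRASE echo train: %d echoes, %.1f ms spacing (TE %.0f-%.0f ms), T1 assumed %.2f s\n",
              x$n_echoes, 1000 * x$echo_spacing, 1000 * x$echo_spacing,
              1000 * x$echo_spacing * x$n_echoes, x$t1_assumed))
  invisible(x)
}

#' Echo times of a sequence
#'
#' @param seq a [grase_sequence()].
#' @return numeric vector of echo times in seconds, `n * echo_spacing`.
#' @export
echo_times <- function(seq) {
  stopifnot(inherits(seq, "grase_sequence"))
  seq$echo_spacing * seq_len(seq$n_echoes)
}
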