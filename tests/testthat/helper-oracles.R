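# Independent oracles the implementation is checked against.

# Isochromat-summation simulator: a dense ensemble of spins, each acquiring
# a fixed dephasing angle per half echo-spacing (the crusher), rotated
# explicitly through the pulse train with 3x3 rotation matrices. With
# equally spaced dephasing angles and n_iso larger than the highest
# configuration order reached, the ensemble average equals the EPG result
# exactly. Shares no code with the EPG recursion.
isochromat_decay <- function(t2, t1, refocus_flip, seq,
                             n_iso = 8L * seq$n_echoes + 9L) {
  n <- seq$n_echoes; tau <- seq$echo_spacing
  th <- 2 * pi * (seq_len(n_iso) - 1) / n_iso
  ct <- cos(th); st <- sin(th)
  e2 <- exp(-tau / (2 * t2)); e1 <- exp(-tau / (2 * t1))
  a <- refocus_flip * pi / 180; ca <- cos(a); sa <- sin(a)
  Mx <- numeric(n_iso); My <- rep(1, n_iso); Mz <- numeric(n_iso)
  out <- numeric(n)
  for (e in seq_len(n)) {
    # half interval: relax + dephase
    Mx <- Mx * e2; My <- My * e2; Mz <- Mz * e1
    x <- Mx * ct - My * st; My <- Mx * st + My * ct; Mx <- x
    # refocusing pulse about y
    x <- ca * Mx + sa * Mz; Mz <- -sa * Mx + ca * Mz; Mx <- x
    # half interval: relax + dephase; echo
    Mx <- Mx * e2; My <- My * e2; Mz <- Mz * e1
    x <- Mx * ct - My * st; My <- Mx * st + My * ct; Mx <- x
    out[e] <- Mod(complex(real = mean(Mx), imaginary = mean(My)))
  }
  out
}

# Exhaustive active-set enumeration for small NNLS problems: solve the
# unconstrained least-squares problem on every subset of columns, keep the
# feasible (all-non-negative) solution with the smallest residual.
nnls_enumerate <- function(A, b) {
  p <- ncol(A)
  best_x <- numeric(p)
  best_chi2 <- sum(b^2)            # empty subset
  for (code in seq_len(2^p - 1)) {
    S <- which(bitwAnd(code, 2^(seq_len(p) - 1)) > 0)
    z <- tryCatch(qr.solve(A[, S, drop = FALSE], b),
                  error = function(e) NULL)
    if (is.null(z) || any(z < 0)) next
    r <- b - A[, S, drop = FALSE] %*% z
    chi2 <- sum(r^2)
    if (chi2 < best_chi2 - 1e-12 * max(1, best_chi2)) {
      best_chi2 <- chi2
      best_x <- numeric(p); best_x[S] <- z
    }
  }
  list(x = best_x, chi2 = best_chi2)
}
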