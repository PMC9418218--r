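# Shared fixtures and independent oracles used across the suite.

# Quick inversion settings for unit tests whose tolerances do not need the
# full production term count.
quick_settings <- function(terms = 4000, ...) {
  inversion_settings(durbin_terms = terms, ...)
}

gold_mix <- function(phi = 0.04, shape = "platelet") {
  nanofluid_mixture(particle = "gold", phi = phi, shape = shape)
}

# Independent backward-Euler integrator for the integer-order limit of the
# semi-discrete system (dense solve each step; deliberately shares no code
# with solve_fd beyond the grid container).
backward_euler_oracle <- function(params, coeff, grid) {
  ny <- grid$ny; nt <- grid$nt; ni <- ny - 2L
  dt <- grid$dt; lam <- coeff$D / grid$dy^2
  A <- diag(1 / dt + coeff$c + 2 * lam, ni)
  for (i in seq_len(ni - 1)) {
    A[i, i + 1] <- -lam
    A[i + 1, i] <- -lam
  }
  U <- matrix(params$theta_init, ny, nt + 1L)
  U[1L, -1L] <- params$theta_left
  U[ny, -1L] <- params$theta_right
  u <- rep(params$theta_init, ni)
  for (n in seq_len(nt)) {
    r <- u / dt + coeff$s
    r[1L] <- r[1L] + lam * params$theta_left
    r[ni] <- r[ni] + lam * params$theta_right
    u <- solve(A, r)
    U[2:(ny - 1L), n + 1L] <- u
  }
  U
}

# Direct (unscaled) evaluation of the Hamilton-Crosser formula, used as an
# arithmetic oracle against the package implementation.
hc_formula <- function(kb, ks, phi, m) {
  kb * (ks + (m - 1) * kb - phi * (m - 1) * (kb - ks)) /
    (ks + (m - 1) * kb + phi * (kb - ks))
}
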