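# Independent oracles used across the suite.

# Literal transcription of the five governing equations, written term by
# term per competition structure, independent of the package's matrix
# formulation.
oracle_rhs <- function(n00, n01, n10, n11, R, p) {
  N <- n00 + n01 + n10 + n11
  K0 <- p$k + p$beta0 * R
  K1 <- p$k + p$beta1 * R
  m0 <- p$alpha * N / K0   # focal dispersal denominator, x = 0 clones
  m1 <- p$alpha * N / K1   # x = 1 clones
  s <- p$structure
  if (s == "I") {
    d00 <- p$r00 * n00 * (1 - (n00 + p$phi * n01 + p$theta * n10 +
                                 p$psi * n11) / K0) - m0 * n00
    d01 <- p$r01 * n01 * (1 - (p$phi * n00 + n01 + p$omega * n10 +
                                 p$nu * n11) / K0) - m0 * n01
    d10 <- p$r10 * n10 * (1 - (p$theta * n00 + p$omega * n01 + n10 +
                                 p$mu * n11) / K1) - m1 * n10
    d11 <- p$r11 * n11 * (1 - (p$psi * n00 + p$nu * n01 + p$mu * n10 +
                                 n11) / K1) - m1 * n11
  } else if (s == "II") {
    d00 <- p$r00 * n00 * (1 - (n00 + p$phi * n01 + p$theta * n10 +
                                 p$psi * n11) / K0) - m0 * n00
    d01 <- p$r01 * n01 * (1 - (p$phi * n00 + n01 + n10 + n11) / K0) -
      m0 * n01
    d10 <- p$r10 * n10 * (1 - (p$theta * n00 + n01 + n10 + n11) / K1) -
      m1 * n10
    d11 <- p$r11 * n11 * (1 - (p$psi * n00 + n01 + n10 + n11) / K1) -
      m1 * n11
  } else {
    d00 <- p$r00 * n00 * (1 - (n00 + n01 + p$theta * n10 +
                                 p$theta * n11) / K0) - m0 * n00
    d01 <- p$r01 * n01 * (1 - (n00 + n01 + p$theta * n10 +
                                 p$theta * n11) / K0) - m0 * n01
    d10 <- p$r10 * n10 * (1 - (p$phi * n00 + p$phi * n01 + n10 +
                                 n11) / K1) - m1 * n10
    d11 <- p$r11 * n11 * (1 - (p$phi * n00 + p$phi * n01 + n10 +
                                 n11) / K1) - m1 * n11
  }
  list(dn = c(d00, d01, d10, d11),
       dR = p$g * (n10 + n11) - p$l * R)
}

# central-difference Jacobian of the frozen-R cell subsystem
fd_jacobian <- function(n, R, p, h_rel = 1e-6) {
  J <- matrix(0, 4, 4)
  for (j in 1:4) {
    h <- h_rel * max(abs(n[j]), 1)
    up <- n; up[j] <- n[j] + h
    dn <- n; dn[j] <- n[j] - h
    fu <- oracle_rhs(up[1], up[2], up[3], up[4], R, p)$dn
    fd <- oracle_rhs(dn[1], dn[2], dn[3], dn[4], R, p)$dn
    J[, j] <- (fu - fd) / (2 * h)
  }
  J
}

# quick accessor for a quasi-equilibrium's abundance of one clone
eq_n <- function(eq, label) eq$n_star[[label]]
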