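# Vectorised algebra on 2x2 complex matrices.
#
# A "matrix" here is a list of four complex vectors (a11, a12, a21, a22),
# one element per CPMG frequency, so an entire dispersion profile is
# propagated with a handful of vectorised operations.  Used by the
# closed-form (spectral) dispersion models; the brute-force propagators in
# bloch_mcconnell_r2eff() use ordinary R matrices instead.

.m2 <- function(a11, a12, a21, a22) list(a11 = a11, a12 = a12, a21 = a21, a22 = a22)

.m2_mul <- function(x, y) {
  .m2(x$a11 * y$a11 + x$a12 * y$a21, x$a11 * y$a12 + x$a12 * y$a22,
      x$a21 * y$a11 + x$a22 * y$a21, x$a21 * y$a12 + x$a22 * y$a22)
}

.m2_conj <- function(x) lapply(x, Conj)

# Matrix-vector product; v is list(x1, x2) of complex vectors.
.m2_vec <- function(x, v) {
  list(x1 = x$a11 * v$x1 + x$a12 * v$x2, x2 = x$a21 * v$x1 + x$a22 * v$x2)
}

# exp(d * (K + i*diag(0, w))) for the two-state exchange matrix
# K = [[-kab, kba], [kab, -kba]], in closed form (2x2 exponential via the
# traceless decomposition).  kab, kba scalars; w, d vectors or scalars.
.m2_exp_exchange <- function(kab, kba, w, d) {
  tr <- -(kab + kba) + 1i * w
  m11 <- -kab - tr / 2            # traceless part; m22 = -m11
  mu <- sqrt(m11 * m11 + kab * kba)
  ch <- cosh(mu * d)
  sh <- ifelse(Mod(mu * d) < 1e-12, d, sinh(mu * d) / mu)
  e <- exp(tr * d / 2)
  .m2(e * (ch + sh * m11), e * sh * kba,
      e * sh * kab,        e * (ch - sh * m11))
}

# Integer matrix power X^k, k a non-negative integer vector (per element),
# via the spectral decomposition; a Jordan-block limit handles (near-)
# degenerate eigenvalues smoothly.
.m2_pow <- function(x, k) {
  tr <- x$a11 + x$a22
  dt <- x$a11 * x$a22 - x$a12 * x$a21
  disc <- sqrt(tr * tr / 4 - dt)
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  near <- Mod(l1 - l2) < 1e-9 * (Mod(l1) + Mod(l2) + 1e-300)
  f <- ifelse(near, 0i, 1 / (l1 - l2))
  e1 <- l1^k
  e2 <- l2^k
  p11 <- (x$a11 - l2) * f
  p22 <- (x$a22 - l2) * f
  out <- .m2(e1 * p11 + e2 * (1 - p11), (e1 - e2) * x$a12 * f,
             (e1 - e2) * x$a21 * f,     e1 * p22 + e2 * (1 - p22))
  if (any(near)) {
    lam <- tr / 2
    elk <- lam^k
    klk <- k * lam^(pmax(k - 1, 0))
    idx <- which(near)
    out$a11[idx] <- (elk + klk * (x$a11 - lam))[idx]
    out$a12[idx] <- (klk * x$a12)[idx]
    out$a21[idx] <- (klk * x$a21)[idx]
    out$a22[idx] <- (elk + klk * (x$a22 - lam))[idx]
  }
  zero <- k == 0
  if (any(zero)) {
    out$a11[zero] <- 1 + 0i; out$a12[zero] <- 0i
    out$a21[zero] <- 0i;     out$a22[zero] <- 1 + 0i
  }
  out
}
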