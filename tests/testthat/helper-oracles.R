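# Independent reference implementations used as oracles.  These deliberately
# take different numerical routes than the package internals: dense matrix
# exponentials (Matrix::expm), an adaptive ODE solver (deSolve::lsoda), and
# direct quadrature of the Rice density.

# Narrow-pulse Karger kernel as 1' expm(-A t) M0, constant q^2 = b/t
oracle_karger_expm <- function(b, eps, t, f, Dn, De, rn) {
  re <- if (f < 1) rn * f / (1 - f) else 0
  q2 <- if (t > 0) b / t else 0
  A <- matrix(c(q2 * Dn * eps^2 + rn, -re,
                -rn, q2 * De + re), 2, 2, byrow = TRUE)
  M <- Matrix::expm(-A * t) %*% c(f, 1 - f)
  sum(M)
}

# Finite-pulse kernel via adaptive lsoda over the trapezoidal waveform
oracle_smex_ode <- function(b, eps, t, delta, ramp, f, Dn, De, rn,
                            rtol = 1e-10) {
  re <- if (f < 1) rn * f / (1 - f) else 0
  G <- gradient_amplitude(b, t, delta, ramp)
  wf <- pgse_waveform(G, t, delta, ramp)
  rhs <- function(tt, y, p) {
    q2 <- wf$q(tt)^2
    A <- matrix(c(q2 * Dn * eps^2 + rn, -re, -rn, q2 * De + re), 2, 2,
                byrow = TRUE)
    list(as.vector(-A %*% y))
  }
  corners <- sort(unique(c(0, ramp, delta, delta + ramp, t, t + ramp,
                           t + delta, t + delta + ramp)))
  out <- deSolve::ode(c(f, 1 - f), corners, rhs, NULL, rtol = rtol,
                      atol = 1e-12)
  sum(out[nrow(out), 2:3])
}

# Rice mean by direct quadrature of x * dRice(x)
oracle_rice_mean <- function(nu, sigma) {
  if (sigma == 0) return(nu)
  # density written with the scaled Bessel so the integrand never overflows:
  # f(x) = (x/sigma^2) exp(-(x - nu)^2 / (2 sigma^2)) I0~(x nu / sigma^2)
  f <- function(x) x * (x / sigma^2) * exp(-(x - nu)^2 / (2 * sigma^2)) *
    besselI(x * nu / sigma^2, 0, expon.scaled = TRUE)
  stats::integrate(f, 0, nu + 12 * sigma, rel.tol = 1e-12,
                   abs.tol = 1e-14)$value
}

# Random 3D rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# small noiseless data set: invariant table + truths, shared by tests
make_clean_invariants <- function(n = 10, seed = 3, lmax = 0,
                                  protocol = "C2", directions = 32,
                                  ranges = list(tex = c(2, 45),
                                                f = c(0.05, 0.95),
                                                Dn = c(1.5, 3),
                                                De = c(0.5, 1.5),
                                                p2 = c(0, 0.3))) {
  scheme <- nexi_protocol(protocol, directions)
  truth <- sample_tissue_params(n, ranges = ranges, seed = seed)
  tab <- nexi_signal_table(truth, scheme, lmax = lmax)
  tab$voxel <- tab$draw
  list(inv = tab[, c("voxel", "b", "t", "l", "value")], truth = truth,
       scheme = scheme)
}

# evaluate an expression while discarding anything printed to stdout
invisible_output <- function(expr) {
  out <- NULL
  capture.output(out <- expr)
  out
}
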