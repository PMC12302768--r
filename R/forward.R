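# Forward signal models for the two-compartment anisotropic Karger model:
# the analytic narrow-pulse kernel (NEXI), the finite-pulse ODE kernel
# (SMEX), Legendre projections, the axially symmetric ODF convolution, and
# the Rice-distribution mean used for noise-floor-aware fitting.

#' Construct a tissue-parameter table
#'
#' Builds (and validates) a tibble of Karger-model tissue parameters.
#' Derived quantities are added: the extracellular-to-neurite rate
#' `re = rn f / (1 - f)` (detailed balance) and the exchange time
#' `tex = 1 / (rn + re) = (1 - f) / rn`.
#'
#' @param f Neurite signal fraction, in `[0, 1]`.
#' @param Dn Along-neurite diffusivity (um^2/ms).
#' @param De Isotropic extracellular diffusivity (um^2/ms).
#' @param rn Neurite-to-extracellular exchange rate (1/ms).
#' @param p2 l = 2 rotational invariant of the ODF (dispersion index), in
#'   `[0, 1]`; default 0 (fully dispersed).
#' @return A tibble with columns `f, Dn, De, rn, p2, re, tex`.
#' @examples
#' tissue_params(f = 0.35, Dn = 2.5, De = 0.9, rn = 0.02)
#' @export
tissue_params <- function(f, Dn, De, rn, p2 = 0) {
  n <- max(length(f), length(Dn), length(De), length(rn), length(p2))
  f <- rep_len(f, n); Dn <- rep_len(Dn, n); De <- rep_len(De, n)
  rn <- rep_len(rn, n); p2 <- rep_len(p2, n)
  if (any(f < 0 | f > 1)) abort("f must lie in [0, 1]")
  if (any(Dn < 0) || any(De < 0)) abort("diffusivities must be >= 0")
  if (any(rn < 0)) abort("rn must be >= 0")
  if (any(p2 < 0 | p2 > 1)) abort("p2 must lie in [0, 1]")
  re <- ifelse(f < 1, rn * f / (1 - f), Inf)
  tex <- ifelse(rn > 0, (1 - f) / rn, Inf)
  tibble(f = f, Dn = Dn, De = De, rn = rn, p2 = p2, re = re, tex = tex)
}

params_matrix <- function(params) {
  params <- as.data.frame(params)
  need <- c("f", "Dn", "De", "rn")
  if (!all(need %in% names(params)))
    abort("params must have columns f, Dn, De, rn")
  p2 <- if ("p2" %in% names(params)) params$p2 else rep(0, nrow(params))
  cbind(f = params$f, Dn = params$Dn, De = params$De, rn = params$rn, p2 = p2)
}

#' Narrow-pulse exchange kernel (NEXI)
#'
#' Analytic two-exponential solution of the coupled Karger magnetization
#' equations under the narrow-pulse approximation:
#' `K = f1' exp(-a1) + f2' exp(-a2)` with the exponents the eigenvalues of
#' the rate-plus-attenuation matrix over the diffusion time and the
#' amplitudes fixed by `f1' + f2' = 1` (b = 0 normalization) and first-moment
#' matching.  Degenerate (coincident-exponent) cases are handled by a stable
#' `sinh(h)/h` limit rather than 0/0 arithmetic.
#'
#' @param b b-value(s) (ms/um^2), `>= 0`.
#' @param eps Cosine(s) of the angle between neurite axis and gradient, in
#'   `[0, 1]`.
#' @param t Diffusion time(s) (ms), `> 0`.
#' @param params A one-row (or recycled) tissue-parameter table from
#'   [tissue_params()], or anything with columns `f, Dn, De, rn`.
#' @return Kernel values in `[0, 1]` (vectorized over `b`, `eps`, `t`).
#' @examples
#' p <- tissue_params(0.5, 2, 1, 0)
#' nexi_kernel(1, 1, 20, p)  # 0.5*exp(-2) + 0.5*exp(-1)
#' @export
nexi_kernel <- function(b, eps, t, params) {
  if (any(b < 0)) abort("b must be >= 0")
  if (any(eps < 0 | eps > 1)) abort("eps must lie in [0, 1]")
  pm <- params_matrix(params)
  n <- max(length(b), length(eps), length(t), nrow(pm))
  b <- rep_len(b, n); eps <- rep_len(eps, n); t <- rep_len(t, n)
  idx <- rep_len(seq_len(nrow(pm)), n)
  cpp_nexi_kernel(b, eps, t, pm[idx, "f"], pm[idx, "Dn"], pm[idx, "De"],
                  pm[idx, "rn"])
}

#' Finite-pulse exchange kernel (SMEX)
#'
#' Integrates the coupled magnetization equations through a trapezoidal
#' pulsed-gradient spin-echo waveform with the time-varying `q^2(t)`
#' coefficient.  The propagation uses piecewise 2x2 matrix exponentials
#' (exact on the constant-q plateau, midpoint-q^2 substeps inside the
#' pulses) with step-doubling until successive refinements change the kernel
#' by less than `tol`.
#'
#' @inheritParams nexi_kernel
#' @param delta Pulse duration, FWHM (ms).
#' @param ramp Ramp time (ms).
#' @param tol Step-doubling tolerance on the kernel value (default 1e-6).
#' @return Kernel values (vectorized).  Errors if the integration fails to
#'   reach `tol`.
#' @export
smex_kernel <- function(b, eps, t, params, delta, ramp, tol = 1e-6) {
  if (any(b < 0)) abort("b must be >= 0")
  if (any(eps < 0 | eps > 1)) abort("eps must lie in [0, 1]")
  pm <- params_matrix(params)
  n <- max(length(b), length(eps), length(t), length(delta), length(ramp),
           nrow(pm))
  b <- rep_len(b, n); eps <- rep_len(eps, n); t <- rep_len(t, n)
  delta <- rep_len(delta, n); ramp <- rep_len(pmax(ramp, 1e-9), n)
  if (any(delta + ramp >= t)) abort("delta + ramp must be < t")
  idx <- rep_len(seq_len(nrow(pm)), n)
  res <- cpp_smex_kernel(b, t, delta, ramp, eps, pm[idx, "f"], pm[idx, "Dn"],
                         pm[idx, "De"], pm[idx, "rn"], tol)
  if (!all(res$converged))
    abort("SMEX integration did not reach the requested tolerance")
  res$K
}

#' Gauss-Legendre nodes on [0, 1]
#' @param n Number of nodes (default 60).
#' @return List with `nodes` and `weights`.
#' @keywords internal
gl_nodes <- function(n = 60) {
  gl <- pracma::gaussLegendre(n, 0, 1)
  list(nodes = gl$x, weights = gl$w)
}

#' Legendre projection of a kernel
#'
#' Projects an orientation kernel `K(eps)` onto the even Legendre
#' polynomials over `eps` in `[0, 1]` by fixed-order Gauss-Legendre
#' quadrature: `Kl = integral_0^1 K(eps) Pl(eps) d eps`.  `K0` is the
#' spherical-mean signal.  Projections are signed; for this kernel family
#' `K2` is typically negative (attenuation is strongest along the neurite).
#'
#' @param K A function of `eps` (vectorized), e.g. a closure over
#'   [nexi_kernel()] at fixed `(b, t)`.
#' @param lmax Highest (even) order to return (default 2).
#' @param n_nodes Quadrature order (default 60).
#' @return Named numeric vector `K0, K2, ...` up to `lmax`.
#' @examples
#' project_legendre(function(e) e^2)  # K0 = 1/3, K2 = 2/15
#' @export
project_legendre <- function(K, lmax = 2, n_nodes = 60) {
  if (lmax %% 2 != 0) abort("lmax must be even")
  gl <- gl_nodes(n_nodes)
  Kv <- K(gl$nodes)
  ls <- seq(0, lmax, by = 2)
  out <- vapply(ls, function(l) {
    sum(gl$weights * Kv * legendre_poly(l, gl$nodes))
  }, numeric(1))
  setNames(out, paste0("K", ls))
}

# Legendre polynomial P_l(x) for even l up to 8
legendre_poly <- function(l, x) {
  switch(as.character(l),
         "0" = rep(1, length(x)),
         "2" = (3 * x^2 - 1) / 2,
         "4" = (35 * x^4 - 30 * x^2 + 3) / 8,
         "6" = (231 * x^6 - 315 * x^4 + 105 * x^2 - 5) / 16,
         "8" = (6435 * x^8 - 12012 * x^6 + 6930 * x^4 - 1260 * x^2 + 35) / 128,
         abort("unsupported Legendre order"))
}

#' Rotationally invariant signal from kernel projections
#'
#' `Sl = pl * Kl` for each even order, with `p0 = 1` by ODF normalization.
#'
#' @param Kl Named vector of kernel projections (`K0`, `K2`, ...).
#' @param pl Named vector of ODF invariants (`p0`, `p2`, ...); `p0` must
#'   be 1 (it is filled in if absent).
#' @return Named vector `S0, S2, ...`.
#' @export
rotinv_signal <- function(Kl, pl = c(p0 = 1)) {
  ls <- as.integer(sub("K", "", names(Kl)))
  if (is.null(pl["p0"]) || is.na(pl["p0"])) pl <- c(p0 = 1, pl)
  if (abs(pl[["p0"]] - 1) > 1e-12) abort("p0 must equal 1")
  out <- vapply(seq_along(ls), function(i) {
    pname <- paste0("p", ls[i])
    p <- if (pname %in% names(pl)) pl[[pname]] else 0
    p * Kl[[i]]
  }, numeric(1))
  setNames(out, paste0("S", ls))
}

#' Model rotational invariants over the shells of a scheme
#'
#' Evaluates the NEXI (or SMEX) forward model of the measured invariants for
#' every tissue-parameter row and every diffusion-weighted shell of a
#' scheme.  `S0` is the spherical mean; `S2 = p2 * |K2|`, matching the
#' non-negative norm-based invariant extracted from data.
#'
#' @param params Tissue-parameter table (rows are voxels/draws).
#' @param scheme A scheme tibble, or a shell table from [scheme_shells()].
#' @param lmax 0 or 2.
#' @param generator `"nexi"` (analytic, narrow pulse) or `"smex"` (finite
#'   pulse, uses the scheme's `delta`/`ramp`).
#' @param delta,ramp Optional overrides of the pulse shape for
#'   `generator = "smex"`.
#' @param exclude_b Shells dropped from the output (default b = 1).
#' @param n_nodes Quadrature order for the Legendre projection.
#' @return A tibble with columns `draw, b, t, l, value` (long form).
#' @export
nexi_signal_table <- function(params, scheme, lmax = 0, generator = "nexi",
                              delta = NULL, ramp = NULL, exclude_b = 1,
                              n_nodes = 60) {
  shells <- if (all(c("b0", "volume") %in% names(scheme)))
    scheme_shells(scheme, exclude_b = exclude_b) else as_tibble(scheme)
  pm <- params_matrix(params)
  gl <- gl_nodes(n_nodes)
  if (generator == "nexi") {
    inv <- cpp_nexi_invariants(pm, shells$b, shells$t, gl$nodes, gl$weights)
  } else if (generator == "smex") {
    d <- if (is.null(delta)) shells$delta[1] else delta
    r <- if (is.null(ramp)) shells$ramp[1] else ramp
    inv <- cpp_smex_invariants(pm[, 1:4, drop = FALSE], shells$b, shells$t,
                               d, max(r, 1e-9), gl$nodes, gl$weights, 1e-6)
  } else abort("generator must be 'nexi' or 'smex'")
  V <- nrow(pm); S <- nrow(shells)
  out <- tibble(draw = rep(seq_len(V), times = S),
                b = rep(shells$b, each = V),
                t = rep(shells$t, each = V),
                l = 0L, value = as.vector(inv$K0))
  if (lmax >= 2) {
    out2 <- out
    out2$l <- 2L
    out2$value <- as.vector(inv$K2) * rep(pm[, "p2"], times = S)
    out2$value <- abs(out2$value)
    out <- bind_rows(out, out2)
  }
  arrange(out, .data$draw, .data$t, .data$b, .data$l)
}

#' Per-direction signals of an axially symmetric voxel
#'
#' Convolves the orientation kernel with an axially symmetric ODF truncated
#' at `lmax`: `S(g) = sum_l (2l+1) pl Kl Pl(u . g)` with signed Legendre
#' projections `Kl`.  Extracting rotational invariants from these signals
#' recovers `S0 = K0` and `|S2| = p2 |K2|`.
#'
#' @param scheme A scheme tibble (per-volume directions are used; b = 0
#'   volumes get signal 1).
#' @param params One-row tissue-parameter table (with `p2`).
#' @param axis Unit 3-vector: ODF symmetry axis.
#' @param lmax 0 or 2.
#' @param generator `"nexi"` or `"smex"`.
#' @param delta,ramp Optional pulse-shape overrides for SMEX generation.
#' @return Numeric vector of per-volume signals, in scheme order.
#' @export
directional_signal <- function(scheme, params, axis = c(0, 0, 1), lmax = 2,
                               generator = "nexi", delta = NULL, ramp = NULL) {
  if (!lmax %in% c(0, 2)) abort("unsupported lmax (use 0 or 2)")
  axis <- axis / sqrt(sum(axis^2))
  pm <- params_matrix(params)
  if (nrow(pm) != 1) abort("directional_signal takes a single parameter row")
  shells <- distinct(filter(scheme, !.data$b0),
                     .data$b, .data$t, .data$delta, .data$ramp)
  gl <- gl_nodes(60)
  inv <- if (generator == "nexi") {
    cpp_nexi_invariants(pm, shells$b, shells$t, gl$nodes, gl$weights)
  } else {
    d <- if (is.null(delta)) shells$delta[1] else delta
    r <- if (is.null(ramp)) shells$ramp[1] else ramp
    cpp_smex_invariants(pm[, 1:4, drop = FALSE], shells$b, shells$t, d,
                        max(r, 1e-9), gl$nodes, gl$weights, 1e-6)
  }
  sig <- numeric(nrow(scheme))
  sig[scheme$b0] <- 1
  dw <- which(!scheme$b0)
  u <- as.matrix(scheme[dw, c("gx", "gy", "gz")]) %*% axis
  shell_id <- match(paste(scheme$b[dw], scheme$t[dw]),
                    paste(shells$b, shells$t))
  s <- inv$K0[1, shell_id]
  if (lmax >= 2)
    s <- s + 5 * pm[1, "p2"] * inv$K2[1, shell_id] * legendre_poly(2, u)
  sig[dw] <- s
  sig
}

#' Mean of the Rice distribution
#'
#' Exact expected magnitude `E |nu + complex N(0, sigma)|` via the
#' scaled-Bessel closed form
#' `sigma sqrt(pi/2) [(1 + tt) I0(tt/2) + tt I1(tt/2)] exp(-tt/2)` with
#' `tt = nu^2 / (2 sigma^2)`, numerically stable over the whole range (the
#' trivial asymptotic `nu + sigma^2/(2 nu)` takes over beyond
#' `nu/sigma > 1e4`).  Monotone nondecreasing in both arguments.
#'
#' @param nu Noise-free magnitude(s), `>= 0`.
#' @param sigma Per-channel Gaussian noise level(s), `>= 0`.
#' @return Expected magnitude(s).
#' @examples
#' rice_mean(0, 1)  # Rayleigh mean sqrt(pi/2)
#' @export
rice_mean <- function(nu, sigma) {
  if (any(nu < 0) || any(sigma < 0)) abort("nu and sigma must be >= 0")
  n <- max(length(nu), length(sigma))
  cpp_rice_mean(rep_len(nu, n), rep_len(sigma, n))
}
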