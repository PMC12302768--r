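test_that("narrow-pulse kernel obeys its analytic limits", {
  p <- tissue_params(0.5, 2, 1, 0)
  # b = 0 normalization
  expect_equal(nexi_kernel(0, 0.7, 20, tissue_params(0.3, 2.5, 0.9, 0.05)), 1)
  # no-exchange bi-exponential
  expect_equal(nexi_kernel(1, 1, 20, p), 0.5 * exp(-2) + 0.5 * exp(-1),
               tolerance = 1e-12)
  grid <- expand.grid(b = c(0.5, 3.5, 17.5), eps = c(0, 0.3, 1))
  p2 <- tissue_params(0.35, 2.8, 0.7, 0)
  closed <- with(grid, 0.35 * exp(-b * 2.8 * eps^2) + 0.65 * exp(-b * 0.7))
  expect_equal(nexi_kernel(grid$b, grid$eps, 21, p2), closed,
               tolerance = 1e-10)
  # fast-exchange mono-exponential limit
  fast <- tissue_params(0.4, 2.5, 1, (1 - 0.4) / 1e-4)  # tex = 1e-4 ms
  mono <- exp(-3 * (0.4 * 2.5 * 0.6^2 + 0.6 * 1))
  expect_equal(nexi_kernel(3, 0.6, 20, fast), mono, tolerance = 1e-4)
  # coincident exponents (rn = 0, b Dn eps^2 = b De) use the limit branch
  pc <- tissue_params(0.5, 1, 1, 0)
  expect_equal(nexi_kernel(2, 1, 20, pc), exp(-2), tolerance = 1e-12)
  # argument validation
  expect_error(nexi_kernel(-1, 0.5, 20, p), "b must")
  expect_error(nexi_kernel(1, 1.5, 20, p), "eps")
})

test_that("narrow-pulse kernel matches the matrix-exponential oracle", {
  set.seed(4)
  for (i in 1:50) {
    f <- runif(1, 0.01, 0.99); Dn <- runif(1, 0.1, 3)
    De <- runif(1, 0.1, Dn); tex <- runif(1, 1, 50)
    rn <- (1 - f) / tex
    b <- runif(1, 0, 17.5); t <- runif(1, 13, 40); eps <- runif(1)
    K <- nexi_kernel(b, eps, t, tissue_params(f, Dn, De, rn))
    expect_equal(K, oracle_karger_expm(b, eps, t, f, Dn, De, rn),
                 tolerance = 1e-12)
  }
})

test_that("finite-pulse kernel matches the adaptive ODE oracle", {
  set.seed(5)
  for (i in 1:8) {
    f <- runif(1, 0.1, 0.9); Dn <- runif(1, 0.5, 3); De <- runif(1, 0.1, Dn)
    rn <- runif(1, 0.005, 0.5); b <- runif(1, 0.5, 17.5); eps <- runif(1)
    K <- smex_kernel(b, eps, 30, tissue_params(f, Dn, De, rn),
                     delta = 6, ramp = 0.83)
    expect_lt(abs(K - oracle_smex_ode(b, eps, 30, 6, 0.83, f, Dn, De, rn)),
              1e-5)
  }
})

test_that("finite-pulse kernel: no encoding and decoupled Gaussian limits", {
  p <- tissue_params(0.4, 2, 1, 0.02)
  expect_equal(smex_kernel(0, 0.5, 30, p, delta = 6, ramp = 0.83), 1,
               tolerance = 1e-9)
  # rn = 0: each compartment is Gaussian under any waveform, so the
  # bi-exponential in the *total* b is exact for finite pulses too
  p0 <- tissue_params(0.4, 2, 1, 0)
  for (eps in c(0, 0.6, 1)) {
    K <- smex_kernel(3, eps, 30, p0, delta = 10, ramp = 1.5)
    expect_equal(K, 0.4 * exp(-3 * 2 * eps^2) + 0.6 * exp(-3 * 1),
                 tolerance = 1e-9)
  }
})

test_that("narrow-pulse limit of the finite-pulse kernel approaches NEXI", {
  p <- tissue_params(0.35, 2.5, 0.9, 0.05)
  Kn <- nexi_kernel(6.5, 0.3, 21, p)
  Ks <- smex_kernel(6.5, 0.3, 21, p, delta = 0.01, ramp = 0.001)
  expect_lt(abs(Kn - Ks) / Kn, 1e-3)
})

test_that("Legendre projection reproduces closed-form integrals", {
  flat <- project_legendre(function(e) rep(0.7, length(e)), lmax = 2)
  expect_equal(unname(flat), c(0.7, 0), tolerance = 1e-12)
  quad <- project_legendre(function(e) e^2, lmax = 2)
  expect_equal(unname(quad), c(1 / 3, 2 / 15), tolerance = 1e-10)
  # pure stick spherical mean: K0 = sqrt(pi/(4 b Dn)) erf(sqrt(b Dn))
  st <- tissue_params(1, 2.2, 1, 0)
  for (b in c(1, 6.5, 17.5)) {
    K0 <- project_legendre(function(e) nexi_kernel(b, e, 20, st), lmax = 0)
    x <- b * 2.2
    expect_equal(unname(K0), sqrt(pi / (4 * x)) * pracma::erf(sqrt(x)),
                 tolerance = 1e-8)
  }
  expect_error(project_legendre(function(e) e, lmax = 3), "even")
})

test_that("rotational invariants are products pl * Kl", {
  expect_equal(rotinv_signal(c(K0 = 0.5))[["S0"]], 0.5)
  expect_equal(rotinv_signal(c(K0 = 0.5, K2 = 0.2), c(p0 = 1, p2 = 0))[["S2"]], 0)
  expect_equal(rotinv_signal(c(K0 = 0.5, K2 = 0.2), c(p0 = 1, p2 = 0.3))[["S2"]],
               0.06)
  expect_error(rotinv_signal(c(K0 = 0.5), c(p0 = 2)), "p0")
})

test_that("directional signals honor the isotropic and b = 0 cases", {
  sch <- nexi_protocol("C2", 32)
  iso <- tissue_params(0.35, 2.5, 0.9, 0.03, p2 = 0)
  sig <- directional_signal(sch, iso, axis = c(1, 1, 1))
  expect_true(all(sig[sch$b0] == 1))
  one_shell <- !sch$b0 & sch$b == 6.5 & sch$t == 21
  expect_lt(diff(range(sig[one_shell])), 1e-12)
  K0 <- project_legendre(function(e) nexi_kernel(6.5, e, 21, iso), lmax = 0)
  expect_equal(unname(unique(round(sig[one_shell], 12))), round(unname(K0), 12))
  expect_error(directional_signal(sch, iso, lmax = 4), "unsupported lmax")
})

test_that("Rice mean matches quadrature, limits and monotonicity", {
  expect_equal(rice_mean(0, 1), sqrt(pi / 2), tolerance = 1e-12)
  expect_equal(rice_mean(0, 0.02), 0.02 * sqrt(pi / 2), tolerance = 1e-12)
  expect_equal(rice_mean(c(0.3, 2.5), c(0, 0)), c(0.3, 2.5))
  for (ratio in c(0, 0.5, 1, 3, 10, 30, 60, 100)) {
    sg <- 0.7
    expect_equal(rice_mean(ratio * sg, sg), oracle_rice_mean(ratio * sg, sg),
                 tolerance = 1e-8)
  }
  # monotone nondecreasing in both arguments, and >= max(nu, Rayleigh floor)
  nu <- seq(0, 3, length.out = 40)
  m <- rice_mean(nu, 0.5)
  expect_true(all(diff(m) > 0))
  expect_true(all(m >= pmax(nu, 0.5 * sqrt(pi / 2))))
  expect_true(all(diff(rice_mean(1, seq(0.01, 2, length.out = 40))) > 0))
  # high-SNR asymptote
  for (ratio in c(30, 50, 100)) {
    sg <- 0.1; nu1 <- ratio * sg
    expect_lt(abs(rice_mean(nu1, sg) - sqrt(nu1^2 + sg^2)) / nu1, 1e-3)
  }
  expect_error(rice_mean(-1, 1), ">= 0")
})

test_that("analytic forward-model gradients match finite differences", {
  sh <- scheme_shells(nexi_protocol("C2", 32))
  gl <- 24
  opts <- fit_options(lmax = 2, n_nodes = gl)
  base <- c(f = 0.35, Dn = 2.5, De = 0.9, rn = 0.04, p2 = 0.25)
  for (rician in c(FALSE, TRUE)) {
    op <- opts; op$rician_mean <- rician
    fw <- nexifit:::model_forward(matrix(base, 1), sh, op, sigma = 0.02,
                                  grad = TRUE)
    dS0 <- matrix(fw$dS0, nrow(sh), 5)
    dS2 <- matrix(fw$dS2, nrow(sh), 5)
    hstep <- 1e-6
    for (k in 1:5) {
      up <- base; up[k] <- up[k] + hstep
      dn <- base; dn[k] <- dn[k] - hstep
      fu <- nexifit:::model_forward(matrix(up, 1), sh, op, sigma = 0.02)
      fd <- nexifit:::model_forward(matrix(dn, 1), sh, op, sigma = 0.02)
      num0 <- (fu$S0[1, ] - fd$S0[1, ]) / (2 * hstep)
      num2 <- (fu$S2[1, ] - fd$S2[1, ]) / (2 * hstep)
      expect_equal(dS0[, k], num0, tolerance = 1e-5)
      expect_equal(dS2[, k], num2, tolerance = 1e-5)
    }
  }
})

test_that("spherical mean decreases with diffusion time iff exchange is on", {
  p_ex <- tissue_params(0.35, 2.5, 0.9, 0.03)
  p_no <- tissue_params(0.35, 2.5, 0.9, 0)
  for (b in c(2.3, 6.5, 17.5)) {
    K0_ex <- vapply(c(13, 21, 30), function(t)
      project_legendre(function(e) nexi_kernel(b, e, t, p_ex), 0)[[1]],
      numeric(1))
    expect_true(all(diff(K0_ex) < 0))
    K0_no <- vapply(c(13, 21, 30), function(t)
      project_legendre(function(e) nexi_kernel(b, e, t, p_no), 0)[[1]],
      numeric(1))
    expect_lt(diff(range(K0_no)), 1e-12)
  }
})

test_that("kernels stay in [0, 1] over the simulation parameter ranges", {
  tp <- sample_tissue_params(100, seed = 8)
  sh <- rbind(scheme_shells(nexi_protocol("C2", 32)),
              scheme_shells(nexi_protocol("C1", 32)))
  for (eps in c(0, 0.5, 1)) {
    idx <- rep(seq_len(nrow(tp)), each = nrow(sh))
    K <- nexi_kernel(rep(sh$b, nrow(tp)), eps, rep(sh$t, nrow(tp)), tp[idx, ])
    expect_true(all(K >= 0 & K <= 1 + 1e-12))
  }
})
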