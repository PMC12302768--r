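test_that("dictionary matching returns the generating entry and flags zeros", {
  dat <- make_clean_invariants(n = 1, seed = 21)
  opts <- fit_options(lmax = 0, dict_size = 500, seed = 7)
  # build the same dictionary the initializer will draw, pick entry 123,
  # and use its clean forward signal as the measurement: self-match
  set.seed(opts$seed)
  rng <- opts$dict_ranges
  pm <- cbind(f = runif(500, rng$f[1], rng$f[2]),
              Dn = runif(500, rng$Dn[1], rng$Dn[2]),
              De = runif(500, rng$De[1], rng$De[2]),
              rn = runif(500, rng$rn[1], rng$rn[2]))
  entry <- tissue_params(pm[123, 1], pm[123, 2], pm[123, 3], pm[123, 4])
  tab <- nexi_signal_table(entry, dat$scheme, lmax = 0)
  tab$voxel <- 1L
  init <- dictionary_init(tab[, c("voxel", "b", "t", "l", "value")],
                          dat$scheme, opts)
  expect_equal(unname(unlist(init[1, c("f", "Dn", "De", "rn")])),
               unname(pm[123, c("f", "Dn", "De", "rn")]))
  expect_false(init$flagged[1])

  # brute-force argmax oracle on a noisy vector
  noisy <- tab
  set.seed(99)
  noisy$value <- noisy$value + rnorm(nrow(noisy), 0, 0.01)
  init2 <- dictionary_init(noisy[, c("voxel", "b", "t", "l", "value")],
                           dat$scheme, opts)
  sh <- scheme_shells(dat$scheme)
  gl <- nexifit:::gl_nodes(opts$n_nodes)
  D <- nexifit:::cpp_nexi_invariants(cbind(pm, 0), sh$b, sh$t,
                                     gl$nodes, gl$weights)$K0
  y <- dplyr::arrange(noisy[noisy$l == 0, ], t, b)$value
  score <- (D / sqrt(rowSums(D^2))) %*% (y / sqrt(sum(y^2)))
  expect_equal(unname(unlist(init2[1, c("f", "Dn", "De", "rn")])),
               unname(pm[which.max(score), ]))

  # all-zero measurement -> flagged midpoint
  zero <- tab
  zero$value <- 0
  init3 <- dictionary_init(zero[, c("voxel", "b", "t", "l", "value")],
                           dat$scheme, opts)
  expect_true(init3$flagged[1])
  expect_equal(init3$f[1], mean(rng$f))
})

test_that("NLLS is a fixed point at the truth on clean data", {
  dat <- make_clean_invariants(n = 3, seed = 22)
  opts <- fit_options(lmax = 0)
  ft <- fit_nlls(dat$inv, dat$scheme, opts, init = dat$truth)
  expect_equal(ft$estimates$f, dat$truth$f, tolerance = 1e-6)
  expect_equal(ft$estimates$rn, dat$truth$rn, tolerance = 1e-6)
  expect_true(all(ft$estimates$loss < 1e-12))
})

test_that("NLLS with dictionary init recovers clean gray-matter-like draws", {
  dat <- make_clean_invariants(n = 40, seed = 23)
  ft <- fit_nlls(dat$inv, dat$scheme, fit_options(lmax = 0, seed = 5))
  rel <- abs(ft$estimates$tex - dat$truth$tex) / dat$truth$tex
  expect_lt(median(rel), 0.01)
  expect_gt(mean(rel < 0.01), 0.9)
})

test_that("batched Adam stays at the truth and stops early (fixed point)", {
  dat <- make_clean_invariants(n = 1, seed = 24)
  opts <- fit_options(lmax = 0, solver = "adam")
  ft <- fit_adam(dat$inv, dat$scheme, opts, init = dat$truth)
  expect_lt(ft$estimates$loss, 1e-10)
  expect_lt(ft$iterations, 10)
  expect_equal(ft$estimates$f, dat$truth$f, tolerance = 1e-8)
})

test_that("batched Adam agrees with NLLS on clean voxels", {
  dat <- make_clean_invariants(n = 30, seed = 25)
  fn <- fit_nlls(dat$inv, dat$scheme, fit_options(lmax = 0, seed = 5))
  fa <- fit_adam(dat$inv, dat$scheme,
                 fit_options(lmax = 0, solver = "adam", seed = 5))
  rel <- abs(fa$estimates$tex - fn$estimates$tex) / fn$estimates$tex
  expect_lt(median(rel), 0.01)
  expect_lt(unname(quantile(rel, 0.9)), 0.05)
})

test_that("total-variation penalty counts scaled absolute differences", {
  expect_equal(tv_penalty(matrix(0.4, 5, 5)), 0)
  expect_equal(tv_penalty(matrix(c(0, 0.25), 1, 2)), 0.25)
  expect_equal(tv_penalty(matrix(c(0, 0.25), 1, 2), voxel_size = c(2, 2)),
               0.125)
  chk <- outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  expect_equal(tv_penalty(chk), 112)  # 2 * 8 * 7 unit edges
  # masked edges are excluded
  m <- matrix(TRUE, 1, 3)
  m[1, 2] <- FALSE
  expect_equal(tv_penalty(matrix(c(0, 5, 1), 1, 3), m), 0)
})

test_that("estimates respect the parameter box on pure-noise input", {
  set.seed(26)
  sch <- nexi_protocol("C2", 32)
  sh <- scheme_shells(sch)
  inv <- tidyr::crossing(voxel = 1:15, sh[, c("b", "t")], l = 0L)
  inv$value <- abs(rnorm(nrow(inv), 0, 0.05))
  opts <- fit_options(lmax = 0, seed = 3)
  for (ft in list(fit_nlls(inv, sch, opts),
                  fit_adam(inv, sch, fit_options(lmax = 0, solver = "adam",
                                                 seed = 3)))) {
    e <- ft$estimates
    expect_true(all(e$f >= 0 & e$f <= 1))
    expect_true(all(e$Dn >= 0.1 & e$Dn <= 3))
    expect_true(all(e$De >= 0.1 & e$De <= 3))
    expect_true(all(e$rn >= 0 & e$rn <= 1))
  }
})

test_that("fits are deterministic given options and seed", {
  dat <- make_clean_invariants(n = 5, seed = 27)
  noisy <- dat$inv
  set.seed(1)
  noisy$value <- noisy$value + rnorm(nrow(noisy), 0, 0.005)
  o <- fit_options(lmax = 0, solver = "adam", seed = 9, max_iter = 300)
  f1 <- fit_adam(noisy, dat$scheme, o)
  f2 <- fit_adam(noisy, dat$scheme, o)
  expect_identical(f1$estimates, f2$estimates)
  n1 <- fit_nlls(noisy, dat$scheme, fit_options(lmax = 0, seed = 9))
  n2 <- fit_nlls(noisy, dat$scheme, fit_options(lmax = 0, seed = 9))
  expect_identical(n1$estimates, n2$estimates)
})

test_that("the Rician-mean flag requires a noise level", {
  dat <- make_clean_invariants(n = 1, seed = 28)
  opts <- fit_options(lmax = 0, rician_mean = TRUE)
  expect_error(fit_nlls(dat$inv, dat$scheme, opts), "sigma")
  expect_error(fit_adam(dat$inv, dat$scheme, opts), "sigma")
})

test_that("ROI fitting recovers truth and keeps the tex identity", {
  sch <- nexi_protocol("C2", 32)
  truth <- sample_tissue_params(6, seed = 29,
                                ranges = list(tex = c(10, 35), f = c(0.25, 0.4),
                                              Dn = c(2.4, 3), De = c(0.7, 1),
                                              p2 = c(0, 0.3)))
  tab <- nexi_signal_table(truth, sch, lmax = 0)
  tab$label <- tab$draw
  roi <- tab[, c("label", "b", "t", "l", "value")]
  est <- fit_roi(roi, sch, fit_options(lmax = 0, seed = 4))
  expect_equal(nrow(est), 6)
  expect_equal(est$tex, truth$tex, tolerance = 1e-3)
  expect_equal(est$tex, (1 - est$f) / pmax(est$rn, 1e-6), tolerance = 1e-9)
  # an ROI with missing shells is rejected
  expect_error(fit_roi(roi[-2, ], sch, fit_options(lmax = 0)), "missing")
})

test_that("ROI averaging tightens tex spread relative to voxel-wise fits", {
  sch <- nexi_protocol("C2", 32)
  p <- tissue_params(0.33, 2.6, 0.85, (1 - 0.33) / 18, p2 = 0.25)
  set.seed(30)
  n_rep <- 60
  sig <- matrix(directional_signal(sch, p, axis = c(0, 0, 1)), n_rep,
                nrow(sch), byrow = TRUE)
  sig <- add_noise(sig, 50, "gaussian")
  norm <- normalize_b0(sig, sch)
  inv <- extract_invariants(norm$signals, norm$scheme)
  vox_fit <- fit_nlls(inv, sch, fit_options(lmax = 0, seed = 2), sigma = 0.02)
  groups <- rep(1:6, each = n_rep / 6)
  roi <- roi_average_invariants(inv, groups)
  roi_fit <- fit_roi(roi, sch, fit_options(lmax = 0, seed = 2), sigma = 0.02)
  expect_lt(IQR(roi_fit$tex), IQR(vox_fit$estimates$tex))
})

test_that("broom-style accessors summarize fits", {
  dat <- make_clean_invariants(n = 4, seed = 31)
  ft <- fit_nlls(dat$inv, dat$scheme, fit_options(lmax = 0, seed = 5))
  td <- tidy(ft)
  expect_true(all(c("voxel", "parameter", "estimate") %in% names(td)))
  expect_setequal(unique(td$parameter), c("f", "Dn", "De", "rn", "tex"))
  gl <- glance(ft)
  expect_equal(gl$n_voxels, 4)
  expect_s3_class(autoplot(ft), "ggplot")
})
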