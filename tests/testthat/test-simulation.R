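test_that("parameter sampling respects ranges, the constraint and the seed", {
  tp <- sample_tissue_params(500, seed = 1)
  expect_true(all(tp$tex >= 1 & tp$tex <= 50))
  expect_true(all(tp$f >= 0.01 & tp$f <= 0.99))
  expect_true(all(tp$Dn >= tp$De))
  expect_true(all(tp$p2 >= 0 & tp$p2 <= 0.3))
  expect_equal(tp$rn, (1 - tp$f) / tp$tex)
  expect_identical(tp, sample_tissue_params(500, seed = 1))
  expect_false(identical(tp$f, sample_tissue_params(500, seed = 2)$f))
  expect_error(
    sample_tissue_params(10, ranges = list(tex = c(1, 50), f = c(0.1, 0.9),
                                           Dn = c(0.1, 0.2), De = c(2, 3),
                                           p2 = c(0, 0.3)), seed = 1),
    "infeasible")
})

test_that("noise injection has the advertised statistics", {
  x <- matrix(0.5, 100, 10)
  expect_identical(add_noise(x, 50, "none"), x)
  expect_error(add_noise(x, -3, "gaussian"), "snr")
  set.seed(2)
  g <- add_noise(matrix(0.5, 1, 1e5), 50, "gaussian")
  expect_lt(abs(mean(g) - 0.5), 3 * 0.02 / sqrt(1e5))
  # Rayleigh floor: zero signal acquires mean sigma * sqrt(pi/2)
  r <- add_noise(matrix(0, 1, 1e5), 50, "rician")
  expect_equal(mean(r), 0.02 * sqrt(pi / 2), tolerance = 0.01)
  expect_true(all(r >= 0))
  # seeded reproducibility
  expect_identical(add_noise(x, 50, "rician", seed = 7),
                   add_noise(x, 50, "rician", seed = 7))
})

test_that("noise propagation is seeded end to end and self-consistent", {
  r1 <- run_noise_propagation("C2", noise = "gaussian", snr = 50, n = 15,
                              directions = 32, seed = 5)
  r2 <- run_noise_propagation("C2", noise = "gaussian", snr = 50, n = 15,
                              directions = 32, seed = 5)
  expect_identical(r1$draws, r2$draws)
  # emitted files are byte-identical
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_propagation(r1, d1); write_propagation(r2, d2)
  expect_identical(readLines(file.path(d1, "draws.tsv")),
                   readLines(file.path(d2, "draws.tsv")))
  # summary is recomputable from the stored draws
  expect_equal(summarize_propagation(r1$draws), r1$summary)
  # accessors
  expect_identical(tidy(r1), r1$draws)
  expect_equal(glance(r1)$n, 15)
  expect_s3_class(autoplot(r1), "ggplot")
})

test_that("a noiseless phantom is recovered label by label", {
  spec <- phantom_spec(nx = 24, ny = 24, n_labels = 6, snr = Inf,
                       protocol = "C2", directions = 32, seed = 6)
  ph <- make_phantom(spec)
  expect_true(all(sort(unique(ph$labels[ph$labels > 0])) %in% ph$truth$label))
  vox <- which(ph$mask)
  dmat <- matrix(ph$dwi, ncol = dim(ph$dwi)[4])[vox, , drop = FALSE]
  norm <- normalize_b0(dmat, ph$scheme)
  inv <- extract_invariants(norm$signals, norm$scheme)
  ft <- fit_nlls(inv, ph$scheme, fit_options(lmax = 2, seed = 2))
  ev <- evaluate_maps(ft$estimates, ph$truth, ph$labels[vox])
  tex_rows <- ev[ev$parameter == "tex", ]
  truth_tex <- ph$truth$tex[match(tex_rows$label, ph$truth$label)]
  expect_true(all(abs(tex_rows$bias) / truth_tex < 0.01))
})

test_that("label ordering of exchange times survives noise", {
  truth <- tibble::tibble(label = 1:6,
                          f = 0.33, Dn = 2.6, De = 0.85,
                          tex = rep(c(10, 40), 3),
                          rn = (1 - f) / tex, p2 = 0.25)
  spec <- phantom_spec(nx = 24, ny = 24, n_labels = 6, snr = 50,
                       protocol = "C2", directions = 32, seed = 7,
                       truth = truth)
  ph <- make_phantom(spec)
  vox <- which(ph$mask)
  dmat <- matrix(ph$dwi, ncol = dim(ph$dwi)[4])[vox, , drop = FALSE]
  norm <- normalize_b0(dmat, ph$scheme)
  inv <- extract_invariants(norm$signals, norm$scheme)
  ft <- fit_nlls(inv, ph$scheme, fit_options(lmax = 2, seed = 2),
                 sigma = ph$sigma)
  med <- tapply(ft$estimates$tex, ph$labels[vox], median)
  fast <- med[as.character(which(truth$tex == 10))]
  slow <- med[as.character(which(truth$tex == 40))]
  expect_true(all(outer(fast, slow, `<`)))
})

test_that("phantom construction validates its ground-truth table", {
  bad <- tibble::tibble(label = 1:3, f = 0.3, Dn = 2.5, De = 0.9,
                        rn = 0.03, p2 = 0.2)
  spec <- phantom_spec(nx = 16, ny = 16, n_labels = 6, snr = 50, seed = 1,
                       truth = bad)
  expect_error(make_phantom(spec), "without ground-truth")
  expect_error(phantom_spec(snr = 0), "snr")
  expect_error(phantom_spec(n_labels = 2), "n_labels")
})

test_that("map evaluation reports exact bias and IQR identities", {
  est <- data.frame(f = c(0.3, 0.31, 0.29, 0.5), tex = c(10, 11, 9, 20))
  truth <- data.frame(f = c(0.3, 0.3, 0.3, 0.5), tex = c(10, 10, 10, 20))
  labels <- c(1, 1, 1, 2)
  ev <- evaluate_maps(est, truth, labels)
  expect_equal(ev$bias[ev$label == 1 & ev$parameter == "f"], 0)
  expect_equal(ev$bias[ev$label == 2 & ev$parameter == "tex"], 0)
  ev2 <- evaluate_maps(transform(est, tex = tex + 1), truth, labels)
  expect_equal(ev2$bias[ev2$parameter == "tex"], c(1, 1))
  expect_equal(ev2$iqr[ev2$label == 2 & ev2$parameter == "tex"], 0)
  expect_error(evaluate_maps(est[1:2, ], truth, labels), "mismatch")
})

test_that("the finite-pulse generator feeds the propagation pipeline", {
  r <- run_noise_propagation("C2", generator = "smex", delta = 6,
                             noise = "none", snr = Inf, n = 8,
                             directions = 32, seed = 8)
  tex_sum <- r$summary[r$summary$parameter == "tex" &
                         r$summary$stratum == "all", ]
  # fitting NEXI to clean finite-pulse signals leaves only the small
  # narrow-pulse model error
  expect_lt(abs(tex_sum$bias), 2)
})
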