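# In-silico experiments: random tissue-parameter sampling, noise injection,
# the end-to-end noise-propagation pipeline (generate -> corrupt -> extract
# invariants -> initialize -> fit -> summarize bias/IQR), and a labelled
# geometric head phantom with evaluation utilities.

#' Sample random tissue parameters
#'
#' Independent uniform draws of `tex`, `f`, `Dn`, `De` (and `p2`), with
#' pairs violating `Dn >= De` redrawn by rejection, and `rn` derived as
#' `(1 - f)/tex`.  Deterministic for a given seed.
#'
#' @param n Number of draws.
#' @param ranges Named list of `c(lower, upper)` ranges.  Defaults:
#'   `tex` in `[1, 50]` ms, `f` in `[0.01, 0.99]`, `Dn` and `De` in
#'   `[0.1, 3]` um^2/ms (with `Dn >= De`), `p2` in `[0, 0.3]`.
#' @param seed Seed.
#' @param require_dn_ge_de Enforce `Dn >= De` by rejection (default `TRUE`).
#' @return A tissue-parameter tibble (see [tissue_params()]).
#' @export
sample_tissue_params <- function(n,
                                 ranges = list(tex = c(1, 50),
                                               f = c(0.01, 0.99),
                                               Dn = c(0.1, 3),
                                               De = c(0.1, 3),
                                               p2 = c(0, 0.3)),
                                 seed = 1, require_dn_ge_de = TRUE) {
  for (nm in names(ranges))
    if (ranges[[nm]][1] > ranges[[nm]][2])
      abort(paste("invalid range for", nm))
  if (require_dn_ge_de && ranges$Dn[2] < ranges$De[1])
    abort("infeasible ranges: Dn can never reach De (Dn >= De required)")
  set.seed(seed)
  tex <- runif(n, ranges$tex[1], ranges$tex[2])
  f <- runif(n, ranges$f[1], ranges$f[2])
  Dn <- runif(n, ranges$Dn[1], ranges$Dn[2])
  De <- runif(n, ranges$De[1], ranges$De[2])
  if (require_dn_ge_de) {
    bad <- which(Dn < De)
    guard <- 0
    while (length(bad)) {
      Dn[bad] <- runif(length(bad), ranges$Dn[1], ranges$Dn[2])
      De[bad] <- runif(length(bad), ranges$De[1], ranges$De[2])
      bad <- bad[Dn[bad] < De[bad]]
      guard <- guard + 1
      if (guard > 10000) abort("rejection sampling cannot satisfy Dn >= De")
    }
  }
  p2 <- runif(n, ranges$p2[1], ranges$p2[2])
  tissue_params(f = f, Dn = Dn, De = De, rn = (1 - f) / tex, p2 = p2)
}

#' Add measurement noise to b0-normalized signals
#'
#' `gaussian` adds real Gaussian noise of standard deviation `1/SNR`;
#' `rician` takes the magnitude of the signal plus complex Gaussian noise
#' (`|s + N(0, sigma) + i N(0, sigma)|`); `none` returns the input.
#'
#' @param signals Numeric vector/matrix of b0-normalized signals.
#' @param snr Signal-to-noise ratio at b = 0 (`sigma = 1/snr`); must be
#'   `> 0` (may be `Inf`).
#' @param mode `"gaussian"`, `"rician"`, or `"none"`.
#' @param seed Optional seed (omit to use the current RNG stream).
#' @return Noisy signals, same shape.
#' @export
add_noise <- function(signals, snr, mode = c("gaussian", "rician", "none"),
                      seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "none") return(signals)
  if (!is.numeric(snr) || snr <= 0) abort("snr must be > 0")
  if (!is.finite(snr)) return(signals)
  if (!is.null(seed)) set.seed(seed)
  sigma <- 1 / snr
  n <- length(signals)
  if (mode == "gaussian") {
    signals + array(rnorm(n, 0, sigma), dim(signals) %||% n)
  } else {
    re <- signals + rnorm(n, 0, sigma)
    im <- rnorm(n, 0, sigma)
    out <- sqrt(re^2 + im^2)
    if (!is.null(dim(signals))) dim(out) <- dim(signals)
    out
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# per-direction signal matrix (draws x volumes) for a parameter table with
# per-draw ODF axes, from signed invariants K0/K2
directional_signal_matrix <- function(params, scheme, axes,
                                      generator = "nexi", delta = NULL,
                                      ramp = NULL, n_nodes = 60) {
  pm <- params_matrix(params)
  shells <- distinct(filter(scheme, !.data$b0),
                     .data$b, .data$t, .data$delta, .data$ramp)
  gl <- gl_nodes(n_nodes)
  inv <- if (generator == "nexi") {
    cpp_nexi_invariants(pm, shells$b, shells$t, gl$nodes, gl$weights)
  } else if (generator == "smex") {
    d <- if (is.null(delta)) shells$delta[1] else delta
    r <- if (is.null(ramp)) shells$ramp[1] else ramp
    cpp_smex_invariants(pm[, 1:4, drop = FALSE], shells$b, shells$t, d,
                        max(r, 1e-9), gl$nodes, gl$weights, 1e-6)
  } else abort("generator must be 'nexi' or 'smex'")
  n <- nrow(pm)
  sig <- matrix(1, n, nrow(scheme))
  dw <- which(!scheme$b0)
  dirs <- as.matrix(scheme[dw, c("gx", "gy", "gz")])
  u <- axes %*% t(dirs)                      # n x ndw
  P2u <- legendre_poly(2, as.vector(u))
  dim(P2u) <- dim(u)
  shell_of <- match(paste(scheme$b[dw], scheme$t[dw]),
                    paste(shells$b, shells$t))
  sig[, dw] <- inv$K0[, shell_of, drop = FALSE] +
    5 * pm[, "p2"] * inv$K2[, shell_of, drop = FALSE] * P2u
  sig
}

random_axes <- function(n) {
  v <- matrix(rnorm(3 * n), n, 3)
  v / sqrt(rowSums(v^2))
}

#' End-to-end noise-propagation experiment
#'
#' Reproduces the simulation pipeline: sample ground-truth tissue
#' parameters, forward-simulate per-direction signals under a fixture
#' protocol (analytic narrow-pulse or finite-pulse generation), corrupt
#' them with Gaussian or Rician noise at the target b = 0 SNR, extract
#' rotational invariants, initialize by dictionary matching, fit, and
#' summarize the estimation error.  Every stage draws from one seeded RNG
#' stream, so identical configurations reproduce identical results.
#'
#' @param protocol `"C1"` or `"C2"`.
#' @param generator `"nexi"` or `"smex"` (finite pulses).
#' @param delta Pulse-duration override (ms) for SMEX generation.
#' @param noise `"gaussian"`, `"rician"` (uncorrected), `"rician-mean"`
#'   (Rician noise with the Rice-mean forward correction), or `"none"`.
#' @param snr b = 0 SNR (default 50; `Inf` allowed with `noise = "none"`).
#' @param n Number of parameter draws.
#' @param lmax Fit order (0 or 2).
#' @param directions Gradient directions per shell (default 64).
#' @param solver `"nlls"` or `"adam"`.
#' @param seed Seed for all stages.
#' @param ranges Ground-truth sampling ranges (see
#'   [sample_tissue_params()]).
#' @param options Optional [fit_options()] override (lmax/seed/rician flags
#'   are set from the arguments above when omitted).
#' @return A `nexi_propagation` object: `$draws` (truth, estimates, errors),
#'   `$summary` (median bias and IQR per parameter, overall and stratified
#'   at tex = 20 ms), `$config`.
#' @export
run_noise_propagation <- function(protocol = "C2", generator = "nexi",
                                  delta = NULL,
                                  noise = c("gaussian", "rician",
                                            "rician-mean", "none"),
                                  snr = 50, n = 1000, lmax = 0,
                                  directions = 64, solver = "nlls",
                                  seed = 1, ranges = NULL, options = NULL) {
  noise <- match.arg(noise)
  if (noise != "none" && (!is.numeric(snr) || snr <= 0))
    abort("snr must be > 0")
  scheme <- nexi_protocol(protocol, directions)
  if (is.null(ranges))
    truth <- sample_tissue_params(n, seed = seed)
  else
    truth <- sample_tissue_params(n, ranges = ranges, seed = seed)
  axes <- random_axes(n)  # consumes the same seeded stream
  sig <- directional_signal_matrix(truth, scheme, axes,
                                   generator = generator, delta = delta)
  noise_mode <- switch(noise, "gaussian" = "gaussian", "none" = "none",
                       "rician")
  sig <- add_noise(sig, snr, noise_mode)
  norm <- normalize_b0(sig, scheme)
  inv <- extract_invariants(norm$signals, norm$scheme, lmax_fit = 4)
  if (is.null(options)) {
    options <- fit_options(lmax = lmax, seed = seed,
                           rician_mean = (noise == "rician-mean"))
  }
  sigma_fit <- if (is.finite(snr)) 1 / snr else 0
  init <- dictionary_init(inv, scheme, options)
  fit <- if (solver == "adam") {
    fit_adam(inv, scheme, options, init = init, sigma = sigma_fit)
  } else {
    fit_nlls(inv, scheme, options, init = init, sigma = sigma_fit)
  }
  est <- fit$estimates
  draws <- tibble(draw = seq_len(n),
                  f_true = truth$f, Dn_true = truth$Dn, De_true = truth$De,
                  rn_true = truth$rn, tex_true = truth$tex,
                  p2_true = truth$p2,
                  f_est = est$f, Dn_est = est$Dn, De_est = est$De,
                  rn_est = est$rn, tex_est = est$tex, p2_est = est$p2)
  config <- list(protocol = protocol, generator = generator, delta = delta,
                 noise = noise, snr = snr, n = n, lmax = lmax,
                 directions = directions, solver = solver, seed = seed)
  structure(list(draws = draws, summary = summarize_propagation(draws),
                 config = config, fit = fit),
            class = "nexi_propagation")
}

#' Bias/IQR summary of a propagation experiment
#'
#' Median error (bias) and interquartile range of the error per parameter,
#' overall and stratified by ground-truth exchange time at 20 ms.
#'
#' @param draws Draw table of a `nexi_propagation` (columns `*_true`,
#'   `*_est`).
#' @return Tibble `parameter, stratum, n, bias, iqr`.
#' @export
summarize_propagation <- function(draws) {
  pars <- c("f", "Dn", "De", "rn", "tex", "p2")
  pars <- pars[paste0(pars, "_est") %in% names(draws)]
  strata <- list(all = rep(TRUE, nrow(draws)),
                 `tex<=20` = draws$tex_true <= 20,
                 `tex>20` = draws$tex_true > 20)
  out <- list()
  for (p in pars) {
    err <- draws[[paste0(p, "_est")]] - draws[[paste0(p, "_true")]]
    if (all(is.na(err))) next
    for (s in names(strata)) {
      sel <- strata[[s]] & is.finite(err)
      out[[length(out) + 1]] <-
        tibble(parameter = p, stratum = s, n = sum(sel),
               bias = median(err[sel]), iqr = IQR(err[sel]))
    }
  }
  bind_rows(out)
}

#' @export
print.nexi_propagation <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<nexi_propagation> %s/%s, noise %s, SNR %s, n = %d, lmax = %d, %s\n",
    cfg$protocol, cfg$generator, cfg$noise, format(cfg$snr), cfg$n,
    cfg$lmax, cfg$solver))
  print(filter(x$summary, .data$stratum == "all"))
  invisible(x)
}

#' @export
tidy.nexi_propagation <- function(x, ...) x$draws

#' @export
glance.nexi_propagation <- function(x, ...) {
  s <- filter(x$summary, .data$parameter == "tex", .data$stratum == "all")
  tibble(protocol = x$config$protocol, generator = x$config$generator,
         noise = x$config$noise, snr = x$config$snr, n = x$config$n,
         lmax = x$config$lmax, solver = x$config$solver,
         tex_bias = s$bias, tex_iqr = s$iqr)
}

#' Error box plots of a propagation experiment
#' @param object A `nexi_propagation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nexi_propagation <- function(object, ...) {
  d <- object$draws
  pars <- c("f", "Dn", "De", "rn", "tex", "p2")
  long <- bind_rows(lapply(pars, function(p) {
    en <- paste0(p, "_est"); tn <- paste0(p, "_true")
    if (!en %in% names(d) || all(is.na(d[[en]]))) return(NULL)
    tibble(parameter = p, error = d[[en]] - d[[tn]])
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$parameter, y = .data$error)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.2, fill = "steelblue") +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(y = "estimate - truth") +
    ggplot2::theme_minimal()
}

#' Write a propagation experiment to TSV files
#'
#' Emits `draws.tsv` and `summary.tsv` (plus a JSON config) in a directory;
#' numbers are written with full precision so identical configurations give
#' byte-identical files.
#'
#' @param x A `nexi_propagation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_propagation <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(df) {
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) sprintf("%.12g", v))
    df
  }
  write.table(fmt(x$draws), file.path(dir, "draws.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(fmt(x$summary), file.path(dir, "summary.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  jsonlite::write_json(x$config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Specification of a labelled geometric phantom
#'
#' A single-slice "head" of concentric parcels: a two-region core
#' surrounded by a cortical-like ribbon split into angular sectors.  Every
#' nonzero label carries one ground-truth tissue-parameter row; defaults
#' span gray-matter-like magnitudes (f 0.25-0.40, Dn 2.4-3.0 um^2/ms,
#' De 0.75-0.95 um^2/ms, tex 10-35 ms, p2 0.18-0.30), drawn
#' deterministically from the seed.
#'
#' @param nx,ny Grid size (default 64 x 64, ~3200 in-mask voxels).
#' @param n_labels Total number of parcels (>= 3; default 20).
#' @param snr b = 0 SNR of the Gaussian noise (`Inf` for noiseless).
#' @param protocol `"C1"` or `"C2"`.
#' @param directions Directions per shell.
#' @param voxel_size In-plane voxel size (mm).
#' @param seed Seed for truth draws, ODF axes and noise.
#' @param truth Optional ground-truth table with columns `label, f, Dn,
#'   De, rn, p2` overriding the defaults.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(nx = 64, ny = 64, n_labels = 20, snr = 50,
                         protocol = "C2", directions = 32,
                         voxel_size = c(2, 2), seed = 1, truth = NULL) {
  if (n_labels < 3) abort("n_labels must be >= 3")
  if (!is.numeric(snr) || snr <= 0) abort("snr must be > 0")
  structure(list(nx = nx, ny = ny, n_labels = n_labels, snr = snr,
                 protocol = protocol, directions = directions,
                 voxel_size = voxel_size, seed = seed, truth = truth),
            class = "phantom_spec")
}

phantom_labels <- function(spec) {
  nx <- spec$nx; ny <- spec$ny
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  xg <- matrix(seq_len(nx), nx, ny)
  yg <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  r <- sqrt((xg - cx)^2 + (yg - cy)^2) / (min(nx, ny) / 2)
  th <- atan2(yg - cy, xg - cx)
  lab <- matrix(0L, nx, ny)
  lab[r <= 0.30] <- 1L                       # deep core
  lab[r > 0.30 & r <= 0.55] <- 2L            # outer core
  ring <- r > 0.55 & r <= 0.95
  nsec <- spec$n_labels - 2
  sec <- pmin(floor((th + pi) / (2 * pi) * nsec), nsec - 1)
  lab[ring] <- 3L + as.integer(sec[ring])
  array(lab, c(nx, ny, 1))
}

default_phantom_truth <- function(n_labels) {
  tibble(label = seq_len(n_labels),
         f = runif(n_labels, 0.25, 0.40),
         Dn = runif(n_labels, 2.4, 3.0),
         De = runif(n_labels, 0.75, 0.95),
         rn = NA_real_,
         tex = runif(n_labels, 10, 35),
         p2 = runif(n_labels, 0.18, 0.30)) %>%
    mutate(rn = (1 - .data$f) / .data$tex)
}

#' Generate a labelled in-silico phantom
#'
#' Forward-simulates per-direction signals for every in-mask voxel from its
#' label's ground-truth parameters (one random ODF axis per voxel), adds
#' Gaussian noise at the specified SNR, and returns the noisy 4D volume
#' with the label map, truth table and scheme.
#'
#' @param spec A [phantom_spec()].
#' @return List with `dwi` (nx x ny x 1 x volumes), `labels`, `mask`,
#'   `truth`, `scheme`, `sigma`, `voxel_size`, `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  labels <- phantom_labels(spec)
  set.seed(spec$seed)
  truth <- spec$truth %||% default_phantom_truth(spec$n_labels)
  present <- sort(unique(labels[labels > 0]))
  missing_lab <- setdiff(present, truth$label)
  if (length(missing_lab))
    abort(paste("labels without ground-truth parameters:",
                paste(missing_lab, collapse = ", ")))
  scheme <- nexi_protocol(spec$protocol, spec$directions)
  mask <- labels > 0
  vox <- which(mask)
  axes <- random_axes(length(vox))
  pv <- truth[match(labels[vox], truth$label), ]
  sig <- directional_signal_matrix(pv, scheme, axes)
  sig <- add_noise(sig, spec$snr, if (is.finite(spec$snr)) "gaussian" else "none")
  dwi <- array(0, c(dim(labels), nrow(scheme)))
  for (j in seq_len(nrow(scheme)))
    dwi[, , , j][vox] <- sig[, j]
  list(dwi = dwi, labels = labels, mask = mask, truth = truth,
       scheme = scheme, sigma = if (is.finite(spec$snr)) 1 / spec$snr else 0,
       voxel_size = spec$voxel_size, spec = spec)
}

#' Per-region bias and IQR of estimated maps
#'
#' For every label and parameter: the median difference between estimates
#' and ground truth (bias) and the interquartile range of the estimates
#' within the region.
#'
#' @param estimates Per-voxel estimate table (columns `f, Dn, De, rn, tex`,
#'   optionally `p2`), one row per in-mask voxel.
#' @param truth Either a per-voxel table of the same shape or a per-label
#'   table with a `label` column.
#' @param labels Integer labels per in-mask voxel (same length/order as
#'   `estimates` rows).
#' @return Tibble `label, parameter, n, bias, iqr`.
#' @export
evaluate_maps <- function(estimates, truth, labels) {
  estimates <- as.data.frame(estimates)
  if (nrow(estimates) != length(labels))
    abort("estimates and labels have mismatched sizes")
  if ("label" %in% names(truth)) {
    truth <- as.data.frame(truth)[match(labels, truth$label), , drop = FALSE]
  } else {
    truth <- as.data.frame(truth)
    if (nrow(truth) != nrow(estimates))
      abort("truth and estimates have mismatched sizes")
  }
  if (!"tex" %in% names(truth) && all(c("f", "rn") %in% names(truth)))
    truth$tex <- (1 - truth$f) / pmax(truth$rn, 1e-6)
  pars <- intersect(c("f", "Dn", "De", "rn", "tex", "p2"), names(estimates))
  pars <- intersect(pars, names(truth))
  out <- list()
  for (lb in sort(unique(labels[labels > 0]))) {
    sel <- labels == lb
    for (p in pars) {
      e <- estimates[[p]][sel]; tr <- truth[[p]][sel]
      if (all(is.na(e))) next
      out[[length(out) + 1]] <-
        tibble(label = lb, parameter = p, n = sum(sel),
               bias = median(e - tr, na.rm = TRUE),
               iqr = IQR(e, na.rm = TRUE))
    }
  }
  bind_rows(out)
}
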