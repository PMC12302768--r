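# Parameter estimation from rotational invariants: dictionary-matching
# initialization, bounded voxel-wise nonlinear least squares, and batched
# Adam optimization of all masked voxels under a single loss, with optional
# 2D total-variation regularization of the neurite-fraction map and an
# optional Rician-mean forward correction of S0.

W_L <- function(l) 1 / sqrt(4 * pi * (2 * l + 1))

#' Fitting options
#'
#' Collects solver settings and bounds.  Rates are in 1/ms throughout (the
#' exchange-time scale `tex = (1 - f)/rn` in milliseconds fixes the unit).
#'
#' @param lmax Fit order: 0 (spherical mean only) or 2 (adds `S2` and the
#'   dispersion invariant `p2`).
#' @param loss Loss for the batched solver: `"l1"` (default), `"l2"`, or
#'   `"mse"`.
#' @param solver `"nlls"` or `"adam"`.
#' @param bounds Named list of `c(lower, upper)` per parameter.
#' @param max_iter,tol Adam stopping rule: iteration cap (4000) and absolute
#'   loss-change tolerance (1e-8).
#' @param lr Adam learning rate on the bounded reparameterization.
#' @param lambda Total-variation weight (mm); 0 disables, 0.002 is the
#'   default regularized setting.
#' @param rician_mean Use the Rice-distribution mean as the l = 0 forward
#'   model (requires `sigma` at fit time).
#' @param dict_size,dict_ranges Dictionary-matching initialization: number
#'   of entries and uniform sampling ranges.
#' @param exclude_b Shells excluded from fitting (default b = 1 ms/um^2).
#' @param n_nodes Gauss-Legendre order of the kernel projection (default 24;
#'   machine-precision accurate over the protocol b-value range).
#' @param seed Seed fixing all stochastic choices (dictionary draws).
#' @return A list of class `nexi_options`.
#' @export
fit_options <- function(lmax = 0, loss = c("l1", "l2", "mse"),
                        solver = c("nlls", "adam"),
                        bounds = list(f = c(0, 1), Dn = c(0.1, 3),
                                      De = c(0.1, 3), rn = c(0, 1),
                                      p2 = c(0, 1)),
                        max_iter = 4000, tol = 1e-8, lr = 0.01,
                        lambda = 0, rician_mean = FALSE,
                        dict_size = 10000,
                        dict_ranges = list(f = c(0.01, 0.99),
                                           Dn = c(1.5, 3), De = c(0.5, 1.5),
                                           rn = c(0.001, 0.99),
                                           p2 = c(0, 0.6)),
                        exclude_b = 1, n_nodes = 24, seed = 1) {
  loss <- match.arg(loss)
  solver <- match.arg(solver)
  if (!lmax %in% c(0, 2)) abort("lmax must be 0 or 2")
  for (nm in names(bounds))
    if (bounds[[nm]][1] >= bounds[[nm]][2])
      abort(paste("invalid bounds for", nm))
  if (lambda < 0) abort("lambda must be >= 0")
  structure(list(lmax = lmax, loss = loss, solver = solver, bounds = bounds,
                 max_iter = max_iter, tol = tol, lr = lr, lambda = lambda,
                 rician_mean = rician_mean, dict_size = dict_size,
                 dict_ranges = dict_ranges, exclude_b = exclude_b,
                 n_nodes = n_nodes, seed = seed),
            class = "nexi_options")
}

param_names <- function(lmax) {
  c("f", "Dn", "De", "rn", if (lmax >= 2) "p2")
}

# long invariant table -> list(Y = V x (S*L) matrix, shells, voxels, lmax)
inv_matrices <- function(inv, shells, lmax) {
  key <- paste(shells$t, shells$b)
  vox <- sort(unique(inv$voxel))
  grab <- function(l) {
    sub <- filter(inv, .data$l == !!l)
    if (!nrow(sub)) return(NULL)
    m <- matrix(NA_real_, length(vox), nrow(shells))
    idx_v <- match(sub$voxel, vox)
    idx_s <- match(paste(sub$t, sub$b), key)
    ok <- !is.na(idx_s)
    m[cbind(idx_v[ok], idx_s[ok])] <- sub$value[ok]
    if (anyNA(m)) abort("invariant table is missing shells required for fitting")
    m
  }
  Y0 <- grab(0L)
  Y2 <- if (lmax >= 2) grab(2L) else NULL
  if (lmax >= 2 && is.null(Y2))
    abort("lmax = 2 fitting requires l = 2 invariants")
  if (!is.null(Y2)) Y2 <- pmax(Y2, 0)  # model S2 = p2|K2| >= 0
  list(Y0 = Y0, Y2 = Y2, voxels = vox, shells = shells)
}

model_forward <- function(pm, shells, opts, sigma = NULL, grad = FALSE) {
  gl <- gl_nodes(opts$n_nodes)
  sg <- if (is.null(sigma)) numeric(0) else as.numeric(sigma)
  cpp_nexi_forward(pm, shells$b, shells$t, gl$nodes, gl$weights,
                   opts$lmax, isTRUE(opts$rician_mean), sg, grad)
}

#' Dictionary-matching initialization
#'
#' Draws `dict_size` parameter sets uniformly over the dictionary ranges,
#' forward-simulates their invariant vectors once, L2-normalizes dictionary
#' entries and measured vectors, and initializes every voxel at the entry
#' with the largest inner product (ties broken by lowest index).  All-zero
#' measured vectors are flagged and set to the range midpoints.
#'
#' @param inv Invariant table `voxel, b, t, l, value`.
#' @param scheme Scheme tibble (shells taken via [scheme_shells()]).
#' @param options A [fit_options()] list (`seed`, `dict_size`,
#'   `dict_ranges`, `lmax` are used).
#' @return Tibble of initial parameters per voxel with a `flagged` column.
#' @export
dictionary_init <- function(inv, scheme, options = fit_options()) {
  shells <- scheme_shells(scheme, exclude_b = options$exclude_b)
  dat <- inv_matrices(inv, shells, options$lmax)
  rng <- options$dict_ranges
  N <- options$dict_size
  set.seed(options$seed)
  draw <- function(r) runif(N, r[1], r[2])
  pm <- cbind(f = draw(rng$f), Dn = draw(rng$Dn), De = draw(rng$De),
              rn = draw(rng$rn),
              p2 = if (options$lmax >= 2) draw(rng$p2) else rep(0, N))
  opts_clean <- options
  opts_clean$rician_mean <- FALSE  # dictionary is built on the clean model
  fw <- model_forward(pm, shells, opts_clean)
  D <- fw$S0
  Y <- dat$Y0
  if (options$lmax >= 2) {
    D <- cbind(D, fw$S2)
    Y <- cbind(Y, dat$Y2)
  }
  Dn2 <- sqrt(rowSums(D^2))
  Dn2[Dn2 == 0] <- 1
  Dnorm <- D / Dn2
  ynorm <- sqrt(rowSums(Y^2))
  flagged <- !is.finite(ynorm) | ynorm == 0
  ysafe <- ifelse(flagged, 1, ynorm)
  score <- (Y / ysafe) %*% t(Dnorm)
  best <- max.col(score, ties.method = "first")
  init <- pm[best, , drop = FALSE]
  if (any(flagged)) {
    mid <- vapply(c("f", "Dn", "De", "rn", "p2"),
                  function(nm) mean(rng[[nm]]), numeric(1))
    init[flagged, ] <- matrix(mid, sum(flagged), 5, byrow = TRUE)
  }
  out <- as_tibble(as.data.frame(init))
  out$voxel <- dat$voxels
  out$flagged <- flagged
  out[, c("voxel", param_names(options$lmax), "flagged")]
}

finish_fit <- function(est, dat, opts, solver, loss_trace = NULL,
                       iterations = NA_integer_, converged = NA) {
  est <- as_tibble(est)
  est$re <- ifelse(est$f < 1, est$rn * est$f / (1 - est$f), Inf)
  est$tex <- (1 - est$f) / pmax(est$rn, 1e-6)
  structure(list(estimates = est, solver = solver, options = opts,
                 shells = dat$shells, loss_trace = loss_trace,
                 iterations = iterations, converged = converged),
            class = "nexi_fit")
}

#' Voxel-wise bounded nonlinear least squares
#'
#' Fits the exchange-model invariants independently per voxel by bounded
#' Levenberg-Marquardt on the weighted residuals
#' `Wl (Sl,meas - Sl,model)` stacked over shells and orders, with analytic
#' Jacobians.  With `rician_mean` enabled the l = 0 model prediction is the
#' directional average of the Rice mean of the per-direction model signal,
#' using each voxel's noise level.
#'
#' @param inv Invariant table `voxel, b, t, l, value`.
#' @param scheme Scheme tibble.
#' @param options A [fit_options()] list.
#' @param init Optional initial parameter table (defaults to
#'   [dictionary_init()]).
#' @param sigma Per-voxel noise level (b0-normalized units); scalar or
#'   vector.  Required when `options$rician_mean` is `TRUE`.
#' @return A `nexi_fit` object; `$estimates` holds per-voxel `f, Dn, De,
#'   rn` (+ `p2`), derived `re`, `tex`, the final sum-of-squares `loss`,
#'   iteration counts and convergence flags.
#' @export
fit_nlls <- function(inv, scheme, options = fit_options(), init = NULL,
                     sigma = NULL) {
  if (isTRUE(options$rician_mean) && is.null(sigma))
    abort("rician_mean fitting requires sigma")
  shells <- scheme_shells(scheme, exclude_b = options$exclude_b)
  dat <- inv_matrices(inv, shells, options$lmax)
  if (is.null(init)) init <- dictionary_init(inv, scheme, options)
  pn <- param_names(options$lmax)
  init_m <- as.matrix(as.data.frame(init)[, pn, drop = FALSE])
  V <- nrow(dat$Y0)
  if (nrow(init_m) != V) abort("init rows do not match voxel count")
  sig <- if (is.null(sigma)) rep(0, V) else rep_len(sigma, V)
  lo <- vapply(pn, function(nm) options$bounds[[nm]][1], numeric(1))
  hi <- vapply(pn, function(nm) options$bounds[[nm]][2], numeric(1))
  w <- c(rep(W_L(0), nrow(shells)),
         if (options$lmax >= 2) rep(W_L(2), nrow(shells)))
  P <- length(pn)

  fit_one <- function(v) {
    yv <- c(dat$Y0[v, ], if (options$lmax >= 2) dat$Y2[v, ])
    resid_fn <- function(par) {
      pm <- matrix(c(par, if (P == 4) 0), 1, 5)
      fw <- model_forward(pm, shells, options, sigma = sig[v])
      pred <- c(fw$S0[1, ], if (options$lmax >= 2) fw$S2[1, ])
      w * (yv - pred)
    }
    jac_fn <- function(par) {
      pm <- matrix(c(par, if (P == 4) 0), 1, 5)
      fw <- model_forward(pm, shells, options, sigma = sig[v], grad = TRUE)
      S <- nrow(shells)
      d0 <- matrix(fw$dS0, S, 5)[, seq_len(P), drop = FALSE]
      J <- d0
      if (options$lmax >= 2)
        J <- rbind(d0, matrix(fw$dS2, S, 5)[, seq_len(P), drop = FALSE])
      -w * J
    }
    p0 <- pmin(pmax(init_m[v, ], lo + 1e-9), hi - 1e-9)
    ft <- suppressWarnings(
      minpack.lm::nls.lm(par = p0, lower = lo, upper = hi,
                         fn = resid_fn, jac = jac_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)))
    c(ft$par, loss = ft$deviance, niter = ft$niter,
      converged = as.numeric(ft$info %in% 1:4))
  }

  res <- t(vapply(seq_len(V), fit_one, numeric(P + 3)))
  est <- as.data.frame(res[, seq_len(P), drop = FALSE])
  names(est) <- pn
  if (!"p2" %in% names(est)) est$p2 <- NA_real_
  est$voxel <- dat$voxels
  est$loss <- res[, P + 1]
  est$niter <- as.integer(res[, P + 2])
  est$conv <- res[, P + 3] > 0
  finish_fit(est, dat, options, "nlls",
             iterations = max(est$niter), converged = all(est$conv))
}

#' Anisotropic 2D total-variation penalty
#'
#' Sum of absolute forward differences of a parameter map along the two
#' in-plane axes, restricted to edges whose both voxels are in the mask,
#' with differences scaled by the reciprocal in-plane voxel size (1/mm) so
#' that a regularization weight expressed in mm is dimensionless against
#' the data loss.
#'
#' @param map 2D or 3D numeric array (the neurite-fraction map).
#' @param mask Logical array of the same shape (default: all `TRUE`).
#' @param voxel_size In-plane voxel sizes (mm), length 2.
#' @return A single number.
#' @examples
#' tv_penalty(matrix(c(0, 0.5), 1, 2))  # one edge: 0.5
#' @export
tv_penalty <- function(map, mask = NULL, voxel_size = c(1, 1)) {
  if (is.null(mask)) mask <- array(TRUE, dim(map))
  d <- dim(map)
  if (length(d) == 2) { map <- array(map, c(d, 1)); mask <- array(mask, c(d, 1)) }
  d <- dim(map)
  acc <- 0
  if (d[1] > 1) {
    dx <- map[-1, , , drop = FALSE] - map[-d[1], , , drop = FALSE]
    mx <- mask[-1, , , drop = FALSE] & mask[-d[1], , , drop = FALSE]
    acc <- acc + sum(abs(dx[mx])) / voxel_size[1]
  }
  if (d[2] > 1) {
    dy <- map[, -1, , drop = FALSE] - map[, -d[2], , drop = FALSE]
    my <- mask[, -1, , drop = FALSE] & mask[, -d[2], , drop = FALSE]
    acc <- acc + sum(abs(dy[my])) / voxel_size[2]
  }
  acc
}

# subgradient of tv_penalty w.r.t. the masked voxels' values
tv_subgrad <- function(map, mask, voxel_size) {
  d <- dim(map)
  g <- array(0, d)
  if (d[1] > 1) {
    dx <- sign(map[-1, , , drop = FALSE] - map[-d[1], , , drop = FALSE])
    mx <- mask[-1, , , drop = FALSE] & mask[-d[1], , , drop = FALSE]
    dx[!mx] <- 0
    g[-1, , ] <- g[-1, , , drop = FALSE] + dx / voxel_size[1]
    g[-d[1], , ] <- g[-d[1], , , drop = FALSE] - dx / voxel_size[1]
  }
  if (d[2] > 1) {
    dy <- sign(map[, -1, , drop = FALSE] - map[, -d[2], , drop = FALSE])
    my <- mask[, -1, , drop = FALSE] & mask[, -d[2], , drop = FALSE]
    dy[!my] <- 0
    g[, -1, ] <- g[, -1, , drop = FALSE] + dy / voxel_size[2]
    g[, -d[2], ] <- g[, -d[2], , drop = FALSE] - dy / voxel_size[2]
  }
  g
}

#' Batched Adam fitting of all masked voxels under one loss
#'
#' All in-mask voxels are optimized jointly: the scalar loss is the norm
#' (L1 by default) of the weighted residuals `Wl (Sl,meas - Sl,model)`
#' summed over voxels, shells and orders, optionally plus
#' `lambda * ||grad f||_1` (anisotropic in-plane total variation of the
#' neurite-fraction map).  Parameters are box-constrained through a scaled
#' logistic reparameterization and updated with Adam using analytic
#' gradients; iteration stops at `max_iter` or when the loss change drops
#' below `tol`.  The procedure is deterministic given the initialization.
#'
#' @inheritParams fit_nlls
#' @param mask Logical 2D/3D array locating the voxels of `inv` on a grid
#'   (required when `options$lambda > 0`); `sum(mask)` must equal the voxel
#'   count.  `NULL` treats voxels as spatially unrelated.
#' @param voxel_size In-plane voxel size (mm) for the TV term.
#' @return A `nexi_fit` object with the per-iteration loss trace.
#' @export
fit_adam <- function(inv, scheme, options = fit_options(solver = "adam"),
                     init = NULL, sigma = NULL, mask = NULL,
                     voxel_size = c(2, 2)) {
  if (isTRUE(options$rician_mean) && is.null(sigma))
    abort("rician_mean fitting requires sigma")
  if (options$lambda > 0 && is.null(mask))
    abort("TV regularization requires a mask grid")
  shells <- scheme_shells(scheme, exclude_b = options$exclude_b)
  dat <- inv_matrices(inv, shells, options$lmax)
  if (is.null(init)) init <- dictionary_init(inv, scheme, options)
  pn <- param_names(options$lmax)
  P <- length(pn)
  V <- nrow(dat$Y0)
  S <- nrow(shells)
  init_m <- as.matrix(as.data.frame(init)[, pn, drop = FALSE])
  if (nrow(init_m) != V) abort("init rows do not match voxel count")
  if (!is.null(mask)) mask <- array(as.logical(mask), dim(mask))
  if (options$lambda > 0) {
    if (sum(mask) != V) abort("mask voxel count does not match data")
    mdim <- dim(mask)
    if (length(mdim) == 2) { dim(mask) <- c(mdim, 1); mdim <- dim(mask) }
    midx <- which(mask)
  }
  sig <- if (is.null(sigma)) rep(0, V) else rep_len(sigma, V)
  lo <- vapply(pn, function(nm) options$bounds[[nm]][1], numeric(1))
  hi <- vapply(pn, function(nm) options$bounds[[nm]][2], numeric(1))
  span <- hi - lo

  # logistic reparameterization z -> theta
  u0 <- (sweep(init_m, 2, lo) %*% diag(1 / span, P))
  u0 <- pmin(pmax(u0, 1e-4), 1 - 1e-4)
  z <- log(u0 / (1 - u0))
  m1 <- matrix(0, V, P); v1 <- matrix(0, V, P)
  b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8
  w0 <- W_L(0); w2 <- W_L(2)
  Y0 <- dat$Y0; Y2 <- dat$Y2
  loss_trace <- numeric(0)
  loss_prev <- Inf
  iterations <- options$max_iter
  for (it in seq_len(options$max_iter)) {
    sgm <- 1 / (1 + exp(-z))
    theta <- sweep(sgm %*% diag(span, P), 2, lo, "+")
    pm <- cbind(theta, if (P == 4) 0)
    fw <- model_forward(pm, shells, options, sigma = sig, grad = TRUE)
    R0 <- fw$S0 - Y0
    dS0 <- array(fw$dS0, c(V, S, 5))
    if (options$loss == "l1") {
      loss <- w0 * sum(abs(R0))
      # subgradient with a numerical deadzone: residuals at machine noise
      # level are treated as exactly zero so a perfect fit is a fixed point
      G0 <- w0 * sign(R0) * (abs(R0) > 1e-12)
    } else {
      sc <- if (options$loss == "mse") 1 / (V * S * ifelse(P == 5, 2, 1)) else 1
      loss <- sc * w0^2 * sum(R0^2)
      G0 <- sc * 2 * w0^2 * R0
    }
    gth <- matrix(0, V, P)
    for (k in seq_len(P))
      gth[, k] <- rowSums(G0 * dS0[, , k, drop = FALSE][, , 1])
    if (options$lmax >= 2) {
      R2 <- fw$S2 - Y2
      dS2 <- array(fw$dS2, c(V, S, 5))
      if (options$loss == "l1") {
        loss <- loss + w2 * sum(abs(R2))
        G2 <- w2 * sign(R2) * (abs(R2) > 1e-12)
      } else {
        sc <- if (options$loss == "mse") 1 / (V * S * 2) else 1
        loss <- loss + sc * w2^2 * sum(R2^2)
        G2 <- sc * 2 * w2^2 * R2
      }
      for (k in seq_len(P))
        gth[, k] <- gth[, k] + rowSums(G2 * dS2[, , k, drop = FALSE][, , 1])
    }
    if (options$lambda > 0) {
      fmap <- array(0, mdim)
      fmap[midx] <- theta[, 1]
      loss <- loss + options$lambda * tv_penalty(fmap, mask, voxel_size)
      gtv <- tv_subgrad(fmap, mask, voxel_size)
      gth[, 1] <- gth[, 1] + options$lambda * gtv[midx]
    }
    if (!is.finite(loss))
      abort("divergent (non-finite) loss in batched optimization")
    loss_trace <- c(loss_trace, loss)
    if (abs(loss_prev - loss) < options$tol) { iterations <- it; break }
    loss_prev <- loss
    gz <- gth * sweep(sgm * (1 - sgm), 2, span, "*")
    m1 <- b1 * m1 + (1 - b1) * gz
    v1 <- b2 * v1 + (1 - b2) * gz^2
    mhat <- m1 / (1 - b1^it)
    vhat <- v1 / (1 - b2^it)
    z <- z - options$lr * mhat / (sqrt(vhat) + epsA)
  }
  sgm <- 1 / (1 + exp(-z))
  theta <- sweep(sgm %*% diag(span, P), 2, lo, "+")
  est <- as.data.frame(theta)
  names(est) <- pn
  if (!"p2" %in% names(est)) est$p2 <- NA_real_
  est$voxel <- dat$voxels
  est$loss <- loss_trace[length(loss_trace)]
  est$niter <- iterations
  est$conv <- iterations < options$max_iter
  finish_fit(est, dat, options, "adam", loss_trace = loss_trace,
             iterations = iterations,
             converged = iterations < options$max_iter)
}

#' Fit ROI-averaged invariants
#'
#' Runs the voxel-wise bounded least-squares fit on each region's averaged
#' invariant vector.
#'
#' @param roi_inv Tibble `label, b, t, l, value` (e.g. from
#'   [roi_average_invariants()]).
#' @param scheme Scheme tibble.
#' @param options A [fit_options()] list.
#' @param sigma Optional noise level (scalar or per label).
#' @return Tibble of parameters per label, including `tex`.
#' @export
fit_roi <- function(roi_inv, scheme, options = fit_options(), sigma = NULL) {
  labs <- sort(unique(roi_inv$label))
  shells <- scheme_shells(scheme, exclude_b = options$exclude_b)
  have <- roi_inv %>% filter(.data$l == 0) %>%
    group_by(.data$label) %>% summarise(n = n())
  if (any(have$n < nrow(shells)))
    abort("some ROI is missing shells required for fitting")
  inv <- roi_inv
  inv$voxel <- match(inv$label, labs)
  ft <- fit_nlls(inv[, c("voxel", "b", "t", "l", "value")], scheme, options,
                 sigma = sigma)
  est <- ft$estimates
  est$label <- labs[est$voxel]
  est %>% select("label", dplyr::any_of(c("f", "Dn", "De", "rn", "p2")),
                 "re", "tex", "loss", "conv")
}

#' @export
print.nexi_fit <- function(x, ...) {
  cat(sprintf("<nexi_fit> %s, lmax = %d, %d voxel(s), %d shell(s)\n",
              x$solver, x$options$lmax, nrow(x$estimates), nrow(x$shells)))
  cat(sprintf("  final loss %.3e; iterations %s; converged: %s\n",
              x$estimates$loss[1], x$iterations, x$converged))
  invisible(x)
}

#' Tidy a fitted exchange model
#' @param x A `nexi_fit` object.
#' @param ... Unused.
#' @return Long tibble `voxel, parameter, estimate`.
#' @export
tidy.nexi_fit <- function(x, ...) {
  x$estimates %>%
    select("voxel", dplyr::any_of(c("f", "Dn", "De", "rn", "p2", "tex"))) %>%
    tidyr::pivot_longer(-"voxel", names_to = "parameter",
                        values_to = "estimate") %>%
    filter(is.finite(.data$estimate))
}

#' One-row fit summary
#' @param x A `nexi_fit` object.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.nexi_fit <- function(x, ...) {
  tibble(solver = x$solver, lmax = x$options$lmax,
         n_voxels = nrow(x$estimates), n_shells = nrow(x$shells),
         iterations = x$iterations,
         median_tex = median(x$estimates$tex),
         total_loss = sum(x$estimates$loss) /
           ifelse(x$solver == "adam", nrow(x$estimates), 1),
         converged = isTRUE(x$converged))
}

#' Parameter histograms of a fit
#' @param object A `nexi_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nexi_fit <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = "grey20") +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "estimate", y = "voxels") +
    ggplot2::theme_minimal()
}
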