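# Measured rotational invariants: b0 normalization, even spherical-harmonic
# fits per (b, t) shell, norm-based invariants S0/S2, and noise-level
# estimation from repeated b = 0 volumes.

#' Real even spherical-harmonic design matrix
#'
#' Orthonormal real spherical harmonics of even order up to `lmax`,
#' evaluated at unit directions.  Column blocks are ordered l = 0, 2, 4, ...
#' with m = -l..l inside each block.
#'
#' @param dirs `n x 3` matrix of unit vectors.
#' @param lmax Even maximum order.
#' @return `n x K` matrix, `K = (lmax+1)(lmax+2)/2`.
#' @keywords internal
sh_design <- function(dirs, lmax = 4) {
  if (lmax %% 2 != 0) abort("lmax must be even")
  z <- dirs[, 3]
  phi <- atan2(dirs[, 2], dirs[, 1])
  cols <- list()
  for (l in seq(0, lmax, by = 2)) {
    P <- pracma::legendre(l, z)  # (l+1) x n, m = 0..l rows
    if (is.null(dim(P))) P <- matrix(P, nrow = l + 1)
    for (m in -l:l) {
      am <- abs(m)
      nrm <- sqrt((2 * l + 1) / (4 * pi) *
                    factorial(l - am) / factorial(l + am))
      base <- nrm * P[am + 1, ]
      colv <- if (m < 0) {
        sqrt(2) * base * sin(am * phi)
      } else if (m == 0) base else sqrt(2) * base * cos(am * phi)
      cols[[length(cols) + 1]] <- colv
    }
  }
  mat <- do.call(cbind, cols)
  colnames(mat) <- unlist(lapply(seq(0, lmax, by = 2),
                                 function(l) paste0("l", l, "m", -l:l)))
  mat
}

#' Normalize diffusion-weighted volumes by the b = 0 signal
#'
#' Divides every diffusion-weighted volume by the voxel-wise mean across
#' b = 0 volumes and drops the b = 0 volumes from the output.  Voxels whose
#' mean b = 0 signal is not positive are flagged and excluded.
#'
#' @param dwi Matrix of signals, voxels x volumes (columns in scheme order),
#'   or a 4D array (reshaped to voxels x volumes).
#' @param scheme The matching scheme tibble.
#' @return A list with `signals` (voxels x DW volumes), `scheme` (the
#'   diffusion-weighted rows), `b0_mean`, and logical `valid` per voxel.
#' @export
normalize_b0 <- function(dwi, scheme) {
  if (is.array(dwi) && length(dim(dwi)) == 4)
    dwi <- matrix(dwi, ncol = dim(dwi)[4])
  dwi <- as.matrix(dwi)
  if (ncol(dwi) != nrow(scheme))
    abort("dwi volume count does not match scheme")
  if (!any(scheme$b0)) abort("scheme contains no b = 0 volume")
  b0_mean <- rowMeans(dwi[, scheme$b0, drop = FALSE])
  valid <- is.finite(b0_mean) & b0_mean > 0
  if (!all(valid))
    warn(sprintf("%d voxel(s) with non-positive mean b0 excluded",
                 sum(!valid)))
  denom <- ifelse(valid, b0_mean, NA_real_)
  signals <- dwi[, !scheme$b0, drop = FALSE] / denom
  list(signals = signals, scheme = scheme[!scheme$b0, ],
       b0_mean = b0_mean, valid = valid)
}

#' Extract rotational invariants per (b, t) shell
#'
#' Least-squares fit of real even spherical harmonics up to `lmax_fit` to
#' the per-direction signals of every shell, then norm-based invariants
#' `Sl = Wl * ||c_l||` with `Wl = 1/sqrt(4 pi (2l+1))`, so that `S0` equals
#' the spherical-mean signal and, on signals generated by
#' [directional_signal()], `S2 = p2 |K2|`.  The l = 4 invariant is computed
#' but only returned on request.
#'
#' @param signals Voxels x DW-volumes matrix of b0-normalized signals (from
#'   [normalize_b0()]).
#' @param scheme The diffusion-weighted scheme rows matching the columns.
#' @param lmax_fit Even spherical-harmonic fit order (default 4).
#' @param return_l4 Also return the l = 4 invariant (default `FALSE`).
#' @return A tibble `voxel, b, t, l, value`.
#' @export
extract_invariants <- function(signals, scheme, lmax_fit = 4,
                               return_l4 = FALSE) {
  signals <- as.matrix(signals)
  if (ncol(signals) != nrow(scheme))
    abort("signal column count does not match scheme")
  shells <- distinct(scheme, .data$b, .data$t)
  nmin <- (lmax_fit + 1) * (lmax_fit + 2) / 2
  ls <- seq(0, lmax_fit, by = 2)
  blocks <- split(seq_along(ls), ls)  # order blocks
  out <- vector("list", nrow(shells))
  for (i in seq_len(nrow(shells))) {
    sel <- which(scheme$b == shells$b[i] & scheme$t == shells$t[i])
    dirs <- as.matrix(scheme[sel, c("gx", "gy", "gz")])
    if (length(sel) < nmin)
      abort(sprintf(
        "shell (b = %g, t = %g) has %d directions; >= %d needed for lmax_fit = %d",
        shells$b[i], shells$t[i], length(sel), nmin, lmax_fit))
    B <- sh_design(dirs, lmax_fit)
    qrB <- qr(B)
    if (qrB$rank < ncol(B))
      abort("rank-deficient spherical-harmonic design (directions degenerate)")
    coef <- t(qr.coef(qrB, t(signals[, sel, drop = FALSE])))  # voxels x K
    res_i <- list()
    col0 <- 1
    for (l in ls) {
      ncoef <- 2 * l + 1
      cl <- coef[, col0:(col0 + ncoef - 1), drop = FALSE]
      col0 <- col0 + ncoef
      Sl <- sqrt(rowSums(cl^2)) / sqrt(4 * pi * (2 * l + 1))
      if (l == 0) Sl <- Sl * sign(coef[, 1])  # S0 keeps the mean's sign
      res_i[[as.character(l)]] <- Sl
    }
    keep <- c(0, if (lmax_fit >= 2) 2, if (return_l4 && lmax_fit >= 4) 4)
    out[[i]] <- bind_rows(lapply(keep, function(l) {
      vals <- unname(res_i[[as.character(l)]])
      tibble(voxel = seq_len(nrow(signals)), b = shells$b[i],
             t = shells$t[i], l = as.integer(l), value = vals)
    }))
  }
  arrange(bind_rows(out), .data$voxel, .data$t, .data$b, .data$l)
}

#' Noise level from repeated b = 0 volumes
#'
#' Per-voxel temporal standard deviation across b = 0 volumes divided by the
#' per-voxel b = 0 mean, i.e. sigma in b0-normalized signal units;
#' `SNR = 1/sigma`.
#'
#' @param b0 Voxels x repeats matrix (>= 3 repeats) or 4D array of b = 0
#'   volumes.
#' @return A list with `sigma` and `snr` vectors.
#' @export
estimate_sigma_b0 <- function(b0) {
  if (is.array(b0) && length(dim(b0)) == 4)
    b0 <- matrix(b0, ncol = dim(b0)[4])
  b0 <- as.matrix(b0)
  if (ncol(b0) < 3) abort("at least 3 b = 0 volumes are required")
  m <- rowMeans(b0)
  s <- apply(b0, 1, sd)
  sigma <- s / m
  list(sigma = sigma, snr = 1 / sigma)
}

#' ROI-averaged invariants
#'
#' Averages an invariant table over label regions; because normalization,
#' the spherical-harmonic fit and the norm at fixed axis are linear in the
#' noiseless regime, this commutes with per-voxel extraction for clean data.
#'
#' @param inv Tibble `voxel, b, t, l, value` from [extract_invariants()].
#' @param labels Integer vector of region labels per voxel (0 = outside).
#' @return Tibble `label, b, t, l, value`.
#' @export
roi_average_invariants <- function(inv, labels) {
  lab <- tibble(voxel = seq_along(labels), label = as.integer(labels))
  inv %>%
    left_join(lab, by = "voxel") %>%
    filter(.data$label > 0) %>%
    group_by(.data$label, .data$b, .data$t, .data$l) %>%
    summarise(value = mean(.data$value), .groups = "drop")
}
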