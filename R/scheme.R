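# Pulsed-gradient spin-echo acquisition schemes: protocol fixtures, file
# readers, and b-value <-> gradient-amplitude arithmetic for trapezoidal
# waveforms.  Conventions (used package-wide):
#  * b in ms/um^2, time in ms, diffusivity in um^2/ms, G in mT/m;
#  * pulse duration delta is the full width at half maximum of the trapezoid,
#    so the pulse area is exactly G * delta;
#  * diffusion time t is the separation between the leading edges of the two
#    pulses (equivalently of their FWHM rectangles).

#' Table of known acquisition protocol fixtures
#'
#' `"C2"` is the high-gradient protocol (Gmax = 500 mT/m, delta = 6 ms, ramp
#' = 0.83 ms, t in {13, 21, 30} ms); `"C1"` the lower-gradient one (Gmax =
#' 300 mT/m, delta = 10 ms, ramp = 1.5 ms, t in {21, 30, 40} ms).  Shells
#' grow with diffusion time: b = 1, 2.3, 3.5, 4.8, 6.5 ms/um^2 at the
#' shortest t, plus 11.5 at the middle and 17.5 at the longest.
#' @keywords internal
protocol_table <- function() {
  list(
    C2 = list(t = c(13, 21, 30), delta = 6, ramp = 0.83, Gmax = 500,
              shells = list(c(1, 2.3, 3.5, 4.8, 6.5),
                            c(1, 2.3, 3.5, 4.8, 6.5, 11.5),
                            c(1, 2.3, 3.5, 4.8, 6.5, 11.5, 17.5))),
    C1 = list(t = c(21, 30, 40), delta = 10, ramp = 1.5, Gmax = 300,
              shells = list(c(1, 2.3, 3.5, 4.8, 6.5),
                            c(1, 2.3, 3.5, 4.8, 6.5, 11.5),
                            c(1, 2.3, 3.5, 4.8, 6.5, 11.5, 17.5)))
  )
}

#' Deterministic near-uniform direction set
#'
#' Golden-angle (Fibonacci) spiral point set on the sphere.  Deterministic,
#' near-uniform, and well conditioned for even spherical-harmonic fits up to
#' l = 4 from 32 directions upward.
#'
#' @param n Number of directions.
#' @return An `n x 3` matrix of unit vectors.
#' @export
direction_set <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

new_scheme <- function(tbl, Gmax = NA_real_, protocol = NA_character_) {
  tbl <- as_tibble(tbl)
  attr(tbl, "Gmax") <- Gmax
  attr(tbl, "gamma") <- GAMMA_H
  attr(tbl, "protocol") <- protocol
  class(tbl) <- c("nexi_scheme", class(tbl))
  tbl
}

#' Validate an acquisition scheme
#'
#' Checks the scheme invariants: non-negative b, `delta + ramp < t` for
#' diffusion-weighted volumes, unit gradient directions, and (when a maximum
#' gradient strength is attached) that the implied flat-top amplitude does
#' not exceed it.
#'
#' @param scheme A scheme tibble as returned by [nexi_protocol()] or
#'   [read_scheme()].
#' @return The scheme, invisibly; errors on violation.
#' @export
validate_scheme <- function(scheme) {
  req <- c("volume", "b", "t", "delta", "ramp", "gx", "gy", "gz", "b0")
  missing_cols <- setdiff(req, names(scheme))
  if (length(missing_cols))
    abort(paste("scheme is missing columns:", paste(missing_cols, collapse = ", ")))
  if (any(scheme$b < 0)) abort("negative b-values in scheme")
  dw <- !scheme$b0
  if (any(scheme$delta[dw] + scheme$ramp[dw] >= scheme$t[dw]))
    abort("delta + ramp must be < t for every diffusion-weighted volume")
  nrm <- sqrt(scheme$gx^2 + scheme$gy^2 + scheme$gz^2)
  if (any(abs(nrm[dw] - 1) > 1e-6))
    abort("non-unit gradient directions for diffusion-weighted volumes")
  Gmax <- attr(scheme, "Gmax")
  if (!is.null(Gmax) && is.finite(Gmax)) {
    G <- gradient_amplitude(scheme$b[dw], scheme$t[dw], scheme$delta[dw],
                            scheme$ramp[dw])
    if (any(G > Gmax * (1 + 1e-9)))
      abort("scheme implies gradient amplitudes above Gmax")
  }
  invisible(scheme)
}

#' Build a fixture acquisition protocol
#'
#' Constructs the full multi-(t, b) pulsed-gradient spin-echo protocol for one
#' of the two fixture scanners, with near-uniformly distributed diffusion
#' directions (deterministic layout) and interleaved b = 0 volumes (one
#' before every 16 diffusion-weighted volumes within each diffusion-time
#' block).
#'
#' @param name `"C1"` or `"C2"`.
#' @param directions_per_shell Number of gradient directions per shell
#'   (default 64).
#' @return A scheme tibble (class `nexi_scheme`) with one row per volume and
#'   columns `volume, b, t, delta, ramp, gx, gy, gz, b0`; attributes `Gmax`,
#'   `gamma` and `protocol`.
#' @examples
#' sch <- nexi_protocol("C2", 32)
#' max(sch$b)  # 17.5 ms/um^2
#' @export
nexi_protocol <- function(name, directions_per_shell = 64) {
  tab <- protocol_table()
  if (!name %in% names(tab))
    abort(paste0("unknown protocol '", name, "' (known: ",
                 paste(names(tab), collapse = ", "), ")"))
  p <- tab[[name]]
  dirs <- direction_set(directions_per_shell)
  rows <- list()
  for (it in seq_along(p$t)) {
    tt <- p$t[it]
    block <- list()
    for (b in p$shells[[it]]) {
      block[[length(block) + 1]] <-
        tibble(b = b, t = tt, delta = p$delta, ramp = p$ramp,
               gx = dirs[, 1], gy = dirs[, 2], gz = dirs[, 3], b0 = FALSE)
    }
    block <- bind_rows(block)
    # interleave one b0 before every 16 DWIs
    nb <- nrow(block)
    out <- list()
    for (k in seq(1, nb, by = 16)) {
      out[[length(out) + 1]] <-
        tibble(b = 0, t = tt, delta = p$delta, ramp = p$ramp,
               gx = 0, gy = 0, gz = 0, b0 = TRUE)
      out[[length(out) + 1]] <- block[k:min(k + 15, nb), ]
    }
    rows[[it]] <- bind_rows(out)
  }
  sch <- bind_rows(rows)
  sch$volume <- seq_len(nrow(sch))
  sch <- sch[, c("volume", "b", "t", "delta", "ramp", "gx", "gy", "gz", "b0")]
  sch <- new_scheme(sch, Gmax = p$Gmax, protocol = name)
  validate_scheme(sch)
  sch
}

#' Trapezoidal PGSE waveform
#'
#' Returns the gradient profile `G(tau)`, accumulated wave vector
#' `q(tau) = gamma * integral(G)`, and total b-value of a trapezoidal
#' pulse pair.  `delta` follows the FWHM convention (pulse area `G * delta`),
#' `t` is the leading-edge separation of the two pulses.
#'
#' @param G Flat-top amplitude (mT/m).
#' @param t Diffusion time (ms).
#' @param delta Pulse duration, FWHM (ms).
#' @param ramp Ramp time (ms).
#' @return A list with functions `G(tau)`, `q(tau)`, the echo/readout time
#'   `duration = t + delta + ramp`, and the exact b-value `b`.
#' @export
pgse_waveform <- function(G, t, delta, ramp) {
  stopifnot(t > delta + ramp, delta > ramp, ramp >= 0)
  r <- max(ramp, 1e-12)
  qmax <- GAMMA_H * G * delta
  qn <- function(tau) {
    vapply(tau, function(x) {
      if (x <= 0) return(0)
      if (x < r) return(x^2 / (2 * r * delta))
      if (x < delta) return((x - r / 2) / delta)
      if (x < delta + r) return(1 - (delta + r - x)^2 / (2 * r * delta))
      if (x < t) return(1)
      u <- x - t
      if (u < r) return(1 - u^2 / (2 * r * delta))
      if (u < delta) return(1 - (u - r / 2) / delta)
      if (u < delta + r) return((delta + r - u)^2 / (2 * r * delta))
      0
    }, numeric(1))
  }
  Gfun <- function(tau) {
    vapply(tau, function(x) {
      amp <- function(u) {
        if (u < 0 || u > delta + r) return(0)
        if (u < r) return(u / r)
        if (u <= delta) return(1)
        (delta + r - u) / r
      }
      G * (amp(x) - amp(x - t))
    }, numeric(1))
  }
  b <- qmax^2 * cpp_bunit_waveform(t, delta, r)
  list(G = Gfun, q = function(tau) qmax * qn(tau),
       duration = t + delta + r, b = b,
       t = t, delta = delta, ramp = r, amplitude = G)
}

#' b-value of a trapezoidal PGSE waveform
#'
#' Exact integral `b = integral(q^2)` for the trapezoidal pulse pair
#' (piecewise-polynomial quadrature, exact to machine precision).  In the
#' rectangular limit (`ramp -> 0`) it converges to
#' `(gamma G delta)^2 (t - delta/3)`.
#'
#' @inheritParams pgse_waveform
#' @return b-value in ms/um^2 (vectorized over the inputs).
#' @export
pgse_bvalue <- function(G, t, delta, ramp) {
  n <- max(length(G), length(t), length(delta), length(ramp))
  G <- rep_len(G, n); t <- rep_len(t, n)
  delta <- rep_len(delta, n); ramp <- rep_len(ramp, n)
  vapply(seq_len(n), function(i) {
    (GAMMA_H * G[i] * delta[i])^2 *
      cpp_bunit_waveform(t[i], delta[i], max(ramp[i], 1e-12))
  }, numeric(1))
}

#' Flat-top gradient amplitude for a requested b-value
#'
#' Inverts the waveform b-integral: since `b` scales as `G^2`, the amplitude
#' is recovered exactly from the unit-amplitude integral.  The round trip
#' through [pgse_bvalue()] reproduces `b` to better than 1e-6 relative.
#'
#' @param b Requested b-value(s) (ms/um^2), `b > 0` (b = 0 returns 0).
#' @param t,delta,ramp Timing parameters (ms); `delta + ramp < t`.
#' @param Gmax Optional maximum gradient strength (mT/m); exceeding it is an
#'   error.
#' @return Amplitude(s) in mT/m.
#' @examples
#' gradient_amplitude(17.5, t = 30, delta = 6, ramp = 0.83)  # ~ 493 mT/m
#' @export
gradient_amplitude <- function(b, t, delta, ramp, Gmax = NULL) {
  if (any(b < 0)) abort("b must be >= 0")
  n <- max(length(b), length(t), length(delta), length(ramp))
  b <- rep_len(b, n); t <- rep_len(t, n)
  delta <- rep_len(delta, n); ramp <- rep_len(ramp, n)
  if (any(delta + ramp >= t)) abort("delta + ramp must be < t")
  G <- vapply(seq_len(n), function(i) {
    bu <- pgse_bvalue(1, t[i], delta[i], ramp[i])
    sqrt(b[i] / bu)
  }, numeric(1))
  if (!is.null(Gmax) && any(G > Gmax * (1 + 1e-9)))
    abort(sprintf("required amplitude %.1f mT/m exceeds Gmax = %.1f mT/m",
                  max(G), Gmax))
  G
}

#' Read an acquisition scheme from FSL-style files
#'
#' @param bval_path Whitespace-separated b-values, one row.  Values above 100
#'   are interpreted as s/mm^2 and converted to ms/um^2 (x 1e-3).
#' @param bvec_path Whitespace-separated 3 x N unit directions.
#' @param timing_path TSV with columns `volume, t, delta, ramp` (ms).
#' @return A scheme tibble (class `nexi_scheme`).
#' @export
read_scheme <- function(bval_path, bvec_path, timing_path) {
  bval <- scan(bval_path, quiet = TRUE)
  bvec <- as.matrix(read.table(bvec_path))
  if (nrow(bvec) != 3) abort("bvec file must have 3 rows")
  if (ncol(bvec) != length(bval))
    abort("bval/bvec volume counts differ")
  timing <- read.table(timing_path, header = TRUE, sep = "\t")
  need <- c("volume", "t", "delta", "ramp")
  if (!all(need %in% names(timing)))
    abort("timing table must have columns volume, t, delta, ramp")
  if (nrow(timing) != length(bval))
    abort("timing table row count does not match bval volume count")
  timing <- timing[order(timing$volume), ]
  if (any(bval > 100)) bval <- bval * 1e-3  # s/mm^2 -> ms/um^2
  b0 <- bval <= 0
  nrm <- sqrt(colSums(bvec^2))
  if (any(abs(nrm[!b0] - 1) > 1e-6))
    abort("non-unit gradient directions for diffusion-weighted volumes")
  sch <- tibble(volume = seq_along(bval), b = bval,
                t = timing$t, delta = timing$delta, ramp = timing$ramp,
                gx = bvec[1, ], gy = bvec[2, ], gz = bvec[3, ], b0 = b0)
  sch <- new_scheme(sch)
  validate_scheme(sch)
  sch
}

#' Write a scheme to a single TSV file
#' @param scheme A scheme tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_scheme <- function(scheme, path) {
  write.table(as.data.frame(scheme), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Unique diffusion-weighted shells of a scheme
#'
#' @param scheme A scheme tibble.
#' @param exclude_b Shells with these b-values are dropped (default 1
#'   ms/um^2, which is reserved for quality control, not fitting).
#' @return Tibble of distinct `(b, t, delta, ramp)` rows, ordered by `t`
#'   then `b`.
#' @export
scheme_shells <- function(scheme, exclude_b = 1) {
  sh <- scheme %>%
    filter(!.data$b0, !(.data$b %in% exclude_b)) %>%
    distinct(.data$b, .data$t, .data$delta, .data$ramp) %>%
    arrange(.data$t, .data$b)
  as_tibble(sh)
}
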