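---
title: "The anisotropic exchange model behind nexifit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The anisotropic exchange model behind nexifit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model and its assumptions

`nexifit` models gray-matter diffusion MRI signal as water exchanging
between two pools: neurites, treated as zero-radius sticks with along-fiber
diffusivity $D_n$, and a single isotropic extracellular pool with
diffusivity $D_e$ that also absorbs soma water (soma–extracellular exchange
is neglected on surface-to-volume grounds, and relaxation times of the two
pools are assumed equal, so $b=0$ normalization removes them). For one
fiber direction the magnetizations obey a rate equation with a diffusion
sink,

$$\frac{d}{dt}\begin{pmatrix}M_n\\M_e\end{pmatrix}
 = -\left(\begin{pmatrix}r_n & -r_e\\ -r_n & r_e\end{pmatrix}
 + q^2(t)\begin{pmatrix}D_n\varepsilon^2 & 0\\ 0 & D_e\end{pmatrix}\right)
 \begin{pmatrix}M_n\\M_e\end{pmatrix},$$

with detailed balance $r_n f = r_e(1-f)$, exchange time
$t_{ex} = 1/(r_n + r_e) = (1-f)/r_n$, and $\varepsilon$ the cosine between
fiber and gradient. This rate description is an effective long-time theory:
it presumes the diffusion time is long enough for the tissue to be
coarse-grained, which is why the package targets $t \gtrsim 13$ ms and
$t_{ex}$ of order 1–50 ms.

Two solutions are implemented:

* **Narrow pulse (analytic).** With $q^2$ constant over the diffusion time,
  the kernel is the two-exponential eigenvalue form
  $K = f_1' e^{-a_1} + f_2' e^{-a_2}$. We write the exponents as
  $a_{1,2} = \bar a \pm h$ with
  $h = \tfrac12\sqrt{(bD_n\varepsilon^2 - bD_e + tr_n - tr_e)^2 + 4t^2r_nr_e}$.
  Note the $t^2 r_n r_e$ term: the dimensionally consistent discriminant,
  verified against a matrix-exponential reference to ~1e-14. Amplitudes are
  fixed by $f_1'+f_2'=1$ (so $K(b{=}0)=1$ exactly) and first-moment
  matching $f_1'a_1+f_2'a_2 = b\,(fD_n\varepsilon^2+(1-f)D_e)$, which
  reproduces the no-exchange bi-exponential limit. Numerically the kernel
  is evaluated as $e^{-\bar a}(\cosh h + (\bar a - m)\sinh h/h)$ with a
  series branch for small $h$, so coincident exponents are a smooth limit,
  not a 0/0.
* **Finite pulse (SMEX).** For trapezoidal pulse pairs the same system is
  integrated through the actual waveform $q(t)$. The propagator is a
  product of closed-form 2×2 matrix exponentials: exact on the constant-$q$
  plateau, and per substep inside the pulses using the *exact* average of
  $q^2$ over the substep (5-node Gauss–Legendre on the piecewise-quartic
  $q^2$). Substeps are doubled until the kernel changes by less than a
  tolerance (default 1e-6). Because the no-exchange system is diagonal and
  therefore commuting, that case is exact for any step count. An adaptive
  ODE solver (`deSolve::lsoda`) serves as the independent cross-check in
  the test suite, not as the production path: the matrix-exponential
  product is orders of magnitude faster, which the batched simulations
  need, and it carries its own step-doubling accuracy control.

### Waveform conventions and units

Units are fixed package-wide: b in ms/µm², diffusivities in µm²/ms, times
in ms, rates in 1/ms, gradient amplitudes in mT/m. The pulse duration
$\delta$ follows the full-width-at-half-maximum convention, which makes the
pulse area exactly $G\delta$; the diffusion time $t$ is the separation of
the two pulses' leading edges. In the rectangular limit the b-value
integral reduces to $(\gamma G\delta)^2(t-\delta/3)$; with these
conventions the top shell of the high-gradient fixture protocol (b = 17.5
ms/µm² at t = 30 ms, δ = 6 ms) requires ≈493 mT/m, consistent with that
scanner's 500 mT/m limit. Whether $t$ is measured edge-to-edge or
center-to-center is not fully constrained by the protocol tables; the
leading-edge convention is used consistently, and because NEXI only sees
$(b, t)$ the choice matters at the $O(\delta/t)$ level probed by the
narrow-pulse robustness experiments.

The printed fitting and dictionary ranges for the exchange rate are
interpreted in 1/ms (not 1/s): the exchange-time identity
$t_{ex} = (1-f)/r_n$ with $t_{ex}$ of 1–50 ms and gray-matter $f \approx
0.3$ forces $r_n \approx 0.01$–0.7 ms⁻¹, so a 1/s reading would be three
orders of magnitude off.

## Rotational invariants and the sign of $K_2$

Voxel signals are the spherical convolution of the kernel with an axially
symmetric orientation distribution truncated at $\ell = 2$ (its $\ell = 4$
weight defaults to zero, matching the simulated dispersion range
$p_2 \in [0, 0.3]$; higher orders are an extension point). Per (b, t)
shell, even real spherical harmonics up to $\ell = 4$ are least-squares
fitted to the directional data and the invariants taken as
$S_\ell = W_\ell\,\lVert c_\ell\rVert$ with
$W_\ell = 1/\sqrt{4\pi(2\ell+1)}$, so $S_0$ equals the spherical mean. The
$\ell = 4$ invariant is computed but not used in fitting.

One convention deserves emphasis: the signed Legendre projection
$K_2 = \int_0^1 K P_2(\varepsilon)\,d\varepsilon$ is *negative* for this
kernel family, because attenuation is strongest along the neurite. The
norm-based measured invariant is non-negative by construction, so the
forward model used in fitting is $S_2 = p_2\,\lvert K_2\rvert$; the signed
value is retained internally wherever the actual directional signal is
needed (most importantly inside the Rician-mean forward model). The
round-trip contract — generate directional signals, extract invariants,
recover $(K_0,\ p_2\lvert K_2\rvert)$ to 1e-4 with 64 directions — pins the
normalization constants and is enforced in the tests.

Projections use fixed-order Gauss–Legendre quadrature on
$\varepsilon \in [0,1]$: 60 nodes in the user-facing
`project_legendre()`, 24 nodes inside the fitting forward model. For this
analytic kernel over the protocols' b-range the 24-node rule agrees with
the 60-node reference to ~1e-16 (asserted in the test suite), and it
halves the cost of every optimizer iteration.

## Noise model and the Rice mean

Magnitude reconstruction turns complex Gaussian noise into Rician noise,
whose floor biases the spherical mean upward at high b and masquerades as
faster-than-real exchange. The forward correction replaces the $\ell = 0$
prediction with the directional average of the exact Rice mean
$E\lvert\nu + \mathcal{CN}(0,\sigma)\rvert$ applied to the per-direction
model signal (the floor arises per DWI, before averaging; for an
$\ell_{max}=0$ model this reduces to the Rice mean of the spherical mean).
The Rice mean is evaluated with the scaled-Bessel closed form
$\sigma\sqrt{\pi/2}\,[(1+t)\tilde I_0(t/2) + t\tilde I_1(t/2)]$,
$t = \nu^2/2\sigma^2$, which is numerically stable across the whole range
used (it matches direct quadrature of the Rice density to ~1e-14 up to
$\nu/\sigma = 100$); only beyond $\nu/\sigma > 10^4$, where the correction
is below machine precision, does the trivial asymptote take over. Its
derivative $\partial E/\partial\nu =
\sqrt{\pi/2}\,(\nu/\sigma)\,(\tilde I_0+\tilde I_1)/2$ feeds the analytic
gradients. The noise level $\sigma$ (in $b_0$-normalized units) is either
known from the simulation or estimated from ≥3 repeated $b=0$ volumes via
temporal statistics.

## Estimation

Fitting minimizes $W_\ell$-weighted residuals between measured and model
invariants over the shells with $b \ge 2.3$ ms/µm² (the b = 1 shell is
excluded by default, as low-b signal carries soma contributions outside the
model; override with `exclude_b`).

* **Dictionary initialization.** 10,000 uniform draws over gray-matter-like
  ranges ($f\in[0.01,0.99]$, $D_n\in[1.5,3]$, $D_e\in[0.5,1.5]$,
  $r_n\in[0.001,0.99]$ ms⁻¹), forward-simulated once; each voxel starts at
  the entry with the largest normalized inner product (ties to the lowest
  index, so initialization is deterministic given the seed). For
  $\ell_{max}=2$ fits the dictionary also needs a dispersion entry; $p_2$
  is drawn uniformly on $[0, 0.6]$, a superset of the simulated
  gray-matter range. All-zero
  measurement vectors are flagged and initialized at the range midpoints.
* **Voxel-wise NLLS.** Bounded Levenberg–Marquardt (`minpack.lm`) with
  analytic Jacobians, bounds $f\in[0,1]$, $D_n, D_e\in[0.1,3]$,
  $r_n\in[0,1]$ ms⁻¹, $p_2\in[0,1]$ (the simulation range for $p_2$ is
  narrower, but the bound is left wide since only the range, not a bound,
  is stated).
* **Batched Adam.** All masked voxels contribute to one scalar loss (L1 by
  default, which outperforms L2 at moderate SNR; L2/MSE available).
  Parameters are box-constrained by a scaled logistic reparameterization,
  updated with Adam (learning rate 0.01, standard momentum constants) for
  at most 4000 iterations or until the loss changes by less than 1e-8.
  The learning rate is the one genuinely open hyperparameter; 0.01 was
  chosen because it gives the closest noiseless agreement with NLLS within
  the iteration cap (larger rates converge faster but plateau farther from
  the optimum on clean data). Gradients are analytic end to end, including
  through the Rice mean and the reparameterization. The L1 subgradient
  treats residuals below 1e-12 as exactly zero so that a perfect fit is a
  fixed point. Because the batch is full and deterministic, identical
  options, initialization and seed give bit-identical results.
* **TV regularization.** With $\lambda > 0$ the loss gains
  $\lambda\,\lVert M\nabla f\rVert_1$: anisotropic forward differences of
  the neurite-fraction map along the two in-plane axes, scaled by the
  reciprocal voxel size in mm so $\lambda$ is expressed in mm
  (default regularized setting 0.002 mm). Only edges with both voxels
  in-mask count.
* **Derived maps.** $t_{ex} = (1-f)/r_n$ with $r_n$ floored at $10^{-6}$
  ms⁻¹ to avoid infinities; floored voxels are listed in the run manifest.

## The synthetic-data generator

`sample_tissue_params()` draws the study conditions: $t_{ex}\sim U[1,50]$
ms, $f\sim U[0.01,0.99]$, $D_n, D_e\sim U[0.1,3]$ µm²/ms with $D_n \ge D_e$
by rejection, $p_2\sim U[0,0.3]$, and $r_n$ derived from $t_{ex}$ and $f$.
`run_noise_propagation()` chains generation (per-direction signals with one
random ODF axis per draw, from the analytic or the finite-pulse kernel),
noise injection at $b_0$-SNR 50 (complex-Gaussian magnitude for Rician,
real for Gaussian; b = 0 volumes are corrupted like any volume), $b_0$
normalization, invariant extraction, dictionary initialization and
fitting, then summarizes the median error (bias) and its interquartile
range, overall and stratified at $t_{ex} = 20$ ms. Every stage draws from
one seeded stream, so configurations reproduce byte-identically.

The phantom (`make_phantom()`) is a single-slice head-like geometry: a
two-region core inside a cortical ribbon split into angular sectors
(default 20 parcels, 64×64 grid, 2 mm in-plane voxels), each parcel
carrying one ground-truth parameter set spanning gray-matter-like
magnitudes ($f$ 0.25–0.40, $D_n$ 2.4–3.0, $D_e$ 0.75–0.95 µm²/ms, $t_{ex}$
10–35 ms, $p_2$ 0.18–0.30). It stands in for an in-vivo-derived phantom
whose ground truth is not publicly available, and is labelled synthetic
accordingly. What the simulations deliberately do *not* emulate: partial
volume and CSF contamination, spatially correlated (denoising-residual)
noise, gradient nonlinearity, motion, or soma-restricted diffusion.
Passing tests therefore demonstrate correctness of the estimator under the
model's own assumptions, not robustness to everything real data contains.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run, per configuration: 200
parameter draws for the narrow-pulse equivalence sweep (both protocols,
five $\varepsilon$ values), 100 draws for noiseless-recovery checks, 500
draws for the noise-floor, finite-pulse and $\ell_{max}$ comparisons, and
a 48×48 phantom (~1650 in-mask voxels, 20 parcels) for the solver
comparison. Solver-agreement statistics follow the ROI-summary convention
(median across parcels of per-parcel median bias and IQR), matching how
the corresponding experiment reports its numbers.

## Known limitations

* The exchange description is an effective theory; at short diffusion
  times or exchange times comparable to packing correlation times the
  parameters are *apparent*, not literal membrane properties.
* $D_n$ is weakly identified at realistic SNR and tends to its upper
  bound — visible in the propagation experiments as a wide $D_n$ IQR; this
  is a property of the model's information content, not of the optimizer.
* The likelihood is flat along curved ridges for low-$f$, slow-exchange
  tissue; dictionary initialization mitigates but cannot remove local
  minima (a handful of noiseless draws per hundred land on a
  signal-equivalent ridge point).
* Only linear PGSE encoding is modelled; free waveforms, tensor-valued
  encoding, compartmental relaxation differences and soma compartments are
  out of scope.
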