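# nexifit

Gray-matter microstructure mapping from multi-shell, multi-diffusion-time
diffusion MRI with the anisotropic two-compartment exchange (Kärger) model.

Water in gray matter exchanges between neurites (modelled as "sticks" with
along-fiber diffusivity *D<sub>n</sub>*) and an isotropic extracellular pool
(diffusivity *D<sub>e</sub>*) at rate *r<sub>n</sub>*. The coupled
magnetizations obey

    d/dt [Mn; Me] = ( [-rn  re; rn  -re] - q²(t) diag(Dn ε², De) ) [Mn; Me]

with detailed balance *r<sub>n</sub> f = r<sub>e</sub>(1−f)* and exchange
time *t<sub>ex</sub> = (1−f)/r<sub>n</sub>*, where *f* is the neurite signal
fraction and *ε = n̂·ĝ* the cosine between neurite and gradient. Solving
this system under the narrow-pulse approximation gives the analytic
two-exponential kernel (NEXI); integrating it through the actual trapezoidal
pulsed-gradient waveform gives its finite-pulse counterpart (SMEX). Voxel
signals are the convolution of this kernel with the fiber orientation
distribution, summarized per (b, t) shell by the rotational invariants
*S<sub>0</sub>* (spherical mean) and *S<sub>2</sub> = p<sub>2</sub>·|K<sub>2</sub>|*,
where *p<sub>2</sub>* indexes orientation dispersion.

The package is for researchers estimating apparent exchange times
(*t<sub>ex</sub>* ≈ 1–50 ms) from high-gradient human or preclinical dMRI.
It provides:

* **Acquisition schemes** — fixture protocols for two high-gradient scanners
  (`nexi_protocol("C1")`, `nexi_protocol("C2")`), FSL bval/bvec + timing-table
  readers, and exact trapezoidal b-value ↔ gradient-amplitude arithmetic.
* **Forward models** — `nexi_kernel()`, `smex_kernel()`,
  `project_legendre()`, `directional_signal()`, and the exact Rice mean
  `rice_mean()` for noise-floor-aware prediction.
* **Invariant extraction** — `normalize_b0()`, `extract_invariants()` (even
  spherical harmonics up to l = 4), `estimate_sigma_b0()`.
* **Estimation** — `dictionary_init()`, voxel-wise bounded `fit_nlls()`,
  batched `fit_adam()` (all masked voxels under one L1 loss, analytic
  gradients, optional 2D total-variation regularization of the *f* map),
  and `fit_roi()` for ROI-averaged signals.
* **Simulation** — `run_noise_propagation()` (seeded
  generate → corrupt → extract → fit → bias/IQR pipelines) and
  `make_phantom()` (labelled geometric phantom with per-parcel ground truth).

All user-facing functions take and return tibbles; fitted objects support
`tidy()`, `glance()` and `autoplot()`.

## Worked example

Reproduce the Rician noise-floor effect on exchange-time estimation: 200
random ground truths, per-direction signals on the C2 protocol, magnitude
(Rician) noise at SNR 50, invariant extraction, dictionary initialization
and bounded least squares:

```r
library(nexifit)

scheme <- nexi_protocol("C2", directions_per_shell = 64)
tissue_params(f = 0.35, Dn = 2.5, De = 0.9, rn = 0.02, p2 = 0.25)
#> # A tibble: 1 x 7
#>       f    Dn    De    rn    p2     re   tex
#>   <dbl> <dbl> <dbl> <dbl> <dbl>  <dbl> <dbl>
#> 1  0.35   2.5   0.9  0.02  0.25 0.0108  32.5

sim <- run_noise_propagation(protocol = "C2", noise = "rician", snr = 50,
                             n = 200, lmax = 0, seed = 7)
sim
#> <nexi_propagation> C2/nexi, noise rician, SNR 50, n = 200, lmax = 0, nlls
#> # A tibble: 5 x 5
#>   parameter stratum     n     bias     iqr
#>   <chr>     <chr>   <int>    <dbl>   <dbl>
#> 1 f         all       200 -0.0337   0.142
#> 2 Dn        all       200 -0.504    1.28
#> 3 De        all       200  0.0242   0.129
#> 4 rn        all       200 -0.00237  0.0106
#> 5 tex       all       200 10.9     23.6
```

The uncorrected magnitude noise floor inflates the median exchange-time
estimate by ~11 ms here. Re-running with `noise = "rician-mean"` (the Rice
mean folded into the forward model) or `noise = "gaussian"` brings the
median bias back to a fraction of a millisecond; `autoplot(sim)` shows the
per-parameter error distributions.

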