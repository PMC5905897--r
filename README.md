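# scdot

Spectrally constrained diffuse optical tomography (SCDOT) reconstruction
with sparse (L1) updates, in R.

Continuous-wave diffuse optical tomography injects near-infrared light into
tissue and measures the transmitted amplitude at the surface; the inverse
problem recovers the interior distribution of oxy- and deoxyhemoglobin
(HbO2, Hb) from those boundary measurements. This package is for
researchers prototyping CW-DOT reconstruction methods and for teaching:
everything runs on desk-scale synthetic phantoms in seconds, with no
external data.

The model chain:

* **Forward**: the CW diffusion equation
  −∇·κ∇Φ + μa Φ = q0, κ = 1/(3(μa+μs′)), with Robin (type III) boundary
  conditions, discretized by linear finite elements (triangles or
  tetrahedra).
* **Spectral constraint**: Beer's law μa(λ) = Σc ε(c,λ)·C(c) couples all
  wavelengths to the chromophore concentrations, which are reconstructed
  jointly; scattering follows the Mie prior μs′ = A(λ/1000 nm)^(−b) and is
  held fixed.
* **Inverse**: a Gauss-Newton outer loop; each linearized update solves
  min ‖ΔΦ − JΔc‖² + λR(Δc) with R = ‖·‖² (Tikhonov) or ‖·‖₁, the latter by
  IRLS, ADMM or FISTA. J is the adjoint-method spectral Jacobian. λ is
  chosen at the maximum-curvature corner of the L-curve computed on the
  first iteration.
* **Evaluation**: average contrast (AC), Pearson correlation (PC) and PSNR
  against ground truth.

## Worked example

Simulate a 25 mm disk phantom with a 4 mm inclusion (+0.005 mM HbO2) at
(0, 12) mm, 16 sources/16 detectors on a ring, 750/850 nm; then
reconstruct with FISTA and an automatically chosen λ:

```r
library(scdot)

spec <- phantom_spec(radius = 25, edge_length = 2.5,
                     inclusions = list(list(center = c(0, 12), radius = 4,
                                            delta_c1 = 0.005)))
ph  <- make_phantom(spec)
ms  <- simulate_experiment(ph)                  # noise-free measurements
bg  <- spec$background[[1]]

st  <- recon_settings(solver = solver_settings("fista"), lambda = "auto",
                      max_outer_iter = 6, c0 = c(bg$c1, bg$c2))
rec <- scdot_reconstruct(ms, ph$mesh, ph$optodes, default_extinction_table(),
                         scatter_prior = list(amplitude = bg$scatter_amplitude,
                                              power = bg$scatter_power),
                         settings = st, truth = ph$truth)
rec
#> scdot reconstruction (fista, lambda = 2.694e-06)
#>   4 outer iteration(s), converged; final ||dphi||_2 = 6.113e-05
#>   347 nodes x 2 chromophores (HbO2, Hb)

recon_metrics(rec, ph$truth)
#> scdot image-quality metrics:
#>  chromophore    AC     PC  PSNR n_region
#>         HbO2 1.092 0.8963 23.51        4
#>           Hb    NA     NA  -Inf        6
```

The recovered HbO2 change peaks 0.8 mm from the true inclusion center with
average contrast 1.09 — the mean recovered change in the activation region
(nodes above 50% of the peak) is within 10% of the true +0.005 mM. PSNR is
the whole-image error in dB against the ground-truth peak. No Hb change
was simulated, so the Hb row's truth field is identically zero: AC and PC
are undefined and PSNR has no reference peak. `plot(rec, type = "map")`
draws the recovered field; `plot(rec)` the residual trace.

Noise, solver choice and λ selection are all first-class:

```r
noisy <- add_noise(ms, noise_spec(level = 0.01, seed = 1))   # 1% proportional
curve <- lcurve_scan(problem, solver_settings("admm"))        # misfit vs ||dc||_1
lcurve_corner(curve)                                          # lambda at the elbow
```

A YAML-driven pipeline (`parse_config()` / `run_pipeline()`) and a thin
CLI (`inst/cli/scdot.R` with subcommands simulate, lcurve, reconstruct,
evaluate, run) tie the stages into reproducible runs; every artifact and
the run manifest are plain text.

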