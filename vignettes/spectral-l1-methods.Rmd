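---
title: "Spectrally constrained diffuse optical tomography with sparse updates: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectrally constrained diffuse optical tomography with sparse updates: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scdot)
```

# The problem

Continuous-wave (CW) diffuse optical tomography measures the amplitude of
near-infrared light transmitted between source and detector fibres on the
tissue surface and reconstructs the interior distribution of absorbing
chromophores — chiefly oxyhemoglobin (HbO2) and deoxyhemoglobin (Hb). With
only CW amplitudes, a single wavelength determines only absorption; the
spectrally constrained formulation therefore inverts all wavelengths
jointly, coupling them through Beer's law,

$$\mu_a(r,\lambda) = \sum_c \varepsilon_{c,\lambda}\, C_c(r),$$

so that the unknowns are the chromophore concentrations $C_c(r)$ directly.
This suppresses crosstalk and artefacts relative to inverting each
wavelength separately. Focal changes (a functional activation, a dyed
inclusion) are *sparse* relative to the background, which motivates an L1
(lasso-type) penalty on the concentration update rather than the classical
quadratic (Tikhonov) one: L1 preserves edges and contrast and is robust to
measurement noise, at the cost of a non-differentiable subproblem.

# Forward model

Light transport is modelled by the CW diffusion approximation

$$-\nabla\cdot\kappa(r)\nabla\Phi(r) + \mu_a(r)\Phi(r) = q_0(r),
\qquad \kappa = \tfrac{1}{3(\mu_a + \mu_s')},$$

with a Robin (type III) boundary condition $\Phi + 2A\kappa\,
\partial_n\Phi = 0$ accounting for the refractive-index mismatch at the
tissue surface. The package discretizes this with linear (P1) finite
elements on triangles (2D) or tetrahedra (3D), assembled in
`assemble_system()`:

* stiffness $\int \kappa \nabla u\cdot\nabla v$ with elementwise-linear
  $\kappa$ (exact, since P1 gradients are constant);
* absorption mass $\int \mu_a u v$ with elementwise-linear $\mu_a$,
  integrated exactly with the third-order basis product formulas — this
  matters because the adjoint Jacobian differentiates this term, and exact
  integration makes the Jacobian the exact derivative of the discrete
  model;
* Robin boundary term $\int_{\partial\Omega} uv/(2A)$. The coefficient $A$
  is computed for a relative refractive index of 1.33 from the effective
  reflection approximation (`robin_coefficient()`, $A \approx 2.79$); $A=1$
  gives the index-matched case. The value is exposed because published
  reconstructions rarely state it.

Sources are unit point loads placed one transport length $1/\mu_s'$ inside
the boundary (the standard CW convention for a collimated fibre),
distributed to the containing element's nodes by barycentric weights;
detector readings are barycentric interpolations of the nodal fluence at
the detector positions. Because load and readout are both interpolation
functionals of the same self-adjoint system, swapping the two points leaves
a reading unchanged to solver precision (discrete reciprocity), and on a
homogeneous disk of radius 40 mm the solution matches the 2D
infinite-medium Green's function $K_0(\mu_{\mathrm{eff}} r)/(2\pi\kappa)$
within 5% in the 5–10 mm annulus (both are acceptance-tested).

Scattering is never updated by the reconstruction: $\mu_s'$ comes from the
Mie-type prior $\mu_s'(\lambda) = A_{sc} (\lambda/1000)^{-b}$ with the
wavelength in micrometers. This convention reproduces the published
head-tissue $\mu_s'$ tables from their amplitude/power pairs to printed
precision, which is how it was validated.

## Extinction coefficients

The package ships hemoglobin extinction values at 750 and 850 nm
(0.1198/0.3226 and 0.2436/0.1596 mm⁻¹mM⁻¹ for HbO2/Hb) — the standard
tabulated hemoglobin spectra in the natural-log convention. They reproduce
the published five-tissue head $\mu_a$ values from the corresponding
concentration pairs to the three printed decimals. Any other table can be
supplied as CSV (`read_extinction_table()`), including a single
"generic dye" chromophore for phantom work.

# Inverse model

`scdot_reconstruct()` runs a Gauss-Newton outer loop. At iteration $k$ the
data mismatch $\Delta\Phi$ between measured and modelled data is formed,
the spectral Jacobian

$$J = \begin{pmatrix}
J_{\lambda_1}\varepsilon_{c_1,\lambda_1} & J_{\lambda_1}\varepsilon_{c_2,\lambda_1}\\
J_{\lambda_2}\varepsilon_{c_1,\lambda_2} & J_{\lambda_2}\varepsilon_{c_2,\lambda_2}
\end{pmatrix}$$

is rebuilt by the adjoint method, and the update $\Delta c$ solves the
regularized linearized problem

$$\Delta c^k = \arg\min_{\Delta c}\;
\|\Delta\Phi - J\,\Delta c\|_2^2 + \lambda R(\Delta c),$$

with $R = \|\cdot\|_2^2$ (Tikhonov) or $R = \|\cdot\|_1$ (the sparse
variant). The per-wavelength Jacobian includes both the absorption-mass
sensitivity and the dependence of $\kappa$ on $\mu_a$, so it is the exact
derivative of the discrete forward model (finite-difference agreement is
acceptance-tested at 1e-3).

**Data transform.** By default the misfit is formed on *log amplitudes*
(`data_transform = "log"`), the Rytov-type choice. CW amplitudes span
several decades across source-detector separations; with raw amplitudes
the misfit and the Jacobian are dominated by the shortest links and the
most superficial nodes, and in our experiments the L-curve then selects
over-sparse superficial solutions. With log data the links are weighted
comparably, and the noise-free recovery experiment places the recovered
peak inside the true inclusion with average contrast near 1. Raw-amplitude
fitting remains available (`data_transform = "raw"`).

**Stopping and step control.** The loop stops when
$\|\Delta\Phi^{k-1}-\Delta\Phi^{k-2}\|_1 \le \mathrm{Tol}$ (default
$10^{-6}\|\Phi^M\|_1$) or after `max_outer_iter` (default 20) iterations.
In addition, an update that *increases* the true misfit — or produces an
unphysical state with non-positive modelled amplitudes — is rejected and
the loop stops at the last accepted state; the residual trace is therefore
non-increasing over accepted iterations. Without this safeguard, holding
$\lambda$ at its first-iteration value lets the sparse solvers keep adding
concentrated updates that slowly re-inflate the residual while the peak
contrast runs away. For the forward evaluation $\mu_a$ is floored at
$10^{-6}$ mm⁻¹ so transiently negative concentration iterates cannot make
the diffusion operator lose ellipticity.

**Initialization.** The initial concentrations `c0` must be supplied; for
synthetic studies they are the known homogeneous background. The
data-calibration procedure some instruments use to estimate `c0` is out of
scope; `calibrate_measurements()` provides the homogeneous-reference ratio
calibration that removes per-link coupling gains and model/data mismatch.

# The four update solvers

All four implement their published update equations literally.

* **Tikhonov** — closed form $(J^TJ+\lambda I)\Delta c = J^T\Delta\Phi$,
  solved by Cholesky factorization.
* **IRLS** — iteratively reweighted least squares: weights
  $w_s = |\Delta c_s|^{-1/2}$ (floored at $1/\varepsilon$ when
  $|\Delta c_s| < \varepsilon$) turn the L1 penalty into a sequence of
  weighted ridge problems $(J^TJ + \lambda W^TW)\Delta c = J^T\Delta\Phi$.
  Fixed $\varepsilon = 0.005$; values in 0.001–0.01 behave equivalently.
  With unit weights one iteration *is* the Tikhonov update (tested to
  machine precision).
* **ADMM** — splitting $v$, scaled multiplier $b$, penalty $\theta$
  (default 0.01): a $\Delta c$ solve with the once-factorized
  $(J^TJ+\theta I)$, soft thresholding at $\lambda/\theta$, and the dual
  update $b \leftarrow b + \Delta c - v$.
* **FISTA** — proximal gradient on the extrapolated point with gradient
  $J^T(J\Delta y - \Delta\Phi)$, threshold $t\lambda$, Nesterov momentum
  $\alpha_i = (1+\sqrt{1+4\alpha_{i-1}^2})/2$, step $t = 0.9/\tilde L$ with
  $\tilde L$ from power iteration, and optional backtracking (halve $t$
  until the quadratic majorization of the smooth term holds). The
  published stopping rule ("relative residual") is undefined; we stop on
  the relative change of the iterate,
  $\|\Delta c^i-\Delta c^{i-1}\|_2 / \max(\|\Delta c^{i-1}\|_2, 10^{-12})
  \le \mathrm{Tol}$.

**The λ-convention.** The published updates are internally mixed between
the $\|r\|_2^2$ and $\tfrac12\|r\|_2^2$ data-term conventions. Working
through the stationarity conditions: the ADMM and FISTA updates use the
half-squared gradient $J^T(J\Delta c - \Delta\Phi)$, and the IRLS weights
$|x|^{-1/2}$ give the penalty $\lambda\sum x^2/|x_{\mathrm{prev}}|$ whose
fixed-point gradient is $2\lambda\,\mathrm{sign}(x)$. Relative to the
objective $\|r\|_2^2 + \lambda_{\mathrm{eff}}\|x\|_1$ all three L1 solvers
therefore carry $\lambda_{\mathrm{eff}} = 2\lambda$ (verified numerically:
each matches a high-precision proximal-gradient oracle to better than
$10^{-3}$ relative in objective under this mapping — one of the acceptance
tests, over 50 random instances). Each solver result records its
`lambda_eff`. In practice $\lambda$ is tuned per solver by the L-curve, so
the constant factor is immaterial to use.

Degenerate input $\Delta\Phi = 0$ returns $\Delta c = 0$ immediately for
every solver, which makes zero data mismatch an exact fixed point of the
outer loop.

# Choosing λ: the L-curve

`lcurve_scan()` solves the *first-iteration* linearized problem once per
ladder value (descending from $\lambda_{\max} = \|J^T\Delta\Phi\|_\infty$,
the smallest weight with an all-zero L1 solution under the implemented
convention; 25 points, factor $10^{0.25}$), warm-starting each solve from
the previous one, and records the misfit $\|\Delta\Phi-J\Delta c\|_2^2$
against the regularizer ($\|\Delta c\|_1$, or $\|\Delta c\|_2^2$ for
Tikhonov). `lcurve_corner()` returns the point of maximum
finite-difference curvature of the log–log polyline (endpoints excluded;
segments shorter than $10^{-6}$ in log–log space — stalled duplicate
points — are skipped; ties break toward larger $\lambda$; an all-negative
curvature profile raises an explicit "no corner" error). The chosen
$\lambda^\*$ is then reused for the remaining outer iterations. A `window`
argument restricts the search range, mirroring the manual refinement step
practitioners apply around the automatic corner; no automatic sparsity
heuristic is layered on top.

# Synthetic phantoms and noise

`phantom_spec()`/`make_phantom()`/`simulate_experiment()` generate the
desk-scale study conditions used by every test:

* a 25 mm disk (or layered disk) meshed at 2.5 mm resolution (~320 nodes)
  by concentric-ring triangulation — chosen so the full pipeline runs in
  seconds on one CPU;
* gray-matter-like background (HbO2 0.0548 mM, Hb 0.0354 mM, scattering
  amplitude 0.5040, power 1.7757), per-layer backgrounds for layered
  phantoms;
* focal disk inclusions, additive (e.g. +0.005 mM ≈ a 5 µM activation) or
  multiplicative (factor 2 = concentration doubling);
* 16 co-located source and detector positions on the boundary ring
  (240 links), wavelengths 750/850 nm.

Measurement noise (`add_noise()`) is proportional Gaussian —
$y \leftarrow y(1 + \ell z)$, $z\sim N(0,1)$ i.i.d. per link and
wavelength, seeded — either at a flat level $\ell$ or binned by
source-detector distance with default edges midway between the nominal
neighbour distances 13/30/40/48 mm and levels 0.12/0.15/0.41/1.42%,
emulating high-density array noise statistics. "x% Gaussian noise" is
read as proportional noise of standard deviation x% of each amplitude; the
alternative (relative to the mean signal) is not used.

Two deliberate pairings of contrast and noise reflect the emulated
experiments: the *noise-free recovery* benchmark uses the small 5 µM
inclusion, while the *1% noise solver comparison* uses the
concentration-doubling inclusion, because a 5 µM change on this desk-scale
geometry produces a data signature several times *smaller* than 1%
proportional noise — no solver can recover it, and the comparison would be
meaningless. (The published small-change experiments correspondingly use
the much weaker distance-binned noise.)

An inverse-crime control is built in: `make_phantom(spec, edge_length =)`
can simulate on a finer mesh than the reconstruction uses, and the test
suite exercises recovery across mesh resolutions.

## What passing these tests does and does not show

The generator emulates idealized conditions: exact Beer's-law physics,
known scattering, known homogeneous background as the initial guess,
perfectly calibrated optodes, Gaussian noise. Real data add coupling
gains, model mismatch, physiological background fluctuations and
non-Gaussian outliers; the ratio calibration addresses only the first two.
Passing the synthetic suite validates the *algorithms*, not instrument
performance.

# Evaluation metrics

`recon_metrics()` scores a reconstruction against ground truth per
chromophore:

* **AC** (average contrast): mean recovered change over the activation
  region — nodes with $|\Delta c| \ge 50\%$ of the maximum recovered
  change — divided by the true contrast; 1 is perfect. Thresholding uses
  the magnitude so negative (Hb) activations work symmetrically.
* **PC**: Pearson correlation of recovered and true change fields.
* **PSNR**: $10\log_{10}(\mathrm{MAX}^2/\mathrm{MSE})$ with MSE over *all*
  nodes and MAX the maximum of the *ground-truth* field, so the metric is
  comparable across methods on one phantom (the published definition
  leaves MAX ambiguous; using the recovered maximum would reward
  overshoot). A zero-MSE reconstruction is flagged `Inf`.

# Numerical choices and limitations

* Inner linear systems use dense Cholesky factorizations (the FEM systems
  use sparse CHOLMOD); the contract is the $10^{-10}$ relative residual,
  not the method.
* Solver defaults: `tol = 1e-6`, `max_inner_iter = 200` (IRLS 20),
  $\theta = 0.01$, $\varepsilon = 0.005$, FISTA safety 0.9. The
  solver-oracle tests use tighter tolerances and a smaller
  $\varepsilon = 10^{-5}$ because the IRLS fixed point approaches the
  exact lasso minimizer only as $\varepsilon \to 0$; the defaults are for
  reconstruction, where such precision is unnecessary.
* On this package's desk-scale phantoms the *converged* IRLS and ADMM
  solutions are markedly over-sparse: with ~320 nodes and 240 links the L1
  minimizer concentrates an inclusion's worth of absorption into 2–3 nodes
  with a corresponding contrast overshoot (AC well above 1). Their AC
  still dominates Tikhonov's (which under-contrasts), but their
  whole-image PSNR can trail a well-regularized Tikhonov reconstruction —
  a small-scale effect: with tens of thousands of nodes an activation is
  resolved by many nodes and the spike pathology dilutes. FISTA's capped
  inner iterations act as additional early-stopping regularization and
  avoid the overshoot; it matches or beats Tikhonov on every metric in the
  packaged experiments. The over-sparsification of fully converged IRLS
  relative to the other solvers is consistent with published observations.
* 2D triangular meshes are the primary tested geometry; the same assembly
  and Jacobian code paths run on tetrahedral meshes (tested on a
  structured cube), but no 3D mesh generator is included.
* No radiative-transfer or Monte Carlo forward model, no frequency- or
  time-domain data, no CSF non-diffusive corrections, no
  scattering-parameter reconstruction, no Lp (0<p<1) or total-variation
  penalties.

# Problem sizes used by the packaged experiments

The test suite and the acceptance script run, per invocation: one 40 mm
disk at 2 mm resolution (~1300 nodes) for the Green's-function check; the
standard 25 mm phantom at 2.5 mm (~320 nodes, 480 stacked measurements,
640 unknowns) for recovery; 10 noise realizations × 4 solvers for the
solver comparison; and 50 random lasso instances (rows 6–20, columns
4–12) for the oracle equivalence. These sizes were chosen so a full run
completes in minutes on a single CPU while every qualitative phenomenon of
interest (depth bias, sparsity, noise robustness) is present.
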