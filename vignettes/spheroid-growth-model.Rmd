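---
title: "Modeling confined tumor spheroid growth with adaptive stress relaxation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling confined tumor spheroid growth with adaptive stress relaxation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheroidgrowth)
```

## The physical picture

A tumor spheroid growing in suspension or inside a gel is, mechanically, a
soft incompressible solid that manufactures its own volume. Nutrient
diffuses in from the boundary and is consumed, so at any appreciable size
the rim proliferates while the core starves and loses volume; the resulting
*differential* growth bends the tissue against itself and stores elastic
stress. Cells are not passive springs, though: junctions and cytoskeleton
turn over, cells rearrange and divide obliquely, and on the timescale of
days the stored stress partially relaxes. On top of this, compressive
stress feeds back on cell behavior — it squeezes water out of cells and can
slow growth — and crowding throttles division. `spheroidgrowth` couples
these ingredients in a radially symmetric Eulerian model with a moving free
boundary, plus an external loading stage (neo-Hookean gel or hydrostatic
pressure, with timed release events) and a calibration layer.

## Governing equations

Stress is normalized by the tissue shear modulus, time by 1 day, length by
1 μm; everything below is dimensionless.

**Reference-map elasticity.** The solver evolves the reference map
$y(r,t)$, the reference radial coordinate of the material point currently
at radius $r$ (the inverse of the deformation). For an incompressible
neo-Hookean tissue the deviatoric stresses are
$$\sigma_{rr} = \Big(\frac{y/r}{y_{,r}}\Big)^{4/3}, \qquad
  \sigma_{\theta\theta} = \sigma_{\phi\phi}
  = \Big(\frac{y_{,r}}{y/r}\Big)^{2/3},$$
so that $\sigma_{rr}\sigma_{\theta\theta}^2 = 1$ identically — a per-node
invariant the test suite checks on random admissible maps. The total stress
is $\boldsymbol\sigma - p\mathbf I$; the pressure comes from the overdamped
force balance
$\alpha v = -p_{,r} + \sigma_{rr,r} + \tfrac2r(\sigma_{rr}-\sigma_{\theta\theta})$
integrated inward from the boundary condition
$\sigma_{rr}^{tot}(R) = -F_{ext}$.

**Adaptive relaxation.** The reference map adapts to the current
configuration at rate $\beta$:
$$\partial_t y + v\, \partial_r y = \beta\,(r - y),$$
so the displacement $u = r - y$ decays at exactly rate $\beta$ when the
tissue is at rest. This is the model's stress-relaxation mechanism; it is
Maxwell-like but formulated entirely in the lab frame, which is what lets
finite elasticity couple cleanly to the Eulerian reaction–diffusion
fields. At a steady radius the relaxation law pins the boundary strain to
$y_{,r}(R_\infty) = \beta / (\beta + \lambda - \lambda_A)\rvert_{R_\infty}$:
$\beta \to 0$ is singular (strain collapses), large $\beta$ restores
$y \approx r$. `check_boundary_strain_relation()` measures the residual of
this relation on equilibrated runs; it is one of the package's acceptance
checks.

**Growth and feedback.** Nutrient follows the quasi-static screened profile
$c(r) = R\sinh(r/L)/(r\sinh(R/L))$ with $c(R)=1$ (evaluated with scaled
exponentials so deep screening does not overflow). Local volume changes at
$\lambda^{net} = \lambda c - \lambda_{A,c} - \lambda_E$ with Hill-type
mechanochemical feedback:

* water efflux
  $\lambda_E = \Delta_A\,\gamma_A\sigma^m 1_{\sigma<0} /
  (1+\gamma_A\sigma^m 1_{\sigma<0})$ — compression squeezes water out,
  saturating at $\Delta_A$;
* growth inhibition
  $\lambda = \lambda_0/(1+\gamma_\lambda \sigma^n 1_{\sigma<0})$;
* crowding-limited division
  $\lambda_c = \lambda_0/(1+\gamma_c|\rho_c-1|^{l} 1_{\rho_c>1})$.

The feedback stress $\sigma$ is the total hoop stress
$\sigma_{\theta\theta}^{tot}$ by default (it represents two of the three
principal directions); a config switch (`feedback_stress = "invariant"`)
substitutes $(2\sigma_{\theta\theta}^{tot}+\sigma_{rr}^{tot})/3$ instead,
with qualitatively similar results. $m,n$ are required even so the stress
powers stay nonnegative. Incompressibility converts $\lambda^{net}$ into
the velocity $v(r)=r^{-2}\int_0^r\lambda^{net}\eta^2 d\eta$ and moves the
boundary by $dR/dt=v(R)$. The cell number density $\rho_c$ is advected,
diluted by volume gain, grown by division, and smoothed by a
density-dependent neighbor-exchange flux with no-flux conditions at center
and boundary.

**Confinement.** Growth into an incompressible neo-Hookean gel (cavity
reference radius $R_0$, relative stiffness $c_H$) loads the boundary with
$F_{ext} = \tfrac{c_H}2\big(5 - R_0(R_0^3+4R^3)/R^4\big)$; the full gel
stress field is available from `gel_stress_profile()`, which integrates the
cavity-expansion equilibrium ODE and reproduces $-F_{ext}$ at the interface
(an oracle-equivalence test). The formula is applied as printed also for
$R < R_0$, where it is negative (an underfilled cavity pulls on the
boundary); shrinkage below the cavity size does not occur in the regimes
the package ships. Hydrostatic loading sets $F_{ext} = \bar p$.

## Numerical scheme

* **Moving grid.** Fields live on the fixed scaled coordinate
  $\xi = r/R(t) \in [0,1]$ (uniform, `N` nodes), so the mesh follows the
  boundary without re-meshing; advection uses the mesh-relative velocity
  $w = v - \xi\,dR/dt$, which vanishes at both ends. The standalone
  `regrid()` (monotone cubic, exact on linears) exists for changing
  resolution, not for ordinary stepping.
* **Splitting.** Per step: nutrient → elastic stress → pressure → rates and
  velocity → transport → boundary. The pressure–velocity coupling through
  the friction term $\alpha v$ is closed with two Picard sweeps seeded by
  the previous velocity ($\alpha \sim 10^{-3}$, so this converges far below
  discretization error). The boundary radius uses a Heun
  predictor–corrector because $R(t)$ is the primary observable; with
  uniform well-fed growth the exact exponential $R_0 e^{\lambda_0 t/3}$ is
  reproduced to 0.012% over a doubling at $N=200$.
* **Transport.** First-order upwind advection; the relaxation source and the
  linear-in-$\rho_c$ reaction are integrated exactly over the step
  (exponential updates — positivity preserving, and exact for the pure
  relaxation and uniform-reaction limits). Diffusion of $\rho_c$ is
  backward-Euler with the density-dependent coefficient lagged one step, in
  conservative finite-volume form with exact spherical shell volumes, so the
  discrete cell number is conserved to round-off under pure no-flux
  diffusion.
* **Quadrature at the origin.** All $\int f\,r^2\,dr$ integrals (velocity,
  averages) use a product-trapezoid rule — piecewise-linear $f$ against the
  exact $r^2$ weight — because the plain trapezoid loses all relative
  accuracy on the first cell at the coordinate singularity. Uniform rates
  then give $v = \lambda^{net} r/3$ exactly.
* **Time step.** $dt = \min(\mathrm{CFL}\cdot\Delta r/\max|w|,\;
  0.1/\max(\beta,\lambda_0))$, CFL = 0.4, trimmed to land exactly on event
  and snapshot times. CFL violations in the transport kernels are hard
  errors, not warnings. The forward model contains no randomness.
* **Verification.** The suite checks the divergence identity
  $r^{-2}(r^2v)_{,r} = \lambda^{net}$ at every snapshot (second-order
  residual, about $10^{-3}$ at $N=100$), the boundary force balance at
  machine precision, conservation along characteristics against an RK4
  oracle, and first-order convergence of $R(T)$ under joint $h, dt$
  refinement ($N \in \{100,200,400\}$, error ratio 2.03).

## Default parameters and the regime they encode

Base rates and feedback strengths for this class of models live in
supplementary material of the experimental literature and are
tissue-specific; the package defaults are deliberately calibration-free
placeholders chosen once to sit in the regime that confined-growth
experiments consistently show, and all documented numbers derive from them:

| parameter | default | meaning |
|---|---|---|
| `lambda0` | 1 /day | base volume growth = base division rate |
| `lambda_Ac` | 0.3 /day | apoptosis |
| `Delta_A`, `gamma_A`, `m` | 0.5 /day, 1, 2 | water-efflux feedback |
| `gamma_lambda`, `n` | 0, 2 | growth feedback (off by default) |
| `gamma_c`, `l_hill` | 1, 2 | crowding feedback on division |
| `L` | 50 μm | nutrient screening length |
| `D` | 1 μm²/day | cell mobility (results insensitive) |
| `alpha` | 1e-3 | friction |
| `beta` | 0.4 /day | stress-relaxation rate |

Three of these were chosen against explicit phenomenological requirements,
after probing the model's regime structure:

* **`L = 50`** (for a ~100 μm seed): with screening much weaker than this
  the equilibrium radius barely exceeds $L$, stress stays compressive
  everywhere and the density maximum sits at the center — the free-growth
  phenomenology (tensile core, compressive rim, inward interior flow,
  rim density maximum) requires $R_\infty$ of a few screening lengths.
* **`gamma_A = 1`, `Delta_A = 0.5`**: stronger saturating efflux makes the
  model bistable — a uniformly compressed small-radius state (compression →
  efflux → volume loss → compression) coexists with the differentiated
  state, the steady size then depends on the initial radius, and sweep
  trajectories can collapse non-monotonically between branches. The shipped
  values are monostable: $R_\infty$ is independent of $R_0 \in [50, 150]$
  to five digits, confinement release is reversible, and the equilibrium
  diagnostics vary monotonically across the packaged sweep box.

The packaged parametric study (`sweep_beta_cH()`) spans
$\beta \in \{0.4, 0.8, 1.2, 1.6\}$, $c_H \in \{0, 0.25, 0.5, 0.75\}$ —
bracketing the relaxation rates ($\beta \sim 0.4\!-\!1$/day) and gel
stiffnesses that fits to published spheroid data land on. Outside this box
the model itself predicts the trends to flatten: under strong confinement
the stress is nearly uniform and set by the boundary load, and size becomes
insensitive to $\beta$ (observable by passing wider grids).

## The synthetic-observation generator

No experimental tables ship with the package, so calibration is exercised
on synthetic data: `generate_observations()` runs the forward model per
condition (shared tumor parameters; per-condition confinement), samples the
radius at irregular times, takes end-point density summaries (volume
average and center value, as ratios to the free condition), and adds
independent Gaussian noise — radius sd 2 μm and ratio sd 0.03 by default,
the measurement precision scale of spheroid imaging. What it deliberately
does *not* emulate: serially correlated measurement error from tracking the
same spheroid, inter-spheroid biological variability, non-Gaussian outliers
from segmentation failures, and digitization error of published figures.
Passing recovery tests therefore certify the estimator and its
implementation (identifiability of $(\beta, c_H)$ at realistic noise, AICc
selecting the generating variant), not robustness to real-data pathologies.

The objective normalizes radius residuals by their noise sd (or the mean
radius when absent) so density summaries contribute on a comparable scale,
and AICc uses the Gaussian least-squares form
$n\ln(SSE/n) + 2k + 2k(k+1)/(n-k-1)$; the feedback variant is charged its
two feedback constants on top of the grid dimensions. Grid search is
exhaustive, deterministic (ties break to the first point), caches forward
runs (the model is deterministic, so this is exact), and reports the
10%-of-best objective band alongside the argmin.

## Design choices where the design was open

* **Anisotropy measure**: $\sigma_{\theta\theta} - \sigma_{rr}$, sign
  retained — zero exactly for hydrostatic states, which is the property the
  equilibrium diagnostics need.
* **Energy density**: $W = \tfrac12(\sigma_{rr} + 2\sigma_{\theta\theta} -
  3)$, the isochoric neo-Hookean invariant consistent with the stress law;
  reported as the volume average $(3/R^3)\int W r^2 dr$.
* **Averaged stress gradient** (a sweep diagnostic):
  $(1/R)\int_0^R |\partial_r \sigma_{\theta\theta}^{tot}|\,dr$.
* **$\rho_c$ boundary condition at $r=R$**: zero diffusive flux with
  advective outflow; only the center condition is physically dictated, and
  the mesh-relative advection velocity vanishes at the boundary anyway.
* **Rate evaluation order**: the efflux computed from the current step's
  stress enters the same step's $\lambda^{net}$ (no lag), consistent with
  the quasi-static force balance.
* **Non-monotone radius flag**: an interior extremum of $R(t)$ deviating
  more than 1% of $R_\infty$ from the enclosing endpoint values — robust to
  discretization wiggle.
* **Steady-state criterion**: $|dR/dt| < 10^{-4} R$ throughout a trailing
  20-day window (well below $\lambda_0$); runs with scheduled release
  events refuse to declare steadiness until a full window after the last
  event.

## Problem sizes

Documented runs use $N = 100$ nodes (200–400 for convergence and
closed-form audits), seed radius 100 μm, horizons of a few hundred days run
to steadiness; calibration examples use 50 μm spheroids, $N = 80$, 7
sampling times over 28 days and 3×3 parameter grids. These choices resolve
every reported diagnostic (refinement checks above) while keeping full
test-suite and acceptance runs in the minutes range on a laptop core.

## Known limitations

* Strictly radial: no symmetry breaking, though the large-anisotropy
  corner of parameter space (small $\beta$, small $c_H$) where non-monotone
  radius dynamics appear is exactly where shape instability would be
  suspected physically.
* No interstitial fluid mechanics: water efflux is a volumetric sink with
  constant porosity; a poroelastic extension would couple efflux to
  interstitial pressure.
* The gel is a closure, not a simulated domain: its stress field comes from
  the incompressible cavity-expansion solution, so gel viscoelasticity or
  fracture is out of scope.
* Nutrient supply at the boundary is held at 1; medium depletion over long
  cultures is not modeled.
* First-order upwind transport: steep density fronts are smeared at coarse
  $N$; refine or regrid when sharp interior structure matters.
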