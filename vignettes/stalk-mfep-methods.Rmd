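---
title: "Methods: minimum free-energy paths for stalk formation"
author: "stalkpath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: minimum free-energy paths for stalk formation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements: the
order-parameter model, the string method and its estimators, the geometric
observables, the choices made where the design was genuinely open, and what
the synthetic validation systems do and do not establish.

## The order parameter and its mapping

Membrane morphology is described by the hydrophobic (lipid-tail) number
density $m(\mathbf c)$ on a collocation grid of cells $\mathbf c$ with
volume $\Delta V = \Delta L_x \Delta L_y \Delta L_z$. Cell lengths are
always derived from the box, $\Delta L_\alpha = L_\alpha / n_\alpha$, so the
grid tiles the box exactly; cell centers sit at $(i + 1/2)\Delta L_\alpha$.
This convention, together with minimum-image distances inside the assignment
kernel, makes the linear (cloud-in-cell) kernel an exact partition of unity
on periodic boxes: mapped fields conserve the particle count to machine
precision, which the suite checks for thousands of random configurations.
Periodic wrap-around support matters physically — a vesicle can form a stalk
with its own periodic image — so periodicity defaults to on for every axis.

A practical note on grid bookkeeping: when a cell volume is quoted alongside
independent cell lengths, the two can disagree (e.g. a nominal
$0.02\,\mathrm{nm^3}$ against $0.3\times0.3\times0.2 =
0.018\,\mathrm{nm^3}$). The package never accepts an independent
$\Delta V$: it derives $\Delta L$ from the box and reports the product, so
such inconsistencies cannot arise internally.

## Free energy, umbrella restraint and the chemical potential

The free energy $F[m]$ of a particle system is unknown; the string method
only needs its gradient, the chemical potential
$\mu(\mathbf c) = \partial F / (\Delta V\, \partial m(\mathbf c))$ (all
energies in $k_BT$; at 300 K, $k_BT = 2.494\ \mathrm{kJ/mol}$). The package
expresses this as a *provider* contract: anything that maps a target field
to a $\mu$ field. Two implementations ship:

* **Analytic providers** evaluate $\mu$ in closed form for quadratic and
  Ginzburg–Landau double-well functionals, optionally with a square-gradient
  penalty (discrete periodic Laplacian) and per-cell linear tilts. They pass
  finite-difference gradient checks on every test run.
* **Sampling providers** wrap a restrained sampler: the umbrella potential
  $\Delta H = \tfrac{\kappa}{2}\sum_{\mathbf c} (n(\mathbf c) -
  \hat n(\mathbf c))^2$ restrains the instantaneous per-cell *counts*
  $\hat n = \hat m \Delta V$ to the target counts, and the estimator
  $\mu(\mathbf c) = \lambda\,[m(\mathbf c) - \langle\hat m(\mathbf
  c)\rangle]$ with $\lambda = \kappa \Delta V / k_BT$ converts the mean
  restrained deviation into the chemical potential.

The restraint strength is exposed directly as $\kappa$ in kJ/mol per squared
count deviation (default 50, the value used for MARTINI lipid production
runs) rather than as the dimensionless field coupling $\lambda$, because the
count form is what an MD engine adds to its force loop and it keeps the
units unambiguous; $\lambda$ is derived where needed. The symbol collision
between the umbrella coupling and the hydration decay length is resolved by
naming them `kappa` and `lambda_hyd`.

The estimator is exact only as $\kappa \to \infty$; on a single-cell
Gaussian reference free energy $F/k_BT = \tfrac{a}{2}\Delta V (m - m^*)^2$
the restrained average is available in closed form and the bias is
$\mu_{\text{exact}}\, a/(a + \lambda)$ — the suite verifies the $1/\kappa$
decay (log-log slope $-1 \pm 0.1$ over $\kappa \in \{25, 50, 100, 200\}$)
with the reference stiffness $a = 0.5$, chosen well below $\lambda$ so the
measurement sits in the asymptotic regime the estimator claims. A *mock
sampler* whose average obeys $\langle\hat m\rangle = m -
\mu_{\text{exact}}/\lambda$ closes the loop algebraically and exercises the
full sampling plumbing with zero stochastic noise.

Umbrella forces use the analytic piecewise-constant derivative of the tent
kernel ($\pm 1/\Delta L_\alpha$); exactly at kernel kinks (cell centers and
faces, a measure-zero set) the left-limit convention applies. Because the
kernel has one-cell support, the restraint force is short-ranged: a sampler
initialized with no kernel overlap with the target feels no attraction. The
toy Langevin analysis therefore starts its walker inside the target's
kernel support, as a restrained MD run starts from a configuration near its
target morphology.

## String method

A path is $n$ field replicas with contour parameters $s_i$. Iterations
alternate (1) an Allen–Cahn relaxation step $m \leftarrow m - \epsilon\mu$
per replica and (2) redistribution to uniform arc length: each cell's value
sequence is fit by a natural cubic spline against the cumulative normalized
segment lengths $\Delta_i$ (Euclidean distances in cell-value space,
normalized to $\sum_i \Delta_i = 1$) and re-evaluated at uniform positions,
iterated up to five passes until distances are uniform to $10^{-3}$
relative. Endpoints are returned bit-identical. Path tangents for the
perpendicular projection $\mu_\perp = \mu - \langle \mu, \dot m\rangle \dot
m / \|\dot m\|^2$ come from the same spline representation, keeping one
consistent description of the path.

Open choices, resolved as follows:

* **Step size.** The production relation $\epsilon \lambda / \Delta V =
  0.03$ fixes the default $\epsilon = 0.03\,k_BT/\kappa$; analytic
  landscapes pass explicit $\epsilon$ below the stability bound
  $2/\max_i h_i$ of the stiffest mode $h_i$ of the functional's Hessian.
* **Endpoints.** Default `evolve`: Allen–Cahn dynamics leaves true minima
  fixed and cleans imperfect endpoint estimates; `pinned` is available for
  comparisons against frozen states.
* **Convergence.** Iteration stops when the max per-cell displacement per
  iteration falls below `tol_disp` ($10^{-4}$ of the max field value by
  default) *and* the free-energy profile changes by less than `tol_F`
  ($10^{-3}$ relative); both are configurable, and non-convergence at the
  iteration cap is a warning with diagnostics, not an error. Iteration
  counts and provider calls are reported separately, since with a sampling
  provider each iteration costs $n$ restrained simulations.
* **Negative densities.** Updates clip negative values to zero (the order
  parameter is a physical density) and log the count; clipping is
  switchable off for analytic landscapes where negativity is meaningful,
  and the analytic validation runs disable it.
* **Spline boundaries.** Natural splines (zero second derivative) at both
  ends, for the reparameterization, the tangents and the integration alike.

## Thermodynamic integration

The profile is the line integral of the gradient along the path,
$$\Delta F(s) = \int_0^s \mathrm{d}s'\; \Delta V \sum_{\mathbf c}
\mu_{s'}(\mathbf c)\, \frac{\mathrm{d}m_{s'}(\mathbf c)}{\mathrm{d}s'},$$
with both $m$ and $\mu$ interpolated per cell by natural cubic splines in
$s$ and the integral accumulated by composite Simpson on $\ge 201$ uniform
points. This is the only form that is a true differential of $F$ along the
path — it vanishes identically for constant paths, is path-independent for
exact gradients (verified to $10^{-6}$ relative against closed-form
endpoint differences over deliberately bent paths), and references
$\Delta F(0) = 0$ exactly. A variant that integrates $\Delta V \sum_c m\mu$
without the $\mathrm{d}m/\mathrm{d}s$ factor is retained behind
`integrate_profile(form = "literal")` for comparison; it is not a line
integral of the gradient and is not the default. The barrier
$\Delta F_b = \max_s \Delta F(s)$ is refined parabolically around the dense
grid maximum with ties broken toward smaller $s$; $\Delta F_{\text{stalk}} =
\Delta F(1)$ is the final-state excess. When $\mu$ fields carry per-cell
standard errors, per-replica errors are propagated as independent with
trapezoidal arc weights — a deliberate approximation, adequate for error
bars, not for inference.

## Geometric observables

Interfaces are iso-density contours at the hydrophobic threshold
$2.2\ \mathrm{nm^{-3}}$ (configurable), with all crossings located by
linear sub-cell interpolation; contours use marching squares.

* $d_w$: for every lateral column parallel to the stalk axis, the circular
  gap spanning each *separating water slab* — a run of axial planes whose
  maximum density is below the threshold — is measured between interpolated
  crossings; $d_w$ is the minimum over columns and slabs. Restricting gaps
  to those spanning a water slab is what prevents a vesicle's interior
  chords from masquerading as intermembrane gaps, and it makes the periodic
  image of a vesicle the second body, as it should be. Connected membranes
  return $d_w = 0$; the bridge is detected as an interior dip of the
  per-plane above-threshold area fraction between the membrane bodies
  (a narrow stalk occupies a small lateral fraction of its planes, membrane
  planes a large one; the dip ratio is 0.3, so necks up to roughly half the
  membrane's lateral fraction are detected).
* $d_{st}$: the mid-plane is the midpoint of the density-weighted centers
  of the two membrane bodies on either side of that dip; on it, the
  above-threshold cross-section containing the densest lateral cell is
  contoured (after circular recentring, so lateral periodic translations
  do not split the polygon) and $d_{st}$ is the diameter of the circle with
  the contour's area. The area-equivalent definition is robust to
  cross-section shape fluctuations and reduces to the geometric diameter
  for circular necks ($2\sqrt{ab}$ for an elliptical neck); a maximal-chord
  alternative sits behind `method = "chord"`. When no above-threshold
  connection spans the gap the diameter is *absent* (`NA`), a value rather
  than an error.
* Azimuthal $(R, z)$ maps bin cells by minimum-image lateral distance from
  the axis; thickness profiles measure per-column segment extents and
  exclude bridged columns (segment count different from the modal count).

Raising the threshold widens $d_w$ and narrows $d_{st}$ on monotone
interfaces; the suite asserts these directions.

## Apposition model

Hydration repulsion between planar membranes is modelled as
$\Delta f_{\text{flat}}(d_w) = A\, e^{-d_w/\lambda_{\text{hyd}}}$ with
$\lambda_{\text{hyd}} = 0.28$ nm for POPC, calibrated by a single anchor
pair — by default $1.2\ k_BT/\mathrm{nm^2}$ at $d_w = 1.2$ nm, the only
quantitative anchor available, giving $A = 87.2\ k_BT/\mathrm{nm^2}$. The
planar excess is proportional to the apposed area and hence unbounded
without a patch size; the Derjaguin construction for two equal spheres,
$\Delta F_{\text{dehydr}} = \pi R_v \lambda_{\text{hyd}}
\Delta f_{\text{flat}}(d_w)$, stays finite. $R_v$ is the *outer* interface
radius, matching the definition of the vesicle radius used throughout.

## Synthetic systems and what passing tests show

The validation landscape of choice is the Ginzburg–Landau double well, not
a lipid force field, because it has exactly computable chemical potentials,
minima, saddles and constrained barriers. Three study systems recur:

* a **two-cell tilted double well** (wells at 0.5 and 2.5 nm⁻³, quartic
  strength 1, gradient coupling 2, per-cell tilts $+0.05/-0.08$): the
  coupling is deliberately stiff enough that the synchronous transition
  through the symmetric saddle is the MFEP — at weak coupling the landscape
  has cheaper stepwise saddles and the symmetric stationary point is an
  index-2 maximum, a useful trap for string implementations but not a
  well-posed oracle test. A damped-Newton root of $\nabla F = 0$, computed
  in the test helpers independently of the string code, supplies the saddle;
  the converged 41-replica string passes through it to better than $10^{-3}$
  per coordinate with the TI barrier matching $F(\text{saddle}) -
  F(\text{min})$ to $10^{-3}$ relative.
* a **20-cell 1D double well** between uniform phases with gradient
  coefficient 15, chosen above the threshold ($\approx 10$ for this grid)
  at which every constrained minimum along the transition is uniform, so
  the barrier has the closed form $N \Delta V\, a\, ((m_2 - m_1)/2)^4 =
  10\ k_BT$ and an independent constrained-scan oracle (minimization over
  the orthogonal complement at fixed interpolation coordinate) agrees.
* **constructed membrane fields**: tanh-profile slabs, shells and catenoid
  bridges at bulk tail density 5 nm⁻³ with 0.25 nm interface widths, whose
  exact threshold crossings are solved at construction and stored as
  fixture metadata, so geometric tests compare against ground truth rather
  than against re-derived numbers. Grids of $40 \times 40 \times 60$ cells
  on 12 nm boxes (planar) and $90^3$ on the $26.31 \times 26.83 \times
  20.74$ nm vesicle box keep every half-cell tolerance binding while the
  whole suite runs in well under a minute.

These systems validate the machinery — mapping, forces, estimators, string
convergence, integration, geometry — not membrane thermodynamics. Real
lipid systems add what the fixtures deliberately omit: thermal interface
fluctuations, sampling noise in $\mu$, slow orthogonal relaxation, and
barriers set by molecular packing rather than by a quartic polynomial.
Passing tests therefore establish correctness of the algorithms, and the
production defaults (24 or 19 replicas, $\kappa = 50$ kJ/mol, $\epsilon
\lambda/\Delta V = 0.03$, 2.2 nm⁻³ threshold) are wired in as
configuration defaults, but quantitative stalk energetics require coupling
the provider contract to an MD engine, which this package intentionally
does not ship.

## Known limitations

* The chemical-potential estimator is first order in $1/\lambda$; no
  higher-order correction is implemented.
* Error propagation in profiles assumes independent per-replica errors.
* Contours are not continued across periodic boundaries (slices are
  recentred instead); fields whose features span more than half a box axis
  laterally can defeat the recentring.
* The bridged-membrane detector assumes the stalk's lateral area fraction
  is well below the membranes'; exotic, plate-like bridges would need the
  threshold ratio adjusted.
* Checkpoints use R's native serialization: bit-exact and versioned, but
  not a cross-language container.
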