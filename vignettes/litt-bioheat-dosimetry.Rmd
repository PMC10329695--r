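---
title: "Bioheat modeling and laser dosimetry planning with littplan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bioheat modeling and laser dosimetry planning with littplan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(littplan)
```

## The problem

Laser-induced interstitial thermotherapy (LITT) ablates unresectable
soft-tissue tumors — pancreatic ductal adenocarcinoma being the motivating
case — by delivering continuous-wave Nd:YAG light (1064 nm, 2–10 W) through
a 300 µm bare optical fiber inserted into the tumor under endoscopic
ultrasound guidance. The clinical question is dosimetry: which output power
$P$ and exposure time $t$ ablate the tumor and a safety margin around it
while keeping nearby vessels and the duodenum below the injury threshold.
`littplan` answers it in silico: it simulates the coupled optical–thermal
problem on synthetic anatomies and searches the $(P, t)$ grid for the
minimum-power setting that meets the treatment criteria.

## The model

### Bioheat equation

Tissue temperature obeys a modified Pennes bioheat equation,

$$\rho C \frac{\partial T}{\partial t}
  = \nabla\!\cdot\!\left(k \nabla T\right)
  - \rho_b C_b \omega_b \,(T - T_b)
  - h_{fg}\frac{dW}{dt}
  + Q_{met} + Q_{laser},$$

with blood at $T_b = 37$ °C ($\rho_b = 1050$ kg/m³, $C_b = 3617$ J/(kg·K)
by default), a capillary perfusion sink $\omega_b$, the latent-heat sink of
tissue water evaporation, and metabolic plus laser sources. Baseline
properties at 37 °C (pancreas: $\rho = 1128$, $k = 0.52$, $C = 3164$,
$\omega_0 = 0.018$ s⁻¹; tumor shares the thermal values with
$\omega_0 = 0.005$ s⁻¹; duodenum and generic soft tissue have their own
entries) live in `tissue_model_set()` and are fully overridable. $Q_{met}$
defaults to 0 W/m³ — no value is established for pancreas, and at ablative
intensities it is negligible against the laser source.

### Laser source

The beam carries a fixed transverse Gaussian profile,
$I(x,y) = I_0 e^{-(x^2+y^2)/2\sigma^2}$ with $I_0 = P / 2\pi\sigma^2$ and
$\sigma = r_f/3 = 50$ µm, so 99 % of the output power passes through the
fiber core radius $r_f = 150$ µm. Along the incidence direction the
deposition follows the Beer–Lambert law with the effective attenuation
coefficient

$$\alpha_{eff} = \sqrt{3\alpha\,(\alpha + \alpha_s (1-g))},$$

giving $Q_{laser} = \alpha_{eff}\, I(x,y)\, e^{-\alpha_{eff} z}$. Native and
coagulated optical coefficients differ (coagulation raises scattering
seven-fold); per cell they are blended linearly by the local necrotic
fraction $\Omega$, and the exponent generalizes to the path integral of the
cell-local $\alpha_{eff}$ from the fiber tip, which reduces exactly to the
homogeneous form when $\Omega$ is uniform.

Because $\sigma$ is far below any practical cell size, the source builder
never point-samples the Gaussian: each beam-aligned cell column receives the
analytically integrated Gaussian mass of its footprint, and each cell the
exact difference of $e^{-\tau}$ across its faces. Total deposited power is
therefore conserved on arbitrarily coarse grids — the volume integral of
$Q_{laser}$ reaches $P$ as the domain grows. This is also why beam
directions are restricted to grid-axis alignment in voxel mode (the axis in
axisymmetric mode): the column decomposition is only well-defined there.

### Temperature-dependent properties

* **Water content** $W(T)$ holds its native fraction $W_0$ (default 0.7, a
  typical soft-tissue value; not fixed by any measurement we reproduce) up
  to 80 °C, then declines along a Weibull-type tail whose scale is pinned so
  that exactly half the water is gone at 103 °C; the decline accelerates
  near 100 °C and the residual is below 1 % of $W_0$ by ~115 °C.
* **Apparent heat capacity.** Rather than carrying $h_{fg}\,dW/dt$ as a
  separate sink, the volumetric heat capacity $C' = \rho C$ carries a
  piecewise-linear peak spanning 80–104 °C whose integral equals
  $h_{fg} \rho W_0$ ($h_{fg} = 2260$ kJ/kg): evaporation enthalpy is paid
  implicitly by the storage term. The anchors are configurable so users can
  substitute digitized measured curves.
* **Conductivity** rises ~30 % towards 100 °C and falls back once
  evaporation completes, mimicking ex vivo measurements on heated liver;
  anchors are likewise replaceable.
* **Perfusion** multiplies $\omega_0$ by printed piecewise quadratics:
  healthy tissue peaks near 45 °C, tumor near 42 °C, reflecting
  hyperthermia-induced vasodilation before vascular destruction. The
  branches are deliberately kept exactly as printed — they are not
  continuous across their breakpoints, and smoothing them would silently
  change the published model. Outside the printed ranges the multiplier is
  1 at or below 37 °C and holds the branch-end value above the last
  breakpoint; it drops to 0 wherever $\Omega = 1$, since coagulated tissue
  has no circulation. Whether the healthy branches apply to duodenum and
  generic soft tissue is not established; the default applies them to every
  perfused non-tumor tissue.

### Damage model

Necrosis uses a threshold dwell-time model:
$\theta = \int_0^{\tau_{irr}} \frac{1}{t_n}(T > T_d)\,dt$ and
$\Omega = \min(\theta, 1)$. Defaults are $T_d = 60$ °C and $t_n = 1$ s —
at 60 °C coagulative necrosis is effectively instantaneous, which makes the
final $\Omega = 1$ region track the 60 °C isotherm closely (the test suite
checks they agree within ~10 %). Both parameters are exposed because $t_n$
is a modeling choice, not a measured constant. The 42 °C isotherm is
reported as the mild-hyperthermia/organ-injury contour.

## Numerics

The solver is a conservative finite-volume discretization on structured
grids — a uniform voxel grid in 3D, a graded $(r, z)$ grid in axisymmetric
mode (fine spacing near the axis and fiber tip, geometric coarsening
outward) — with harmonic-mean interface conductivities and implicit time
integration (backward Euler by default, BDF2 optional) at $\Delta t = 2$ s.
Equivalence with the continuous model is established against analytic
oracles rather than against any particular reference solver: the steady
perfused point source $T(r) = \frac{q}{4\pi k r}e^{-r/\delta} + T_b$,
$\delta = \sqrt{k / \rho_b C_b \omega_b}$, is reproduced within 2 % over
r = 2–10 mm, and the steady conduction–convection slab with a Robin face is
matched at machine precision (the vessel-face conductance combines the
half-cell conduction path with the film coefficient in series, which makes
the discrete steady solution exact at cell centers).

Three numerical choices deserve explanation:

* **Enthalpy-secant Picard iterations.** With a sharp apparent-capacity
  peak, a cell near the fiber can cross the whole 80–104 °C band within one
  2 s step; evaluating $C'$ at the lagged temperature then skips the latent
  heat and makes results strongly time-step dependent (~20 % change in
  ablated volume when halving $\Delta t$). Each step therefore runs up to 4
  Picard iterations whose later iterates replace the point capacity with
  the enthalpy secant $(H(T^{*}) - H(T^n)) / (T^{*} - T^n)$, $H$ being the
  exact integral of the piecewise-linear capacity. The latent heat is then
  paid exactly however far a cell moves in one step, and halving $\Delta t$
  changes the final ablated volume by ~0.1 %. Iterations stop early once
  the iterate moves less than 1 mK.
* **No temperature clamp.** Above water depletion the property curves are
  extrapolations — the model has no charring chemistry — and the solver
  says so with a once-per-run warning when any cell exceeds 150 °C. It does
  not clamp temperatures there: a hard clamp discards enthalpy in a
  time-step-dependent way and distorts the fluxes that drive the ablation
  front, and pinning the core at 150 °C suppresses ablation volumes well
  below the ex vivo range. Charring tissue at a fiber tip genuinely reaches
  such temperatures; the reported peak should be read as "beyond validity",
  while the 60 °C front that defines the ablation zone remains in the
  trusted range. An optional `cap_temperature` clamp exists purely as a
  numerical guard, with its discarded enthalpy tracked in the ledger.
* **Energy ledger.** Every step records deposited, metabolic, stored,
  boundary and perfusion energy computed from the same discrete operators
  as the solve, so the budget closes to round-off on every run; the closure
  is re-checked (≤ 2 %) as an acceptance property.

### Mesh-independence check

`mesh_convergence_check()` re-examines the classic refinement sweep for the
laser source, Δx ∈ {0.12, 0.08, 0.04, 0.02} mm. One subtlety: the source
builder stores exact cell averages, and a cell average differs from the
on-axis point value by $O(\Delta^2/\sigma^2)$ — with $\sigma = 50$ µm that
representation gap alone is ~4 % between 0.04 and 0.02 mm, regardless of
any solver property. Comparing a point-valued profile across grids
therefore first deconvolves cell averages to point values with the standard
fourth-order finite-volume correction
$u_i \approx \bar u_i - (\bar u_{i+1} - 2\bar u_i + \bar u_{i-1})/24$
(applied along both transverse axes and the beam axis). The successive
max-relative profile changes are then 18 %, 8.6 % and 0.9 %: the profile is
converged (< 2 %) at Δx = 0.04 mm — about one tenth of the fiber diameter —
while 0.12 → 0.08 mm clearly is not.

```{r}
mesh_convergence_check(c(0.12, 0.08, 0.04, 0.02))
```

## Synthetic phantoms

No patient imaging ships with the package; `build_voxel_phantom()`
rasterizes a parametric stand-in: an ellipsoidal tumor in a pancreas
ellipsoid, a safety-margin shell obtained by true Euclidean dilation of the
voxelized tumor (default 5 mm, the clinical margin), cylindrical vessels
with per-vessel film coefficients (aorta 511, superior mesenteric artery
1000, portal/splenic/renal veins 750 W/(m²·K)), a 1 mm soft-tissue sheath
around each vessel (the layer between pancreas and vessels is described
only qualitatively in the source model, so its thickness is configurable),
an optional duodenum slab, and an embedding background cube whose outer
surface holds the 37 °C Dirichlet condition. Vessel interiors are excluded
from conduction — blood flow is modeled purely as the surface convective
flux $h\,(T_b - T)$. Probes default to ±15 mm laterally from the fiber,
matching the sensor layout used to argue safety at distance.

What the phantoms deliberately do not emulate: real segmented organ shapes,
heterogeneous perfusion fields, peristalsis or flow-dependent $h$, and
respiratory motion. Passing tests therefore demonstrate the correctness of
the model implementation and the internal consistency of the dosimetry
logic on idealized anatomies — not patient-level predictive accuracy, which
would require the imaging-derived geometries that are out of scope here.

## Dose optimization

`dose_grid_search()` sweeps powers (default 2–10 W by 1 W) against exposure
times (default 50–600 s by 50 s — exposures in the motivating study end
near 600 s and the selected optima land on 550 s). Because $\Omega$ is
monotone in time, one time-marching run per power fills the whole duration
axis: ablated percentage of the tumor-plus-margin union and the running
organ-at-risk maximum temperature are read out as the march passes each
duration. `select_optimal_dose()` keeps combinations with ablated fraction
≥ 55 % and organ-at-risk maximum ≤ 42 °C and returns the minimum-power one,
breaking power ties by minimum duration (minimum energy $E = P\,t$); an
empty selection is a valid outcome reported as such. The 55 % default
reflects the margin-to-tumor volume ratios of the motivating cases, where
55 % of the union covers the tumor itself; higher requirements push the
selection toward higher powers and more collateral risk, so the threshold
is exposed as a parameter. The organ at risk defaults to the labeled organ
nearest the fiber tip (a vessel wall or the duodenum) and can be designated
explicitly.

## Problem sizes and determinism

The package's own test and acceptance runs use desk-scale grids chosen to
keep every oracle comparison honest: axisymmetric grids of roughly 30–100 ×
50–100 cells with 0.1–0.3 mm fine spacing for the solver benchmarks, and
24³-voxel phantoms at 1.25–1.5 mm spacing for the 3D dose-grid logic.
Finer grids sharpen the same comparisons without changing any conclusion,
and the mesh-independence machinery quantifies exactly what refinement
buys. There is no randomness anywhere in the model: rebuilding a phantom or
rerunning a simulation from the same configuration is bit-reproducible.

## Known limitations

* Property curves above ~115 °C are extrapolations; peak temperatures at
  the fiber should not be interpreted quantitatively.
* The perfusion polynomials derive from animal hyperthermia experiments
  with 30–40 min exposures; their transfer to ~10 min LITT exposures is an
  assumption inherited from the underlying model.
* Single fiber, continuous wave only: no pull-back protocols, no pulsed
  duty cycles, no multi-fiber arrays.
* No Arrhenius damage kinetics — the dwell-time threshold model is
  deliberately simple and its $t_n$ is a tunable, not a tissue constant.
* No photon transport beyond the Beer–Lambert/effective-attenuation form:
  scattering-dominated fluence redistribution near the tip is absorbed into
  $\alpha_{eff}$.
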