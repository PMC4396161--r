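---
title: "An electrodiffusion–reaction model of the cardiac action potential"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An electrodiffusion–reaction model of the cardiac action potential}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`npcable` simulates the electrical activity of a single cardiac cell as a
fully continuous reaction–electrodiffusion system. This vignette is the
package's account of the science: the model and its assumptions, the unit
regime, the discretisation and time-marching algorithm, the parameters
that matter, what the verification machinery does and does not show, and
the design decisions taken where the problem statement was genuinely
open.

## The model

The cell is the ellipse Ω = {x²/a² + y²/b² ≤ 1} with a = 2, b = 1,
centred at the stimulation site (0, 0). Six ionic species — the reactants
of a suicide-substrate network, see below — carry concentrations
C₁…C₆ (μM) governed by Nernst–Planck transport with mass-action reaction:

$$\partial_t C_i = \nabla\cdot\big(d_i \nabla C_i + m_i C_i \nabla\varphi\big) + F_i(C),
\qquad (d_i\nabla C_i + m_i C_i\nabla\varphi)\cdot n = 0 \ \text{on}\ \partial\Omega,$$

where the mobility follows the Einstein relation
$m_i = d_i z_i F_a/(R\,T_e)$, signed by the valence $z_i$. The closed-cell
(no-flux) boundary condition makes each species' total amount change only
through reaction.

The membrane is an RC circuit distributed over the cell: resistivity ρ and
capacitance per area C_m give a cable equation for the potential with an
effective diffusion coefficient $D = 1/(\rho S C_m)$ (S the
surface-to-volume ratio). The ionic current is carried by all species, so
its density is the valence-weighted net production rate, and the external
stimulus is a point current at the centre:

$$\partial_t \varphi = D\,\Delta\varphi - \frac{F_a}{C_m}\sum_i z_i F_i(C)
 + \frac{1}{C_m} I_{stim}(t)\, f(x), \qquad \varphi = \varphi_{rest}\ \text{on}\ \partial\Omega,$$

with the Dirac mollified as $f = \exp(-1000\,(x^2+y^2))$. An optional
linear leak $-g_{leak}(\varphi - \varphi_{rest})/C_m$ (default
`g_leak = 0`, i.e. off) is available for sensitivity studies. The exact
functional form of the ionic-current density is a reconstruction from the
stated ingredients (valences, production rates, capacitance); it is the
simplest form in which every species contributes its charge production,
and it is switchable in principle but not silently altered.

### Units: one consistent model regime

The published parameter set mixes conventions: rate constants in s⁻¹,
times in seconds, D quoted in cm²/ms, species diffusivities quoted in
m²/s against a domain of semi-axes 2 and 1, and no numeric values at all
for $F_a$, $R$ or $T_e$. The package resolves this with one decision,
applied everywhere: **the solver works in a single consistent model-unit
system whose time unit is the second**, taking every printed number at
face value. Concretely:

* `cable_diffusion(162, 0.2, 2.0)` performs the one genuine unit
  conversion in the package (μm⁻¹ → cm⁻¹, μF → F) and returns
  0.00154 cm²/ms; the PDE uses the identical physical quantity expressed
  per second, `cable_diffusion(..., unit = "cm2_per_s")` = 1.5432. This is
  forced by consistency: with `dt = 1e-5` s and rates in s⁻¹ the cm²/ms
  number would freeze the potential field (nothing would repolarise within
  T = 0.006 s, leaving a sustained plateau, contrary to the triangular AP
  the model is meant to produce).
* The species diffusivities `d = (1e-3, 2e-3, 5e-3, 1e-3, 2e-3, 4e-6)`
  are physically enormous if read as m²/s; they are taken as model-unit
  numbers. Over T = 6 ms they transport almost nothing, so concentrations
  are dominated by reaction plus local drift — which is the regime the
  model explores.
* The electromigration factor $F_a/(R T_e)$ is never pinned down
  numerically; it defaults to **1** in model units (`Fa = R = Te = 1` in
  `physical_constants()`), and is configurable for users who want the SI
  value. The ionic-current coefficient $F_a/C_m$ then defaults to 1/2.

### Suicide-substrate kinetics

The reaction network is mechanism-based enzyme inhibition: substrate S
binds enzyme E reversibly (k₁, k₋₁) to X, which commits (k₂) to an
intermediate Y that either turns over productively to E + P (k₃) or
inactivates the enzyme to E_i (k₄). Mass action gives, with
e, s, x, y, p, e_i the concentrations,

$$F_E = -k_1 e s + k_{-1} x + k_3 y,\quad F_S = -k_1 e s + k_{-1} x,\quad
F_X = k_1 e s - (k_{-1}+k_2)x,$$
$$F_Y = k_2 x - (k_3+k_4)y,\quad F_P = k_3 y,\quad F_{E_i} = k_4 y.$$

Two moieties are conserved identically: the enzyme moiety
$e + x + y + e_i$ and the substrate moiety $s + x + y + p + e_i$. The
second deserves a remark: the inactivated complex E_i contains the
substrate-derived inhibitor, so it belongs to *both* moieties; the naive
sum $s + x + y + p$ is **not** conserved (its rate is $-k_4 y$). The test
suite asserts the correct pair, algebraically and along trajectories.

The dimensionless numbers are the partition ratio $r = k_3/k_4$ and
$\mu = e_0/s_0$. The Tatsunami factor $(1+r)\mu$ classifies the long-time
outcome: substrate exhausted above 1, enzyme fully inactivated below 1,
both exactly at 1 (the Waley factor $r\mu$ is reported alongside). With
the standard constants (k = 2, 4, 12, 10, 2 s⁻¹; e₀ = s₀ = 0.5 μM) the
factor is 6, and the well-mixed integrator confirms exhaustion with
surviving active enzyme. Since no numeric criterion for "exhausted" /
"inactivated" comes with the classification, the package operationalises
them at the horizon $T_\infty = 50/k_4$ as $s < 10^{-3} s_0$ and
$e + x + y < 10^{-3} e_0$ respectively.

A curiosity of the printed valences z = (1, −1, 1, 1, 1, −1): the binding
step E + S → X does not conserve charge (+1 − 1 → +1). The package
implements the table exactly as given and does not correct it; the drift
term is unaffected by the inconsistency, only its physical
interpretation is.

## Discretisation

Space: P1 Lagrange triangles. The element integrals are exact closed
forms — mass $(A/12)(\mathbf{1}+I)$, stiffness from the constant basis
gradients, and the drift form
$A(\varphi)_{ij} = m\,\int \psi_j\, \nabla\varphi_h\cdot\nabla\psi_i$
which is exact because $\nabla\varphi_h$ is element-wise constant. The
integration-by-parts direction for the drift is chosen so that the
no-flux species boundary condition generates *no* boundary integral;
consequently the drift operator has zero column sums and the transport
step conserves discrete mass to solver roundoff (the tests bound the
per-step moiety drift by 10⁻¹⁰; in practice it sits at ~10⁻¹⁴ over a full
run). The mass matrix is kept consistent; row-sum lumping is available as
an option (`assemble_mass(lumped = TRUE)`) for stability experiments.

The Gaussian stimulus is far sharper than the mesh
(σ = 1/√2000 ≈ 0.022), so its load vector is integrated with a 7-point
Gauss rule on an adaptive quartering of each element near the centre,
stopping when sub-elements resolve σ/2; the assembled total matches the
closed-form $\pi/\text{sharpness}$ to well under 1 %.

Meshing is deterministic by design (reproducible tests, bit-identical
reruns): ring j of a concentric-ring triangulation of the unit disc
carries 6j nodes, adjacent rings are zipped sector-wise into 6·nr²
triangles, and the disc is mapped affinely onto the ellipse. The ring
count is increased until the achieved mesh size h (maximal element
diameter) is at most 1.5× the target; the achieved h is recorded in every
report, since targets like h = 0.15 are not exactly realisable. Boundary
nodes land exactly on the ellipse. Gmsh MSH v2.2 ASCII import/export is
provided for external meshes; uniform red refinement
(`refine_mesh()`) halves h exactly.

## Time marching

One step of the IMEX algorithm, from state $(\varphi^n, C^n)$:

1. **Potential, explicit RK2 (Heun).**
   $\varphi^* = \varphi^n + \delta t\,\Phi(\varphi^n, C^n)$,
   $\varphi^{n+1} = \varphi^n + \tfrac{\delta t}{2}(\Phi(\varphi^n, C^n) + \Phi(\varphi^*, C^n))$,
   with the Dirichlet value re-imposed after each stage and Φ the
   consistent-mass Galerkin right-hand side. "Second-order Runge–Kutta"
   admits several two-stage variants; Heun's is used as the most common
   one. A warning fires when δt exceeds the explicit diffusion bound
   $h_{min}^2/(2D)$ (at the default δt = 10⁻⁵ s the margin is two orders
   of magnitude).
2. **Transport, implicit with Picard.** For each species,
   $(M + \delta t K_i + \delta t A_i(\varphi^{n+1}))\,C_i^{(k+1)} = M C_i^n + \delta t\, M F_i(C^{(k)})$,
   the reaction lagged and iterated over k until the maximal relative
   update over species falls below `picard_tol` (default 10⁻¹⁰, cap 50
   iterations — the defaults converge in 3–6 iterations because
   $\delta t \cdot \text{Lipschitz}(F) \sim 10^{-4}$). The six sparse
   systems are LU-factorised once per step (the matrix is fixed within
   the step) and reused across Picard iterations. A Newton variant via
   the analytic `reaction_jacobian()` is available to callers but the
   lagged iteration is the default, matching the initialise-then-iterate
   structure of the algorithm. The φ↔C coupling is *not* re-iterated
   within a step: the potential uses $C^n$, the transport uses
   $\varphi^{n+1}$, once.

Negative nodal concentrations (possible at 10⁻¹⁴ level from roundoff) are
clipped to zero *only* at reaction-rate evaluations; `reaction_rates()`
itself refuses negative input, making the clipping policy explicit and
local.

The initial state is φ = φ₀ = −80 mV in the interior (φ_rest = 0 on the
boundary, a deliberately discontinuous projection) and spatially uniform
concentrations. Before the stimulus onset the centre of the cell is
screened from the boundary layer — √(4DT) ≈ 0.19 against a half-width of
1 — so the probe stays at φ₀ to within ~10⁻³ mV for the whole run, which
is the operational meaning of "at rest" here.

## Verification

**Manufactured solutions** (`mms_convergence_study()`). On the
pure-diffusion subproblem the smooth field
$u = e^{-t/2}\cos(0.9x)\cos(0.7y)$ is made exact by injecting its residual
as a source, with the exact trace as Dirichlet data. Time stepping is
backward Euler with $\delta t \propto h^2$, so the O(δt) time error scales
with the expected O(h²) spatial error and the log–log slope isolates the
spatial order. Over the levels h ∈ {0.2, 0.15, 0.1} the fitted order is
2.0 within a few per cent — the checkable core of the scheme's
second-order spatial accuracy. The error norm is the mass-weighted
nodal L2 norm at final time, $\sqrt{e^\top M e}$ (the maximum over steps
is reported alongside). Historically reported absolute errors for this
scheme (19·10⁻⁵ at h = 0.2 down to 95·10⁻⁶ at h = 0.1) were produced with
an unspecified norm and time-step rule and are **not** reproduced here;
note that that pair implies a two-point order of exactly 1.0, in tension
with the second-order claim — the package records the discrepancy and
asserts only its own, fully specified study.

**Stability** (`stability_study()`). The full scenario is run on one
fixed mesh at δt ∈ {10⁻⁵, 5·10⁻⁶, 2.5·10⁻⁶} s and the final-time fields
compared in max norm. Differences are at the 10⁻⁵ mV / 10⁻⁴ μM level —
"quasi the same" — and shrink as δt decreases (the concentration
differences halve, reflecting the first-order transport step; the
potential differences shrink more slowly because they inherit the
concentration coupling).

**Electrophysiology** (`validate_electrophysiology()`). Three classical
single-cell criteria, each needing an operational definition the problem
statement does not supply:

* *Excitability*: the no-stimulus run must stay at rest — centre-probe
  drift below 0.5 mV over the full run (measured: ~1.5·10⁻³ mV).
* *All-or-none*: an AP is declared when the probe deviation from the
  no-stimulus baseline reaches half the peak deviation of the full
  −200 μA/cm² run; the threshold amplitude is bisected between 0 and
  −200 (7 iterations), and half that threshold must elicit no AP. In
  this model the sub-threshold response scales essentially linearly with
  amplitude, so the half-peak criterion is what gives the all-or-none
  dichotomy its discrete character; the measured threshold is ≈ −100
  μA/cm².
* *Morphology*: the AP must be triangular, i.e. no sustained plateau:
  the fraction of the AP duration (time above half peak) spent within
  5 % of the peak must be below 0.2 (measured: ≈ 0.11), and the
  deviation at T must have decayed below half its peak (repolarisation).

The AP itself is small (≈ −0.027 mV at the centre probe) because the
stimulus charge is spread over the Gaussian footprint and the default
electromigration scale is the model-unit 1; the validation criteria are
deliberately formulated scale-free (relative to the supra-threshold run)
so they test the dynamics, not an amplitude convention.

**Oracle equivalences.** Element matrices are checked against an
independent quadrature assembler to 10⁻¹²; spatially uniform PDE runs
against the hand-written RK4 well-mixed integrator (itself cross-checked
against `deSolve`) to 10⁻⁴ relative; the Poisson problem on the unit disc
against the radial closed form u(0) = 1/4.

## Problem sizes and defaults

The standard configuration — ellipse (2, 1) at h = 0.15 (≈ 820 nodes),
δt = 10⁻⁵ s, T = 0.006 s (600 steps) — *is* the study condition; the
verification studies use it unchanged (the stability study trebles the
step count, the validation runs it about ten times for the bisection).
Unit tests use coarser meshes (h = 0.35–0.6) and shorter horizons chosen
once as the smallest problems that still exhibit each property being
tested; none of the physical parameters differ from the defaults
anywhere in the suite.

## Known limitations

* The ionic-current density and the alternating-stimulus waveform are
  reconstructions (simplest forms consistent with the stated
  properties); both are isolated behind `potential_rhs()` and
  `stim_amplitude()`.
* The transport step is first-order in time; the headline second-order
  claim concerns space. No operator-splitting error analysis is
  attempted.
* No SUPG/upwind stabilisation: at the default mobilities the drift is
  far from dominant, but large `Fa/(R*Te)` values would need it.
* Straight-edged (non-isoparametric) boundary triangles: the O(h²)
  geometric error is part of what the MMS study measures.
* Anisotropic resistivity, 3D domains, cell-volume changes and detailed
  channel pharmacology are out of scope.
* The printed valence table breaks charge conservation in the binding
  step; it is implemented verbatim, not corrected.
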