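---
title: "Methods: orthotropic second-gradient bone remodeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: orthotropic second-gradient bone remodeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(osteoadapt)
```

## The model and its assumptions

`osteoadapt` simulates functional adaptation of trabecular bone as the
coupled evolution of three descriptor families on a 2D continuum:

1. **Displacement** `u(x, t)` in quasi-static equilibrium under slowly
   varying loads.  Inertia is neglected on the grounds of time-scale
   separation: remodeling takes days to months, loading transients minutes.
   Strains are measured by the linearized tensor `E = sym(∇u)`.
2. **Material symmetry orientation** `ψ(x, t)`: the angle of the
   orthotropy axis `A1`, macroscopically representing the dominant
   trabecular direction.  `ψ` matters only modulo π (the axes enter the
   energy quadratically).
3. **Evolving stiffnesses** `μ, β1, β2` (shear modulus and the two fiber
   stretch stiffnesses) and their **stimulus fields** `S_μ, S_β1, S_β2`.
   All other moduli are constitutively frozen.

The stored energy is orthotropic and quadratic, plus a second-gradient
(strain-gradient) part penalizing fiber stretch gradients and fiber
bending.  The second-gradient terms model the high property contrast of a
rarefied strut lattice; they require a C¹ discretization and admit
double-force boundary actions (supported in the interface, zero in both
stock scenarios).  Small-strain linearization is used throughout,
including in the stretch-gradient/bending measures: the finite-deformation
decomposition (fiber stretch `λ_i`, geodesic curvature `η_i`) is taken at
leading order (`λ_i → 1`, directions frozen at `A_i`), which is the
consistent order for a quadratic energy.  The normal convention is
`N1 = A2`, `N2 = −A1`; the energy is insensitive to these signs, they are
fixed only so reported bending measures are reproducible.

### Evolution laws

The orientation obeys a gradient flow: stationarity of the virtual-work
balance under misalignment variations gives

    c_γ γ̇ + τ_γ γ − ∂w_m/∂ψ = 0,    γ = ϑ − ψ,

with ϑ the polar-decomposition rotation of `F = I + ∇u`.  The source
formulation never writes this strong form; adopting it is this package's
central modeling commitment, and two observations support it: the printed
restoring coefficient (`τ_γ = 1e-3` Pa against GPa moduli) is only
meaningful if the energy torque dominates, and only the torque term can
produce the eigen-alignment the experiments show.  Within a staggered step
ϑ is frozen, so `ψ̇ = −γ̇`.

Each evolving modulus relaxes toward homeostasis,
`c_p ṗ = τ_p (S_p − S_p⁰) − χ U_p`, with `χ = 0` by default: the literal
variational reading would inject the energy share `U_p` directly (`χ = 1`,
available for study), but the pure stimulus-driven form is what the model
family this work extends uses, and it is the only choice for which
`S = S⁰` is exactly a fixed point.  Moduli are floored at 1% of their
initial value (configurable) so ellipticity survives sustained resorption;
the source model never bounds them.

Stimuli obey `d ∂S/∂t = ∇·(κ∇S) + U_p − R S` with no-flux boundaries,
zero initial condition, and unit proportionality between source and energy
share.  Diffusion makes the stimulus nonlocal: signal generated in loaded
regions reaches unloaded ones, the standard rationale for
diffusion-based mechanotransduction.  The printed coefficient tables are
adopted verbatim even though the balance is dimensionally heterogeneous as
printed (see "Known limitations").

## Discretization and numerical choices

* **Space**: tensor-product B-splines of degree 2 (C¹) on the structured
  rectangle, open knot vectors, 3×3 Gauss quadrature per element.  Both
  experiment domains are rectangles, so no unstructured machinery is
  carried.  Dirichlet/symmetry conditions are imposed by coefficient
  elimination (exact for whole edges with open knots).  Free edges carry
  the natural (traction-free, double-force-free) conditions.
* **Equilibrium**: sparse symmetric assembly as `Bᵀ C B` triple products;
  direct Cholesky solve.  Heterogeneous `ψ, μ, β1, β2` live at quadrature
  points.
* **Contact**: frictionless penalty against rigid circular pins, force
  `k_pen · g` along the outward pin normal on penetrating boundary
  quadrature points, Newton iteration on the active set with a step cap of
  `0.1 min(Lx, Ly)` and tiny grounding springs (`1e-8` of the mean
  stiffness diagonal) that regularize the rigid mode before the support
  engages.  Pin radius (5 mm) and penalty (1e3 × the largest modulus per
  meter) are unreported upstream; both are configurable and recorded in
  the run manifest.
* **Stimulus**: backward Euler (unconditionally stable) with the same step
  as the remodeling loop; mass and diffusion matrices on the same spline
  basis; the factorization is reused across steps.
* **Orientation integrator**: the flow is integrated inside each staggered
  step at frozen strain with per-point sub-stepping, each sub-update
  damped L-stably (`Δψ = Δt·rate / (1 + Δt·k)`, `k` the local stiffness of
  the flow) and capped at 0.1 rad.  Rationale: under the three-point load
  the local relaxation time `c_γ / (∂²w/∂ψ²)` is O(1 s) against a staggered
  step of 604.8 s; halving the *outer* step (an equilibrium solve per
  halving) would need thousands of solves, while the sub-stepped flow
  reaches the same torque-free state at the cost of a few vector
  operations.  Non-stiff points reduce to explicit Euler.
* **Moduli**: explicit Euler (their drift per step is minuscule by
  construction), clamped at the floor.
* **Units**: moduli in Pa (tables print GPa; converted at construction);
  2D energies are per unit area under an implicit unit-thickness
  convention, so edge tractions in N/m compose dimensionally.  Specimen
  thickness is never stated upstream.

## Scenarios as stated worlds

The **cantilever** uses the printed world exactly: 75×25 mm, left edge
clamped, right edge under uniform shear traction ramped smoothly
(`τ(t) = τ0 [t/T_s − sin(2π t/T_s)/(2π)]`, `τ0 = 1.25e5 N/m`,
`T_s = 60480 s`), initial `ψ = 0`.

The **three-point flexure** span is printed as `11/6 L = 137.5 mm`, which
exceeds the 75 mm domain; the only consistent reading is that the 75×25 mm
rectangle is the *half* domain of a 150×25 mm specimen.  We therefore put
the symmetry plane (`u1 = 0`) on the left edge, the support pin tangent
under the lower face at 68.75 mm, and the loading pin tangent above the
midline, descending by the same ramp to `u0 = 2 mm`.  Pins start exactly
tangent so contact engages at `t = 0⁺`.  Displacement control is realized
through the moving pin barrier, not a Dirichlet condition.

**Horizons and the `scaled` profile.**  The sources report no simulated
horizon.  The default horizon is 10 ramp durations (604 800 s, one week);
with the printed `c_γ`, orientation relaxation times range from ~1e4 s in
strongly loaded regions to months where strains are small, so a desk-scale
run divides `c_γ` and `c_p` by the `scaled` factor.  The acceptance runs
use `scaled = 100`, which makes the orientation flow quasi-instantaneous
relative to the staggered step (the physically expected limit: trabecular
reorientation is slow against loading but fast against the stiffness
drift) while leaving every fixed point, sign and alignment target
untouched — scaling viscosities cannot move a gradient flow's minima.

## What a green test does and does not establish

The synthetic fixtures (`random_strain_states()`, affine/quadratic
manufactured fields, manufactured uniform sources) exercise exact
properties: invariant identities, derivative consistency against finite
differences, patch tests, scalar ODE closed forms.  Green here means the
implementation computes the stated model correctly — it says nothing about
whether the model describes real bone.

The scenario-level tests assert the model's qualitative predictions at
coarse resolution (30×10 elements): ≥90% (cantilever) and ≥85%
(three-point) of the unmasked area aligned within 10° of the principal
strain directions modulo π/2.  Two caveats:

* The ~10% residually misaligned band is *structural*: in near-pure-shear
  states (neutral axis) the energy minimizer over ψ sits 45° off the
  eigenframe whenever `(β1 + β2)/2 − β3 > 0` and the mean strain is small
  — with the default calibration that combination is +0.08 GPa.
  Eigen-alignment is exact only where `|tr E|` is not small against the
  eigenvalue gap.  The diagnostic masks points whose eigenvalue gap is
  below 1% of the field maximum; the alignment tolerance (10°) and mask
  threshold are configurable and reported.
* Real trabecular bone is heterogeneous, porous and 3D; the simulated
  specimen is homogeneous 2D tissue with literature moduli.

## Known limitations

* **Stimulus units / criterion 7b.**  The printed reaction–diffusion
  balance is dimensionally heterogeneous, and the homeostatic references
  `S⁰` equal the energy *shares* at 1000 microstrain (3660 / 1484.8 /
  734.29 Pa) rather than share/absorption ratios.  Implemented verbatim,
  the steady-state stimulus under the cantilever load is `U/R ≈ 1 Pa`,
  far below `S⁰`, so every evolving modulus resorbs (with the correct
  spatial *pattern* — least at the clamped outer fibers, most at the
  neutral axis) and the "β1 increases near the clamp" expectation cannot
  be met under the printed tables at the printed load.  The acceptance
  test asserts it anyway and is intentionally red.  Under the three-point
  test (strains ~1e-2) stimuli do exceed `S⁰` at the outer fibers and
  growth occurs.
* The reciprocal coupling of orientation variations into the momentum
  balance is omitted (staggered scheme), justified by the model's own
  time-scale separation.
* 3D, inertial dynamics, poroelasticity, damage and cell-population
  dynamics are out of scope.
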