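---
title: "A two-field growth model of cortical folding: methods and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-field growth model of cortical folding: methods and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortigrow)
```

This vignette is the package's own account of the model it implements,
the numerical choices behind the solver, and what the test suite does
and does not establish.

## The physical picture

Between gestational weeks 11 and 36 the human cortex folds. In the
mechanical picture implemented here, folding is a buckling instability:
neurons produced in two germinal zones — the ventricular zone (VZ) at
the ventricular surface and the outer subventricular zone (OSVZ) above
it — migrate radially along glial fibers into the cortical plate, where
their accumulation drives strong tangential growth of a thin, stiff
layer bonded to a softer, more slowly growing foundation. Past a
critical compression the surface wrinkles; under continued growth every
second sulcus deepens while its neighbors grow shallow (period
doubling). The OSVZ is the distinctive ingredient: a second
proliferative band whose outer boundary moves outward over time as its
progenitors translocate radially before division (mitotic somal
translocation, MST), so its cell output grows with its area.

## Governing equations

**Kinematics and mechanics.** With deformation gradient `F` and
multiplicative split `F = Fe·Fg`, only the elastic part stresses the
tissue. The growth tensor is transversely isotropic about the reference
fiber direction `N` (radial):

* `Fg = θ⊥ (I − N⊗N) + θ∥ N⊗N`, with `θ• = (1 + κ•(ri) c)^α`.
* `κ⊥ = κs + κs(βκ − 1) H(ri − r_cp; 20)` and
  `κ∥ = κs + κs(1/βκ − 1) H(ri − r_cp; 20)`: isotropic growth deep in
  the subcortex, tangentially amplified (and radially reduced) in the
  cortex.

`H(x; γ) = e^{γx}/(1 + e^{γx})` is the logistic step used everywhere a
smooth transition is needed. Stress is compressible neo-Hookean,
`ψ = λ/2 ln²Je + μ/2 (Fe:Fe − 3 − 2 ln Je)` (plane strain: the 2×2
`Fe` is embedded with unit out-of-plane stretch), giving
`σ = (1/Je)[λ ln Je I + μ(Fe Feᵀ − I)]`. The shear modulus blends from
the subcortical `μs = μ∞/βμ` to the cortical `μc` across `r_cp`; in the
*varying* mode `μc` ramps linearly with the local density between
`c_min` and `c_max`, in the *constant* mode it is `μ∞` throughout.

**Cell density.** The spatial balance
`(J̇/J)c + ċ = −∇·[v̂c − d∇c] + r1 + r2` carries:

* migration `v̂ = H(c − c0; γc) · v(ri) · n/‖n‖` along the *deformed*
  fiber `n = F·N` — cells only move once the local density passes the
  threshold `c0`, and the speed profile `v(ri)` shuts off at the
  cortex;
* cortical diffusion `d(ri) = d_cc H(ri − r_cp; 10)` standing in for
  connectivity-driven spreading;
* sources `r1 = G_vz^s(s)·[1 − H(ri − r_vz; 50)]` and
  `r2 = G_osvz^s(s)·[H(ri − r_isvz; 50) − H(ri − r_osvz(t); 50)]`, with
  `r_osvz(t) = min(r_isvz + m_mst·t, r_cp)` and the stretch feedback
  `G^s(s) = G − (s−1)G` for `s < 1.8`, saturating at `0.2 G`, where `s`
  is the maximum principal stretch of `F` over the domain.

## Defaults and units

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| R, r | 2, 0.4 | mm | outer/inner radius of the quarter annulus |
| r_vz, r_isvz, r_cp | 0.5, 0.8, 1.8 | mm | material zone boundaries |
| m_mst | 0.02 | mm/day | OSVZ boundary speed (MST) |
| μ∞, ν | 2.07, 0.38 | kPa, – | cortical modulus, Poisson ratio |
| βμ | 3 (varying) / 8 (constant) | – | stiffness ratio μ∞/μs |
| c_min, c_max | 200, 700 | mm⁻² | stiffness-ramp thresholds |
| κs, α, βκ | 4.07e−4, 1.65, 3 | mm², –, – | growth law |
| G_vz, G_osvz | 120, 20 | mm⁻²day⁻¹ | initial division rates |
| v, c0, γc | 5, 500, 0.008 | mm/day, mm⁻², mm² | migration law |
| d_cc | 0.11 | mm²/day | cortical diffusivity |

Notes on two readings that were genuinely open:

* **Diffusivity units.** We use mm²/day for `d_cc`, the only
  dimensionally consistent unit for a diffusivity of an areal density.
* **βκ.** Two candidate values (1.5 and 3) exist for the growth ratio;
  we default to 3, which gives pronounced tangential cortical growth,
  and expose it in the configuration.
* **λ.** Only ν is specified; we compute `λ = 2μν/(1 − 2ν)` from the
  *local* μ, holding ν fixed so compressibility is uniform.
* **Irreversibility.** The algebraic law `θ(c)` would shrink if the
  density dropped (e.g. by dilution); growth is treated as a ratchet
  (`updateGrowthState`), the componentwise maximum over history, with a
  switch to disable it.
* **Stretch measure.** The feedback stretch `s` is taken from the total
  `F` (a purely kinematic quantity), lagged one step.
* **r_osvz cap.** The OSVZ boundary is capped at `r_cp` (it reaches it
  at t = 50 days with defaults); an uncapped band would invade the
  cortex, which has no biological reading.
* **Boundary/initial conditions for c.** Zero flux on all boundaries
  (no cell exchange with the exterior) and `c(x, 0) = 0` (density is
  built up by the sources from week 11 on).

## Discretization and coupling

Bilinear quadrilaterals with 2×2 Gauss quadrature on a structured
quarter-annulus mesh; the radial spacing is graded so the cortical band
holds at least four element layers. Mechanics is assembled in total
Lagrangian form with the exact consistent tangent (verified against
finite differences to 1e−4 and in practice agreeing to ~1e−10); the
linearized systems are solved with sparse LU (Matrix). Dirichlet
conditions pin the inner (ventricular) boundary; the two straight edges
carry symmetry conditions (zero normal displacement); the outer surface
is traction-free.

Transport uses implicit Euler on the deformed configuration *frozen at
the previous mechanics solve*. The nonlinear migration gate and the
stretch feedback are lagged one step (Picard linearization), so each
step costs one sparse linear solve; the self-convergence test confirms
the expected first-order accuracy in Δt. Two stabilizations act on the
advective term:

* a conservative streamline-upwind (SU) diffusion
  `τ (v̂·∇w)(v̂·∇c)` with `τ = h/(2‖v̂‖ + 4d/h)`, whose row sums vanish
  so it cannot create or destroy cells; and
* the residual-based artificial viscosity
  `ν_c = C_art · h · |R_e| / (‖∇c‖ + ε)`, capped at `d_cc`, where
  `R_e` is the element-mean strong residual of the previous step. It
  vanishes where the discrete balance holds; on smooth resolved
  solutions it decays essentially linearly in h (the refinement test
  measures a factor ≈3 per 4× refinement). At interior extrema of `c`
  the gradient normalization saturates the cap, but the associated
  stabilizing *flux* `ν_c ∇c` still vanishes there, so consistency is
  unaffected.

The dilution term `(J̇/J)c` is realized by conservation: after each
mechanics solve the nodal density is rescaled by the ratio of old to
new nodal Jacobian (lumped projection), which conserves the total cell
number `∫ c J dV` exactly and reproduces the closed form `c = c0/J`
under uniform growth. Density is clipped at zero after each step and
the clipped cell number is logged.

Per time step the staggered sequence is: transport → growth update
(ratchet) → Newton mechanics → dilution; `coupling =
"staggered_iterated"` adds one fixed-point sweep. On Newton failure the
step is halved, up to `max_subdivisions` times.

**Symmetry breaking.** A perfect discrete annulus stays on the unfolded
branch well past the critical load. We therefore perturb the outer
boundary radius by eight random-phase cosine modes of amplitude 0.1% of
R (tapering to zero below `r_cp`), drawn from the run seed. This makes
the bifurcation — including the secondary period doubling — exactly
reproducible; no branch-switching machinery is used.

**Stopping.** Deep sulci eventually bring opposite walls into contact;
contact is not modeled. Each accepted step checks the outer surface
polyline for self-intersection and stops the run cleanly with a logged
event when it occurs. With the default parameters the replica runs
reach self-contact between roughly t = 29 and 40 days; the density
maximum is still rising at that point, so late-time density plateaus
are outside what these runs can show.

## Desk-scale study conditions

All simulation-backed tests and the acceptance script run one fixed
desk-scale condition, chosen once: a 20×48 mesh (960 elements),
Δt = 0.5 day, horizon 45–60 days, seed 1. At this resolution a
wrinkle wavelength of ~1.3–1.9 mm is resolved by 15–25 elements, a full
replica run takes a few seconds, and the whole suite stays within a few
minutes on one CPU. A mesh-sensitivity check (20×48 vs 30×72) bounds
the pre-instability folding-evolution difference below 5%.

## What the tests do and do not show

The oracle suite verifies the constitutive law against
finite-difference energy gradients and rotation objectivity; the
mechanics against a stress-free uniform-growth patch test, a
finite-difference tangent check, and rigid-mode elimination; the
transport against exact cell-number conservation, the 1D heat kernel,
the uniform-growth dilution law, and stabilization consistency under
refinement. The replica trends confirm, at desk scale: earlier
instability, higher density and faster folding with larger OSVZ
division rate; decreasing inter-sulcal distance (at a common
comparison time — the runs end at different self-contact times);
a constant-stiffness wrinkling wavelength within 30% of the
film-on-substrate estimate `2π t_c (μf/3μs)^{1/3}`; a faster density
rise when proliferation is shifted from the VZ into the (larger) OSVZ;
density increasing with the MST factor; and an OSVZ that ends up
thicker beneath gyri than beneath sulci.

Two desk-scale limitations are left visible as failing expectations
rather than papered over. First, with the explicit seeded imperfection,
the *placement* of the first folds follows the imperfection, not the
angular heterogeneity of the OSVZ division rate: the runs self-contact
before OSVZ-derived cells (held back by the migration threshold) build
more than ~1% angular contrast in cortical density. Removing the
imperfection does not help — the system then simply does not fold
within the window. Fold *spacing* being insensitive to the
heterogeneity pattern is confirmed. Second, reference values quoted for
the final inter-sulcal distances of the sweep are larger than the
entire outer perimeter of the 2 mm domain and thus cannot be
commensurable with this geometry at face value; the package reports its
own computed distances (≈0.7–1.0 mm) with the expected ordering, and
the peak density of the strongest-OSVZ run is bounded by the
self-contact stop (~450 mm⁻² rather than ~1100).

Finally, the synthetic fixtures (wavy and period-doubled boundaries,
Gaussian zone-density states) exercise the morphometrics against closed
forms; they emulate the geometry of folded states, not their mechanics,
so passing them says nothing about real tissue — that burden falls on
the oracle and trend suites above.
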