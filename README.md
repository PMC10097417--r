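# cortigrow

A two-field finite-element simulator of cortical folding in the
developing human brain, for computational biomechanics and
developmental-neurobiology researchers who want to study how
proliferation in the brain's germinal zones — in particular the outer
subventricular zone (OSVZ) — shapes gyrification.

## The model

The simulated domain is a 2D quarter-annulus section of the fetal
frontal lobe at gestational week 11 (inner radius r = 0.4 mm, outer
radius R = 2 mm), with material zone boundaries at the ventricular zone
(r_vz = 0.5), inner subventricular zone (r_isvz = 0.8) and cortical
plate (r_cp = 1.8 mm). Two coupled fields evolve over gestational time:

**Mechanics (finite growth).** The deformation gradient is split
multiplicatively, F = Fe·Fg, into an elastic part and an irreversible
growth part

    Fg = θ⊥ (I − N⊗N) + θ∥ N⊗N,     θ• = (1 + κ•(r_i) c)^α,

where N is the radial glial-fiber direction and c the local neuron
density: growth is isotropic in the subcortex (κ⊥ = κ∥ = κs) and
tangentially biased in the cortex (κ⊥ → κs·βκ, κ∥ → κs/βκ). Stress
follows a compressible neo-Hookean law in plane strain,
σ = (1/Je)[λ ln Je I + μ (Fe·Feᵀ − I)], with the cortical shear modulus
μc either constant or ramping linearly with cell density between c_min
and c_max ("varying stiffness"). Quasi-static equilibrium ∇·σ = 0 is
solved by Newton iteration on bilinear quadrilaterals.

**Cell density (advection–diffusion–reaction).**

    (J̇/J) c + ċ = −∇·[ v̂ c − d ∇c ] + r1 + r2,

with radial migration along the deformed fibers gated by a logistic
threshold H(c − c0; γc), diffusion acting only in the cortex, a VZ
source r1 = G_vz^s(s)·[1 − H(r_i − r_vz)], and an OSVZ source r2 active
on the band [r_isvz, r_osvz(t)] whose outer boundary grows at the
mitotic somal translocation (MST) rate, r_osvz = r_isvz + m_mst·t.
Both division rates decrease with the maximum stretch s in the domain
(down to 20% of their initial value): a mechanical feedback on
proliferation.

Cell-driven tangential cortical growth compresses the stiff outer
layer on its soft foundation until it wrinkles (primary instability,
visible as a kink in the "folding evolution" — the outer perimeter
over its initial value), and later period-doubles (every second sulcus
deepens, a pitchfork in the per-sulcus depth curves).

## Worked example

```r
library(cortigrow)

cfg <- presetConfig("varying_g120_o20",               # G_vz=120, G_osvz=20
                    mesh   = list(n_radial = 20, n_circumferential = 48),
                    solver = list(dt = 0.5, t_end = 35))
res <- runSimulation(cfg)
print(res)
#> cortigrow run: 65 steps to t = 32.5 days (GW 15.6 )
#>   folding evolution: 1.3004  max density: 446.1 mm^-2

detectInstabilityPoints(res$trace)
#> $t_primary   16.5      # sulci first exceed the imperfection depth
#> $t_secondary 27        # period doubling (pitchfork) begins
#> $t_kink      30.5      # kink of the folding-evolution curve

mean(intersulcalDistance(surfaceTrace(res$mesh, res$state$u)))
#> 0.945                  # mm, mean chord between neighboring sulci

tk <- osvzThicknessMap(res$state)
tapply(tk$thickness, tk$class, mean)
#>   gyrus  sulcus
#>   0.731   0.688          # mm: the OSVZ ends up thicker beneath gyri
```

The run stops at t = 32.5 days because deep sulci come into
self-contact, which the model does not resolve (a logged stopping
event). The folding evolution of 1.30 says the outer perimeter has
grown 30% beyond its initial value; the density maximum of 446 mm⁻²
sits in the cortex, where it drives the tangential growth that folds
the surface.

Other presets replicate the remaining experiments:
`varying_g120_o{0,10,20,30}` and `constant_g120_o{0,10,20}` (OSVZ
division-rate sweeps for both stiffness modes),
`tradeoff_{120_0,90_10,60_20,30_30}`, `mst_sweep`, `hetero_gradient`
and `hetero_random`. A command-line driver is installed under
`inst/cli/cortigrow` (`run`, `metrics`, `profile` subcommands), and
`inst/extdata/example_run.yaml` shows the YAML configuration format.

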