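---
title: "Mechanochemical simulation of contractile actomyosin networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanochemical simulation of contractile actomyosin networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

cytomech simulates small active cytoskeletal networks — actin filaments,
alpha-actinin cross-linkers and non-muscle myosin IIA (NMIIA) mini-filament
ensembles — by alternating spatially resolved stochastic chemistry with
mechanical equilibration of a coarse-grained polymer force field, and by
feeding the post-equilibration forces back into the reaction rates. This
vignette explains the models, the tunable parameters and their units, the
numerical choices, and what the desk-scale simulations this package can run
do and do not show about real actomyosin systems. Units are nm, s, pN and
pN nm throughout; kBT = 4.1 pN nm.

## Chemical model

Space is divided into cubic compartments (default side `h = 500` nm, a
scale on which the reaction-diffusion system is locally well mixed, in the
spirit of the Kuramoto-length argument: molecules diffuse across a
compartment faster than they react). Diffusing species — G-actin monomers,
alpha-actinin dimers and NMIIA mini-filaments — hop between face-adjacent
compartments as a jump process with propensity `D/h^2` per molecule per
face, the standard discretization of the reaction-diffusion master
equation. Within a compartment, reactions follow mass action: unimolecular
`a = k n`, bimolecular `a = k n1 n2 / (NA V)` with `V = h^3`.

Filaments are explicit objects overlaid on the grid: ordered minus-to-plus
chains of cylinders, each cylinder carrying an integer number of 2.7 nm
monomers. Polymerization consumes a diffusing monomer in the compartment of
the growing tip and lengthens the filament by 2.7 nm; depolymerization
reverses this. Both ends are active, with standard actin kinetics as
defaults (plus end 11.6 uM^-1 s^-1 on / 1.4 s^-1 off; minus end
1.3 uM^-1 s^-1 / 0.8 s^-1 — these literature defaults stand in for
constants the source material does not print, and are tagged in
`defaultChemistry()`). The turnover factor `chi` multiplies all four
constants, controlling how fast filaments exchange material at fixed
steady-state length.

Binding sites sit every 27 nm of filament, at midpoints of consecutive
27 nm intervals from the minus end. Sites are anchored to absolute monomer
positions, so an occupied site never relocates when the filament
(de)polymerizes at either end — occupancy is sticky to material, not to a
fractional coordinate. Cross-linker and motor binding reactions are
*dynamically registered*: after every mechanical equilibration the engine
enumerates all unoccupied site pairs on distinct filaments whose separation
lies within the species' binding window (35 ± 5 nm for alpha-actinin,
200 ± 25 nm for NMIIA mini-filaments, from the molecules' physical lengths)
and creates one binding channel per candidate pair in the compartment of
the pair midpoint, with propensity `k_on/(NA V)` times the local copy
number. Channels whose geometric precondition has vanished are removed.
Binding consumes the diffusing species and creates a bound element with
fixed fractional positions; unbinding releases the species in the
compartment of the element's midpoint. A configuration flag
(`binding_site_exclusive`) switches between dual occupancy of a site by a
linker and a motor (the default) and mutual exclusion.

Two exact stochastic engines are implemented over the same channel set: the
Gillespie direct method, and the Gibson–Bruck next-reaction method (an
indexed priority queue of putative firing times with dependency-driven
updates; channels reactivated from zero propensity redraw a fresh
exponential, which is exact by memorylessness). The next-reaction method is
the default — the network is sparse and spatially localized, so only a
handful of propensities change per event. Propensities are always
recomputed from the current state by a single function; the engines only
decide which channels to refresh, so incrementally maintained values can
never drift from a from-scratch evaluation (this is under test).

## Mechanical model

Each filament is a chain of cylinders of rest length `l0 = n_mono × 2.7` nm
(40 monomers = 108 nm by default), treated as stiff springs connecting
their endpoint beads. Growing tips are variable-length cylinders promoted
to a fresh tip when full. The energy is a sum of:

* **Stretching**: `U = 1/2 K (|l| − l0)^2` per cylinder. `K` scales as
  `1/l0` (constant extensional modulus — springs in series), so short tip
  cylinders are appropriately stiff; `k_str = 100` pN/nm refers to the
  108 nm cylinder.
* **Bending**: `eps_bend (1 − cos θ)` at each joint between consecutive
  cylinders; `eps_bend = lp kBT / l0 ≈ 380` pN nm from an actin persistence
  length of ~10 um. Joints are scaled by the actual joint length and
  skipped while a freshly promoted tip is shorter than ~13.5 nm (it has no
  meaningful direction of its own yet).
* **Excluded volume**: the inverse-quartic pair kernel `1/|r_i − r_j|^4`
  integrated analytically over both segments (arc-length measure),
  `U = K_vol ∫∫ dl_i dl_j / r^4`. The closed form reduces the inner
  integral to rational and arctangent terms and the outer integral — after
  integrating the arctangent terms by parts against `d/dt[(At+B)/(K√Δ)]` —
  to partial fractions of rational functions, giving analytic energies and,
  by differentiating the closed form with respect to the six scalar
  invariants of the pair geometry, analytic endpoint gradients (the
  derivative evaluation is code-generated with common-subexpression
  elimination and cross-validated against a dual-number evaluation of the
  same formula and against finite differences). The arc-length measure is a
  normalization choice: energy scales with the amount of interacting
  material, and the far-field limit is `K_vol L_i L_j / d^4`. The network
  force field evaluates a *softened* kernel `1/(r^2 + r0^2)^2`
  (`ev_soft = 2` nm) — the identical closed form with the constant
  invariant shifted — so contact forces stay bounded during the transiently
  deep overlaps that stochastic growth can produce between equilibrations;
  `r_soft = 0` recovers the pure kernel and is what the oracle tests
  compare against quadrature. Degenerate geometries (parallel or
  intersecting support lines, where denominators of the closed form
  vanish) are evaluated after a documented 1e-3 nm perturbation and never
  return non-finite values; a smooth `tanh` cap at 1e5 pN nm (relative
  distortion below 3e-9 at physical energies) is a last-resort bound.
  Pairs are found with an exact segment-segment distance filter at a 60 nm
  cutoff (the truncated pair force there is ~0.02 pN, far below the 1 pN
  equilibration tolerance); adjacent cylinders of one filament (which share
  a bead and are already coupled by bending) and branch partners are
  excluded.
* **Branching**: a mother-daughter junction combines a tether
  `K_br (|d| − d0)^2` between the daughter's minus bead and the mother
  anchor at fraction γ, an angular term `eps_ang (1 − cos(θ − θ0))` with
  θ0 = 70° (the Arp2/3 equilibrium branch angle), and a dihedral
  `eps_dihed (1 − cos(φ − φ0))` about the tether between the plane of the
  mother segment and tether and the plane of the tether and daughter axis.
  The dihedral uses unit plane normals, so the trivial equilibrium
  (θ = θ0, |d| = d0, φ = φ0) has exactly zero energy. Exactly planar
  configurations make the dihedral a discrete 0/π variable with no
  in-plane torque, so the `branch_junction` fixture is built generically:
  the tether points ahead of the daughter's opening path, slightly out of
  plane, which places the junction in the basin of the 70° equilibrium.
* **Motor/linker bonds**: `1/2 K (|l_m| − l0)^2` between attachment points
  at fractional positions `(1−α) x1 + α x2`; forces are distributed to the
  endpoints by the lever rule with weights (1−α, α). Fractions never change
  during a minimization. Defaults: NMIIA `K = 2.5` pN/nm, rest length
  200 nm; alpha-actinin `K = 8` pN/nm, rest length 35 nm (single-molecule
  pulling scales).
* **Boundary**: non-deformable shells (cube, sphere or capsule) repel the
  nearer endpoint of each cylinder with `eps exp(−d/λ)`; `λ = 2.7` nm makes
  an effectively hard wall, and `d` is signed so the repulsion keeps
  growing outside the shell.

Equilibration minimizes the total energy in the bead coordinates until the
largest per-bead force falls below `tol` (default 1 pN), leaving all
fractional positions and chemistry untouched. Two descent methods share a
two-evaluation quadratic line search with a backtracking fallback (energy
is non-increasing across accepted steps for either): Polak–Ribière(+)
conjugate gradients with restarts and a diagonal stiffness preconditioner,
and the default limited-memory BFGS using the same preconditioner as its
initial metric. On the very stiff spectrum of these networks (stretch
constants of 100–4000 pN/nm against bending and orientational modes a
thousand times softer) L-BFGS reaches the same tolerance in roughly five
times fewer iterations, which is what makes the desk-scale campaigns below
affordable; conjugate gradients remain available (`method = "cg"`) and are
covered by the same monotonicity and convergence tests. Production cycles
cap the iteration count (default 150) and flag non-convergence in the
trajectory diagnostics rather than failing — under sustained motor driving
the network is never exactly at equilibrium, and the next cycle continues
the relaxation.

## Mechanochemical coupling

One simulation cycle is: (1) a burst of stochastic chemistry, (2)
re-registration of the dynamic binding channels, (3) mechanical
equilibration, (4) update of the force-dependent rate multipliers. The
burst size adapts so that about 1% of the total actin changes per burst
(bounding the out-of-equilibrium drift the minimizer must relax), with an
overall cap on mechanically relevant events; snapshot times additionally
bound the burst.

After each equilibration:

* **Filament tips** feel the compressive component of the boundary plus
  excluded-volume force along the tip tangent; polymerization is slowed by
  the Brownian-ratchet factor `exp(−F δ / kBT)` with δ = 2.7 nm (one
  monomer).
* **Cross-linkers** unbind faster under tension by the slip-bond factor
  `exp(+F x_slip / kBT)` (`x_slip = 0.35` nm).
* **Motor ensembles** of 10–30 heads (drawn uniformly at binding) walk
  toward each host filament's plus end in 6 nm steps at
  `v0 (1 − F/F_stall)+` with `F_stall = n_heads × 2.5` pN, and unbind at
  `k0 exp(−F/F_char)` (`k0 = 0.2` s^-1, i.e. a 5 s unloaded attachment
  time; `F_char = 12.5` pN) — attachment strengthens under load, the
  stress-stabilized behavior of myosin II. These parametric laws are a
  deliberately simple stand-in for detailed motor-ensemble kinetics,
  isolated in one module so a more detailed model can be swapped in.

One refinement departs from a strict "rates change only at step 4" rule:
the *walk* propensity evaluates its stall factor against the instantaneous
bond strain (current fractional positions on the between-burst geometry).
With the stall factor frozen across a burst, an ensemble can overshoot its
stall force by many 6 nm steps before the next equilibration, injecting
strain no real motor could generate; evaluating the stall condition
continuously is the physically safer discretization at desk-scale
equilibration cadence. Unbinding and ratchet factors are still updated only
after minimization.

When the whole coupling is disabled (`mechanochemistry$enabled = FALSE`)
every multiplier is pinned to one and the chemistry reproduces
force-independent kinetics exactly.

## Synthetic initial conditions and what the desk-scale runs show

A simulation starts from `n_seed_filaments` (default 50) two-monomer
filaments at uniform random positions and orientations inside the boundary,
with diffusing pools set from concentrations
(`copy number = conc × volume × NA`; 20 uM in 1 um^3 gives 12044 monomers).
The seeds grow for 10 s in the presence of G-actin and alpha-actinin before
diffusing NMIIA mini-filaments are introduced — the pre-growth phase uses
the same cycle with motor channels absent.

The reference desk-scale campaign (used by the acceptance checks and
`scripts/acceptance.R`) is a 1 × 1 × 1 um^3 box at 20 uM actin with molar
ratios `R_m:a = 0.01` and `R_alpha:a = 0.1`, `chi = 1`, 10 s pre-growth
plus 100 s of active evolution, four random seeds. To keep four
trajectories plus controls inside a desk-scale compute budget these runs
use 80-monomer (216 nm) cylinders — still far below the 10 um persistence
length, with the joint bending stiffness rescaled accordingly and the
27 nm site lattice unchanged — a burst budget of ~5% of monomers between
equilibrations with snapshots every 2 s, and the 150-iteration cap above.
The 40-monomer default and 1% bursts remain the recommended settings when
fidelity matters more than wall time; all of these are ordinary
configuration keys.

At these conditions the model reproduces the qualitative phenomenology of
contractile actomyosin: motors and linkers drive the initially random
network into compact bundled structures (the radius of gyration of the
cylinder ensemble falls; without motors and linkers it stays flat), and
filament centers move super-diffusively (MSD exponent ν > 1 from a log-log
ordinary-least-squares fit of the time-and-ensemble MSD — the fit uses all
available lags by default, since these runs are much shorter than the
kinetic-arrest regime that motivates a 1000 s cutoff at production scale,
where `fit_window_s` applies).

What these runs do *not* show: quantitative heat maps over concentration
grids, long-time (thousands of seconds) morphology, kinetic arrest and the
sub-diffusive tail, or statistics at in-vivo filament lengths — those
require production-scale campaigns far beyond a single desk CPU. The
generator also idealizes real systems: monodisperse species, no capping,
severing, formin nucleation or nucleotide aging of monomers (the channel
set is extensible to these event types but they are not implemented), an
implicit single-bond motor ensemble rather than explicit heads, and hard
non-deformable boundaries.

## Numerical choices and degenerate inputs

* Compartment indexing uses half-open intervals `[k h, (k+1) h)`; points
  marginally pushed outside the box by soft-boundary dynamics are clamped
  to the nearest compartment for bookkeeping, while user-facing queries
  raise an error outside the grid.
* A depolymerization that would remove the material under a bound element
  forcibly unbinds it, releasing the species locally; filaments never
  shrink below their two-monomer seed.
* Binding channels for sites freed by an unbinding event, and for sites
  created by growth, appear at the next registration (once per cycle);
  occupancy conflicts are checked at execution so a stale channel can
  never fire.
* The minimizer treats pathological transients (deep overlaps with forces
  above 1e4 pN) with a tightened step cap, and stops early when energy
  progress stalls for eight consecutive iterations below a 1e-8 relative
  threshold.
* The excluded-volume neighbor list is cached across a minimization with a
  30 nm skin and rebuilt when accumulated displacement could change it.
* Ties and degenerate frames in angular terms (collinear vectors, undefined
  dihedral planes) contribute their finite energy with the gradient of the
  offending term omitted — a documented finite fallback on a measure-zero
  set.
* All randomness flows from one integer seed: R's RNG places seeds and
  derives the engine seed; the compiled engine uses its own xoshiro256++
  stream, so equal seeds give bit-identical trajectories.

## Known limitations

The equilibration cadence (not the chemistry) limits fidelity at high motor
activity: between bursts the geometry is frozen, so binding-site positions
and walk strains are evaluated against slightly stale coordinates. The
next-reaction engine is exact for the channel set as registered; the
burst-level granularity of candidate-pair registration is the approximation.
Excluded-volume truncation at 60 nm and the 2 nm contact softening are
deliberate regularizations, both far below the force tolerance and both
configurable. Branch chemistry is implemented only as far as the mechanics
needs (the optional nucleation channel and the branch force field); the
full dendritic-nucleation chemistry is out of scope.
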