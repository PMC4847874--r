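# cytomech

Desk-scale mechanochemical simulation of contractile actomyosin networks
in R.

Active cytoskeletal matter — actin filaments driven by myosin II motor
ensembles and coupled by transient cross-linkers — reorganizes far from
equilibrium: initially random networks contract into bundles, align, and
transport material super-diffusively. cytomech lets a structural
biophysicist reproduce this phenomenology on a single CPU by coupling three
ingredients in one loop:

1. **Compartmentalized stochastic chemistry.** Diffusing G-actin,
   α-actinin and NMIIA mini-filaments hop between cubic compartments
   (propensity `D/h²` per face) and react by mass action, simulated exactly
   with either the Gillespie direct method or the Gibson–Bruck next-reaction
   method. Filaments are explicit monomer-resolved polymers; binding
   reactions are registered dynamically for every site pair within the
   species' binding window (one site per 27 nm of filament; 35 ± 5 nm for
   α-actinin, 200 ± 25 nm for NMIIA).
2. **Coarse-grained polymer mechanics.** Filaments are chains of
   stretchable cylinders with angular bending
   `U = ε_bend (1 − cos θ)`, branch junctions
   (tether + angle at θ₀ = 70° + dihedral), harmonic motor/linker bonds
   attached at fractional positions via the lever rule, boundary
   repulsion `ε e^{−d/λ}`, and an **analytic segment–segment excluded
   volume**: the inverse-quartic pair kernel integrated in closed form over
   both cylinders, `U = K_vol ∫∫ dl_i dl_j / |r_i − r_j|⁴`, with analytic
   endpoint gradients — no numerical quadrature in the force loop. The
   network is equilibrated after each chemistry burst by preconditioned
   L-BFGS or Polak–Ribière conjugate gradients until the maximum per-bead
   force drops below tolerance.
3. **Mechanochemical feedback.** Post-equilibration forces rescale
   reaction rates: Brownian-ratchet slowdown `e^{−Fδ/kBT}` of tip
   polymerization under load, slip-bond acceleration `e^{+F x/kBT}` of
   cross-linker unbinding, and coarse-grained motor-ensemble kinetics
   (stall-linear walking in 6 nm steps, load-stabilized attachment with a
   5 s unloaded lifetime).

The analysis suite computes the standard observables of contraction and
alignment: radius of gyration of the cylinder ensemble
`Rg = sqrt(mean |r_i − r_GC|²)`, the nematic ordering tensor
`Q = 3/2 (⟨u uᵀ⟩ − I/3)` with order parameter `S = λ_max(Q)`, the
time-and-ensemble MSD of filament centers with its anomalous exponent ν
(`⟨Δx²⟩ ~ t^ν`), and bundle polarity fractions.

## Worked example

```r
library(cytomech)

cfg <- simulationConfig(box = 1000, actin_uM = 20,
                        r_motor_actin = 0.01, r_linker_actin = 0.1,
                        chi = 1, t_total = 100, n_seed_filaments = 50,
                        seed = 1,
                        flags = list(monomers_per_cylinder = 80L),
                        protocol = list(snapshot_interval = 2, n_chem = 600))
tr <- runSimulation(cfg)          # ~2 min on one CPU
tail(rgRatio(tr), 1)              # contraction proxy
msdExponent(tr)$nu                # anomalous diffusion exponent
orderParameter(tr$frames[[length(tr$frames)]])$S
```

Output from this exact run:

```
#>    time       rg     ratio
#> 56  110 161.7817 0.3551177
#> nu: 1.478
#> S: 0.062
```

50 seed filaments grow for 10 s at 20 µM actin, NMIIA mini-filaments are
added, and over the next 100 s the motor–linker system pulls the random
network into a compact structure: the radius of gyration falls to ~36% of
its value at motor introduction, while a control without motors and
linkers stays at ratio ≈ 1.0. Filament centers move super-diffusively
(ν ≈ 1.4–1.5 across seeds). Alignment (S) is modest at this box size and
time; global polar bundling develops on longer timescales than a
desk-scale run covers.

Command-line wrappers around the same functions live in `inst/cli/`
(`cytomech-simulate --config cfg.yml --seed 1 --out dir`,
`cytomech-analyze --traj dir/trajectory.txt --metrics rg,order,msd`,
`cytomech-validate-config cfg.yml`).

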