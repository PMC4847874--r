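# Scaled-down contractile actomyosin system: 1 um^3, 20 uM actin,
# R_m:a = 0.01, R_alpha:a = 0.1. Units: nm, s, pN, uM.
geometry:
  box: [1000, 1000, 1000]
  compartment_h: 500
  boundary: {shape: cube, eps: 100, lambda: 2.7}
species:
  actin: {conc_uM: 20, D: 2.5e6}
  linker: {ratio: 0.1, D: 1.0e6}
  motor: {ratio: 0.01, D: 2.0e5}
reactions:
  chi: 1
protocol:
  t_total: 100
  pre_growth: 10
  n_seed_filaments: 50
  n_chem: 600
  snapshot_interval: 2
  seed: 1
flags:
  binding_site_exclusive: false
  algorithm: nrm
  monomers_per_cylinder: 80
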