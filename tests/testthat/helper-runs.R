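# Scaled-down actomyosin study conditions shared by the acceptance checks:
# 1 um^3 box, 20 uM actin, R_m:a = 0.01, R_alpha:a = 0.1, chi = 1,
# 50 seed filaments, 10 s pre-growth + 100 s active, four seeds, plus
# motor/linker-free controls. Trajectories are computed once per session.
.cmRunCache <- new.env(parent = emptyenv())

actomyosinTrajectories <- function(seeds = 1:4) {
  key <- paste0("active_", paste(seeds, collapse = "_"))
  if (is.null(.cmRunCache[[key]])) {
    .cmRunCache[[key]] <- lapply(seeds, function(sd) {
      cfg <- simulationConfig(box = 1000, actin_uM = 20,
                              r_motor_actin = 0.01, r_linker_actin = 0.1,
                              chi = 1, t_total = 100, n_seed_filaments = 50,
                              seed = sd,
                              flags = list(monomers_per_cylinder = 80L),
                              protocol = list(snapshot_interval = 2,
                                              n_chem = 600))
      runSimulation(cfg)
    })
  }
  .cmRunCache[[key]]
}

passiveTrajectories <- function(seeds = 1:4) {
  key <- paste0("passive_", paste(seeds, collapse = "_"))
  if (is.null(.cmRunCache[[key]])) {
    .cmRunCache[[key]] <- lapply(seeds, function(sd) {
      cfg <- simulationConfig(box = 1000, actin_uM = 20,
                              r_motor_actin = 0, r_linker_actin = 0,
                              t_total = 100, n_seed_filaments = 50,
                              seed = sd,
                              flags = list(monomers_per_cylinder = 80L),
                              protocol = list(snapshot_interval = 2,
                                              n_chem = 600))
      runSimulation(cfg)
    })
  }
  .cmRunCache[[key]]
}
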