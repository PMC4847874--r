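#' Default force-field constants
#'
#' Units are nm, s, pN, pN nm throughout. The bending energy derives from an
#' actin persistence length of ~10 um (`eps_bend = lp kBT / l0` at the
#' default 108 nm cylinder); the stretching constant is of the order of the
#' measured filament extensional stiffness at this segment length; motor and
#' linker spring constants follow single-molecule pulling experiments
#' (NMIIA ~2.5 pN/nm, alpha-actinin ~8 pN/nm). The excluded-volume scale
#' `k_vol` (pN nm^3, arc-length normalization) is set so that two crossing
#' cylinders ~20 nm apart pay a few kBT. Values not printed in the source
#' literature are tagged `"default"` in the `provenance` attribute.
#'
#' @return Named list of force-field constants.
#' @export
defaultForceField <- function() {
  p <- list(
    eps_bend = 380,          # pN nm
    k_str = 100,             # pN/nm
    k_vol = 280,             # pN nm^3
    ev_cutoff = 60,          # nm
    ev_soft = 2,             # nm contact softening of the pair kernel
    k_branch_str = 100,      # pN/nm
    d0 = 6,                  # nm
    eps_branch_ang = 100,    # pN nm
    theta0 = 70 * pi / 180,  # rad, Arp2/3 equilibrium branch angle
    eps_branch_dihed = 50,   # pN nm
    phi0 = 0,                # rad
    k_motor = 2.5,           # pN/nm
    l0_motor = 200,          # nm
    k_linker = 8,            # pN/nm
    l0_linker = 35           # nm
  )
  attr(p, "provenance") <- c(
    eps_bend = "derived: lp ~ 10 um", k_str = "default",
    k_vol = "default", ev_cutoff = "default", ev_soft = "default",
    k_branch_str = "default", d0 = "default",
    eps_branch_ang = "default", theta0 = "stated: 70 deg",
    eps_branch_dihed = "default", phi0 = "default",
    k_motor = "literature", l0_motor = "stated: 200 nm window",
    k_linker = "literature", l0_linker = "stated: 35 nm window")
  p
}

#' Default chemical rate constants
#'
#' Standard actin kinetics (plus end 11.6 uM^-1 s^-1 on / 1.4 s^-1 off,
#' minus end 1.3 uM^-1 s^-1 / 0.8 s^-1), diffusion constants for cytosolic
#' G-actin, alpha-actinin and NMIIA mini-filaments, per-candidate-pair
#' binding rates, and the motor ensemble walking rate (6 nm steps). The
#' turnover factor `chi` multiplies all four actin (de)polymerization
#' constants. Binding windows are 35 +/- 5 nm (linker) and 200 +/- 25 nm
#' (motor).
#'
#' @return Named list of chemical parameters.
#' @export
defaultChemistry <- function() {
  p <- list(
    k_poly_plus = 11.6,    # uM^-1 s^-1
    k_poly_minus = 1.3,    # uM^-1 s^-1
    k_depoly_plus = 1.4,   # s^-1
    k_depoly_minus = 0.8,  # s^-1
    chi = 1,
    d_actin = 2.5e6,       # nm^2/s
    d_linker = 1e6,        # nm^2/s
    d_motor = 2e5,         # nm^2/s
    k_on_linker = 0.7,     # uM^-1 s^-1 per candidate pair
    k_off_linker = 0.3,    # s^-1
    k_on_motor = 0.2,      # uM^-1 s^-1 per candidate pair
    k_off_motor = 0.2,     # s^-1 -> 5 s unloaded attachment time
    v0_walk = 15,          # steps/s per bound ensemble end
    nucleation_rate = 0,   # s^-1 per compartment (fixtures only)
    motor_range = 200, motor_tol = 25,   # nm
    linker_range = 35, linker_tol = 5    # nm
  )
  attr(p, "provenance") <- c(
    k_poly_plus = "literature", k_poly_minus = "literature",
    k_depoly_plus = "literature", k_depoly_minus = "literature",
    chi = "stated", d_actin = "default", d_linker = "default",
    d_motor = "default", k_on_linker = "default", k_off_linker = "default",
    k_on_motor = "default", k_off_motor = "stated: 5 s attachment",
    v0_walk = "default", nucleation_rate = "default",
    motor_range = "stated: 200 +/- 25 nm", motor_tol = "stated",
    linker_range = "stated: 35 +/- 5 nm", linker_tol = "stated")
  p
}

#' Default mechanochemical coupling parameters
#'
#' Brownian-ratchet distance (one 2.7 nm monomer), alpha-actinin slip
#' distance, per-head stall force for NMIIA ensembles of 10-30 heads, the
#' characteristic force of load-stabilized motor attachment, and kBT =
#' 4.1 pN nm at room temperature.
#'
#' @return Named list of mechanochemical parameters.
#' @export
defaultMechanochemistry <- function() {
  p <- list(
    ratchet_delta = 2.7,    # nm
    x_slip = 0.35,          # nm
    f_stall_per_head = 2.5, # pN
    f_char = 12.5,          # pN
    kBT = 4.1,              # pN nm
    enabled = TRUE
  )
  attr(p, "provenance") <- c(
    ratchet_delta = "stated: 2.7 nm monomer", x_slip = "default",
    f_stall_per_head = "default", f_char = "default", kBT = "stated",
    enabled = "stated")
  p
}
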