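#' Build a simulation configuration
#'
#' Assembles the full declarative description of a simulation: geometry
#' (cubic box, compartment size, boundary potential), species (actin
#' concentration in uM plus molar ratios `r_motor_actin` = NMIIA : actin and
#' `r_linker_actin` = alpha-actinin : actin), reaction constants, force
#' field, mechanochemistry and protocol (total time, 10 s pre-growth before
#' motors appear, chemistry events per mechanical equilibration, snapshot
#' cadence, minimizer tolerance, RNG seed). Any value omitted falls back to
#' the package defaults.
#'
#' @param box Box edge lengths in nm (length-3 numeric or scalar).
#' @param compartment_h Compartment side in nm (default 500).
#' @param actin_uM Total actin concentration in uM.
#' @param r_motor_actin,r_linker_actin Molar concentration ratios relative
#'   to actin.
#' @param chi Turnover factor multiplying all four actin
#'   (de)polymerization constants.
#' @param t_total Simulated time in s (after the pre-growth phase starts at
#'   0; motors appear at `pre_growth`).
#' @param n_seed_filaments Number of short seed filaments nucleated at t=0.
#' @param seed RNG seed (integer).
#' @param reactions,forcefield,mechanochemistry,protocol,flags,boundary
#'   Named lists overriding individual defaults.
#' @return Object of class `cmConfig`.
#' @export
simulationConfig <- function(box = 1000, compartment_h = 500,
                             actin_uM = 20, r_motor_actin = 0.01,
                             r_linker_actin = 0.1, chi = 1,
                             t_total = 100, n_seed_filaments = 50,
                             seed = 1L,
                             reactions = list(), forcefield = list(),
                             mechanochemistry = list(), protocol = list(),
                             flags = list(), boundary = list()) {
  if (length(box) == 1) box <- rep(box, 3)
  rx <- modifyList(defaultChemistry(), reactions)
  rx$chi <- chi
  cfg <- list(
    geometry = list(
      box = as.numeric(box),
      compartment_h = compartment_h,
      boundary = modifyList(list(shape = "cube", eps = 100, lambda = 2.7),
                            boundary)),
    species = list(
      actin = list(conc_uM = actin_uM, D = rx$d_actin),
      linker = list(ratio = r_linker_actin, D = rx$d_linker),
      motor = list(ratio = r_motor_actin, D = rx$d_motor)),
    reactions = rx,
    forcefield = modifyList(defaultForceField(), forcefield),
    mechanochemistry = modifyList(defaultMechanochemistry(), mechanochemistry),
    protocol = modifyList(list(
      t_total = t_total, pre_growth = 10,
      n_seed_filaments = n_seed_filaments,
      n_chem = 0, snapshot_interval = 2,
      tol = 1, max_iter_minimize = 150, seed = as.integer(seed)),
      protocol),
    flags = modifyList(list(binding_site_exclusive = FALSE,
                            algorithm = "nrm",
                            monomers_per_cylinder = 40L), flags))
  class(cfg) <- "cmConfig"
  validateConfig(cfg)
}

.cmConfigSchema <- function() {
  list(
    geometry = c("box", "compartment_h", "boundary"),
    species = c("actin", "linker", "motor"),
    reactions = names(defaultChemistry()),
    forcefield = names(defaultForceField()),
    mechanochemistry = names(defaultMechanochemistry()),
    protocol = c("t_total", "pre_growth", "n_seed_filaments", "n_chem",
                 "snapshot_interval", "tol", "max_iter_minimize", "seed"),
    flags = c("binding_site_exclusive", "algorithm",
              "monomers_per_cylinder"))
}

#' Validate a configuration
#'
#' Rejects unknown keys at every level, missing required sections, negative
#' rates or concentrations, non-positive geometry, and unknown algorithm or
#' boundary-shape names. Returns the config invisibly unchanged so it can be
#' used as a pipeline check.
#'
#' @param cfg A `cmConfig` object or plain nested list.
#' @return The validated config (class `cmConfig`).
#' @export
validateConfig <- function(cfg) {
  schema <- .cmConfigSchema()
  missing_sec <- setdiff(names(schema), names(cfg))
  if (length(missing_sec) > 0)
    stop("config is missing section(s): ", paste(missing_sec, collapse = ", "))
  extra_sec <- setdiff(names(cfg), names(schema))
  if (length(extra_sec) > 0)
    stop("unknown config section(s): ", paste(extra_sec, collapse = ", "))
  for (sec in names(schema)) {
    extra <- setdiff(names(cfg[[sec]]), schema[[sec]])
    if (length(extra) > 0)
      stop("unknown key(s) in ", sec, ": ", paste(extra, collapse = ", "))
  }
  g <- cfg$geometry
  if (length(g$box) != 3 || any(!is.finite(g$box)) || any(g$box <= 0))
    stop("geometry$box must be 3 positive lengths (nm)")
  if (g$compartment_h <= 0) stop("compartment_h must be positive")
  if (!g$boundary$shape %in% c("cube", "sphere", "capsule"))
    stop("unknown boundary shape: ", g$boundary$shape)
  for (sp in names(cfg$species)) {
    s <- cfg$species[[sp]]
    conc <- if (!is.null(s$conc_uM)) s$conc_uM else s$ratio
    if (is.null(conc) || !is.finite(conc) || conc < 0)
      stop("species ", sp, ": concentration/ratio must be >= 0")
    if (s$D < 0) stop("species ", sp, ": negative diffusion constant")
  }
  rx <- cfg$reactions
  rateKeys <- c("k_poly_plus", "k_poly_minus", "k_depoly_plus",
                "k_depoly_minus", "k_on_linker", "k_off_linker",
                "k_on_motor", "k_off_motor", "v0_walk", "nucleation_rate")
  for (k in rateKeys)
    if (rx[[k]] < 0) stop("negative rate constant: ", k)
  if (rx$chi <= 0) stop("chi must be positive")
  ffKeys <- setdiff(names(cfg$forcefield), c("theta0", "phi0"))
  for (k in ffKeys)
    if (cfg$forcefield[[k]] < 0) stop("negative force-field constant: ", k)
  mcKeys <- c("ratchet_delta", "x_slip", "f_stall_per_head", "f_char", "kBT")
  for (k in mcKeys)
    if (cfg$mechanochemistry[[k]] <= 0)
      stop("mechanochemical parameter must be positive: ", k)
  p <- cfg$protocol
  if (p$t_total < 0 || p$pre_growth < 0) stop("negative protocol time")
  if (p$n_chem < 0) stop("n_chem must be >= 0 (0 = adaptive, ~1% of monomers)")
  if (p$tol <= 0) stop("minimizer tolerance must be positive")
  if (!cfg$flags$algorithm %in% c("nrm", "direct"))
    stop("algorithm must be 'nrm' or 'direct'")
  mpc <- cfg$flags$monomers_per_cylinder
  if (mpc < 2 || (mpc * 2.7) %% 27 != 0)
    stop("monomers_per_cylinder must make l0 a multiple of the 27 nm site spacing")
  class(cfg) <- "cmConfig"
  invisible(cfg)
}

#' Read a configuration from a YAML file
#'
#' The file holds the same sectioned structure that [simulationConfig()]
#' builds; omitted keys are filled from package defaults and the result is
#' validated. Values round-trip losslessly through [saveConfig()].
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `cmConfig`.
#' @export
loadConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- simulationConfig()
  cfg <- base
  for (sec in names(raw)) {
    if (!sec %in% names(base))
      stop("unknown config section: ", sec)
    cfg[[sec]] <- modifyList(base[[sec]], raw[[sec]])
  }
  validateConfig(cfg)
}

#' Write a configuration to a YAML file
#'
#' @param cfg A `cmConfig`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
saveConfig <- function(cfg, path) {
  validateConfig(cfg)
  plain <- rapply(unclass(cfg), function(x) x, how = "replace")
  yaml::write_yaml(plain, path, precision = 17)
  invisible(path)
}

#' @export
print.cmConfig <- function(x, ...) {
  cat("cytomech simulation configuration\n")
  cat(sprintf("  box: %s nm, compartments of %g nm\n",
              paste(x$geometry$box, collapse = " x "),
              x$geometry$compartment_h))
  cat(sprintf("  actin %g uM, R_m:a = %g, R_a:a = %g, chi = %g\n",
              x$species$actin$conc_uM, x$species$motor$ratio,
              x$species$linker$ratio, x$reactions$chi))
  cat(sprintf("  t_total %g s (pre-growth %g s), %d seeds, seed %d, %s\n",
              x$protocol$t_total, x$protocol$pre_growth,
              x$protocol$n_seed_filaments, x$protocol$seed,
              x$flags$algorithm))
  invisible(x)
}
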