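#' Register dynamic reaction channels from current geometry
#'
#' Rebuilds the full channel set: diffusion jumps, per-filament
#' (de)polymerization, one bind channel per current candidate site pair
#' (see [pairCandidates()]), one unbind channel per bound element (plus two
#' walk channels per motor), nucleation and bulk reactions. Channels whose
#' geometric precondition has vanished disappear; putative firing times are
#' redrawn from current propensities. Call after every mechanical
#' equilibration (the run loop in [runSimulation()] does this).
#'
#' @param state A `cmState`.
#' @return The state, invisibly.
#' @export
registerBindings <- function(state) {
  cmRegister(state$ptr)
  invisible(state)
}

#' Current reaction channels and propensities
#'
#' `a` is the propensity last maintained incrementally by the engine;
#' `a_fresh` is recomputed from scratch from the current state. The two are
#' always equal (an engine invariant under test).
#'
#' @param state A `cmState`.
#' @return data.frame of channels.
#' @export
reactionChannels <- function(state) cmChannels(state$ptr)

#' Advance the stochastic chemistry
#'
#' Executes events with the configured engine (next-reaction method or
#' direct method) until `n_mech` mechanically relevant events (anything but
#' a diffusion jump) have fired, time reaches `t_stop`, or `max_events`
#' events in total.
#'
#' @param state A `cmState`.
#' @param n_mech Mechanical-event budget (-1 for unlimited).
#' @param t_stop Absolute stop time, s.
#' @param max_events Total event cap (-1 for unlimited).
#' @param record If `TRUE`, return the event log (time, kind, channel).
#' @param n_poly Separate budget on monomer-changing events
#'   (polymerization, depolymerization, nucleation; -1 for unlimited).
#' @return List: `time`, `n_events`, and `events` when recorded.
#' @export
runChemistry <- function(state, n_mech = -1, t_stop = Inf, max_events = -1,
                         record = FALSE, n_poly = -1) {
  cmRun(state$ptr, as.numeric(n_mech), t_stop, as.numeric(max_events), record,
        as.numeric(n_poly))
}

#' Mass-action propensity of an elementary channel
#'
#' Reference implementation of the propensity laws used by the engine:
#' unimolecular `a = k n`; bimolecular within one compartment
#' `a = k n1 n2 / (NA V)` with `V = h^3` (k in uM^-1 s^-1); diffusion jump
#' `a = (D / h^2) n` per adjacent face.
#'
#' @param kind `"unimolecular"`, `"bimolecular"` or `"diffusion"`.
#' @param k Rate constant (1/s, uM^-1 s^-1, or D in nm^2/s).
#' @param n,n2 Copy numbers.
#' @param h Compartment side, nm.
#' @return Propensity, 1/s.
#' @export
massActionPropensity <- function(kind = c("unimolecular", "bimolecular",
                                          "diffusion"),
                                 k, n, n2 = NULL, h = 500) {
  kind <- match.arg(kind)
  na_conv <- 6.022e-7 # molecules per (nm^3 uM)
  switch(kind,
         unimolecular = k * n,
         bimolecular = k * n * n2 / (na_conv * h^3),
         diffusion = k / h^2 * n)
}

#' Build a well-mixed / compartmentalized test reaction network
#'
#' A chemistry-only state (no filaments) for exercising the stochastic
#' engines: species A, B, C (mapped onto the actin/linker/motor slots),
#' optional diffusion between compartments, and bulk mass-action reactions
#' of order 0-2.
#'
#' @param counts Integer matrix (n_compartments x 3) of initial copy
#'   numbers.
#' @param reactions List of lists with elements `react` (integer vector of
#'   species indices 0-2, up to 2), `prod` (up to 3), and `k` (1/s for
#'   order 0/1, uM^-1 s^-1 for order 2).
#' @param box,compartment_h Geometry, nm.
#' @param D Length-3 diffusion constants (nm^2/s); zero disables jumps.
#' @param algorithm `"nrm"` or `"direct"`.
#' @param seed Engine seed.
#' @return A registered `cmState` ready for [runChemistry()].
#' @export
reactionNetwork <- function(counts, reactions = list(), box = 500,
                            compartment_h = 500, D = c(0, 0, 0),
                            algorithm = "nrm", seed = 1L) {
  st <- newNetworkState(box, compartment_h,
                        chemistry = list(d_actin = D[1], d_linker = D[2],
                                         d_motor = D[3]),
                        flags = list(algorithm = algorithm), seed = seed)
  counts <- as.matrix(counts)
  if (nrow(counts) != prod(st$dims))
    stop("counts must have one row per compartment (", prod(st$dims), ")")
  setSpeciesCounts(st, counts)
  for (r in reactions)
    cmAddBulkReaction(st$ptr, as.integer(r$react), as.integer(r$prod), r$k)
  registerBindings(st)
  st
}
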