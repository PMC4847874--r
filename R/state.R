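#' Create an empty network state
#'
#' Allocates the mutable simulation state: compartment grid, boundary,
#' force-field/chemistry/mechanochemistry parameters and RNG. Filaments,
#' bound elements and species copy numbers are added afterwards (see
#' [addFilament()], [setSpeciesCounts()], [generateFixture()]).
#'
#' @param box Box edge lengths, nm (scalar or length 3).
#' @param compartment_h Compartment side, nm.
#' @param boundary,forcefield,chemistry,mechanochemistry,flags Named lists
#'   overriding defaults (see [simulationConfig()]).
#' @param seed Integer seed for the engine RNG.
#' @return Object of class `cmState`.
#' @export
newNetworkState <- function(box = 1000, compartment_h = 500,
                            boundary = list(), forcefield = list(),
                            chemistry = list(), mechanochemistry = list(),
                            flags = list(), seed = 1L) {
  if (length(box) == 1) box <- rep(box, 3)
  ptr <- cmNewState(as.numeric(box), compartment_h, boundary, forcefield,
                    chemistry, mechanochemistry, flags, as.numeric(seed))
  st <- list(ptr = ptr, box = as.numeric(box), h = compartment_h,
             dims = pmax(1L, as.integer(round(box / compartment_h))))
  class(st) <- "cmState"
  st
}

#' Build a state from a configuration (without seeding filaments)
#' @param cfg A `cmConfig`.
#' @param seed Engine seed; defaults to the config seed.
#' @return A `cmState`.
#' @keywords internal
stateFromConfig <- function(cfg, seed = cfg$protocol$seed) {
  newNetworkState(cfg$geometry$box, cfg$geometry$compartment_h,
                  boundary = cfg$geometry$boundary,
                  forcefield = cfg$forcefield,
                  chemistry = chemForCpp(cfg),
                  mechanochemistry = cfg$mechanochemistry,
                  flags = cfg$flags, seed = seed)
}

# flatten config reactions + species D into the names the C++ side reads
chemForCpp <- function(cfg) {
  rx <- cfg$reactions
  rx$d_actin <- cfg$species$actin$D
  rx$d_linker <- cfg$species$linker$D
  rx$d_motor <- cfg$species$motor$D
  rx
}

#' Add a filament to a state
#'
#' A filament is an ordered minus-to-plus chain of cylinders; `beads` has
#' one more row than `n_monomers` has entries. Cylinder equilibrium lengths
#' are `n_monomers * 2.7` nm.
#'
#' @param state A `cmState`.
#' @param beads Numeric matrix (n_cyl + 1) x 3 of bead positions, nm.
#' @param n_monomers Integer vector of monomers per cylinder (full cylinder
#'   = 40 monomers = 108 nm).
#' @return Filament id (integer), invisibly the state is modified in place.
#' @export
addFilament <- function(state, beads, n_monomers) {
  stopifnot(inherits(state, "cmState"))
  cmAddFilament(state$ptr, as.matrix(beads), as.integer(n_monomers))
}

#' Set / get diffusing species copy numbers
#'
#' `counts` is an (n_compartments x 3) integer matrix with columns actin,
#' linker, motor; compartments are ordered x-fastest (see
#' [compartmentOf()]).
#'
#' @param state A `cmState`.
#' @param counts Integer matrix of copy numbers.
#' @return `getSpeciesCounts` returns the matrix; `setSpeciesCounts` the
#'   state, invisibly.
#' @export
setSpeciesCounts <- function(state, counts) {
  cmSetSpeciesCounts(state$ptr, as.matrix(counts))
  invisible(state)
}

#' @rdname setSpeciesCounts
#' @export
getSpeciesCounts <- function(state) cmGetSpeciesCounts(state$ptr)

#' Enumerate binding sites of a filament
#'
#' One binding site per 27 nm of filament, placed at midpoints of
#' consecutive 27 nm intervals from the minus end and anchored to absolute
#' monomer positions, so sites never relocate under polymerization
#' (occupancy is sticky to material, not to fractional position).
#'
#' @param state A `cmState`.
#' @param filament Filament id.
#' @return data.frame with site index, cylinder, fractional position,
#'   contour distance from the minus end (nm), and occupancy flags.
#' @export
enumerateBindingSites <- function(state, filament) {
  cmBindingSites(state$ptr, as.integer(filament))
}

#' Candidate site pairs for motor / linker binding
#'
#' All unoccupied site pairs on distinct filaments whose Euclidean
#' site-to-site distance lies within the configured window (35 +/- 5 nm for
#' alpha-actinin, 200 +/- 25 nm for NMIIA mini-filaments), keyed by the
#' compartment containing the pair midpoint.
#'
#' @param state A `cmState`.
#' @param kind Optional filter, `"linker"` or `"motor"`.
#' @return data.frame of candidate pairs.
#' @export
pairCandidates <- function(state, kind = NULL) {
  df <- cmPairCandidates(state$ptr)
  if (!is.null(kind)) df <- df[df$kind == kind, , drop = FALSE]
  df
}

#' Compartment containing a point
#'
#' Half-open intervals `[k h, (k+1) h)` per axis, 0-based indices; points
#' outside the grid raise an error (geometry/boundary inconsistency).
#'
#' @param state A `cmState`.
#' @param point Length-3 position, nm.
#' @return Named integer vector `ix, iy, iz, linear`.
#' @export
compartmentOf <- function(state, point) {
  cmCompartmentOf(state$ptr, as.numeric(point))
}

#' Total actin in a state (diffusing + polymerized monomers)
#' @param state A `cmState`.
#' @return Monomer count.
#' @export
totalActin <- function(state) cmTotalActin(state$ptr)

#' Snapshot the current state
#'
#' @param state A `cmState`.
#' @return A `cmFrame`: time, filaments (bead coordinates, per-cylinder
#'   monomer counts, minus-end offset), bound elements with material
#'   positions and loads, and per-compartment species counts.
#' @export
networkSnapshot <- function(state) {
  fr <- cmSnapshot(state$ptr)
  class(fr) <- "cmFrame"
  fr
}

#' @export
print.cmState <- function(x, ...) {
  s <- cmSnapshot(x$ptr)
  cat(sprintf("cytomech state: %d filaments, %d bound elements, t = %.3f s\n",
              length(s$filaments), nrow(s$elements), s$time))
  cat(sprintf("  box %s nm, %s compartments\n",
              paste(x$box, collapse = " x "),
              paste(x$dims, collapse = " x ")))
  cat(sprintf("  diffusing: %s\n",
              paste(sprintf("%s=%d", c("actin", "linker", "motor"),
                            colSums(s$species)), collapse = ", ")))
  invisible(x)
}

#' @export
print.cmFrame <- function(x, ...) {
  nmono <- sum(vapply(x$filaments, function(f) sum(f$nmono), numeric(1)))
  cat(sprintf("cytomech frame at t = %.3f s: %d filaments (%d monomers), %d elements\n",
              x$time, length(x$filaments), nmono, nrow(x$elements)))
  invisible(x)
}
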