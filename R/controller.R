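#' Initialize an actomyosin system from a configuration
#'
#' Nucleates `n_seed_filaments` two-monomer filaments at uniform random
#' positions and orientations inside the boundary, and fills the diffusing
#' pools from concentrations (`copy number = conc x volume x NA`,
#' distributed evenly over compartments with the remainder assigned in
#' compartment order). Motors are not present initially; [runSimulation()]
#' introduces them after the pre-growth phase. All randomness derives from
#' `seed` (R RNG for placement, engine RNG for events), so equal seeds give
#' identical initial states.
#'
#' @param cfg A `cmConfig`.
#' @param seed Overrides `cfg$protocol$seed`.
#' @return A registered `cmState` at t = 0.
#' @export
initializeSystem <- function(cfg, seed = cfg$protocol$seed) {
  validateConfig(cfg)
  box <- cfg$geometry$box
  vol <- prod(box)
  nseed <- cfg$protocol$n_seed_filaments
  nActinTotal <- round(cfg$species$actin$conc_uM * vol * 6.022e-7)
  if (nActinTotal < 2 * nseed)
    stop("box too small: ", nActinTotal, " monomers cannot seed ",
         nseed, " filaments")
  st <- stateFromConfig(cfg, seed)
  set.seed(seed)
  margin <- 30
  if (any(box <= 2 * margin + 6)) stop("box too small for seed filaments")
  for (i in seq_len(nseed)) {
    p0 <- runif(3, margin, box - margin)
    u <- rnorm(3)
    u <- u / sqrt(sum(u^2))
    addFilament(st, rbind(p0, p0 + 5.4 * u), 2L)
  }
  ncomp <- prod(st$dims)
  counts <- matrix(0L, ncomp, 3)
  counts[, 1] <- .spreadCount(nActinTotal - 2L * nseed, ncomp)
  nLinker <- round(cfg$species$linker$ratio * cfg$species$actin$conc_uM *
                     vol * 6.022e-7)
  counts[, 2] <- .spreadCount(nLinker, ncomp)
  setSpeciesCounts(st, counts)
  registerBindings(st)
  st
}

.spreadCount <- function(n, ncomp) {
  base <- n %/% ncomp
  rem <- n %% ncomp
  as.integer(base + (seq_len(ncomp) <= rem))
}

#' Run a mechanochemical trajectory
#'
#' The iterative protocol: (1) a burst of stochastic chemistry (`n_chem`
#' mechanically relevant events; with the default `n_chem = 0` the burst
#' size adapts to ~1% of the total actin monomers, bounding the
#' out-of-equilibrium drift the minimizer must relax), (2) re-registration
#' of dynamic binding
#' channels, (3) conjugate-gradient mechanical equilibration, (4) update of
#' force-dependent rate multipliers. Snapshots are emitted every
#' `snapshot_interval` seconds. Diffusing NMIIA mini-filaments are
#' introduced when the pre-growth phase (default 10 s, G-actin and
#' alpha-actinin only) ends; trajectory time is measured from the start of
#' pre-growth. Total actin is conserved throughout; a fixed seed gives a
#' bit-identical trajectory.
#'
#' @param cfg A `cmConfig`.
#' @param seed Overrides the config seed.
#' @param state Optionally, a pre-initialized `cmState` (skips
#'   [initializeSystem()]).
#' @param quiet Suppress per-phase messages.
#' @return A `cmTrajectory`: list of frames, snapshot times, the config,
#'   seed, and per-cycle minimizer diagnostics.
#' @export
runSimulation <- function(cfg, seed = cfg$protocol$seed, state = NULL,
                          quiet = TRUE) {
  validateConfig(cfg)
  pr <- cfg$protocol
  st <- if (is.null(state)) initializeSystem(cfg, seed) else state
  # burst budgets: ~1% of monomers may change per burst; an overall cap on
  # mechanically relevant events (mostly motor steps and linker exchange)
  # bounds the strain injected between equilibrations
  nPoly <- if (pr$n_chem > 0) pr$n_chem else max(20, round(0.01 * totalActin(st)))
  nChem <- max(2000, 12 * nPoly)
  tEnd <- pr$pre_growth + pr$t_total
  snapTimes <- seq(0, tEnd, by = pr$snapshot_interval)
  frames <- list()
  times <- numeric(0)
  diag <- list(n_cycles = 0L, n_events = 0, n_nonconverged = 0L,
               minimizer_iters = 0)
  motorsIn <- FALSE
  takeSnap <- function() {
    fr <- networkSnapshot(st)
    fr$energy <- networkEnergy(st)
    frames[[length(frames) + 1]] <<- fr
    times[length(times) + 1] <<- fr$time
  }
  takeSnap()
  nextSnap <- 2L
  repeat {
    tNow <- cmTime(st$ptr)
    if (tNow >= tEnd - 1e-9) break
    if (!motorsIn && tNow >= pr$pre_growth - 1e-9) {
      nMotor <- round(cfg$species$motor$ratio * cfg$species$actin$conc_uM *
                        prod(cfg$geometry$box) * 6.022e-7)
      counts <- getSpeciesCounts(st)
      counts[, 3] <- counts[, 3] + .spreadCount(nMotor, nrow(counts))
      setSpeciesCounts(st, counts)
      registerBindings(st)
      motorsIn <- TRUE
      if (!quiet) message(sprintf("t = %.2f s: %d NMIIA mini-filaments added",
                                  tNow, nMotor))
    }
    tStop <- min(tEnd,
                 if (!motorsIn) pr$pre_growth else Inf,
                 if (nextSnap <= length(snapTimes)) snapTimes[nextSnap] else Inf)
    res <- runChemistry(st, n_mech = nChem, t_stop = tStop, n_poly = nPoly)
    diag$n_events <- diag$n_events + res$n_events
    registerBindings(st)
    m <- suppressWarnings(equilibrate(st, pr$tol, pr$max_iter_minimize))
    diag$n_cycles <- diag$n_cycles + 1L
    diag$minimizer_iters <- diag$minimizer_iters + m$iters
    if (!m$converged) diag$n_nonconverged <- diag$n_nonconverged + 1L
    updateReactionRates(st)
    registerBindings(st)
    tNow <- cmTime(st$ptr)
    while (nextSnap <= length(snapTimes) && tNow >= snapTimes[nextSnap] - 1e-9) {
      takeSnap()
      nextSnap <- nextSnap + 1L
    }
  }
  if (!quiet)
    message(sprintf("done: %d cycles, %.0f events, %d frames",
                    diag$n_cycles, diag$n_events, length(frames)))
  traj <- list(frames = frames, times = times, config = cfg,
               seed = seed, diagnostics = diag)
  class(traj) <- "cmTrajectory"
  traj
}

#' @export
print.cmTrajectory <- function(x, ...) {
  cat(sprintf("cytomech trajectory: %d frames to t = %.1f s (seed %d)\n",
              length(x$frames), max(x$times), x$seed))
  cat(sprintf("  %d chemistry-mechanics cycles, %.3g events\n",
              x$diagnostics$n_cycles, x$diagnostics$n_events))
  invisible(x)
}
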