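#' Total mechanical energy and its decomposition
#'
#' @param state A `cmState`.
#' @return List with `total` and the per-term energies (pN nm): `stretch`,
#'   `bend`, `exclvol`, `motor`, `linker`, `branch`, `boundary`.
#' @export
networkEnergy <- function(state) cmEnergy(state$ptr)

#' Forces at all beads (minus the energy gradient)
#'
#' @param state A `cmState`.
#' @return List with bead ids, an n x 3 force matrix (pN) and `max_force`.
#' @export
networkForces <- function(state) cmForces(state$ptr)

#' Mechanical equilibration (energy minimization)
#'
#' Minimizes the network energy until the largest per-bead force drops
#' below `tol` (pN), leaving fractional binding positions (alpha, beta,
#' gamma) and all chemistry untouched. Two descent strategies share the
#' same quadratic-interpolation line search: the default limited-memory
#' BFGS (with a diagonal stiffness preconditioner as initial metric), which
#' converges in far fewer iterations on the stiff stretching / soft bending
#' spectrum of these networks, and Polak-Ribiere(+) nonlinear conjugate
#' gradients with restarts. Energy is non-increasing across accepted steps
#' for either method.
#'
#' @param state A `cmState`.
#' @param tol Convergence tolerance on the max per-bead force, pN.
#' @param max_iter Iteration cap; non-convergence returns the best state
#'   reached with `converged = FALSE` (a warning, not an error).
#' @param method `"lbfgs"` (default) or `"cg"`.
#' @return List: `converged`, `iters`, `U0`, `U1`, `max_force`,
#'   `energy_trace` (accepted energies).
#' @export
equilibrate <- function(state, tol = 1, max_iter = 2000,
                        method = c("lbfgs", "cg")) {
  method <- match.arg(method)
  res <- cmMinimize(state$ptr, tol, as.integer(max_iter), method)
  if (!res$converged)
    warning(sprintf("minimizer not converged: max force %.3g pN after %d iters",
                    res$max_force, res$iters))
  res
}

#' Update mechanochemical rate multipliers from current forces
#'
#' Applies the force-to-rate maps after an equilibration: Brownian-ratchet
#' factor on tip polymerization, slip-bond factor on linker unbinding,
#' stall-linear walk rate and load-stabilized unbinding for motor
#' ensembles.
#'
#' @param state A `cmState`.
#' @return List of data.frames: per-element loads and multipliers, and
#'   per-filament polymerization multipliers.
#' @export
updateReactionRates <- function(state) cmUpdateRates(state$ptr)

#' Bending energy of a cylinder joint
#'
#' `eps_bend (1 - cos theta)` between two consecutive cylinders sharing the
#' middle bead; gradient at the three beads.
#'
#' @param x0,x1,x2 Bead positions (nm): first cylinder `x0 -> x1`, second
#'   `x1 -> x2`.
#' @param eps_bend Bending energy, pN nm.
#' @return List `U` (pN nm) and 3 x 3 `grad` (pN).
#' @export
bendingEnergy <- function(x0, x1, x2, eps_bend) {
  cmTermBend(as.numeric(x0), as.numeric(x1), as.numeric(x2), eps_bend)
}

#' Stretching energy of a cylinder
#'
#' `1/2 k_str (|l| - l0)^2` with equal and opposite axial end forces.
#'
#' @param x1,x2 Endpoint positions, nm.
#' @param k_str Stretching constant, pN/nm.
#' @param l0 Equilibrium length, nm.
#' @return List `U` and 2 x 3 `grad`.
#' @export
stretchingEnergy <- function(x1, x2, k_str, l0) {
  cmTermStretch(as.numeric(x1), as.numeric(x2), k_str, l0)
}

#' Analytic segment-segment excluded-volume energy
#'
#' Closed-form double integral of the inverse-quartic pair kernel over both
#' cylinders (arc-length measure), with the analytic gradient at all four
#' endpoints. Degenerate geometries (parallel or intersecting support
#' lines) are evaluated after a documented 1e-3 nm perturbation and never
#' return non-finite values.
#'
#' @param xi1,xi2,xj1,xj2 Cylinder endpoints, nm.
#' @param k_vol Repulsion scale, pN nm^3.
#' @param r_soft Contact-softening length, nm: the kernel becomes
#'   `1/(r^2 + r_soft^2)^2` (same closed form with the constant invariant
#'   shifted). The default 0 is the pure inverse-quartic kernel; the network
#'   force field uses `ev_soft` (2 nm) to bound contact forces.
#' @return List `U` and 4 x 3 `grad`.
#' @export
excludedVolumeEnergy <- function(xi1, xi2, xj1, xj2, k_vol, r_soft = 0) {
  cmTermExclVol(as.numeric(xi1), as.numeric(xi2), as.numeric(xj1),
                as.numeric(xj2), k_vol, r_soft)
}

#' Branching junction energy (stretch + angle + dihedral)
#'
#' Tether `k_branch_str (|d| - d0)^2` between the daughter minus bead and
#' the mother anchor at fraction `gamma`, angular term
#' `eps_branch_ang (1 - cos(theta - theta0))` between the cylinder axes,
#' and a dihedral term around the tether. Mother-side gradients are
#' distributed by the lever rule at `gamma`.
#'
#' @param xi1,xi2 Mother cylinder endpoints, nm.
#' @param gamma Fractional anchor position on the mother, in `[0, 1]`.
#' @param xj1,xj2 Daughter cylinder endpoints (`xj1` is the attached minus
#'   bead).
#' @param params Named list of branching constants (`k_branch_str`, `d0`,
#'   `eps_branch_ang`, `theta0`, `eps_branch_dihed`, `phi0`); defaults from
#'   [defaultForceField()].
#' @return List `U` and 4 x 3 `grad` (xi1, xi2, xj1, xj2).
#' @export
branchingEnergy <- function(xi1, xi2, gamma, xj1, xj2, params = list()) {
  p <- modifyList(defaultForceField(), params)
  cmTermBranch(as.numeric(xi1), as.numeric(xi2), gamma, as.numeric(xj1),
               as.numeric(xj2), p)
}

#' Motor / linker bond energy with fractional attachment
#'
#' `1/2 K (|l_m| - l0)^2` between attachment points
#' `(1-alpha) xi1 + alpha xi2` and `(1-beta) xj1 + beta xj2`; endpoint
#' forces via lever-rule weights.
#'
#' @param xi1,xi2,xj1,xj2 Host cylinder endpoints, nm.
#' @param alpha,beta Fractional positions in `[0, 1]`.
#' @param K Spring constant, pN/nm.
#' @param l0 Rest length, nm.
#' @return List `U` and 4 x 3 `grad`.
#' @export
bondEnergy <- function(xi1, xi2, xj1, xj2, alpha, beta, K, l0) {
  cmTermBond(as.numeric(xi1), as.numeric(xi2), as.numeric(xj1),
             as.numeric(xj2), alpha, beta, K, l0)
}

#' Boundary repulsion energy of a cylinder
#'
#' `eps_boundary exp(-d / lambda)` on the cylinder endpoint nearer to the
#' wall, `d` being the signed inside distance.
#'
#' @param x1,x2 Cylinder endpoints, nm.
#' @param box Boundary dimensions, nm (length 3).
#' @param shape `"cube"`, `"sphere"` or `"capsule"`.
#' @param eps Repulsion energy scale, pN nm.
#' @param lambda Screening length, nm.
#' @return List `U` and 2 x 3 `grad`.
#' @export
boundaryEnergy <- function(x1, x2, box, shape = "cube", eps = 100,
                           lambda = 2.7) {
  if (length(box) == 1) box <- rep(box, 3)
  cmTermBoundary(as.numeric(x1), as.numeric(x2), as.numeric(box), shape,
                 eps, lambda)
}
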