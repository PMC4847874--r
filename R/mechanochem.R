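#' Brownian-ratchet polymerization multiplier
#'
#' A filament tip growing against a compressive load `F` polymerizes at a
#' rate reduced by `exp(-F delta / kBT)`, `delta` being the length added
#' per monomer (2.7 nm).
#'
#' @param F Compressive load along the tip axis, pN (>= 0).
#' @param params Mechanochemical parameters, see
#'   [defaultMechanochemistry()].
#' @return Dimensionless multiplier in (0, 1].
#' @export
ratchetMultiplier <- function(F, params = defaultMechanochemistry()) {
  stopifnot(all(F >= 0))
  exp(-F * params$ratchet_delta / params$kBT)
}

#' Slip-bond unbinding multiplier (alpha-actinin)
#'
#' Tension accelerates cross-linker unbinding: `exp(+F x_slip / kBT)`.
#'
#' @param F Tension on the linker, pN (>= 0).
#' @inheritParams ratchetMultiplier
#' @return Dimensionless multiplier >= 1.
#' @export
slipMultiplier <- function(F, params = defaultMechanochemistry()) {
  stopifnot(all(F >= 0))
  exp(F * params$x_slip / params$kBT)
}

#' Coarse-grained NMIIA ensemble rates under load
#'
#' Parametric stand-in for detailed motor-ensemble kinetics: the walking
#' rate decreases linearly to zero at the ensemble stall force
#' `n_heads * f_stall_per_head`, and the unbinding rate decreases
#' exponentially with load (`k0 exp(-F / F_char)`), reflecting the
#' stress-stabilized attachment of myosin II mini-filaments. At zero load
#' the attachment time is `1 / k0` (5 s at defaults).
#'
#' @param F Load opposing walking, pN (>= 0).
#' @param n_heads Number of myosin heads in the ensemble (10-30).
#' @param k0_unbind Unloaded unbinding rate, 1/s.
#' @param v0 Unloaded walking rate, steps/s.
#' @inheritParams ratchetMultiplier
#' @return List with `walk_rate` and `unbind_rate` (1/s).
#' @export
motorRates <- function(F, n_heads = 20, k0_unbind = 0.2, v0 = 15,
                       params = defaultMechanochemistry()) {
  stopifnot(all(F >= 0), all(n_heads > 0))
  f_stall <- n_heads * params$f_stall_per_head
  list(walk_rate = v0 * pmax(0, 1 - F / f_stall),
       unbind_rate = k0_unbind * exp(-F / params$f_char))
}
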