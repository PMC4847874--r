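#' Deterministic toy states for testing and exploration
#'
#' Each kind builds a small `cmState` exercising one force-field term or
#' binding rule; all randomness is controlled by `seed`.
#'
#' * `single_filament`: one straight filament of `n_cyl` full cylinders.
#' * `branch_junction`: mother + daughter cylinder joined by a branch
#'   element; the initial mother-daughter angle is `angle_deg` and the
#'   tether is placed ahead of the daughter's opening path (slightly out of
#'   plane) so that minimization relaxes into the equilibrium basin.
#' * `crossing_pair`: two skew filaments crossing at `cross_angle_deg`
#'   (default 60) with gap `gap_nm` (default 30), giving positive
#'   excluded-volume energy.
#' * `bundle_parallel` / `bundle_antiparallel`: `n_fil` aligned filaments
#'   35 nm apart, all plus ends together or alternating.
#' * `random_network`: `n_fil` filaments of 2-4 cylinders at uniform random
#'   positions/orientations plus diffusing species.
#'
#' @param kind Fixture name (see above).
#' @param seed RNG seed.
#' @param box Box edge, nm.
#' @param angle_deg Initial branch angle (branch_junction).
#' @param cross_angle_deg,gap_nm Crossing geometry (crossing_pair).
#' @param n_fil,n_cyl Filament counts / lengths.
#' @param ... Passed to [newNetworkState()] (e.g. `forcefield`, `flags`).
#' @return A `cmState`; branch fixtures carry attribute `"filaments"` with
#'   the mother/daughter ids.
#' @export
generateFixture <- function(kind = c("single_filament", "branch_junction",
                                     "crossing_pair", "bundle_parallel",
                                     "bundle_antiparallel", "random_network"),
                            seed = 1L, box = 2000, angle_deg = 30,
                            cross_angle_deg = 60, gap_nm = 30, n_fil = 10,
                            n_cyl = 3, ...) {
  kind <- match.arg(kind)
  set.seed(seed)
  ctr <- rep(box / 2, 3)
  st <- switch(
    kind,
    single_filament = {
      st <- newNetworkState(box, 500, boundary = list(eps = 0), ...)
      start <- ctr - c(n_cyl * 54, 0, 0)
      beads <- t(sapply(0:n_cyl, function(i) start + c(108 * i, 0, 0)))
      addFilament(st, beads, rep(40L, n_cyl))
      st
    },
    branch_junction = {
      st <- newNetworkState(box, 500, boundary = list(eps = 0),
                            forcefield = list(k_vol = 0), ...)
      th <- angle_deg * pi / 180
      mother <- addFilament(st, rbind(ctr - c(54, 0, 0), ctr + c(54, 0, 0)),
                            40L)
      # tether ahead of the opening path, tilted slightly out of plane
      td <- 130 * pi / 180
      base <- ctr + 6 * c(cos(td), sin(td), 0)
      u <- c(cos(th), sin(th), 0.05)
      u <- u / sqrt(sum(u^2))
      daughter <- addFilament(st, rbind(base, base + 108 * u), 40L)
      cmAddBranch(st$ptr, mother, 54, daughter)
      attr(st, "filaments") <- c(mother = mother, daughter = daughter)
      st
    },
    crossing_pair = {
      st <- newNetworkState(box, 500, boundary = list(eps = 0), ...)
      th <- cross_angle_deg * pi / 180
      a <- addFilament(st, rbind(ctr - c(108, 0, 0), ctr, ctr + c(108, 0, 0)),
                       c(40L, 40L))
      u <- c(cos(th), sin(th), 0)
      base <- ctr + c(0, 0, gap_nm)
      b <- addFilament(st, rbind(base - 108 * u, base, base + 108 * u),
                       c(40L, 40L))
      attr(st, "filaments") <- c(a = a, b = b)
      st
    },
    bundle_parallel = ,
    bundle_antiparallel = {
      st <- newNetworkState(box, 500, boundary = list(eps = 0), ...)
      for (i in seq_len(n_fil)) {
        off <- c(0, 35 * (i - (n_fil + 1) / 2), 0)
        start <- ctr + off - c(n_cyl * 54, 0, 0)
        beads <- t(sapply(0:n_cyl, function(k) start + c(108 * k, 0, 0)))
        if (kind == "bundle_antiparallel" && i %% 2 == 0)
          beads <- beads[rev(seq_len(nrow(beads))), , drop = FALSE]
        addFilament(st, beads, rep(40L, n_cyl))
      }
      st
    },
    random_network = {
      st <- newNetworkState(box, 500, ...)
      for (i in seq_len(n_fil)) {
        nc <- sample(2:4, 1)
        p0 <- runif(3, 0.15 * box, 0.85 * box)
        u <- rnorm(3)
        u <- u / sqrt(sum(u^2))
        beads <- t(sapply(0:nc, function(k) p0 + 108 * k * u))
        addFilament(st, beads, rep(40L, nc))
      }
      counts <- matrix(0L, prod(st$dims), 3)
      counts[, 1] <- 200L
      counts[, 2] <- 20L
      counts[, 3] <- 5L
      setSpeciesCounts(st, counts)
      st
    })
  registerBindings(st)
  st
}
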